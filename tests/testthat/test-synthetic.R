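test_that("observer simulation hits its degenerate limits", {
  d <- fixture_design()
  sched <- build_trial_schedule(d, seed = 2)
  # visual capture: near-noiseless vision, useless audition, forced fusion
  cap <- observer_spec(bci_params(1, 1e3, 1e3, 1e-6, 1e-6), "FUSION", 1)
  tr <- simulate_behavior(cap, sched, seed = 1)
  av_v <- tr$modality == "AV" & tr$task == "V"
  expect_equal(tr$resp_button[av_v], bin_nearest(tr$v_loc[av_v]))
  # an audiovisual-segregating observer shows no visual influence on
  # auditory report: regression weights beta_V ~ 0 in all cells
  seg <- observer_spec(bci_params(0, 36.4, 4.4, 0.3, 3.5), "SEG_VA", 2)
  tr2 <- simulate_behavior(seg, sched, seed = 3)
  av <- tr2[tr2$modality == "AV", ]
  w <- fit_wav_regression(av$resp_loc, av)
  aud <- wav_cells()$task == "A"
  expect_true(all(abs(w$beta_V[aud]) < 0.06))
  expect_true(all(w$beta_A[aud] > 0.5))
})

test_that("a causal-inference observer shows the task-by-disparity signature", {
  # the separation between auditory- and visual-report weight angles should
  # widen at large disparity (integration breaks down)
  tr <- fixture_trials()
  av <- tr[tr$modality == "AV", ]
  w <- fit_wav_regression(av$resp_loc, av)
  cells <- wav_cells()
  sep <- function(dg) {
    a <- circ_mean(w$w_av[cells$task == "A" & cells$disparity_group == dg])
    v <- circ_mean(w$w_av[cells$task == "V" & cells$disparity_group == dg])
    abs((v - a + 180) %% 360 - 180)
  }
  expect_gt(sep("D+"), sep("D-"))
})

test_that("simulated response frequencies converge to the predicted pmfs", {
  # the two implementations are independent: per-trial simulation with its
  # own draws vs Monte Carlo marginalisation inside the fitting path
  d <- fixture_design()
  sched <- build_trial_schedule(d, seed = 4)
  p <- group_mean_params()
  obs <- observer_spec(p, "BCI_AVG", 1)
  reps <- do.call(rbind, lapply(1:6, function(k) {
    simulate_behavior(obs, sched, seed = 40 + k)
  }))
  av <- reps[reps$modality == "AV", ]
  for (id in sample(unique(av$condition_id), 6)) {
    sub <- av[av$condition_id == id, ]   # 576 trials
    emp <- tabulate(sub$resp_button, 4) / nrow(sub)
    pmf <- predict_response_pmf(p, "BCI_AVG", d[d$condition_id == id, ],
                                n_sim = 40000, seed = 9)$probs
    # binomial error: 4 SE at n = 576 plus pmf error at n_sim = 40000
    tol <- 4 * sqrt(pmax(pmf * (1 - pmf), 0.002) / nrow(sub))
    expect_true(all(abs(emp - pmf) < tol + 0.02))
  }
})

test_that("cohort generation jitters on the optimisation scales", {
  base <- group_mean_params()
  same <- simulate_observer_cohort(base, 4, list(), seed = 1)
  expect_length(same, 4)
  expect_true(all(vapply(same, function(o) {
    isTRUE(all.equal(unclass(o$params), unclass(base)))
  }, logical(1))))
  coh <- simulate_observer_cohort(base, 13, list(p_common = 0.4,
                                                 sigma_A = 0.2), seed = 2)
  expect_length(coh, 13)
  pcs <- vapply(coh, function(o) o$params$p_common, numeric(1))
  sas <- vapply(coh, function(o) o$params$sigma_A, numeric(1))
  expect_gt(stats::sd(pcs), 0)
  expect_gt(stats::sd(sas), 0)
  expect_true(all(pcs > 0 & pcs < 1))
  expect_true(all(sas > 0))
  # sigma_P untouched when its jitter is zero
  expect_equal(unique(vapply(coh, function(o) o$params$sigma_P, numeric(1))),
               base$sigma_P)
  expect_error(simulate_observer_cohort(base, 3, list(sigma_A = -1)),
               "nonnegative")
})

test_that("synthetic EEG encodes the configured stages and nothing else", {
  d <- fixture_design()
  sched <- build_trial_schedule(d, seed = 5)
  obs <- observer_spec(group_mean_params(), "BCI_AVG", 1)
  tr <- simulate_behavior(obs, sched, seed = 6)
  av <- tr[tr$modality == "AV", ]
  keep <- unlist(lapply(split(seq_len(nrow(av)), av$condition_id), head, 8))
  av <- av[sort(keep), ]
  cfg <- eeg_sim_config(n_channels = 16, times = seq(-100, 700, by = 20),
                        noise_sd = 0.05)
  eeg <- simulate_eeg(av, cfg, seed = 1)
  expect_s3_class(eeg, "erp_dataset")
  expect_equal(dim(eeg$activity), c(nrow(av), 16L, 41L))
  # pre-stimulus samples are pure noise: tiny variance across trials
  pre <- eeg$activity[, , eeg$times < 0]
  expect_lt(stats::sd(pre), 0.08)
  # visual window activity correlates with S_V through the visual template
  tmpl <- avbci:::stage_templates(16, 3, 1)
  t_vis <- which(eeg$times == 80)
  proj <- eeg$activity[, , t_vis] %*% tmpl[, 1]
  expect_gt(cor(proj, av$v_loc), 0.99)
  # causal-inference window tracks the model-averaging estimate
  t_ci <- which(eeg$times == 500)
  proj_ci <- eeg$activity[, , t_ci] %*% tmpl[, 3]
  expect_gt(cor(proj_ci, av$est_ci), 0.99)
  # reproducibility and seed separation
  eeg2 <- simulate_eeg(av, cfg, seed = 1)
  expect_identical(eeg$activity, eeg2$activity)
  eeg3 <- simulate_eeg(av, cfg, seed = 2)
  expect_false(identical(eeg$activity, eeg3$activity))
  # missing latents are refused
  av_bad <- av
  av_bad$est_ci <- NA_real_
  expect_error(simulate_eeg(av_bad, cfg, seed = 1), "latent")
})

test_that("zero encoding gain yields chance decoding at every time point", {
  d <- fixture_design()
  sched <- build_trial_schedule(d, seed = 7)
  obs <- observer_spec(group_mean_params(), "BCI_AVG", 1)
  tr <- simulate_behavior(obs, sched, seed = 8)
  av <- tr[tr$modality == "AV" & tr$a_loc == tr$v_loc, ]
  keep <- unlist(lapply(split(seq_len(nrow(av)), av$condition_id), head, 24))
  av <- av[sort(keep), ]
  cfg <- eeg_sim_config(n_channels = 12, times = seq(-100, 700, by = 50),
                        encoding_gain = 0, noise_sd = 1)
  eeg <- simulate_eeg(av, cfg, seed = 2)
  ps <- make_pseudo_trials(eeg, 8, seed = 1)
  acc <- crossval_decode_timecourse(ps, decoder_config(n_folds = 3),
                                    seed = 1)
  expect_lt(mean(abs(acc)), 0.35)
  expect_lt(max(acc), 0.85)
})

test_that("unisensory EEG shares a code across modalities only in its window", {
  # Under near-deterministic encodings the correlation accuracy of a
  # cross-modal decoder is +-1 with a subject-specific random sign wherever
  # the codes are modality-specific; only the shared window generalises with
  # a consistent positive sign. The check therefore averages over subjects
  # (their own templates), exactly as the group statistics do.
  d <- fixture_design()
  sched <- build_trial_schedule(d, seed = 9)
  obs <- observer_spec(group_mean_params(), "BCI_AVG", 1)
  tr <- simulate_behavior(obs, sched, seed = 10)
  uni <- tr[tr$modality %in% c("A", "V"), ]
  keep <- unlist(lapply(split(seq_len(nrow(uni)), uni$condition_id),
                        head, 16))
  uni <- uni[sort(keep), ]
  cfg <- eeg_sim_config(n_channels = 12, times = seq(-100, 700, by = 25),
                        noise_sd = 0.3, shared_window = c(160, 360),
                        early_window = c(60, 160))
  cross_acc <- function(config, subject_seed) {
    eeg <- simulate_unisensory_eeg(uni, config, seed = subject_seed)
    is_a <- eeg$trial_meta$modality == "A"
    a_ps <- make_pseudo_trials(
      erp_dataset(eeg$activity[is_a, , ], eeg$times,
                  eeg$trial_meta[is_a, ]), 8, seed = 1)
    v_ps <- make_pseudo_trials(
      erp_dataset(eeg$activity[!is_a, , ], eeg$times,
                  eeg$trial_meta[!is_a, ]), 8, seed = 2)
    temporal_generalization(a_ps, v_ps, decoder_config(n_folds = 4),
                            seed = 1)$accuracy
  }
  accs <- lapply(1:5, function(s) cross_acc(cfg, s))
  gmean <- Reduce(`+`, accs) / length(accs)
  times <- cfg$times
  shared <- times >= 185 & times <= 335   # inside the ramps
  early <- times >= 85 & times <= 135
  expect_gt(mean(gmean[shared, shared]), 0.8)
  # modality-specific early code: random-signed, cancels across subjects
  expect_lt(mean(abs(gmean[early, early])), 0.5)
  expect_lt(mean(gmean[early, early]), mean(gmean[shared, shared]) - 0.4)
  # disabling the shared window removes cross-modal generalisation there
  cfg0 <- cfg
  cfg0$shared_window <- NULL
  accs0 <- lapply(1:5, function(s) cross_acc(cfg0, s))
  gmean0 <- Reduce(`+`, accs0) / length(accs0)
  expect_lt(mean(abs(gmean0[shared, shared])), 0.35)
})
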