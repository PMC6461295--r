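# A tiny linear-encoding world: activity = template * location + noise,
# built directly so decoding behaviour is checkable against construction.

make_linear_erp <- function(n_per_cond = 24, n_channels = 12, locs = av_locations(),
                            noise_sd = 0.05, times = seq(0, 100, by = 20),
                            seed = 1, modality = "V") {
  set.seed(seed)
  template <- rnorm(n_channels)
  template <- template / sqrt(sum(template^2))
  meta <- data.frame(condition_id = rep(seq_along(locs), each = n_per_cond))
  meta$v_loc <- if (modality == "A") NA_real_ else locs[meta$condition_id]
  meta$a_loc <- if (modality == "A") locs[meta$condition_id] else NA_real_
  meta$reliability <- if (modality == "A") NA_character_ else "VR+"
  meta$task <- if (modality == "A") "A" else "V"
  meta$modality <- modality
  n <- nrow(meta)
  act <- array(rnorm(n * n_channels * length(times), sd = noise_sd),
               c(n, n_channels, length(times)))
  loc <- if (modality == "A") meta$a_loc else meta$v_loc
  for (t in seq_along(times)) {
    act[, , t] <- act[, , t] + outer(loc, template)
  }
  erp_dataset(act, times, meta)
}

test_that("pseudo-trial averaging partitions conditions and drops remainders", {
  erp <- make_linear_erp(n_per_cond = 96, n_channels = 4,
                         times = c(0, 10), noise_sd = 1)
  ps <- make_pseudo_trials(erp, group_size = 8, seed = 1)
  expect_equal(nrow(ps$trial_meta), 4 * 12)   # 96/8 = 12 per condition
  expect_equal(as.integer(table(ps$trial_meta$condition_id)), rep(12L, 4))
  # 8 trials -> a single pseudo-trial equal to their mean
  small <- erp_dataset(erp$activity[1:8, , , drop = FALSE], erp$times,
                       erp$trial_meta[1:8, ])
  one <- make_pseudo_trials(small, group_size = 8, seed = 2)
  expect_equal(dim(one$activity)[1], 1L)
  expect_equal(one$activity[1, , ],
               colMeans(erp$activity[1:8, , , drop = FALSE], dims = 1))
  # remainder rule: 95 trials -> 11 pseudo-trials
  m95 <- erp_dataset(erp$activity[1:95, , , drop = FALSE], erp$times,
                     erp$trial_meta[1:95, ])
  expect_equal(dim(make_pseudo_trials(m95, 8, 1)$activity)[1], 11L)
  # too few trials errors
  m5 <- erp_dataset(erp$activity[1:5, , , drop = FALSE], erp$times,
                    erp$trial_meta[1:5, ])
  expect_error(make_pseudo_trials(m5, 8, 1), "fewer than")
  # reproducible given the seed; counts stable across seeds
  ps2 <- make_pseudo_trials(erp, group_size = 8, seed = 1)
  expect_identical(ps$activity, ps2$activity)
  ps3 <- make_pseudo_trials(erp, group_size = 8, seed = 99)
  expect_equal(dim(ps3$activity), dim(ps$activity))
  expect_false(identical(ps$activity, ps3$activity))
})

test_that("decoding is near-perfect for clean encodings and at chance for noise", {
  cfg <- decoder_config(n_folds = 6)
  erp <- make_linear_erp(n_per_cond = 12, noise_sd = 0.02, seed = 2)
  acc <- crossval_decode_timecourse(erp, cfg, seed = 1)
  expect_true(all(acc > 0.95))
  # pure noise: accuracy stays small
  noise <- erp
  set.seed(3)
  noise$activity[] <- rnorm(length(noise$activity))
  acc0 <- crossval_decode_timecourse(noise, cfg, seed = 1)
  expect_true(all(abs(acc0) < 0.5))
  expect_lt(mean(abs(acc0)), 0.25)
  # label shuffling destroys decodability
  shuf <- erp
  set.seed(4)
  perm <- sample.int(nrow(shuf$trial_meta))
  shuf$trial_meta$v_loc <- shuf$trial_meta$v_loc[perm]
  shuf$trial_meta$condition_id <- shuf$trial_meta$condition_id[perm]
  acc_s <- crossval_decode_timecourse(shuf, cfg, seed = 1)
  expect_lt(mean(acc_s), 0.3)
})

test_that("temporal generalisation reflects the stability of the encoding", {
  cfg <- decoder_config(n_folds = 6)
  # one constant template at all times: uniformly high off-diagonal accuracy
  erp <- make_linear_erp(n_per_cond = 12, noise_sd = 0.05, seed = 5)
  g <- temporal_generalization(erp, erp, cfg, seed = 1)
  expect_true(all(g$accuracy > 0.9))
  expect_equal(dim(g$accuracy), c(6L, 6L))
  # two disjoint stage templates -> block structure; under low-noise
  # encodings the off-block correlations are +-1 with a random sign per
  # template draw, so the check averages over template seeds (signs cancel)
  locs <- av_locations()
  meta <- data.frame(condition_id = rep(1:4, each = 12),
                     v_loc = rep(locs, each = 12), a_loc = NA_real_,
                     reliability = "VR+", task = "V", modality = "V")
  g2 <- Reduce(`+`, lapply(1:5, function(sd_i) {
    set.seed(sd_i)
    t1 <- rnorm(12); t1 <- t1 / sqrt(sum(t1^2))
    t2 <- rnorm(12); t2 <- t2 - t1 * sum(t1 * t2); t2 <- t2 / sqrt(sum(t2^2))
    act <- array(rnorm(48 * 12 * 4, sd = 2), c(48, 12, 4))
    for (t in 1:2) act[, , t] <- act[, , t] + outer(meta$v_loc, t1)
    for (t in 3:4) act[, , t] <- act[, , t] + outer(meta$v_loc, t2)
    erp2 <- erp_dataset(act, c(0, 20, 40, 60), meta)
    temporal_generalization(erp2, erp2, cfg, seed = 1)$accuracy
  })) / 5
  expect_true(all(g2[1:2, 1:2] > 0.85))
  expect_true(all(g2[3:4, 3:4] > 0.85))
  expect_true(all(abs(g2[1:2, 3:4]) < 0.4))
  expect_true(all(abs(g2[3:4, 1:2]) < 0.4))
  # the no-CV path on identical data is refused (leakage guard)
  expect_error(temporal_generalization(erp, erp, cfg, cross_validate = FALSE),
               "own training trials")
  # channel mismatch
  erp3 <- make_linear_erp(n_channels = 5)
  expect_error(temporal_generalization(erp, erp3, cfg), "channel")
})

test_that("within-modality generalisation diagonal equals the decoding time course", {
  cfg <- decoder_config(n_folds = 6)
  erp <- make_linear_erp(n_per_cond = 12, noise_sd = 0.3, seed = 8)
  acc <- crossval_decode_timecourse(erp, cfg, seed = 4)
  g <- temporal_generalization(erp, erp, cfg, seed = 4)
  expect_equal(unname(diag(g$accuracy)), unname(acc), tolerance = 1e-9)
})

test_that("congruent-trained decoding tracks the encoded audiovisual content", {
  # audiovisual world whose activity encodes only the visual location
  locs <- av_locations()
  grid <- expand.grid(a_loc = locs, v_loc = locs,
                      reliability = c("VR+", "VR-"), task = c("A", "V"),
                      stringsAsFactors = FALSE)
  meta <- grid[rep(seq_len(nrow(grid)), each = 6), ]
  meta$condition_id <- rep(seq_len(nrow(grid)), each = 6)
  meta$modality <- "AV"
  rownames(meta) <- NULL
  set.seed(9)
  tmpl <- rnorm(10); tmpl <- tmpl / sqrt(sum(tmpl^2))
  n <- nrow(meta)
  act <- array(rnorm(n * 10 * 3, sd = 0.05), c(n, 10, 3))
  for (t in 1:3) act[, , t] <- act[, , t] + outer(meta$v_loc, tmpl)
  erp <- erp_dataset(act, c(0, 20, 40), meta)
  dec <- decode_av_estimates(erp, decoder_config(n_folds = 6), seed = 1)
  # every pseudo-trial (congruent and incongruent) decodes to ~ S_V
  expect_true(all(abs(dec$estimates - meta$v_loc) < 2.5))
  # and the implied neural weight profile is purely visual
  w <- fit_wav_regression(dec$estimates[, 2], dec$trial_meta)
  expect_equal(w$w_av, rep(90, 8), tolerance = 3)
  # fusion-encoding world: decoded estimates track the fused location
  p <- group_mean_params()
  fus <- fusion_estimate(meta$a_loc, meta$v_loc, p$sigma_V1, p)
  act2 <- array(rnorm(n * 10 * 3, sd = 0.05), c(n, 10, 3))
  for (t in 1:3) act2[, , t] <- act2[, , t] + outer(fus, tmpl)
  erp2 <- erp_dataset(act2, c(0, 20, 40), meta)
  dec2 <- decode_av_estimates(erp2, decoder_config(n_folds = 6), seed = 1)
  expect_gt(cor(dec2$estimates[, 2], fus), 0.98)
  # congruent trials must exist
  inc <- meta$a_loc != meta$v_loc
  expect_error(decode_av_estimates(
    erp_dataset(act[inc, , , drop = FALSE], c(0, 20, 40), meta[inc, ]),
    decoder_config(n_folds = 6), seed = 1), "congruent")
})

test_that("conjunction mask is an elementwise intersection", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  expect_equal(conjunction_mask(a, b),
               matrix(c(TRUE, FALSE, FALSE, FALSE), 2))
  expect_equal(conjunction_mask(a, a), a)
  expect_error(conjunction_mask(a, matrix(TRUE, 3, 2)), "shape")
})
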