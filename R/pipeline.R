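# End-to-end orchestration: simulate a cohort, fit and compare observer
# models, run the weight-index statistics, and chain the neural stage
# (synthetic EEG -> decoding -> neural weights -> time-resolved model
# comparison -> behavioural-neural correlation), all from one seeded
# configuration.

#' Pipeline run configuration
#'
#' One list that seeds and sizes every stage. All sub-seeds are derived
#' deterministically from `seed`, so re-running a configuration reproduces
#' every numeric output bit for bit.
#'
#' @param seed Master seed.
#' @param n_subjects Cohort size (default 13, the study cohort).
#' @param base_params Group-mean generative parameters (defaults to the
#'   group-mean estimates of the behavioural fits: `p_common` 0.15,
#'   `sigma_P` 36.4, `sigma_A` 4.4, `sigma_V1` 0.3, `sigma_V2` 3.5 degrees).
#' @param between_subject_sd Parameter jitter on the transformed scales
#'   (see [simulate_observer_cohort()]).
#' @param strategy Generating decision rule.
#' @param behav_models Model set fitted to behavioural responses (default
#'   BCI, forced fusion, audiovisual segregation).
#' @param neural_models Model set fitted to decoded estimates (default adds
#'   the purely auditory and purely visual read-out models).
#' @param fit Behavioural [fit_options()].
#' @param neural_fit [fit_options()] for the per-time-point neural fits.
#' @param decoder A [decoder_config()].
#' @param eeg An [eeg_sim_config()].
#' @param eeg_trials_per_condition Trials per AV condition entering the
#'   synthetic EEG (subsampled from the schedule to bound memory).
#' @param fit_window Analysis window (ms) for the neural weight index and
#'   model fits (default 55-700 ms).
#' @param fit_time_step Fit the neural models every this-many time samples
#'   within the window.
#' @param n_perm Permutations for all randomisation tests.
#' @param n_mc Dirichlet samples for exceedance probabilities.
#' @param smooth_ms Moving-average width for neural weight time courses.
#' @param output_dir Directory for CSV/JSON outputs, or `NULL` to skip
#'   writing.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, n_subjects = 13L,
                       base_params = bci_params(0.15, 36.4, 4.4, 0.3, 3.5),
                       between_subject_sd = list(p_common = 0.3,
                                                 sigma_P = 0.15,
                                                 sigma_A = 0.1,
                                                 sigma_V1 = 0.2,
                                                 sigma_V2 = 0.1),
                       strategy = "BCI_AVG",
                       behav_models = c("BCI_AVG", "FUSION", "SEG_VA"),
                       neural_models = c("SEG_A", "SEG_V", "SEG_VA",
                                         "FUSION", "BCI_AVG"),
                       fit = fit_options(n_sim = 2000L),
                       neural_fit = fit_options(
                         n_sim = 1000L,
                         grid = list(sigma_P = c(2, 8, 32),
                                     sigma_A = c(1, 4, 16),
                                     sigma_V1 = c(1, 4, 16),
                                     sigma_V2 = c(1, 4, 16))),
                       decoder = decoder_config(),
                       eeg = eeg_sim_config(),
                       eeg_trials_per_condition = 24L,
                       fit_window = c(55, 700), fit_time_step = 8L,
                       n_perm = 5000L, n_mc = 1e6, smooth_ms = 20,
                       output_dir = NULL) {
  cfg <- structure(list(seed = as.integer(seed),
                        n_subjects = as.integer(n_subjects),
                        base_params = base_params,
                        between_subject_sd = between_subject_sd,
                        strategy = strategy, behav_models = behav_models,
                        neural_models = neural_models, fit = fit,
                        neural_fit = neural_fit, decoder = decoder,
                        eeg = eeg,
                        eeg_trials_per_condition =
                          as.integer(eeg_trials_per_condition),
                        fit_window = fit_window,
                        fit_time_step = as.integer(fit_time_step),
                        n_perm = as.integer(n_perm), n_mc = n_mc,
                        smooth_ms = smooth_ms, output_dir = output_dir),
                   class = "run_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

# cheap deterministic fingerprint of a configuration
config_hash <- function(cfg) {
  cfg$hash <- NULL
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", derive_seed(0L, txt))
}

#' Read a run configuration from a YAML file
#'
#' Thin convenience wrapper: scalar fields of the YAML override the
#' [run_config()] defaults.
#'
#' @param path YAML file.
#' @return A \code{run_config} list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_("reading YAML configurations requires the yaml package")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop_("unknown configuration fields: %s",
                             paste(unknown, collapse = ", "))
  if (!is.null(vals$base_params)) {
    vals$base_params <- do.call(bci_params, vals$base_params)
  }
  do.call(run_config, vals)
}

# simulate cohort + per-subject trial tables from a config
simulate_cohort_trials <- function(config) {
  design <- build_factorial_design()
  schedule <- build_trial_schedule(design, config$seed)
  cohort <- simulate_observer_cohort(config$base_params, config$n_subjects,
                                     config$between_subject_sd,
                                     config$strategy,
                                     seed = derive_seed(config$seed,
                                                        "cohort"))
  trials <- lapply(cohort, function(obs) {
    simulate_behavior(obs, schedule, seed = derive_seed(config$seed,
                                                        "behav"))
  })
  list(design = design, schedule = schedule, cohort = cohort,
       trials = trials)
}

write_json_out <- function(x, dir, file) {
  jsonlite::write_json(x, file.path(dir, file), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
}

#' Run the behavioural analysis pipeline
#'
#' Simulates the cohort on the full factorial schedule, fits the behavioural
#' model set per subject, performs random-effects Bayesian model selection
#' on the `-BIC` evidences, computes the behavioural weight-index table with
#' circular means and confidence intervals, and runs the factorial
#' permutation tests.
#'
#' @param config A [run_config()].
#' @return A report list: `config_hash`, `fits` (per subject), `evidence`
#'   (subjects x models), `bms`, `wav` (long data.frame), `wav_matrix`
#'   (subjects x 8), `cell_summary` (circular mean and 68% CI per cell),
#'   `effect_tests` (per effect \code{stat_result}), `trials`, `cohort`.
#' @export
run_behavioural_pipeline <- function(config = run_config()) {
  sim <- simulate_cohort_trials(config)
  fits <- lapply(seq_along(sim$trials), function(s) {
    opts <- config$fit
    opts$seed <- derive_seed(config$seed, paste0("fit", s))
    stats::setNames(lapply(config$behav_models, function(v) {
      fit_model(sim$trials[[s]], v, opts)
    }), config$behav_models)
  })
  evidence <- t(vapply(fits, function(f) {
    vapply(f, `[[`, numeric(1), "evidence")
  }, numeric(length(config$behav_models))))
  colnames(evidence) <- config$behav_models
  bms <- rfx_bms(evidence, n_mc = config$n_mc,
                 seed = derive_seed(config$seed, "bms"))
  wav_list <- lapply(seq_along(sim$trials), function(s) {
    tr <- sim$trials[[s]]
    av <- tr[tr$modality == "AV", , drop = FALSE]
    w <- fit_wav_regression(av$resp_loc, av)
    w$subject <- s
    w
  })
  wav <- do.call(rbind, wav_list)
  wav_matrix <- as_wav_matrix(wav)
  cells <- wav_cells()
  cell_summary <- cbind(cells, t(apply(wav_matrix, 2L, circ_mean_ci)))
  effects <- c("VR", "TR", "D", "VRxTR", "VRxD", "TRxD", "VRxTRxD")
  effect_tests <- stats::setNames(lapply(effects, function(e) {
    perm_test_effect(wav_matrix, e, n_perm = config$n_perm,
                     seed = derive_seed(config$seed, "effects"))
  }), effects)
  report <- list(config_hash = config$hash, fits = fits,
                 evidence = evidence, bms = bms, wav = wav,
                 wav_matrix = wav_matrix, cell_summary = cell_summary,
                 effect_tests = effect_tests, trials = sim$trials,
                 cohort = sim$cohort)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cbind(config_hash = config$hash, wav),
                     file.path(config$output_dir, "wav_behavioural.csv"),
                     row.names = FALSE)
    write_json_out(list(config_hash = config$hash,
                        evidence = evidence,
                        bms = bms[c("alpha", "expected_freq", "ep", "bor",
                                    "pep")],
                        fits = lapply(fits, function(f) {
                          lapply(f, function(m) {
                            list(variant = m$variant,
                                 params = unclass(m$params),
                                 log_likelihood = m$log_likelihood,
                                 r2_scaled = m$r2_scaled, bic = m$bic,
                                 converged = m$converged)
                          })
                        })),
                   config$output_dir, "behavioural_fits.json")
    write_json_out(list(config_hash = config$hash,
                        effects = lapply(effect_tests, function(e) {
                          list(statistic = e$statistic, p = e$p_value,
                               n_permutations = e$n_permutations,
                               seed = config$seed)
                        })),
                   config$output_dir, "behavioural_stats.json")
  }
  report
}

# 20-ms moving average of per-cell regression weights over time; the weight
# angle is recomputed from the smoothed weights (averaging the angle itself
# would misbehave at the wrap-around).
smooth_betas <- function(x, times, width_ms) {
  if (width_ms <= 0 || length(times) < 2L) return(x)
  dt <- stats::median(diff(times))
  half <- max(0L, floor(width_ms / dt / 2))
  if (half == 0L) return(x)
  nt <- length(times)
  out <- x
  for (t in seq_len(nt)) {
    win <- max(1L, t - half):min(nt, t + half)
    out[t] <- mean(x[win])
  }
  out
}

#' Run the neural analysis pipeline
#'
#' Simulates stage-wise EEG for every subject from the behavioural latents,
#' decodes spatial estimates from a model trained on the congruent
#' conditions, computes neural weight-index time courses with cluster
#' statistics for the seven factorial effects, fits the five-model set to
#' the binned decoded estimates across time for a protected-exceedance-
#' probability time course, and correlates the neural with the behavioural
#' weight profiles.
#'
#' @param config A [run_config()].
#' @param behav Optional report from [run_behavioural_pipeline()] under the
#'   same config; when omitted, the cohort and trial tables are resimulated
#'   (identical seeds) and only the behavioural weight matrix is computed.
#' @param stages Character subset of
#'   `c("decode", "wav", "model_comparison", "correlation")`.
#' @return A report list: `config_hash`, `times`, `window_index`,
#'   `decoded` (per subject), `wav_time` (subjects x 8 x time),
#'   `effect_clusters`, `pep` (fit-times x models), `fit_times`,
#'   `behav_neural` and the behavioural weight matrix used.
#' @export
run_neural_pipeline <- function(config = run_config(), behav = NULL,
                                stages = c("decode", "wav",
                                           "model_comparison",
                                           "correlation")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(behav)) {
    sim <- simulate_cohort_trials(config)
    trials <- sim$trials
    wav_b <- t(vapply(trials, function(tr) {
      av <- tr[tr$modality == "AV", , drop = FALSE]
      fit_wav_regression(av$resp_loc, av)$w_av
    }, numeric(8L)))
  } else {
    trials <- behav$trials
    wav_b <- behav$wav_matrix
  }
  # decode spatial estimates per subject
  decoded <- vector("list", length(trials))
  for (s in seq_along(trials)) {
    tr <- trials[[s]]
    av <- tr[tr$modality == "AV", , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(av)), av$condition_id),
                          utils::head, config$eeg_trials_per_condition))
    av <- av[sort(keep), , drop = FALSE]
    eeg <- simulate_eeg(av, config$eeg,
                        seed = derive_seed(config$seed, paste0("eeg", s)))
    pseudo <- make_pseudo_trials(eeg, config$decoder$group_size,
                                 seed = derive_seed(config$seed,
                                                    paste0("pseudo", s)))
    decoded[[s]] <- decode_av_estimates(pseudo, config$decoder,
                                        seed = derive_seed(config$seed,
                                                           paste0("dec", s)))
  }
  times <- decoded[[1L]]$times
  win <- which(times >= config$fit_window[1L] &
                 times <= config$fit_window[2L])
  report <- list(config_hash = config$hash, times = times,
                 window_index = win, decoded = decoded, wav_b = wav_b)
  if ("wav" %in% stages) {
    nt <- length(times)
    n_sub <- length(decoded)
    beta_a <- array(NA_real_, c(n_sub, 8L, nt))
    beta_v <- array(NA_real_, c(n_sub, 8L, nt))
    for (s in seq_len(n_sub)) {
      meta <- decoded[[s]]$trial_meta
      for (t in seq_len(nt)) {
        w <- fit_wav_regression(decoded[[s]]$estimates[, t], meta)
        beta_a[s, , t] <- w$beta_A
        beta_v[s, , t] <- w$beta_V
      }
      for (j in seq_len(8L)) {
        beta_a[s, j, ] <- smooth_betas(beta_a[s, j, ], times,
                                       config$smooth_ms)
        beta_v[s, j, ] <- smooth_betas(beta_v[s, j, ], times,
                                       config$smooth_ms)
      }
    }
    wav_time <- wav_index(beta_v, beta_a)
    report$wav_time <- wav_time
    effects <- c("VR", "TR", "D", "VRxTR", "VRxD", "TRxD", "VRxTRxD")
    report$effect_clusters <- stats::setNames(lapply(effects, function(e) {
      wav_cluster_test(wav_time[, , win, drop = FALSE], e,
                       n_perm = config$n_perm,
                       seed = derive_seed(config$seed, "clusters"))
    }), effects)
  }
  if ("model_comparison" %in% stages) {
    fit_idx <- win[seq(1L, length(win), by = config$fit_time_step)]
    n_models <- length(config$neural_models)
    lme <- array(NA_real_, c(length(fit_idx), length(decoded), n_models))
    for (s in seq_along(decoded)) {
      meta <- decoded[[s]]$trial_meta
      opts <- config$neural_fit
      opts$seed <- derive_seed(config$seed, paste0("nfit", s))
      for (ti in seq_along(fit_idx)) {
        pseudo_trials <- meta
        pseudo_trials$resp_button <-
          bin_estimates(decoded[[s]]$estimates[, fit_idx[ti]])
        for (m in seq_len(n_models)) {
          lme[ti, s, m] <- fit_model(pseudo_trials,
                                     config$neural_models[m],
                                     opts)$evidence
        }
      }
    }
    bms_tc <- compare_timecourse(lme, n_mc = config$n_mc,
                                 seed = derive_seed(config$seed, "nbms"))
    pep <- attr(bms_tc, "pep")
    colnames(pep) <- config$neural_models
    report$pep <- pep
    report$fit_times <- times[fit_idx]
    report$bms_timecourse <- bms_tc
  }
  if ("correlation" %in% stages && !is.null(report$wav_time)) {
    report$behav_neural <- behav_neural_corr_test(
      wav_b, report$wav_time[, , win, drop = FALSE],
      n_perm = config$n_perm,
      seed = derive_seed(config$seed, "bncorr"))
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(report$pep)) {
      utils::write.csv(
        data.frame(config_hash = config$hash,
                   time = rep(report$fit_times,
                              ncol(report$pep)),
                   model = rep(colnames(report$pep),
                               each = nrow(report$pep)),
                   pep = as.vector(report$pep)),
        file.path(config$output_dir, "pep_timecourse.csv"),
        row.names = FALSE)
    }
    if (!is.null(report$effect_clusters)) {
      write_json_out(list(config_hash = config$hash,
                          effects = lapply(report$effect_clusters,
                                           function(e) {
                            list(clusters = e$clusters, p = e$p_value,
                                 n_permutations = e$n_permutations,
                                 seed = config$seed)
                          })),
                     config$output_dir, "neural_stats.json")
    }
  }
  report
}
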