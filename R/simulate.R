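# Synthetic-data generators: behavioural responses from simulated observers
# and stage-wise synthetic neural activity (early visual -> fused ->
# causal-inference encodings) so every downstream analysis stage runs
# end-to-end without external recordings.

#' Specification of one simulated observer
#'
#' @param params A [bci_params()] object.
#' @param strategy The observer's decision rule, one of [model_variants()].
#' @param subject_id Integer subject identifier.
#' @return A list of class \code{observer_spec}.
#' @export
observer_spec <- function(params, strategy = "BCI_AVG", subject_id = 1L) {
  stopifnot(inherits(params, "bci_params"))
  strategy <- match.arg(strategy, model_variants())
  structure(list(params = params, strategy = strategy,
                 subject_id = as.integer(subject_id)),
            class = "observer_spec")
}

#' Simulate an observer's localisation responses
#'
#' For each audiovisual trial, draws internal samples
#' `x_A ~ N(S_A, sigma_A^2)` and `x_V ~ N(S_V, sigma_V^2(reliability))`,
#' computes the observer's final estimate for the trial's task under its
#' decision strategy and bins it to the nearest response button. Unisensory
#' trials use the corresponding segregated estimate. The latent fusion and
#' model-averaging (causal-inference) estimates are stored per trial for the
#' neural simulator.
#'
#' @param observer An [observer_spec()].
#' @param schedule A [build_trial_schedule()] object.
#' @param seed Integer seed.
#' @return The schedule's trial table with added columns `subject`, `x_a`,
#'   `x_v`, `est_fusion`, `est_ci` (task-relevant model-averaging estimate),
#'   `estimate` (the observer's own continuous estimate), `resp_button`
#'   (1..4) and `resp_loc` (button degrees).
#' @export
simulate_behavior <- function(observer, schedule, seed = 1L) {
  stopifnot(inherits(observer, "observer_spec"),
            inherits(schedule, "trial_schedule"))
  trials <- schedule$trials
  params <- observer$params
  n <- nrow(trials)
  with_seed(derive_seed(seed, paste0("behav", observer$subject_id)), {
    z_a <- stats::rnorm(n)
    z_v <- stats::rnorm(n)
    u <- stats::runif(n)
  })
  sv <- ifelse(is.na(trials$reliability), params$sigma_V2,
               sigma_for_reliability(params, trials$reliability))
  x_a <- trials$a_loc + params$sigma_A * z_a
  x_v <- trials$v_loc + sv * z_v
  est <- numeric(n)
  est_fus <- rep(NA_real_, n)
  est_ci <- rep(NA_real_, n)
  av <- trials$modality == "AV"
  if (any(av)) {
    est[av] <- final_estimate(x_a[av], x_v[av], sv[av], params,
                              observer$strategy, trials$task[av], u[av])
    est_fus[av] <- fusion_estimate(x_a[av], x_v[av], sv[av], params)
    est_ci[av] <- final_estimate(x_a[av], x_v[av], sv[av], params,
                                 "BCI_AVG", trials$task[av])
  }
  ao <- trials$modality == "A"
  vo <- trials$modality == "V"
  est[ao] <- segregated_estimate(x_a[ao], params$sigma_A, params)
  est[vo] <- segregated_estimate(x_v[vo], sv[vo], params)
  trials$subject <- observer$subject_id
  trials$x_a <- x_a
  trials$x_v <- x_v
  trials$est_fusion <- est_fus
  trials$est_ci <- est_ci
  trials$estimate <- est
  trials$resp_button <- bin_estimates(est)
  trials$resp_loc <- av_locations()[trials$resp_button]
  trials
}

#' Simulate a cohort of observers
#'
#' Per-subject parameters are jittered around the base parameters on the
#' optimisation scales: additive Gaussian noise on logit `p_common` and on
#' the log of each SD.
#'
#' @param base_params A [bci_params()] object (the group means).
#' @param n_subjects Cohort size (the study cohort is 13).
#' @param between_subject_sd Named list of jitter SDs on the transformed
#'   scales; recognised names `p_common`, `sigma_P`, `sigma_A`, `sigma_V1`,
#'   `sigma_V2`. Missing names default to 0 (identical observers).
#' @param strategy Decision rule shared by the cohort.
#' @param seed Integer seed.
#' @return List of [observer_spec()] objects.
#' @export
simulate_observer_cohort <- function(base_params, n_subjects = 13L,
                                     between_subject_sd = list(),
                                     strategy = "BCI_AVG", seed = 1L) {
  sds <- list(p_common = 0, sigma_P = 0, sigma_A = 0, sigma_V1 = 0,
              sigma_V2 = 0)
  for (nm in names(between_subject_sd)) {
    if (!nm %in% names(sds)) stop_("unknown parameter `%s`", nm)
    if (between_subject_sd[[nm]] < 0) stop_("jitter SDs must be nonnegative")
    sds[[nm]] <- between_subject_sd[[nm]]
  }
  lapply(seq_len(n_subjects), function(s) {
    p <- with_seed(derive_seed(seed, paste0("cohort", s)), {
      list(
        p_common = inv_logit(logit(min(max(base_params$p_common, 1e-6),
                                       1 - 1e-6)) +
                               stats::rnorm(1, 0, sds$p_common)),
        sigma_P = exp(log(base_params$sigma_P) +
                        stats::rnorm(1, 0, sds$sigma_P)),
        sigma_A = exp(log(base_params$sigma_A) +
                        stats::rnorm(1, 0, sds$sigma_A)),
        sigma_V1 = exp(log(base_params$sigma_V1) +
                         stats::rnorm(1, 0, sds$sigma_V1)),
        sigma_V2 = exp(log(base_params$sigma_V2) +
                         stats::rnorm(1, 0, sds$sigma_V2)))
    })
    observer_spec(bci_params(p$p_common, p$sigma_P, p$sigma_A, p$sigma_V1,
                             p$sigma_V2), strategy = strategy,
                  subject_id = s)
  })
}

#' Synthetic EEG configuration
#'
#' Stage timings follow the qualitative staging the decoding analysis is
#' designed to resolve: an early visual-dominant encoding, a fused
#' (reliability-weighted) encoding, and a late causal-inference encoding;
#' unisensory simulations add a window in which both modalities share one
#' template, so cross-modal generalisation succeeds only there.
#'
#' @param n_channels Number of channels (default 64).
#' @param times Time grid in ms (default -100 to 700 in 5-ms steps).
#' @param stage_windows Named list of `(onset, offset)` ms pairs for stages
#'   `visual`, `fusion`, `ci`.
#' @param encoding_gain Scalar gain applied to every encoded location.
#' @param noise_sd Additive Gaussian noise SD per channel and sample.
#' @param shared_window `(onset, offset)` ms of the cross-modal shared
#'   template for unisensory simulation, or `NULL` to disable.
#' @param early_window `(onset, offset)` ms of the modality-specific
#'   unisensory encoding.
#' @param ramp_ms Raised-cosine on/off ramp duration of every stage gate.
#' @return A list of class \code{eeg_sim_config}.
#' @export
eeg_sim_config <- function(n_channels = 64L, times = seq(-100, 700, by = 5),
                           stage_windows = list(visual = c(60, 100),
                                                fusion = c(100, 250),
                                                ci = c(350, 700)),
                           encoding_gain = 1, noise_sd = 1,
                           shared_window = c(160, 360),
                           early_window = c(60, 160), ramp_ms = 10) {
  if (noise_sd <= 0) stop_("noise_sd must be positive")
  for (w in stage_windows) {
    if (w[1L] < min(times) || w[2L] > max(times)) {
      stop_("stage windows must lie within the time grid")
    }
  }
  structure(list(n_channels = as.integer(n_channels), times = times,
                 stage_windows = stage_windows,
                 encoding_gain = encoding_gain, noise_sd = noise_sd,
                 shared_window = shared_window, early_window = early_window,
                 ramp_ms = ramp_ms),
            class = "eeg_sim_config")
}

# Raised-cosine gate: 0 outside (onset, offset), 1 inside, cosine ramps of
# ramp_ms at both edges (avoids degenerate single-sample clusters).
stage_gate <- function(times, window, ramp_ms) {
  g <- numeric(length(times))
  on <- window[1L]
  off <- window[2L]
  g[times >= on + ramp_ms & times <= off - ramp_ms] <- 1
  rising <- times >= on & times < on + ramp_ms
  g[rising] <- 0.5 * (1 - cos(pi * (times[rising] - on) / ramp_ms))
  falling <- times > off - ramp_ms & times <= off
  g[falling] <- 0.5 * (1 - cos(pi * (off - times[falling]) / ramp_ms))
  g
}

# Orthonormal random channel templates, one column per stage.
stage_templates <- function(n_channels, n_stages, seed) {
  with_seed(derive_seed(seed, "templates"), {
    m <- matrix(stats::rnorm(n_channels * n_stages), n_channels, n_stages)
    qr.Q(qr(m))
  })
}

# Core assembly: activity = sum_stage gate(t) template(ch) gain enc(trial)
# + white noise.
assemble_eeg <- function(encodings, gates, templates, config, seed) {
  n <- nrow(encodings)
  nt <- length(config$times)
  nc <- config$n_channels
  act <- with_seed(derive_seed(seed, "eeg-noise"), {
    array(stats::rnorm(n * nc * nt, sd = config$noise_sd), c(n, nc, nt))
  })
  for (s in seq_len(ncol(encodings))) {
    src <- config$encoding_gain * encodings[, s, drop = FALSE] %*%
      t(templates[, s, drop = FALSE])      # trials x channels
    for (t in which(gates[, s] > 0)) {
      act[, , t] <- act[, , t] + gates[t, s] * src
    }
  }
  act
}

#' Simulate stage-wise audiovisual EEG activity
#'
#' Builds trials x channels x time activity in which the visual stage
#' encodes the true visual location, the fusion stage encodes the
#' reliability-weighted fused estimate, and the causal-inference stage
#' encodes the task-relevant model-averaging estimate, each through its own
#' (orthonormal, seeded) channel template gated by a raised-cosine window;
#' pre-stimulus samples are pure noise.
#'
#' @param trials A [simulate_behavior()] trial table restricted (or
#'   restrictable) to audiovisual trials; must carry the latent columns
#'   `est_fusion` and `est_ci`.
#' @param config An [eeg_sim_config()].
#' @param seed Integer seed.
#' @return An [erp_dataset()].
#' @export
simulate_eeg <- function(trials, config = eeg_sim_config(), seed = 1L) {
  av <- trials[trials$modality == "AV", , drop = FALSE]
  if (!nrow(av)) stop_("no audiovisual trials")
  if (anyNA(av$est_fusion) || anyNA(av$est_ci)) {
    stop_("missing latent estimates; simulate behaviour first")
  }
  enc <- cbind(visual = av$v_loc, fusion = av$est_fusion, ci = av$est_ci)
  gates <- vapply(c("visual", "fusion", "ci"), function(s) {
    stage_gate(config$times, config$stage_windows[[s]], config$ramp_ms)
  }, numeric(length(config$times)))
  templates <- stage_templates(config$n_channels, 3L, seed)
  act <- assemble_eeg(enc, gates, templates, config, seed)
  erp_dataset(act, config$times, av)
}

#' Simulate unisensory EEG with a cross-modal shared code
#'
#' Early activity encodes the stimulated location through modality-specific
#' templates; within the shared window both modalities encode it through
#' one common template, so cross-modal generalisation can succeed only
#' there.
#'
#' @param trials Trial table of unisensory trials (modality `"A"` or
#'   `"V"`).
#' @param config An [eeg_sim_config()]; `shared_window = NULL` disables the
#'   shared code.
#' @param seed Integer seed.
#' @return An [erp_dataset()].
#' @export
simulate_unisensory_eeg <- function(trials, config = eeg_sim_config(),
                                    seed = 1L) {
  uni <- trials[trials$modality %in% c("A", "V"), , drop = FALSE]
  if (!nrow(uni)) stop_("no unisensory trials")
  loc <- ifelse(uni$modality == "A", uni$a_loc, uni$v_loc)
  is_a <- as.numeric(uni$modality == "A")
  enc <- cbind(early_a = loc * is_a, early_v = loc * (1 - is_a),
               shared = loc)
  gates <- cbind(
    early_a = stage_gate(config$times, config$early_window, config$ramp_ms),
    early_v = stage_gate(config$times, config$early_window, config$ramp_ms),
    shared = if (is.null(config$shared_window)) {
      numeric(length(config$times))
    } else {
      stage_gate(config$times, config$shared_window, config$ramp_ms)
    })
  templates <- stage_templates(config$n_channels, 3L, seed)
  act <- assemble_eeg(enc, gates, templates, config, seed)
  erp_dataset(act, config$times, uni)
}
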