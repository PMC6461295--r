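# Hierarchical Bayesian causal inference observer model for audiovisual
# spatial localisation: generative model, causal posterior, fusion and
# segregation estimates, decision rules, and Monte Carlo predicted response
# distributions over the four response buttons.

#' Observer model variants
#'
#' The seven model variants: Bayesian causal inference with model averaging
#' (\code{"BCI_AVG"}), model selection (\code{"BCI_SEL"}) or probability
#' matching (\code{"BCI_MATCH"}); forced fusion (\code{"FUSION"}, the BCI
#' model with the common-cause prior fixed at 1); audiovisual full
#' segregation (\code{"SEG_VA"}, common-cause prior fixed at 0, reads out the
#' task-relevant segregated estimate); and the purely unisensory read-out
#' models \code{"SEG_A"} and \code{"SEG_V"}.
#' @export
model_variants <- function() {
  c("BCI_AVG", "BCI_SEL", "BCI_MATCH", "FUSION", "SEG_VA", "SEG_A", "SEG_V")
}

#' Observer generative parameters
#'
#' @param p_common Prior probability of a common cause, in `[0, 1]`.
#' @param sigma_P Standard deviation (degrees) of the central spatial prior.
#' @param sigma_A Auditory sensory noise SD (degrees).
#' @param sigma_V1 Visual sensory noise SD at high reliability (degrees).
#' @param sigma_V2 Visual sensory noise SD at low reliability (degrees).
#' @param mu_P Mean of the spatial prior; fixed at 0 (central bias) and not a
#'   free parameter.
#' @return An object of class \code{bci_params}.
#' @export
bci_params <- function(p_common, sigma_P, sigma_A, sigma_V1, sigma_V2,
                       mu_P = 0) {
  vals <- c(p_common = p_common, sigma_P = sigma_P, sigma_A = sigma_A,
            sigma_V1 = sigma_V1, sigma_V2 = sigma_V2, mu_P = mu_P)
  if (any(!is.finite(vals))) stop_("all parameters must be finite")
  if (p_common < 0 || p_common > 1) stop_("p_common must lie in [0, 1]")
  if (any(vals[c("sigma_P", "sigma_A", "sigma_V1", "sigma_V2")] <= 0)) {
    stop_("all standard deviations must be strictly positive")
  }
  structure(as.list(vals), class = "bci_params")
}

#' @export
print.bci_params <- function(x, ...) {
  cat(sprintf(
    "BCI observer parameters: p_common=%.3g, sigma_P=%.3g, sigma_A=%.3g, sigma_V1=%.3g, sigma_V2=%.3g (mu_P=%g)\n",
    x$p_common, x$sigma_P, x$sigma_A, x$sigma_V1, x$sigma_V2, x$mu_P))
  invisible(x)
}

# visual noise SD for a reliability label ("VR+" high / "VR-" low)
sigma_for_reliability <- function(params, reliability) {
  ifelse(reliability == "VR+", params$sigma_V1, params$sigma_V2)
}

#' Posterior probability of a common cause
#'
#' Combines the common-cause prior with the sensory evidence by Bayes rule,
#' using the closed-form Gaussian marginal likelihoods of the internal
#' samples under the common-cause structure (one latent source integrated
#' out) and the independent-cause structure (two latent sources integrated
#' out).
#'
#' @param x_A,x_V Internal auditory and visual samples (degrees). Vectorised.
#' @param sigma_V Visual noise SD for the trial's reliability level.
#' @param params A [bci_params()] object.
#' @return `p(C = 1 | x_A, x_V)`.
#' @export
posterior_common_cause <- function(x_A, x_V, sigma_V, params) {
  if (any(!is.finite(x_A)) || any(!is.finite(x_V))) {
    stop_("internal samples must be finite")
  }
  va <- params$sigma_A^2
  vv <- sigma_V^2
  vp <- params$sigma_P^2
  mu <- params$mu_P
  # p(xA, xV | C = 1) = Int N(xA; S, va) N(xV; S, vv) N(S; mu, vp) dS
  d1 <- va * vv + va * vp + vv * vp
  l1 <- exp(-0.5 * ((x_A - x_V)^2 * vp + (x_A - mu)^2 * vv +
                      (x_V - mu)^2 * va) / d1) / (2 * pi * sqrt(d1))
  # p(xA, xV | C = 2) = N(xA; mu, va + vp) N(xV; mu, vv + vp)
  l2 <- stats::dnorm(x_A, mu, sqrt(va + vp)) *
    stats::dnorm(x_V, mu, sqrt(vv + vp))
  num <- l1 * params$p_common
  num / (num + l2 * (1 - params$p_common))
}

#' Forced-fusion spatial estimate
#'
#' Reliability-weighted average of the auditory sample, the visual sample
#' and the spatial prior — the optimal estimate under a common cause.
#'
#' @inheritParams posterior_common_cause
#' @return Fused location estimate (degrees).
#' @export
fusion_estimate <- function(x_A, x_V, sigma_V, params) {
  va <- params$sigma_A^2
  vv <- sigma_V^2
  vp <- params$sigma_P^2
  (x_A / va + x_V / vv + params$mu_P / vp) / (1 / va + 1 / vv + 1 / vp)
}

#' Segregated (unisensory) spatial estimate
#'
#' Combination of one modality's sample with the spatial prior — the optimal
#' estimate under independent causes.
#'
#' @param x Internal sample (degrees).
#' @param sigma Sensory noise SD of that modality.
#' @param params A [bci_params()] object.
#' @return Segregated location estimate (degrees).
#' @export
segregated_estimate <- function(x, sigma, params) {
  v <- sigma^2
  vp <- params$sigma_P^2
  (x / v + params$mu_P / vp) / (1 / v + 1 / vp)
}

#' Final spatial estimate under a model variant
#'
#' Combines the fusion and task-relevant segregation estimates according to
#' the variant's decision rule: posterior-weighted averaging
#' (\code{"BCI_AVG"}), selection of the more probable causal structure
#' (\code{"BCI_SEL"}; a posterior of exactly 0.5 routes to segregation),
#' stochastic selection against a uniform draw \code{u}
#' (\code{"BCI_MATCH"}), mandatory fusion (\code{"FUSION"}), the
#' task-relevant segregated estimate (\code{"SEG_VA"}), or the auditory /
#' visual segregated estimate regardless of task (\code{"SEG_A"} /
#' \code{"SEG_V"}).
#'
#' @inheritParams posterior_common_cause
#' @param variant One of [model_variants()].
#' @param task `"A"` for auditory report, `"V"` for visual report.
#' @param u Uniform draw(s) in `[0, 1]`; required for `"BCI_MATCH"` only.
#' @return Final location estimate(s) in degrees.
#' @export
final_estimate <- function(x_A, x_V, sigma_V, params, variant = "BCI_AVG",
                           task = "A", u = NULL) {
  variant <- match.arg(variant, model_variants())
  stopifnot(all(task %in% c("A", "V")))
  seg_A <- segregated_estimate(x_A, params$sigma_A, params)
  seg_V <- segregated_estimate(x_V, sigma_V, params)
  if (variant == "SEG_A") return(seg_A)
  if (variant == "SEG_V") return(seg_V)
  seg_task <- ifelse(task == "A", seg_A, seg_V)
  if (variant == "SEG_VA") return(seg_task)
  fus <- fusion_estimate(x_A, x_V, sigma_V, params)
  if (variant == "FUSION") return(fus)
  post <- posterior_common_cause(x_A, x_V, sigma_V, params)
  switch(variant,
         BCI_AVG = post * fus + (1 - post) * seg_task,
         BCI_SEL = ifelse(post > 0.5, fus, seg_task),
         BCI_MATCH = {
           if (is.null(u)) stop_("BCI_MATCH requires uniform draws `u`")
           ifelse(post > u, fus, seg_task)
         })
}

# Bin continuous estimates to button indices 1..4 (buttons at -10, -3.3,
# 3.3, 10); midpoint ties go to the leftmost button (left-open intervals).
bin_estimates <- function(est) {
  breaks <- c(-6.65, 0, 6.65)
  findInterval(est, breaks, left.open = TRUE) + 1L
}

# Tabulate button indices per condition into a 4 x n_cond count matrix.
# `cond_index` must align with `bins`.
bin_counts_by_condition <- function(bins, cond_index, n_cond) {
  counts <- tabulate(bins + 4L * (cond_index - 1L), nbins = 4L * n_cond)
  matrix(counts, nrow = 4L, ncol = n_cond)
}

# Draw the fixed standard-normal (and uniform) variates used for Monte Carlo
# marginalisation, one independent substream per condition so that any
# subset of conditions reproduces bit-for-bit.
draw_condition_noise <- function(n_sim, condition_ids, seed) {
  n_cond <- length(condition_ids)
  z_A <- matrix(0, n_sim, n_cond)
  z_V <- matrix(0, n_sim, n_cond)
  u <- matrix(0, n_sim, n_cond)
  for (j in seq_len(n_cond)) {
    with_seed(derive_seed(seed, paste0("cond", condition_ids[j])), {
      z_A[, j] <- stats::rnorm(n_sim)
      z_V[, j] <- stats::rnorm(n_sim)
      u[, j] <- stats::runif(n_sim)
    })
  }
  list(z_A = z_A, z_V = z_V, u = u)
}

# Vectorised predicted pmfs for a set of AV conditions given pre-drawn
# noise. conditions: data.frame with a_loc, v_loc, reliability, task.
# noise: list(z_A, z_V, u) with n_sim rows and one column per condition.
# With `pcs = NULL` returns one 4 x n_cond probability matrix at
# params$p_common; with a vector `pcs` returns a list of such matrices, one
# per common-cause prior, sharing all p_common-independent computation
# (internal samples, estimates, likelihood ratio).
predict_pmf_core <- function(params, variant, conditions, noise,
                             pcs = NULL) {
  single <- is.null(pcs)
  if (single) pcs <- params$p_common
  n_cond <- nrow(conditions)
  n_sim <- nrow(noise$z_A)
  cond_index <- rep(seq_len(n_cond), each = n_sim)
  bycol <- function(v) v[cond_index]         # recycle per-condition values
  va <- params$sigma_A^2
  vp <- params$sigma_P^2
  mu <- params$mu_P
  sv <- sigma_for_reliability(params, conditions$reliability)
  vv <- sv^2
  x_A <- noise$z_A * params$sigma_A + bycol(conditions$a_loc)
  x_V <- noise$z_V * bycol(sv) + bycol(conditions$v_loc)
  wA <- 1 / va
  wP <- 1 / vp
  wV <- 1 / vv
  task_a <- conditions$task == "A"
  pmf_of <- function(est) {
    bin_counts_by_condition(bin_estimates(est), cond_index, n_cond) / n_sim
  }
  seg_A <- if (variant %in% c("SEG_A", "SEG_VA", "BCI_AVG", "BCI_SEL",
                              "BCI_MATCH")) {
    (x_A * wA + mu * wP) / (wA + wP)
  }
  seg_V <- if (variant %in% c("SEG_V", "SEG_VA", "BCI_AVG", "BCI_SEL",
                              "BCI_MATCH")) {
    (x_V * bycol(wV) + mu * wP) * bycol(1 / (wV + wP))
  }
  if (variant == "SEG_A") return(rep_pmf(pmf_of(seg_A), single))
  if (variant == "SEG_V") return(rep_pmf(pmf_of(seg_V), single))
  if (variant %in% c("SEG_VA", "BCI_AVG", "BCI_SEL", "BCI_MATCH")) {
    seg_task <- seg_V
    seg_task[, task_a] <- seg_A[, task_a]
  }
  if (variant == "SEG_VA") return(rep_pmf(pmf_of(seg_task), single))
  xVwV <- x_V * bycol(wV)
  fus <- (x_A * wA + xVwV + mu * wP) * bycol(1 / (wA + wV + wP))
  if (variant == "FUSION") return(rep_pmf(pmf_of(fus), single))
  # likelihood ratio p(x|C=2)/p(x|C=1), shared across p_common values;
  # assembled as exp(log_l2 - log_l1) with the squared deviations reused
  d1 <- va * vv + va * vp + vv * vp
  dxa2 <- (x_A - mu)^2
  dxv2 <- (x_V - mu)^2
  q1 <- ((x_A - x_V)^2 * vp + dxa2 * bycol(vv) + dxv2 * va) * bycol(1 / (2 * d1))
  delta <- q1 -                                  # -log_l1 (quadratic part)
    dxa2 / (2 * (va + vp)) -                     # log_l2, auditory part
    dxv2 * bycol(1 / (2 * (vv + vp)))            # log_l2, visual part
  const <- log(2 * pi * sqrt(d1)) - 0.5 * log(2 * pi * (va + vp)) -
    0.5 * log(2 * pi * (vv + vp))
  lr <- exp(delta + bycol(const))
  out <- lapply(pcs, function(pc) {
    post <- if (pc >= 1) 1 else if (pc <= 0) 0 else 1 / (1 + (1 - pc) / pc * lr)
    est <- switch(variant,
                  BCI_AVG = post * fus + (1 - post) * seg_task,
                  BCI_SEL = {
                    e <- seg_task
                    sel <- post > 0.5
                    e[sel] <- fus[sel]
                    e
                  },
                  BCI_MATCH = {
                    e <- seg_task
                    sel <- post > noise$u
                    e[sel] <- fus[sel]
                    e
                  })
    pmf_of(est)
  })
  if (single) out[[1L]] else out
}

rep_pmf <- function(pmf, single, k = 1L) {
  if (single) pmf else rep(list(pmf), k)
}

#' Predicted response distribution for one condition
#'
#' Marginalises over the observer's internal samples by Monte Carlo: draws
#' `n_sim` pairs `x_A ~ N(S_A, sigma_A^2)`, `x_V ~ N(S_V, sigma_V^2)`,
#' computes the variant's final estimate on each draw, bins each estimate to
#' the nearest response button and returns normalised counts. Unisensory
#' conditions sample only the relevant modality and use the segregated
#' estimate.
#'
#' @param params A [bci_params()] object.
#' @param variant One of [model_variants()].
#' @param condition One row of a [build_factorial_design()] table (or any
#'   list with `condition_id`, `modality`, `a_loc`, `v_loc`, `reliability`,
#'   `task`).
#' @param n_sim Number of Monte Carlo draws (default 10,000).
#' @param seed Integer seed; the draw stream is derived from
#'   `(seed, condition_id)` so pmfs are reproducible per condition.
#' @return A list of class \code{response_pmf} with `condition_id` and
#'   `probs` (length 4, sums to 1) over buttons at -10, -3.3, 3.3, 10
#'   degrees.
#' @export
predict_response_pmf <- function(params, variant, condition, n_sim = 10000L,
                                 seed = 1L) {
  stopifnot(n_sim >= 1)
  variant <- match.arg(variant, model_variants())
  cond <- as.list(condition)
  if (cond$modality == "AV") {
    noise <- draw_condition_noise(n_sim, cond$condition_id, seed)
    probs <- predict_pmf_core(params, variant,
                              as.data.frame(cond[c("a_loc", "v_loc",
                                                   "reliability", "task")]),
                              noise)[, 1L]
  } else {
    with_seed(derive_seed(seed, paste0("cond", cond$condition_id)), {
      z <- stats::rnorm(n_sim)
    })
    est <- if (cond$modality == "A") {
      segregated_estimate(cond$a_loc + params$sigma_A * z, params$sigma_A,
                          params)
    } else {
      sv <- sigma_for_reliability(params, cond$reliability)
      segregated_estimate(cond$v_loc + sv * z, sv, params)
    }
    probs <- tabulate(bin_estimates(est), nbins = 4L) / n_sim
  }
  structure(list(condition_id = cond$condition_id, probs = probs),
            class = "response_pmf")
}
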