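# Maximum-likelihood fitting of observer models to discrete localisation
# responses: button binning, multinomial log likelihood via Monte Carlo
# marginalisation with common random numbers, grid search plus Nelder-Mead
# simplex refinement, scaled coefficient of determination and BIC.

#' Fitting options
#'
#' @param n_sim Monte Carlo draws per condition for the predicted response
#'   distributions (at least 1,000 for fitting; default 10,000).
#' @param grid Named list of candidate values per parameter for the initial
#'   grid search (`p_common`, `sigma_P`, `sigma_A`, `sigma_V1`, `sigma_V2`).
#'   Defaults to `p_common` in 0.1..0.9 (step 0.2) and 0.5, 1, 2, 4, 8, 16,
#'   32 degrees for every SD.
#' @param grid_n_sim Monte Carlo draws per condition during the grid-search
#'   stage only (default: same as `n_sim`); the simplex stage always runs at
#'   `n_sim`. A coarser grid stage only picks the simplex start point.
#' @param polish_n_sim Optional larger simulation size for a final simplex
#'   restart from the incumbent solution; a more precise likelihood surface
#'   settles the optimum along nearly flat parameter ridges.
#' @param simplex_tolerance Relative convergence tolerance of the simplex.
#' @param max_iterations Simplex iteration cap (per restart).
#' @param restarts Number of simplex restarts from the incumbent solution;
#'   Nelder-Mead in five dimensions can terminate on a collapsed simplex, and
#'   restarting rebuilds it.
#' @param use_simplex Set `FALSE` to stop at the best grid point.
#' @param seed Seed for the per-condition Monte Carlo draw streams; the
#'   draws are held fixed across optimisation steps (common random numbers)
#'   so the likelihood surface is deterministic for the optimiser.
#' @param pmf_floor Probability floor applied to predicted response
#'   probabilities inside the log likelihood, in `(0, 0.01]`.
#' @return A list of class \code{fit_options}.
#' @export
fit_options <- function(n_sim = 10000L, grid = NULL, grid_n_sim = NULL,
                        polish_n_sim = NULL, simplex_tolerance = 1e-7,
                        max_iterations = 1000L, restarts = 2L,
                        use_simplex = TRUE, seed = 1L, pmf_floor = 1e-6) {
  if (n_sim < 1000) stop_("n_sim must be at least 1,000 for fitting")
  if (pmf_floor <= 0 || pmf_floor > 0.01) {
    stop_("pmf_floor must lie in (0, 0.01]")
  }
  sd_grid <- c(0.5, 1, 2, 4, 8, 16, 32)
  default <- list(p_common = seq(0.1, 0.9, by = 0.2), sigma_P = sd_grid,
                  sigma_A = sd_grid, sigma_V1 = sd_grid, sigma_V2 = sd_grid)
  for (nm in names(grid %||% list())) default[[nm]] <- grid[[nm]]
  structure(list(n_sim = as.integer(n_sim), grid = default,
                 grid_n_sim = as.integer(grid_n_sim %||% n_sim),
                 polish_n_sim = if (!is.null(polish_n_sim))
                   as.integer(polish_n_sim),
                 simplex_tolerance = simplex_tolerance,
                 max_iterations = as.integer(max_iterations),
                 restarts = as.integer(restarts),
                 use_simplex = isTRUE(use_simplex), seed = as.integer(seed),
                 pmf_floor = pmf_floor),
            class = "fit_options")
}

#' Bin a continuous estimate to the nearest response button
#'
#' Buttons sit at -10, -3.3, 3.3 and 10 degrees; exact midpoint ties go to
#' the leftmost candidate.
#'
#' @param estimate Location estimate(s) in degrees, finite.
#' @return Integer button index in 1..4.
#' @export
bin_nearest <- function(estimate) {
  if (any(!is.finite(estimate))) stop_("estimates must be finite")
  # rounding absorbs float noise so exact midpoints resolve as ties
  d <- round(abs(outer(estimate, av_locations(), `-`)), 9L)
  max.col(-d, ties.method = "first")
}

#' Per-condition multinomial log likelihood
#'
#' `sum_j counts_j * ln(max(p_j, floor))`; the count-only multinomial
#' coefficient is omitted as it is constant across models.
#'
#' @param counts Four nonnegative response counts over the buttons.
#' @param pmf A [predict_response_pmf()] object or a numeric probability
#'   vector of length 4 aligned with the buttons.
#' @param floor Probability floor.
#' @return Log likelihood in nats.
#' @export
condition_log_likelihood <- function(counts, pmf, floor = 1e-6) {
  p <- if (inherits(pmf, "response_pmf")) pmf$probs else pmf
  stopifnot(length(counts) == 4L, length(p) == 4L)
  if (any(counts < 0)) stop_("counts must be nonnegative")
  sum(counts * log(pmax(p, floor)))
}

# Response counts (4 x n_cond) and the matching AV condition frame (ordered
# by condition_id) extracted from a trial table carrying `resp_button`.
av_counts_from_trials <- function(trials) {
  av <- trials[trials$modality == "AV", , drop = FALSE]
  if (!nrow(av)) stop_("no audiovisual trials present")
  if (is.null(av$resp_button)) stop_("trials must carry `resp_button`")
  ids <- sort(unique(av$condition_id))
  design_av <- unique(av[c("condition_id", "a_loc", "v_loc", "reliability",
                           "task")])
  design_av <- design_av[order(design_av$condition_id), , drop = FALSE]
  expected <- 64L
  if (length(ids) < expected) {
    stop_("missing AV conditions in trial table: expected 64, found %d",
          length(ids))
  }
  counts <- bin_counts_by_condition(as.integer(av$resp_button),
                                    match(av$condition_id, ids),
                                    length(ids))
  list(counts = counts, conditions = design_av, ids = ids)
}

#' Total log likelihood of a model over the audiovisual conditions
#'
#' Sums the per-condition multinomial log likelihoods over the 64 AV
#' conditions, using Monte Carlo predicted response distributions with a
#' fixed per-condition draw stream derived from `options$seed`.
#'
#' @param trials Trial table (from [simulate_behavior()] or equivalent) with
#'   a `resp_button` column.
#' @param variant One of [model_variants()].
#' @param params A [bci_params()] object.
#' @param options A [fit_options()] object.
#' @return Log likelihood in nats.
#' @export
total_log_likelihood <- function(trials, variant, params,
                                 options = fit_options()) {
  dat <- av_counts_from_trials(trials)
  noise <- draw_condition_noise(options$n_sim, dat$ids, options$seed)
  pmf <- predict_pmf_core(params, variant, dat$conditions, noise)
  sum(dat$counts * log(pmax(pmf, options$pmf_floor)))
}

# Free parameters per variant and the fixed values of the rest.
variant_free_params <- function(variant) {
  switch(variant,
         BCI_AVG = , BCI_SEL = , BCI_MATCH =
           c("p_common", "sigma_P", "sigma_A", "sigma_V1", "sigma_V2"),
         FUSION = , SEG_VA = c("sigma_P", "sigma_A", "sigma_V1", "sigma_V2"),
         SEG_A = c("sigma_P", "sigma_A"),
         SEG_V = c("sigma_P", "sigma_V1", "sigma_V2"),
         stop_("unknown variant `%s`", variant))
}

variant_fixed_p_common <- function(variant) {
  switch(variant, FUSION = 1, SEG_VA = 0, SEG_A = 0, SEG_V = 0, NA_real_)
}

#' Number of free parameters of a model variant
#' @param variant One of [model_variants()].
#' @return Integer count (BCI variants 5, fusion and audiovisual segregation
#'   4, auditory-only segregation 2, visual-only segregation 3).
#' @export
k_params <- function(variant) {
  length(variant_free_params(match.arg(variant, model_variants())))
}

# Assemble a bci_params object from a named vector of free values.
params_from_free <- function(free, variant) {
  full <- list(p_common = variant_fixed_p_common(variant), sigma_P = 1,
               sigma_A = 1, sigma_V1 = 1, sigma_V2 = 1)
  if (is.na(full$p_common)) full$p_common <- 0.5
  for (nm in names(free)) full[[nm]] <- unname(free[nm])
  bci_params(full$p_common, full$sigma_P, full$sigma_A, full$sigma_V1,
             full$sigma_V2)
}

# Transform free parameters to the unconstrained optimisation scale
# (logit for p_common, log for SDs) and back.
to_opt_scale <- function(free) {
  out <- free
  for (nm in names(free)) {
    out[nm] <- if (nm == "p_common") {
      logit(min(max(free[nm], 1e-6), 1 - 1e-6))
    } else {
      log(free[nm])
    }
  }
  out
}

from_opt_scale <- function(theta) {
  out <- theta
  for (nm in names(theta)) {
    out[nm] <- if (nm == "p_common") inv_logit(theta[nm]) else exp(theta[nm])
  }
  out
}

# Grid-search log likelihoods. For BCI variants the internal samples,
# estimates and the likelihood-ratio term are shared across p_common values
# within one SD combination (see predict_pmf_core).
grid_search_ll <- function(variant, grid, counts, conditions, noise, floor) {
  free <- variant_free_params(variant)
  sd_names <- setdiff(free, "p_common")
  sd_grid <- expand.grid(grid[sd_names], KEEP.OUT.ATTRS = FALSE)
  has_pc <- "p_common" %in% free
  pcs <- if (has_pc) grid$p_common else variant_fixed_p_common(variant)
  best <- list(ll = -Inf, free = NULL)
  for (i in seq_len(nrow(sd_grid))) {
    sds <- unlist(sd_grid[i, , drop = FALSE])
    params <- params_from_free(sds, variant)
    pmfs <- predict_pmf_core(params, variant, conditions, noise, pcs = pcs)
    for (j in seq_along(pmfs)) {
      ll <- sum(counts * log(pmax(pmfs[[j]], floor)))
      if (ll > best$ll) {
        best <- list(ll = ll,
                     free = if (has_pc) {
                       c(p_common = unname(pcs[j]), sds)
                     } else {
                       sds
                     })
      }
    }
  }
  best$free <- best$free[free]
  best
}

#' Fit an observer model to discrete localisation responses
#'
#' Maximum-likelihood fit by grid search over `options$grid` followed by
#' Nelder-Mead simplex refinement from the best grid point. Noise SDs are
#' optimised on a log scale and the common-cause prior on a logit scale; the
#' Monte Carlo draw streams are held fixed across optimisation steps so the
#' likelihood surface is deterministic.
#'
#' @inheritParams total_log_likelihood
#' @return A list of class \code{model_fit}: `variant`, `params`
#'   ([bci_params()]), `log_likelihood` (nats), `n_trials`, `k_params`,
#'   `r2_scaled`, `bic` (as printed, natural log), `evidence` (`-bic`, the
#'   model-evidence proxy consumed by [rfx_bms()]) and `converged`.
#' @export
fit_model <- function(trials, variant, options = fit_options()) {
  variant <- match.arg(variant, model_variants())
  dat <- av_counts_from_trials(trials)
  noise <- draw_condition_noise(options$n_sim, dat$ids, options$seed)
  grid_noise <- if (options$grid_n_sim == options$n_sim) noise else
    draw_condition_noise(options$grid_n_sim, dat$ids, options$seed)
  floor <- options$pmf_floor
  best <- grid_search_ll(variant, options$grid, dat$counts, dat$conditions,
                         grid_noise, floor)
  if (options$grid_n_sim != options$n_sim) {
    # re-evaluate the winning grid point at the full simulation size
    pmf <- predict_pmf_core(params_from_free(best$free, variant), variant,
                            dat$conditions, noise)
    best$ll <- sum(dat$counts * log(pmax(pmf, floor)))
  }
  converged <- TRUE
  if (options$use_simplex) {
    objective <- function(theta) {
      free <- from_opt_scale(stats::setNames(theta, names(best$free)))
      params <- params_from_free(free, variant)
      pmf <- predict_pmf_core(params, variant, dat$conditions, noise)
      -sum(dat$counts * log(pmax(pmf, floor)))
    }
    theta <- unname(to_opt_scale(best$free))
    value <- Inf
    for (r in seq_len(max(1L, options$restarts + 1L))) {
      opt <- stats::optim(theta, objective, method = "Nelder-Mead",
                          control = list(maxit = options$max_iterations,
                                         reltol = options$simplex_tolerance))
      converged <- opt$convergence == 0L
      improved <- opt$value < value - 1e-6
      theta <- opt$par
      value <- opt$value
      if (!improved && r > 1L) break
    }
    if (-value >= best$ll) {
      best <- list(ll = -value,
                   free = from_opt_scale(stats::setNames(theta,
                                                         names(best$free))))
    }
  }
  if (options$use_simplex && !is.null(options$polish_n_sim)) {
    polish_noise <- draw_condition_noise(options$polish_n_sim, dat$ids,
                                         options$seed)
    objective_p <- function(theta) {
      free <- from_opt_scale(stats::setNames(theta, names(best$free)))
      params <- params_from_free(free, variant)
      pmf <- predict_pmf_core(params, variant, dat$conditions, polish_noise)
      -sum(dat$counts * log(pmax(pmf, floor)))
    }
    opt <- stats::optim(unname(to_opt_scale(best$free)), objective_p,
                        method = "Nelder-Mead",
                        control = list(maxit = options$max_iterations,
                                       reltol = options$simplex_tolerance))
    converged <- converged && opt$convergence == 0L
    best <- list(ll = -opt$value,
                 free = from_opt_scale(stats::setNames(opt$par,
                                                       names(best$free))))
  }
  n <- sum(dat$counts)
  k <- length(best$free)
  structure(list(variant = variant,
                 params = params_from_free(best$free, variant),
                 log_likelihood = best$ll, n_trials = n, k_params = k,
                 r2_scaled = r2_scaled(best$ll, n),
                 bic = bic(best$ll, k, n),
                 evidence = -bic(best$ll, k, n),
                 converged = converged),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: logL = %.1f nats (n = %d, k = %d), scaled R2 = %.3f, BIC = %.1f%s\n",
              x$variant, x$log_likelihood, x$n_trials, x$k_params,
              x$r2_scaled, x$bic,
              if (x$converged) "" else " [not converged]"))
  print(x$params)
  invisible(x)
}

#' Scaled coefficient of determination
#'
#' Likelihood-based R-squared against a discrete-uniform null (probability
#' 0.25 per button), scaled by its maximum attainable value so a perfect fit
#' maps to 1: `raw = 1 - exp(-(2/n)(l_fit - l0))` with `l0 = n ln(0.25)`,
#' `max = 1 - exp((2/n) l0) = 0.9375`, result `clip(raw/max, 0, 1)`.
#'
#' @param l_fit Fitted-model log likelihood in nats (multinomial coefficient
#'   omitted, matching [condition_log_likelihood()]).
#' @param n Number of data points (trials).
#' @return Scaled R-squared in `[0, 1]`.
#' @export
r2_scaled <- function(l_fit, n) {
  stopifnot(n >= 1)
  l0 <- n * log(0.25)
  raw <- 1 - exp(-(2 / n) * (l_fit - l0))
  max_r2 <- 1 - exp((2 / n) * l0)
  min(max(raw / max_r2, 0), 1)
}

#' Bayesian information criterion (as printed)
#'
#' `-l_fit + k ln(n)`, in nats with natural logarithms. This is the form the
#' analysis is defined with; the conventional `-2 l_fit + k ln(n)` is
#' available via `conventional = TRUE`. The model evidence consumed by
#' [rfx_bms()] is `-bic(...)`.
#'
#' @param l_fit Log likelihood in nats.
#' @param k Number of free parameters.
#' @param n Number of data points.
#' @param conventional Use the conventional `-2 ln L + k ln n` form.
#' @return BIC in nats.
#' @export
bic <- function(l_fit, k, n, conventional = FALSE) {
  stopifnot(n >= 1, k >= 0)
  if (conventional) -2 * l_fit + k * log(n) else -l_fit + k * log(n)
}
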