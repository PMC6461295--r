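# Random-effects Bayesian model selection at the group level: variational
# Dirichlet scheme over model frequencies, exceedance probabilities by
# Dirichlet sampling, Bayes omnibus risk by free-energy comparison against
# the equal-frequency null, and protected exceedance probabilities.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Random-effects Bayesian model selection
#'
#' Treats the model generating each subject's data as a random effect drawn
#' from population frequencies `r ~ Dirichlet(alpha)`. A variational scheme
#' with uniform prior (`alpha0 = 1`) is iterated to convergence; exceedance
#' probabilities are estimated from `n_mc` Dirichlet samples; the Bayes
#' omnibus risk (BOR) compares the free energy of the random-effects model
#' with the null of equal model frequencies; and the protected exceedance
#' probability is `pep = ep * (1 - bor) + bor / K`.
#'
#' @param log_evidence Subjects x models matrix of log model evidences
#'   (typically `-BIC` from [fit_model()]).
#' @param n_mc Dirichlet samples for the exceedance probabilities
#'   (default 1e6).
#' @param seed Seed for the Dirichlet sampling.
#' @return A list of class \code{bms_result}: `alpha` (Dirichlet
#'   pseudo-counts), `expected_freq`, `ep`, `bor`, `pep`.
#' @export
rfx_bms <- function(log_evidence, n_mc = 1e6, seed = 1L) {
  lme <- as.matrix(log_evidence)
  if (ncol(lme) < 2L) stop_("at least two models are required")
  if (nrow(lme) < 1L) stop_("at least one subject is required")
  if (any(!is.finite(lme))) stop_("log evidences must be finite")
  n <- nrow(lme)
  K <- ncol(lme)
  alpha0 <- rep(1, K)
  alpha <- alpha0
  g <- matrix(1 / K, n, K)
  for (iter in seq_len(200L)) {
    elog_r <- digamma(alpha) - digamma(sum(alpha))
    lg <- sweep(lme, 2L, elog_r, `+`)
    lg <- lg - apply(lg, 1L, max)
    g_new <- exp(lg)
    g_new <- g_new / rowSums(g_new)
    alpha_new <- alpha0 + colSums(g_new)
    done <- max(abs(alpha_new - alpha)) < 1e-8
    alpha <- alpha_new
    g <- g_new
    if (done) break
  }
  expected_freq <- alpha / sum(alpha)
  # exceedance probabilities by Monte Carlo over Dirichlet(alpha)
  ep <- with_seed(derive_seed(seed, "bms-ep"), {
    draws <- matrix(stats::rgamma(n_mc * K, shape = rep(alpha, each = n_mc)),
                    nrow = n_mc, ncol = K)
    tabulate(max.col(draws, ties.method = "random"), nbins = K) / n_mc
  })
  # free energy of the RFX model (at convergence) and of the null of equal
  # frequencies; bor = p(null | data)
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  f1 <- sum(g * lme) - sum(g * log(pmax(g, 1e-300))) +
    lgamma(sum(alpha0)) - sum(lgamma(alpha0)) -
    lgamma(sum(alpha)) + sum(lgamma(alpha)) +
    sum((colSums(g) + alpha0 - alpha) * elog_r)
  f0 <- sum(apply(lme - log(K), 1L, log_sum_exp))
  bor <- 1 / (1 + exp(f1 - f0))
  pep <- ep * (1 - bor) + bor / K
  structure(list(alpha = alpha, expected_freq = expected_freq, ep = ep,
                 bor = bor, pep = pep, models = colnames(lme)),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  nm <- x$models %||% paste0("M", seq_along(x$pep))
  cat("Random-effects Bayesian model selection\n")
  cat(sprintf("  BOR = %.4g\n", x$bor))
  for (i in seq_along(x$pep)) {
    cat(sprintf("  %-10s Ef = %.3f  EP = %.4f  PEP = %.4f\n", nm[i],
                x$expected_freq[i], x$ep[i], x$pep[i]))
  }
  invisible(x)
}

#' Model comparison across a time course
#'
#' Runs [rfx_bms()] independently at every time point of a
#' time x subjects x models log-evidence array.
#'
#' @param fits 3-D array (time x subjects x models) of log evidences, or a
#'   list of subjects x models matrices with a consistent model set.
#' @param n_mc,seed Passed to [rfx_bms()] (a distinct sub-seed per time).
#' @return A list of \code{bms_result}, one per time point, with the PEP
#'   time course in the `"pep"` attribute (time x models matrix).
#' @export
compare_timecourse <- function(fits, n_mc = 1e6, seed = 1L) {
  if (is.array(fits) && length(dim(fits)) == 3L) {
    d <- dim(fits)
    arr <- fits
    fits <- lapply(seq_len(d[1L]), function(t) {
      matrix(arr[t, , ], nrow = d[2L], ncol = d[3L])
    })
  }
  dims <- vapply(fits, function(m) dim(as.matrix(m)), integer(2))
  if (length(unique(dims[2L, ])) != 1L || length(unique(dims[1L, ])) != 1L) {
    stop_("ragged input: all time points need the same subjects x models shape")
  }
  res <- lapply(seq_along(fits), function(t) {
    rfx_bms(as.matrix(fits[[t]]), n_mc = n_mc,
            seed = derive_seed(seed, paste0("t", t)))
  })
  pep <- do.call(rbind, lapply(res, `[[`, "pep"))
  attr(res, "pep") <- pep
  res
}
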