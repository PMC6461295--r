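# Shared fixtures: group-mean generative parameters of the behavioural fits
# and small design objects rebuilt once per test run.

group_mean_params <- function() bci_params(0.15, 36.4, 4.4, 0.3, 3.5)

fixture_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_factorial_design()
    cache
  }
})

fixture_av_conditions <- function() {
  d <- fixture_design()
  d[d$modality == "AV", , drop = FALSE]
}

# a small observer dataset on the full schedule, cached across tests
fixture_trials <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sched <- build_trial_schedule(fixture_design(), seed = 3L)
      obs <- observer_spec(group_mean_params(), "BCI_AVG", 1L)
      cache <<- simulate_behavior(obs, sched, seed = 7L)
    }
    cache
  }
})

# deterministic von Mises sampler (degrees) for circular-statistics tests
rvm_deg <- function(n, mu_deg, kappa) {
  # Best & Fisher (1979) rejection sampler
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  (mu_deg + out * 180 / pi) %% 360
}

# pmf for one condition computed with a shared draw stream (independent of
# the condition id), so pmfs of different conditions are exactly comparable
predict_pmf_fixture <- function(params, variant, cond, n_sim = 4000L) {
  noise <- avbci:::draw_condition_noise(n_sim, 0L, 123L)
  avbci:::predict_pmf_core(params, variant,
                           cond[, c("a_loc", "v_loc", "reliability", "task")],
                           noise)[, 1L]
}
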