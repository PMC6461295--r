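# GLM-based audiovisual weight analysis and its factorial permutation
# inference: per-cell regression of reported/decoded locations on the true
# auditory and visual locations, the circular weight index per cell, von
# Mises LRTS for the 2x2x2 (reliability x task x disparity) factorial with
# the matching within-participant permutation schemes, cluster correction
# over time, and the behavioural-neural correlation test.

#' The eight cells of the reliability x task x disparity factorial
#'
#' Canonical ordering used by every weight table in the package.
#' @return Data.frame with columns `reliability`, `task`, `disparity_group`.
#' @export
wav_cells <- function() {
  expand.grid(reliability = c("VR+", "VR-"), task = c("A", "V"),
              disparity_group = c("D-", "D+"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Per-cell audiovisual weight regression
#'
#' One ordinary-least-squares regression of the reported (or decoded)
#' locations on 16 slope regressors — the true visual and auditory locations
#' switched on only within each of the eight factorial cells — plus an
#' intercept. Returns the per-cell visual and auditory weights and the
#' circular weight index.
#'
#' @param estimates Per-trial spatial estimates in degrees (button locations
#'   for behaviour, continuous decoded estimates for EEG), aligned with the
#'   rows of `trial_info`.
#' @param trial_info Audiovisual trial table with `a_loc`, `v_loc`,
#'   `reliability`, `task` (and optionally `disparity_group`, else derived).
#' @return Data.frame of class \code{wav_cells_fit}: the eight [wav_cells()]
#'   rows with `beta_A`, `beta_V`, `w_av` (degrees); the intercept is in
#'   attribute `"intercept"`.
#' @export
fit_wav_regression <- function(estimates, trial_info) {
  stopifnot(length(estimates) == nrow(trial_info))
  info <- trial_info
  if (is.null(info$disparity_group)) {
    info$disparity_group <- disparity_group(disparity(info$a_loc, info$v_loc))
  }
  cells <- wav_cells()
  cell_of <- interaction(info$reliability, info$task, info$disparity_group,
                         drop = FALSE)
  cell_key <- interaction(cells$reliability, cells$task,
                          cells$disparity_group)
  idx <- match(cell_of, cell_key)
  if (anyNA(idx)) stop_("trials outside the 2x2x2 factorial design")
  X <- matrix(0, nrow(info), 16L)
  for (j in seq_len(8L)) {
    in_cell <- idx == j
    if (!any(in_cell)) {
      stop_("empty factorial cell: %s/%s/%s", cells$reliability[j],
            cells$task[j], cells$disparity_group[j])
    }
    X[in_cell, 2L * j - 1L] <- info$v_loc[in_cell]
    X[in_cell, 2L * j] <- info$a_loc[in_cell]
  }
  fit <- stats::lm.fit(cbind(1, X), estimates)
  if (any(is.na(fit$coefficients))) {
    stop_("rank-deficient weight regression (degenerate cell design)")
  }
  beta <- fit$coefficients[-1L]
  out <- cells
  out$beta_V <- beta[seq(1L, 15L, by = 2L)]
  out$beta_A <- beta[seq(2L, 16L, by = 2L)]
  out$w_av <- wav_index(out$beta_V, out$beta_A)
  attr(out, "intercept") <- unname(fit$coefficients[1L])
  class(out) <- c("wav_cells_fit", "data.frame")
  out
}

# Accept a subjects x 8 matrix (canonical cell order) or a long data.frame
# with subject + cell columns + w_av; return the matrix.
as_wav_matrix <- function(wav) {
  if (is.matrix(wav)) {
    if (ncol(wav) != 8L) stop_("weight table must have 8 cells")
    return(wav)
  }
  cells <- wav_cells()
  key <- interaction(cells$reliability, cells$task, cells$disparity_group)
  got <- interaction(wav$reliability, wav$task, wav$disparity_group)
  subjects <- unique(wav$subject)
  m <- matrix(NA_real_, length(subjects), 8L)
  for (i in seq_along(subjects)) {
    rows <- wav$subject == subjects[i]
    m[i, match(got[rows], key)] <- wav$w_av[rows]
  }
  if (anyNA(m)) stop_("incomplete weight table")
  m
}

wav_effects <- function() {
  c("VR", "TR", "D", "VRxTR", "VRxD", "TRxD", "VRxTRxD",
    "VR@A", "VR@V", "VR@D-", "VR@D+", "TR@D-", "TR@D+")
}

factor_column <- function(f) {
  switch(f, VR = "reliability", TR = "task", D = "disparity_group",
         stop_("unknown factor `%s`", f))
}

# Parse an effect name into its type and factors.
parse_effect <- function(effect) {
  if (!effect %in% wav_effects()) {
    stop_("unknown effect `%s` (see wav_effects())", effect)
  }
  if (grepl("@", effect, fixed = TRUE)) {
    parts <- strsplit(effect, "@", fixed = TRUE)[[1L]]
    level <- parts[2L]
    at_factor <- if (level %in% c("A", "V")) "TR" else "D"
    list(type = "simple", f = parts[1L], at_factor = at_factor,
         at_level = level)
  } else {
    fs <- strsplit(effect, "x", fixed = TRUE)[[1L]]
    list(type = c("main", "two_way", "three_way")[length(fs)], fs = fs)
  }
}

# Precompute the column bookkeeping of an effect so that the statistic (and
# its thousands of permutation replicates) reduces to a few trigonometric
# sums. `pairs` holds difference columns for interaction effects; `g1`/`g2`
# index the contrasted groups (into the raw cells, or into the difference
# columns).
effect_plan <- function(effect) {
  cells <- wav_cells()
  eff <- parse_effect(effect)
  if (eff$type == "main" || eff$type == "simple") {
    f <- if (eff$type == "main") eff$fs else eff$f
    active <- if (eff$type == "main") seq_len(8L) else
      which(cells[[factor_column(eff$at_factor)]] == eff$at_level)
    col <- factor_column(f)
    lv <- unique(cells[[col]])
    list(type = "groups",
         g1 = active[cells[[col]][active] == lv[1L]],
         g2 = active[cells[[col]][active] == lv[2L]])
  } else if (eff$type == "two_way") {
    d <- diff_pairs(cells, eff$fs[1L])
    col <- factor_column(eff$fs[2L])
    lv <- unique(cells[[col]])
    list(type = "diff",
         i1 = d$i1, i2 = d$i2,
         g1 = which(d$cells[[col]] == lv[1L]),
         g2 = which(d$cells[[col]] == lv[2L]))
  } else {
    d1 <- diff_pairs(cells, eff$fs[1L])
    d2 <- diff_pairs(d1$cells, eff$fs[2L])
    col <- factor_column(eff$fs[3L])
    lv <- unique(d2$cells[[col]])
    list(type = "diff2",
         i1 = d1$i1[d2$i1], i2 = d1$i2[d2$i1],
         i3 = d1$i1[d2$i2], i4 = d1$i2[d2$i2],
         g1 = which(d2$cells[[col]] == lv[1L]),
         g2 = which(d2$cells[[col]] == lv[2L]))
  }
}

# column pairing for within-subject differences across the levels of `f`
diff_pairs <- function(cells, f) {
  col <- factor_column(f)
  lv <- unique(wav_cells()[[col]])
  others <- setdiff(names(cells), col)
  key <- interaction(cells[others])
  i1 <- which(cells[[col]] == lv[1L])
  i2 <- which(cells[[col]] == lv[2L])
  i2 <- i2[match(key[i1], key[i2])]
  list(i1 = i1, i2 = i2, cells = cells[i1, others, drop = FALSE])
}

# the LRTS from a subjects x 8 matrix of angles (degrees) given a plan
lrts_plan_stat <- function(m, plan) {
  rad <- m * (pi / 180)
  if (plan$type == "groups") {
    a1 <- rad[, plan$g1]
    a2 <- rad[, plan$g2]
  } else if (plan$type == "diff") {
    d <- rad[, plan$i1, drop = FALSE] - rad[, plan$i2, drop = FALSE]
    a1 <- d[, plan$g1]
    a2 <- d[, plan$g2]
  } else {
    dd <- rad[, plan$i1, drop = FALSE] - rad[, plan$i2, drop = FALSE] -
      rad[, plan$i3, drop = FALSE] + rad[, plan$i4, drop = FALSE]
    a1 <- dd[, plan$g1]
    a2 <- dd[, plan$g2]
  }
  s1 <- sum(sin(a1)); c1 <- sum(cos(a1)); n1 <- length(a1)
  s2 <- sum(sin(a2)); c2 <- sum(cos(a2)); n2 <- length(a2)
  r_full <- sqrt(s1^2 + c1^2) + sqrt(s2^2 + c2^2)
  r_null <- sqrt((s1 + s2)^2 + (c1 + c2)^2)
  n <- n1 + n2
  ll <- function(rsum) {
    kappa <- a1inv(rsum / n)
    kappa * rsum - n * (log(2 * pi) + log_bessel_i0(kappa))
  }
  max(2 * (ll(r_full) - ll(r_null)), 0)
}

#' Likelihood-ratio statistic for an effect on the weight index
#'
#' Under a von Mises likelihood with a common ML concentration, compares a
#' full model with separate mean directions for the levels contrasted by the
#' effect against a null that pools them: `2 (logL_full - logL_null)`. Main
#' and simple effects are tested on the raw angles; a two-way interaction
#' `F1xF2` is the main-effect statistic of `F2` applied to the within-subject
#' angular differences across the levels of `F1`; the three-way interaction
#' applies a second difference.
#'
#' @param wav Subjects x 8 matrix of weight angles (degrees) in
#'   [wav_cells()] order, or a long data.frame with `subject`,
#'   `reliability`, `task`, `disparity_group`, `w_av`.
#' @param effect One of [wav_effects()]: `"VR"`, `"TR"`, `"D"`, their
#'   interactions (`"VRxTR"`, ..., `"VRxTRxD"`), or simple effects such as
#'   `"VR@A"` (reliability within auditory report) and `"TR@D+"`.
#' @return Nonnegative LRTS value.
#' @export
lrts_effect <- function(wav, effect) {
  m <- as_wav_matrix(wav)
  if (anyNA(m)) stop_("incomplete weight table")
  lrts_plan_stat(m, effect_plan(effect))
}

# Exchangeability blocks of the 8 cells for an effect's permutation scheme:
# main/simple effects permute the tested factor within the levels of the
# nontested factors; two-way interactions permute the simple main effects
# of the two factors of interest within the levels of the third; the
# three-way permutes freely across all cells.
effect_blocks <- function(effect) {
  cells <- wav_cells()
  eff <- parse_effect(effect)
  switch(eff$type,
    main = split(seq_len(8L), interaction(
      cells[setdiff(c("reliability", "task", "disparity_group"),
                    factor_column(eff$fs))])),
    simple = split(seq_len(8L), interaction(
      cells[setdiff(c("reliability", "task", "disparity_group"),
                    factor_column(eff$f))])),
    two_way = split(seq_len(8L),
                    cells[[factor_column(setdiff(c("VR", "TR", "D"),
                                                 eff$fs))]]),
    three_way = list(seq_len(8L))
  )
}

# One random within-participant permutation of the 8 cell columns given the
# effect's exchangeability blocks; returns a subjects x 8 index matrix.
permute_cells <- function(n_subjects, blocks) {
  idx <- matrix(rep(seq_len(8L), each = n_subjects), n_subjects, 8L)
  for (b in blocks) {
    k <- length(b)
    if (k == 2L) {
      swap <- stats::runif(n_subjects) < 0.5
      idx[swap, b] <- idx[swap, rev(b)]
    } else {
      for (s in seq_len(n_subjects)) idx[s, b] <- b[sample.int(k)]
    }
  }
  idx
}

apply_cell_perm <- function(m, idx) {
  n <- nrow(m)
  matrix(m[cbind(rep(seq_len(n), 8L), as.vector(idx))], n, 8L)
}

#' Permutation test for a factorial effect on the weight index
#'
#' Randomisation test of [lrts_effect()] with permutations performed within
#' each participant: tested-factor labels are shuffled within the levels of
#' the nontested factors (main and simple effects), the four cells of the
#' two factors of interest are shuffled within the levels of the third
#' (two-way interactions), or all eight cells are shuffled freely
#' (three-way). The p-value is `(b + 1) / (B + 1)` and never exactly zero.
#'
#' @inheritParams lrts_effect
#' @param n_perm Number of permutations (default 5,000).
#' @param seed Integer seed.
#' @return A list of class \code{stat_result}: `statistic`, `p_value`,
#'   `n_permutations`, `null` (the permutation distribution).
#' @export
perm_test_effect <- function(wav, effect, n_perm = 5000L, seed = 1L) {
  if (n_perm < 1L) stop_("n_perm must be positive")
  m <- as_wav_matrix(wav)
  plan <- effect_plan(effect)
  blocks <- effect_blocks(effect)
  obs <- lrts_plan_stat(m, plan)
  null <- with_seed(derive_seed(seed, paste0("perm-", effect)), {
    vapply(seq_len(n_perm), function(i) {
      lrts_plan_stat(apply_cell_perm(m, permute_cells(nrow(m), blocks)),
                     plan)
    }, numeric(1))
  })
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 effect = effect, null = null),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("Permutation test%s: statistic = %.3f, p = %.4g (%d permutations)\n",
              if (!is.null(x$effect)) paste0(" [", x$effect, "]") else "",
              if (length(x$statistic) == 1L) x$statistic else max(x$statistic),
              x$p_value, x$n_permutations))
  if (!is.null(x$clusters) && nrow(x$clusters)) {
    cat("clusters:\n")
    print(x$clusters)
  }
  invisible(x)
}

#' One-sample permutation test (sign flips)
#'
#' Two-tailed Monte Carlo permutation test of the one-sample t statistic
#' against zero, by random sign flips of the per-subject values.
#'
#' @param values Per-subject scalars, length at least 2.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @return A \code{stat_result} list with the t statistic and the
#'   permutation p-value (floored at `1/(n_perm + 1)`).
#' @export
perm_test_onesample <- function(values, n_perm = 5000L, seed = 1L) {
  n <- length(values)
  if (n < 2L) stop_("need at least 2 subjects")
  tstat <- function(v) {
    s <- stats::sd(v)
    if (s == 0) {
      if (mean(v) == 0) 0 else sign(mean(v)) * Inf
    } else {
      mean(v) / (s / sqrt(n))
    }
  }
  obs <- tstat(values)
  null <- with_seed(derive_seed(seed, "onesample"), {
    vapply(seq_len(n_perm), function(i) {
      tstat(values * sample(c(-1, 1), n, replace = TRUE))
    }, numeric(1))
  })
  p <- (sum(abs(null) >= abs(obs)) + 1) / (n_perm + 1)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm),
            class = "stat_result")
}
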