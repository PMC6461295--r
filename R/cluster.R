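# Cluster-based permutation inference: maxsum cluster correction over 1-D
# time courses and 2-D training x testing time matrices, and the
# behavioural-neural weight-index correlation test.

# contiguous supra-threshold runs of a logical vector -> list of index runs
runs_1d <- function(supra) {
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) starts[i]:ends[i])
}

# cluster masses for one vector of statistics given supra-threshold mask
cluster_masses_1d <- function(stat, supra) {
  vapply(runs_1d(supra), function(ix) sum(stat[ix]), numeric(1))
}

#' Cluster-based permutation test over a time course
#'
#' Generic maxsum cluster correction: a statistic is computed per time point
#' on the observed data and under `n_perm` permutations (the same
#' permutation applied across all time points). Time points whose statistic
#' exceeds the permutation `1 - alpha` quantile at that time (per tail) are
#' clustered by temporal contiguity; each cluster's mass (summed statistic)
#' is compared against the permutation distribution of the maximum cluster
#' mass.
#'
#' @param stat_fn Function `(data_t, perm)` returning a scalar statistic for
#'   one time point; `perm = NULL` requests the observed statistic.
#' @param data_over_time List with one element per time point (e.g. a
#'   subjects x cells matrix per time).
#' @param n_perm Number of permutations (default 5,000).
#' @param seed Integer seed.
#' @param perm_fn Function `()` drawing one permutation object from the
#'   current RNG; the object is passed unchanged to `stat_fn` for every time
#'   point of that iteration.
#' @param alpha Cluster-defining threshold (default 0.05).
#' @param tail `"greater"` for nonnegative statistics such as the LRTS,
#'   `"two.sided"` for signed statistics (clusters formed per sign, null
#'   from the maximum absolute mass).
#' @return A \code{stat_result} list: `statistic` (observed time course),
#'   `clusters` (data.frame `start`, `end`, `mass`, `p`), `p_value` (the
#'   smallest cluster p, or 1 with no clusters), `n_permutations`.
#' @export
cluster_perm_timecourse <- function(stat_fn, data_over_time, n_perm = 5000L,
                                    seed = 1L, perm_fn, alpha = 0.05,
                                    tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  nt <- length(data_over_time)
  if (!nt) stop_("no time points supplied")
  obs <- vapply(data_over_time, function(d) stat_fn(d, NULL), numeric(1))
  perm_stats <- with_seed(derive_seed(seed, "cluster-tc"), {
    t(vapply(seq_len(n_perm), function(i) {
      perm <- perm_fn()
      vapply(data_over_time, function(d) stat_fn(d, perm), numeric(1))
    }, numeric(nt)))
  })
  cluster_from_stats(obs, perm_stats, alpha, tail, n_perm)
}

# Shared cluster logic given observed stats (length T) and a permutation
# matrix (n_perm x T).
cluster_from_stats <- function(obs, perm_stats, alpha, tail, n_perm) {
  if (tail == "greater") {
    crit_hi <- apply(perm_stats, 2L, stats::quantile, probs = 1 - alpha,
                     names = FALSE)
    supra_obs <- obs > crit_hi
    masses <- cluster_masses_1d(obs, supra_obs)
    ranges <- runs_1d(supra_obs)
    null_max <- vapply(seq_len(n_perm), function(i) {
      s <- perm_stats[i, ]
      m <- cluster_masses_1d(s, s > crit_hi)
      if (length(m)) max(m) else 0
    }, numeric(1))
    mass_abs <- masses
  } else {
    crit_hi <- apply(perm_stats, 2L, stats::quantile, probs = 1 - alpha / 2,
                     names = FALSE)
    crit_lo <- apply(perm_stats, 2L, stats::quantile, probs = alpha / 2,
                     names = FALSE)
    pos <- runs_1d(obs > crit_hi)
    neg <- runs_1d(obs < crit_lo)
    ranges <- c(pos, neg)
    masses <- vapply(ranges, function(ix) sum(obs[ix]), numeric(1))
    null_max <- vapply(seq_len(nrow(perm_stats)), function(i) {
      s <- perm_stats[i, ]
      m <- c(vapply(runs_1d(s > crit_hi), function(ix) sum(s[ix]),
                    numeric(1)),
             vapply(runs_1d(s < crit_lo), function(ix) sum(s[ix]),
                    numeric(1)))
      if (length(m)) max(abs(m)) else 0
    }, numeric(1))
    mass_abs <- abs(masses)
  }
  clusters <- if (length(ranges)) {
    data.frame(start = vapply(ranges, min, integer(1)),
               end = vapply(ranges, max, integer(1)),
               mass = masses,
               p = vapply(mass_abs, function(m) {
                 (sum(null_max >= m) + 1) / (n_perm + 1)
               }, numeric(1)))
  } else {
    data.frame(start = integer(0), end = integer(0), mass = numeric(0),
               p = numeric(0))
  }
  structure(list(statistic = obs, clusters = clusters,
                 p_value = if (nrow(clusters)) min(clusters$p) else 1,
                 n_permutations = n_perm),
            class = "stat_result")
}

#' Cluster-corrected factorial effect over a neural weight time course
#'
#' Applies [lrts_effect()] at every time point of a subjects x 8 x time
#' weight-index array with the effect's within-participant permutation
#' scheme, correcting over time by maxsum clusters.
#'
#' @param wav_time Subjects x 8 cells x time array of weight angles
#'   (degrees), cells in [wav_cells()] order.
#' @param effect One of [wav_effects()].
#' @inheritParams cluster_perm_timecourse
#' @return A \code{stat_result} list (see [cluster_perm_timecourse()]).
#' @export
wav_cluster_test <- function(wav_time, effect, n_perm = 5000L, seed = 1L,
                             alpha = 0.05) {
  stopifnot(length(dim(wav_time)) == 3L, dim(wav_time)[2L] == 8L)
  n_sub <- dim(wav_time)[1L]
  data_over_time <- lapply(seq_len(dim(wav_time)[3L]),
                           function(t) wav_time[, , t, drop = FALSE][, , 1L])
  plan <- effect_plan(effect)
  blocks <- effect_blocks(effect)
  stat_fn <- function(d, perm) {
    m <- if (is.null(perm)) d else apply_cell_perm(d, perm)
    lrts_plan_stat(m, plan)
  }
  perm_fn <- function() permute_cells(n_sub, blocks)
  cluster_perm_timecourse(stat_fn, data_over_time, n_perm = n_perm,
                          seed = derive_seed(seed, paste0("wavtc-", effect)),
                          perm_fn = perm_fn, alpha = alpha, tail = "greater")
}

# Vectorised one-sample t statistics under sign flips: values is a
# subjects x T matrix, flips an n_perm x subjects matrix of +-1.
# Returns n_perm x T matrix of t statistics (flipping leaves sums of
# squares unchanged, so the variance follows from the flipped mean alone).
signflip_t_matrix <- function(values, flips) {
  n <- nrow(values)
  ss <- colSums(values^2)
  m <- flips %*% values / n
  v <- sweep(-n * m^2, 2L, ss, `+`) / (n - 1)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  # degenerate (zero-variance) cells: an extreme but finite statistic keeps
  # the sign information (e.g. identical perfect correlations)
  deg <- !is.finite(t)
  t[deg] <- sign(m[deg]) * 1e6
  t
}

#' Correlation between behavioural and neural weight profiles over time
#'
#' For each subject and time point, the circular correlation between the
#' eight behavioural and eight neural weight-index cells; the Fisher
#' z-transformed coefficients are tested against zero with a group-level
#' one-sample t statistic under sign-flip permutations (the same flips at
#' every time point) and maxsum cluster correction over time (two-tailed).
#'
#' @param wav_b Subjects x 8 matrix of behavioural weight angles (degrees).
#' @param wav_n Subjects x 8 x time array of neural weight angles.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @param alpha Cluster-defining threshold.
#' @return A list: `r` (time course of the across-subject mean Fisher-z
#'   correlation), `subject_z` (subjects x time Fisher-z matrix), `stat`
#'   (a \code{stat_result} with the t time course and clusters).
#' @export
behav_neural_corr_test <- function(wav_b, wav_n, n_perm = 5000L, seed = 1L,
                                   alpha = 0.05) {
  stopifnot(nrow(wav_b) == dim(wav_n)[1L], ncol(wav_b) == 8L,
            dim(wav_n)[2L] == 8L)
  n_sub <- nrow(wav_b)
  nt <- dim(wav_n)[3L]
  z <- matrix(NA_real_, n_sub, nt)
  for (s in seq_len(n_sub)) {
    for (t in seq_len(nt)) {
      r <- circ_corr(wav_b[s, ], wav_n[s, , t])
      z[s, t] <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    }
  }
  flips <- with_seed(derive_seed(seed, "bn-corr"), {
    matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE), n_perm, n_sub)
  })
  obs <- signflip_t_matrix(z, matrix(1, 1L, n_sub))[1L, ]
  perm_stats <- signflip_t_matrix(z, flips)
  stat <- cluster_from_stats(obs, perm_stats, alpha, "two.sided", n_perm)
  list(r = colMeans(z), subject_z = z, stat = stat)
}

# --- 2-D clusters (training time x testing time matrices) ----------------

# Label 4-connected components of a logical matrix; returns an integer
# matrix of labels (0 = background).
label_clusters_2d <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  current <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      r <- (i - 1L) %% nr + 1L
      cl <- (i - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) i - 1L, if (r < nr) i + 1L,
              if (cl > 1L) i - nr, if (cl < nc) i + nr)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- current
      queue <- c(queue, nb)
    }
  }
  labels
}

max_cluster_mass_2d <- function(stat, mask_hi, mask_lo = NULL) {
  out <- 0
  if (any(mask_hi)) {
    lab <- label_clusters_2d(mask_hi)
    out <- max(out, max(abs(vapply(seq_len(max(lab)), function(k) {
      sum(stat[lab == k])
    }, numeric(1)))))
  }
  if (!is.null(mask_lo) && any(mask_lo)) {
    lab <- label_clusters_2d(mask_lo)
    out <- max(out, max(abs(vapply(seq_len(max(lab)), function(k) {
      sum(stat[lab == k])
    }, numeric(1)))))
  }
  out
}

#' Group cluster test on temporal generalisation matrices
#'
#' Fisher z-transforms per-subject accuracy matrices, computes a one-sample
#' t statistic against zero per (training time, testing time) cell, forms
#' 4-connected 2-D clusters at a `p < alpha` threshold (per tail, from the
#' sign-flip permutation distribution) and tests each cluster's maxsum mass
#' against the permutation null of the maximum cluster mass (two-tailed).
#'
#' @param matrices Subjects x train-time x test-time array of decoding
#'   accuracies (Pearson correlations).
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @param alpha Cluster-defining threshold.
#' @return A \code{stat_result} list: `statistic` (t matrix), `clusters`
#'   (data.frame with cluster id, size, mass, p), `sig_mask` (logical matrix
#'   of cells in clusters with `p < 0.05`), `p_value`, `n_permutations`.
#' @export
group_cluster_test_matrix <- function(matrices, n_perm = 5000L, seed = 1L,
                                      alpha = 0.05) {
  stopifnot(length(dim(matrices)) == 3L)
  n_sub <- dim(matrices)[1L]
  if (n_sub < 2L) stop_("need at least 2 subjects")
  nt1 <- dim(matrices)[2L]
  nt2 <- dim(matrices)[3L]
  z <- atanh(pmin(pmax(matrices, -1 + 1e-12), 1 - 1e-12))
  zf <- matrix(z, n_sub, nt1 * nt2)   # subjects x cells
  flips <- with_seed(derive_seed(seed, "cluster-2d"), {
    matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE), n_perm, n_sub)
  })
  obs <- signflip_t_matrix(zf, matrix(1, 1L, n_sub))[1L, ]
  perm <- signflip_t_matrix(zf, flips)
  crit_hi <- apply(perm, 2L, stats::quantile, probs = 1 - alpha / 2,
                   names = FALSE)
  crit_lo <- apply(perm, 2L, stats::quantile, probs = alpha / 2,
                   names = FALSE)
  tmat <- matrix(obs, nt1, nt2)
  hi <- matrix(obs > crit_hi, nt1, nt2)
  lo <- matrix(obs < crit_lo, nt1, nt2)
  null_max <- vapply(seq_len(n_perm), function(i) {
    s <- matrix(perm[i, ], nt1, nt2)
    max_cluster_mass_2d(s, matrix(perm[i, ] > crit_hi, nt1, nt2),
                        matrix(perm[i, ] < crit_lo, nt1, nt2))
  }, numeric(1))
  clusters <- data.frame(cluster = integer(0), size = integer(0),
                         mass = numeric(0), p = numeric(0))
  sig_mask <- matrix(FALSE, nt1, nt2)
  kid <- 0L
  for (mask in list(hi, lo)) {
    if (!any(mask)) next
    lab <- label_clusters_2d(mask)
    for (k in seq_len(max(lab))) {
      kid <- kid + 1L
      cells <- lab == k
      mass <- sum(tmat[cells])
      p <- (sum(null_max >= abs(mass)) + 1) / (n_perm + 1)
      clusters <- rbind(clusters,
                        data.frame(cluster = kid, size = sum(cells),
                                   mass = mass, p = p))
      if (p < 0.05) sig_mask <- sig_mask | cells
    }
  }
  structure(list(statistic = tmat, clusters = clusters, sig_mask = sig_mask,
                 p_value = if (nrow(clusters)) min(clusters$p) else 1,
                 n_permutations = n_perm),
            class = "stat_result")
}

#' Conjunction of two significance masks
#'
#' Elementwise AND, e.g. for cells significant in both the
#' auditory-to-visual and the visual-to-auditory cross-modal generalisation.
#'
#' @param sig_a2v,sig_v2a Logical matrices of equal shape.
#' @return Logical matrix.
#' @export
conjunction_mask <- function(sig_a2v, sig_v2a) {
  if (!identical(dim(sig_a2v), dim(sig_v2a))) {
    stop_("significance masks must have identical shapes")
  }
  sig_a2v & sig_v2a
}
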