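# Multivariate decoding of spatial estimates from trials x channels x time
# activity: pseudo-trial averaging, per-time-point linear support-vector
# regression, temporal generalisation within and across modalities, and
# decoding of all audiovisual conditions from a model trained on the
# spatially congruent ones.

#' ERP-style dataset container
#'
#' @param activity Numeric array trials x channels x time.
#' @param times Time stamps in milliseconds relative to stimulus onset,
#'   strictly increasing, one per time sample.
#' @param trial_meta Data.frame with one row per trial; must contain
#'   `condition_id` and the condition descriptors (`a_loc`, `v_loc`,
#'   `reliability`, `task`, `modality`).
#' @return An object of class \code{erp_dataset}.
#' @export
erp_dataset <- function(activity, times, trial_meta) {
  stopifnot(length(dim(activity)) == 3L)
  if (any(!is.finite(activity))) stop_("activity must be finite")
  if (any(diff(times) <= 0)) stop_("times must be strictly increasing")
  if (dim(activity)[3L] != length(times)) {
    stop_("third activity dimension must match times")
  }
  if (dim(activity)[1L] != nrow(trial_meta)) {
    stop_("trial_meta must have one row per trial")
  }
  structure(list(activity = activity, times = times,
                 trial_meta = as.data.frame(trial_meta)),
            class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("erp_dataset: %d trials x %d channels x %d times (%g..%g ms)\n",
              d[1L], d[2L], d[3L], min(x$times), max(x$times)))
  invisible(x)
}

#' Decoder configuration
#'
#' Linear support-vector regression with the LIBSVM defaults used throughout
#' the analysis.
#'
#' @param cost SVR cost parameter C (default 1).
#' @param epsilon SVR tube width (default 0.001).
#' @param n_folds Stratified cross-validation folds (default 12).
#' @param group_size Trials averaged per pseudo-trial (default 8).
#' @return A list of class \code{decoder_config}.
#' @export
decoder_config <- function(cost = 1, epsilon = 0.001, n_folds = 12L,
                           group_size = 8L) {
  structure(list(cost = cost, epsilon = epsilon,
                 n_folds = as.integer(n_folds),
                 group_size = as.integer(group_size), kernel = "linear"),
            class = "decoder_config")
}

#' Average trials into pseudo-trials
#'
#' Within each condition, trials are randomly partitioned into disjoint sets
#' of `group_size` and averaged; remainder trials are dropped. Pseudo-trial
#' averaging boosts the signal-to-noise ratio before decoding.
#'
#' @param data An [erp_dataset()].
#' @param group_size Trials per pseudo-trial.
#' @param seed Integer seed for the random partition.
#' @return An [erp_dataset()] of pseudo-trials; `trial_meta` keeps the
#'   condition descriptors plus `n_averaged`.
#' @export
make_pseudo_trials <- function(data, group_size = 8L, seed = 1L) {
  stopifnot(inherits(data, "erp_dataset"))
  meta <- data$trial_meta
  ids <- unique(meta$condition_id)
  n_per <- table(meta$condition_id)
  if (any(n_per < group_size)) {
    stop_("condition(s) with fewer than %d trials: %s", group_size,
          paste(names(n_per)[n_per < group_size], collapse = ", "))
  }
  groups <- with_seed(derive_seed(seed, "pseudo"), {
    lapply(ids, function(id) {
      rows <- sample(which(meta$condition_id == id))
      k <- length(rows) %/% group_size
      lapply(seq_len(k), function(j) {
        rows[((j - 1L) * group_size + 1L):(j * group_size)]
      })
    })
  })
  groups <- unlist(groups, recursive = FALSE)
  d <- dim(data$activity)
  out <- array(0, c(length(groups), d[2L], d[3L]))
  keep_cols <- intersect(c("subject", "condition_id", "a_loc", "v_loc",
                           "reliability", "task", "modality"), names(meta))
  new_meta <- meta[vapply(groups, `[`, integer(1), 1L), keep_cols,
                   drop = FALSE]
  for (i in seq_along(groups)) {
    out[i, , ] <- colMeans(data$activity[groups[[i]], , , drop = FALSE],
                           dims = 1L)
  }
  new_meta$n_averaged <- group_size
  rownames(new_meta) <- NULL
  erp_dataset(out, data$times, new_meta)
}

# Decoding label: the stimulated location (visual unless auditory-only;
# equal to both for congruent audiovisual trials).
decode_labels <- function(meta) {
  ifelse(meta$modality == "A", meta$a_loc, meta$v_loc)
}

# Stratified fold assignment: within each condition, pseudo-trials are
# shuffled and dealt round-robin over folds. Errors if a stratum is smaller
# than the number of folds.
assign_folds <- function(meta, n_folds, seed) {
  folds <- integer(nrow(meta))
  with_seed(derive_seed(seed, "folds"), {
    for (id in unique(meta$condition_id)) {
      rows <- which(meta$condition_id == id)
      if (length(rows) < n_folds) {
        stop_("condition %s has %d pseudo-trials, fewer than %d folds",
              id, length(rows), n_folds)
      }
      folds[rows] <- (seq_along(rows) - 1L) %% n_folds + 1L
      folds[rows] <- folds[rows][sample.int(length(rows))]
    }
  })
  folds
}

# Channel-wise standardisation statistics from the training rows of one
# time slice; degenerate channels get unit scale.
scale_stats <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

apply_scale <- function(x, st) {
  sweep(sweep(x, 2L, st$mu, `-`), 2L, st$sd, `/`)
}

# Linear SVR weight vector via LIBSVM (e1071); prediction is x %*% w + b.
svr_weights <- function(x, y, config) {
  fit <- e1071::svm(x, y, type = "eps-regression", kernel = "linear",
                    cost = config$cost, epsilon = config$epsilon,
                    scale = FALSE)
  list(w = crossprod(fit$SV, fit$coefs), b = -fit$rho)
}

#' Time-resolved cross-validated decoding accuracy
#'
#' At every time point, a linear SVR is trained on the channel patterns of
#' the training folds and evaluated on the held-out folds (stratified by
#' condition); accuracy is the Pearson correlation between the true and the
#' decoded stimulus locations pooled over folds.
#'
#' @param data An [erp_dataset()] of pseudo-trials.
#' @param config A [decoder_config()].
#' @param seed Integer seed for the fold assignment.
#' @return Numeric vector of accuracies, one per time point (named by time).
#' @export
crossval_decode_timecourse <- function(data, config = decoder_config(),
                                       seed = 1L) {
  stopifnot(inherits(data, "erp_dataset"))
  y <- decode_labels(data$trial_meta)
  folds <- assign_folds(data$trial_meta, config$n_folds, seed)
  nt <- length(data$times)
  n <- dim(data$activity)[1L]
  acc <- numeric(nt)
  for (t in seq_len(nt)) {
    xt <- matrix(data$activity[, , t], n)
    pred <- numeric(length(y))
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      st <- scale_stats(xt[tr, , drop = FALSE])
      m <- svr_weights(apply_scale(xt[tr, , drop = FALSE], st), y[tr], config)
      pred[!tr] <- apply_scale(xt[!tr, , drop = FALSE], st) %*% m$w + m$b
    }
    acc[t] <- stats::cor(y, pred)
  }
  stats::setNames(acc, data$times)
}

#' Temporal generalisation matrix
#'
#' Trains an SVR at every training time point and evaluates it at every
#' testing time point. Within-modality (when `train` and `test` are the same
#' dataset) the matrix is cross-validated: models fit on training folds at
#' the training time decode the held-out folds at every testing time.
#' Across modalities, the model is trained on all pseudo-trials of one
#' dataset and tested on all of the other (disjoint data, no
#' cross-validation needed).
#'
#' @param train,test [erp_dataset()] objects sharing the channel space.
#' @param config A [decoder_config()].
#' @param seed Integer seed for the fold assignment.
#' @param cross_validate Force (`TRUE`) or forbid (`FALSE`) the
#'   cross-validated path; by default it is chosen automatically. Requesting
#'   `FALSE` while `train` and `test` are the same data is refused, since
#'   decoding trials with a model trained on them leaks information.
#' @return A list of class \code{generalization_matrix}: `accuracy`
#'   (train-time x test-time Pearson correlations), `train_times`,
#'   `test_times`.
#' @export
temporal_generalization <- function(train, test, config = decoder_config(),
                                    seed = 1L, cross_validate = NULL) {
  stopifnot(inherits(train, "erp_dataset"), inherits(test, "erp_dataset"))
  if (dim(train$activity)[2L] != dim(test$activity)[2L]) {
    stop_("channel spaces of train and test do not match")
  }
  same <- identical(train, test)
  if (is.null(cross_validate)) cross_validate <- same
  if (same && !cross_validate) {
    stop_("refusing to test a decoder on its own training trials; use the cross-validated path")
  }
  nt1 <- length(train$times)
  nt2 <- length(test$times)
  n_tr <- dim(train$activity)[1L]
  acc <- matrix(NA_real_, nt1, nt2)
  if (cross_validate) {
    y <- decode_labels(train$trial_meta)
    folds <- assign_folds(train$trial_meta, config$n_folds, seed)
    for (t1 in seq_len(nt1)) {
      pred_t1 <- matrix(NA_real_, n_tr, nt2)
      for (f in seq_len(config$n_folds)) {
        tr <- folds != f
        x1 <- matrix(train$activity[, , t1], n_tr)
        st1 <- scale_stats(x1[tr, , drop = FALSE])
        m <- svr_weights(apply_scale(x1[tr, , drop = FALSE], st1), y[tr],
                         config)
        for (t2 in seq_len(nt2)) {
          x2 <- matrix(train$activity[, , t2], n_tr)
          st2 <- scale_stats(x2[tr, , drop = FALSE])
          pred_t1[!tr, t2] <- apply_scale(x2[!tr, , drop = FALSE], st2) %*%
            m$w + m$b
        }
      }
      acc[t1, ] <- stats::cor(y, pred_t1)
    }
  } else {
    y_tr <- decode_labels(train$trial_meta)
    y_te <- decode_labels(test$trial_meta)
    n_te <- dim(test$activity)[1L]
    for (t1 in seq_len(nt1)) {
      x1 <- matrix(train$activity[, , t1], n_tr)
      st1 <- scale_stats(x1)
      m <- svr_weights(apply_scale(x1, st1), y_tr, config)
      for (t2 in seq_len(nt2)) {
        x2 <- matrix(test$activity[, , t2], n_te)
        st2 <- scale_stats(matrix(train$activity[, , t2], n_tr))
        acc[t1, t2] <- stats::cor(y_te, apply_scale(x2, st2) %*% m$w + m$b)
      }
    }
  }
  structure(list(accuracy = acc, train_times = train$times,
                 test_times = test$times),
            class = "generalization_matrix")
}

#' Decode spatial estimates for all audiovisual conditions
#'
#' Trains the SVR at each time point on the spatially congruent audiovisual
#' pseudo-trials (`a_loc == v_loc`), pooled over task relevance and visual
#' reliability, and decodes every audiovisual pseudo-trial. Congruent trials
#' are decoded by cross-validation so no trial is decoded by a model trained
#' on it; incongruent trials are decoded by the model trained on all
#' congruent pseudo-trials.
#'
#' @param data An [erp_dataset()] of audiovisual pseudo-trials.
#' @param config A [decoder_config()].
#' @param seed Integer seed for the congruent fold assignment.
#' @return A list of class \code{decoded_estimates}: `estimates`
#'   (pseudo-trials x time matrix of decoded degrees), `trial_meta`,
#'   `times`.
#' @export
decode_av_estimates <- function(data, config = decoder_config(), seed = 1L) {
  stopifnot(inherits(data, "erp_dataset"))
  meta <- data$trial_meta
  av <- meta$modality == "AV"
  congr <- av & !is.na(meta$a_loc) & !is.na(meta$v_loc) &
    abs(meta$a_loc - meta$v_loc) < 1e-9
  if (!any(congr)) stop_("no spatially congruent audiovisual pseudo-trials")
  ci <- which(congr)
  y_c <- meta$v_loc[ci]
  # stratify congruent folds by location only (training pools task and
  # reliability by construction)
  meta_c <- data.frame(condition_id = meta$v_loc[ci])
  folds <- assign_folds(meta_c, config$n_folds, seed)
  n <- dim(data$activity)[1L]
  nt <- length(data$times)
  est <- matrix(NA_real_, n, nt)
  other <- setdiff(which(av), ci)
  for (t in seq_len(nt)) {
    xt <- matrix(data$activity[, , t], n)
    xc <- xt[ci, , drop = FALSE]
    # held-out decoding of the congruent trials
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      st <- scale_stats(xc[tr, , drop = FALSE])
      m <- svr_weights(apply_scale(xc[tr, , drop = FALSE], st), y_c[tr],
                       config)
      est[ci[!tr], t] <- apply_scale(xc[!tr, , drop = FALSE], st) %*% m$w +
        m$b
    }
    # incongruent trials decoded by the model trained on all congruent ones
    if (length(other)) {
      st <- scale_stats(xc)
      m <- svr_weights(apply_scale(xc, st), y_c, config)
      est[other, t] <- apply_scale(xt[other, , drop = FALSE], st) %*% m$w +
        m$b
    }
  }
  structure(list(estimates = est, trial_meta = meta, times = data$times),
            class = "decoded_estimates")
}
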