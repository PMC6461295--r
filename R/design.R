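# Factorial experimental design, disparity groupings and trial schedules for
# the audiovisual ventriloquist paradigm.

#' Stimulus location grid (degrees azimuth)
#'
#' The four possible azimuthal locations used for both the auditory and the
#' visual stimulus, and equally the four response buttons.
#' @export
av_locations <- function() c(-10, -3.3, 3.3, 10)

# The four realisable |S_A - S_V| levels on the location grid.
disparity_levels <- function() c(0, 6.6, 13.3, 20)

#' Build the factorial condition table
#'
#' Constructs the 4 (visual location) x 4 (auditory location) x 2 (visual
#' reliability: \code{"VR+"} high, \code{"VR-"} low) x 2 (task relevance:
#' auditory vs. visual report) audiovisual design (64 conditions), plus
#' 4 x 2 unisensory visual and 4 unisensory auditory conditions, 76 in total.
#'
#' @return A data.frame of class \code{condition_table} with columns
#'   \code{condition_id}, \code{modality} (\code{"AV"}, \code{"V"},
#'   \code{"A"}), \code{a_loc}, \code{v_loc} (degrees, \code{NA} where the
#'   modality is absent), \code{reliability} (\code{"VR+"}/\code{"VR-"},
#'   \code{NA} for auditory-only), \code{task} (\code{"A"}/\code{"V"} report),
#'   \code{disparity} and \code{disparity_group} (\code{"D-"}/\code{"D+"},
#'   AV rows only).
#' @export
build_factorial_design <- function() {
  locs <- av_locations()
  av <- expand.grid(v_loc = locs, a_loc = locs,
                    reliability = c("VR+", "VR-"), task = c("A", "V"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  av$modality <- "AV"
  vo <- expand.grid(v_loc = locs, reliability = c("VR+", "VR-"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vo$a_loc <- NA_real_
  vo$task <- "V"
  vo$modality <- "V"
  ao <- data.frame(a_loc = locs, v_loc = NA_real_,
                   reliability = NA_character_, task = "A", modality = "A",
                   stringsAsFactors = FALSE)
  cols <- c("modality", "a_loc", "v_loc", "reliability", "task")
  tab <- rbind(av[, cols], vo[, cols], ao[, cols])
  tab$condition_id <- seq_len(nrow(tab))
  tab$disparity <- NA_real_
  tab$disparity_group <- NA_character_
  is_av <- tab$modality == "AV"
  tab$disparity[is_av] <- vapply(which(is_av), function(i) {
    disparity(tab$a_loc[i], tab$v_loc[i])
  }, numeric(1))
  tab$disparity_group[is_av] <- disparity_group(tab$disparity[is_av])
  rownames(tab) <- NULL
  class(tab) <- c("condition_table", "data.frame")
  tab
}

#' Audiovisual spatial disparity
#'
#' Absolute azimuthal separation between the auditory and visual stimulus,
#' snapped to the four design levels 0, 6.6, 13.3, 20 degrees. Snapping (to
#' within 0.1 degrees) absorbs the rounding of the printed location grid,
#' whose one-step separations are 6.6 or 6.7 degrees depending on sign.
#'
#' @param a_loc,v_loc Auditory and visual locations in degrees. Vectorised.
#' @return Disparity in degrees.
#' @export
disparity <- function(a_loc, v_loc) {
  if (any(!is.finite(a_loc)) || any(!is.finite(v_loc))) {
    stop_("disparity is undefined for non-audiovisual conditions")
  }
  d <- abs(a_loc - v_loc)
  lv <- disparity_levels()
  snap <- vapply(d, function(x) {
    i <- which.min(abs(lv - x))
    if (abs(lv[i] - x) <= 0.1 + 1e-9) lv[i] else x
  }, numeric(1))
  snap
}

#' Disparity grouping
#'
#' Classifies spatial disparities as small (\code{"D-"}, at most 6.6 degrees)
#' or large (\code{"D+"}, above 6.6 degrees).
#'
#' @param d Disparity in degrees, nonnegative. Vectorised.
#' @return Character vector of \code{"D-"}/\code{"D+"}.
#' @export
disparity_group <- function(d) {
  if (any(d < 0)) stop_("disparity must be nonnegative")
  ifelse(d <= 6.6 + 1e-9, "D-", "D+")
}

#' Build a balanced pseudo-random trial schedule
#'
#' Produces the 60-run session: 24 audiovisual runs per report modality,
#' 6 unisensory-visual and 6 unisensory-auditory runs, each of 128 trials
#' with every eligible condition occurring equally often within the run
#' (4 per AV condition, 16 per unisensory-visual, 32 per unisensory-auditory).
#' Run order and within-run trial order are pseudo-randomised by `seed`;
#' response hand alternates over pairs of runs within each run type.
#'
#' @param design A \code{condition_table} from [build_factorial_design()].
#' @param seed Integer seed controlling the ordering only; condition counts
#'   are identical for every seed.
#' @return A list of class \code{trial_schedule} with elements \code{trials}
#'   (data.frame: \code{trial}, \code{run}, \code{condition_id}, \code{a_loc},
#'   \code{v_loc}, \code{reliability}, \code{task}, \code{modality},
#'   \code{hand}) and \code{runs} (data.frame: \code{run}, \code{run_type},
#'   \code{task}, \code{hand}).
#' @export
build_trial_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "condition_table"))
  run_defs <- list(
    list(run_type = "AV-A", task = "A", n_runs = 24L,
         ids = design$condition_id[design$modality == "AV" & design$task == "A"],
         reps = 4L),
    list(run_type = "AV-V", task = "V", n_runs = 24L,
         ids = design$condition_id[design$modality == "AV" & design$task == "V"],
         reps = 4L),
    list(run_type = "V", task = "V", n_runs = 6L,
         ids = design$condition_id[design$modality == "V"], reps = 16L),
    list(run_type = "A", task = "A", n_runs = 6L,
         ids = design$condition_id[design$modality == "A"], reps = 32L)
  )
  runs <- do.call(rbind, lapply(run_defs, function(rd) {
    data.frame(run_type = rd$run_type, task = rd$task,
               within = seq_len(rd$n_runs), stringsAsFactors = FALSE)
  }))
  # hands alternate across runs within a run type (balanced for every even
  # run count, including the 6-run unisensory types)
  runs$hand <- ifelse(runs$within %% 2L == 1L, "L", "R")
  with_seed(derive_seed(seed, "schedule"), {
    runs <- runs[sample.int(nrow(runs)), , drop = FALSE]
    runs$run <- seq_len(nrow(runs))
    trials <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
      rd <- run_defs[[match(runs$run_type[i], vapply(run_defs, `[[`,
                                                    character(1), "run_type"))]]
      ids <- rep(rd$ids, rd$reps)
      data.frame(run = runs$run[i], condition_id = ids[sample.int(length(ids))],
                 hand = runs$hand[i], stringsAsFactors = FALSE)
    }))
  })
  trials$trial <- seq_len(nrow(trials))
  keep <- c("condition_id", "a_loc", "v_loc", "reliability", "task", "modality")
  trials <- cbind(trials[c("trial", "run")],
                  design[match(trials$condition_id, design$condition_id), keep],
                  hand = trials$hand)
  rownames(trials) <- NULL
  rownames(runs) <- NULL
  structure(list(trials = trials,
                 runs = runs[order(runs$run),
                             c("run", "run_type", "task", "hand")]),
            class = "trial_schedule")
}

#' Write a condition table or trial schedule to CSV
#'
#' @param x A \code{condition_table} or \code{trial_schedule}.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(x, path) {
  df <- if (inherits(x, "trial_schedule")) x$trials else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
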