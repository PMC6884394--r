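# Beta-series functional connectivity.
#
# Trial-wise covariation between a seed region and target regions is measured
# by correlating their single-trial beta series; learning-related coupling
# change is the Fisher-z correlation difference between late implementation
# trials (stimulus repetitions 7 and 8) and early trials (repetitions 1 and
# 2), contrasted between the intentional-learning and control conditions.

#' Fisher-z beta-series correlation
#'
#' @param seed_series,target_series Numeric per-trial beta series.
#' @param trial_subset Optional logical/integer subset of trials.
#' @return Fisher z-transformed Pearson correlation (`atanh(r)`).
#' @export
beta_series_r <- function(seed_series, target_series, trial_subset = NULL) {
  if (!is.null(trial_subset)) {
    seed_series <- seed_series[trial_subset]
    target_series <- target_series[trial_subset]
  }
  if (length(seed_series) != length(target_series))
    stop_input("series lengths differ")
  if (length(seed_series) < 4L)
    stop_input("need at least 4 trials for a beta-series correlation")
  if (stats::var(seed_series) == 0 || stats::var(target_series) == 0)
    stop_input("zero variance in a beta series")
  r <- stats::cor(seed_series, target_series)
  if (abs(r) >= 1 - 1e-12)
    stop_input("perfect correlation: Fisher z undefined")
  atanh(r)
}

# Region-mean beta series with trial metadata.
region_beta_series <- function(beta_set, mask) {
  cols <- roi_columns(beta_set, mask)
  rowMeans(beta_set$betas[, cols, drop = FALSE])
}

#' Early-to-late connectivity change contrast
#'
#' Computes, per condition, the Fisher-z beta-series correlation between the
#' seed and each target within the early window (repetitions 1 and 2) and the
#' late window (repetitions 7 and 8), pooling trials across that condition's
#' blocks, and returns the subject-level contrast
#' `(z_late - z_early)[learning] - (z_late - z_early)[control]`.
#' Error trials are excluded.
#'
#' @param beta_set A subject-level `trial_beta_set` from an 8-repetition
#'   design.
#' @param seed_mask Seed-region mask (region-mean series).
#' @param target_masks Named list of target masks.
#' @param correct_flags Logical vector aligned to trials; incorrect trials are
#'   dropped. Defaults to all trials.
#' @param conditions Length-2 character vector: the learning condition first,
#'   the control condition second.
#' @param early_reps,late_reps Repetition windows (defaults 1:2 and 7:8).
#' @param per_block If `TRUE`, correlations are computed per block and
#'   averaged (Fisher-z domain) instead of pooling trials across blocks.
#' @return Data frame: target, z_early_learning, z_late_learning,
#'   z_early_control, z_late_control, contrast. A window with fewer than 4
#'   usable trials yields `NA` for that target.
#' @export
connectivity_change <- function(beta_set, seed_mask, target_masks,
                                correct_flags = NULL,
                                conditions = c("learning", "control"),
                                early_reps = 1:2, late_reps = 7:8,
                                per_block = FALSE) {
  meta <- beta_set$meta
  if (max(meta$repetition, na.rm = TRUE) < max(late_reps))
    stop_input("design lacks the late repetition window (need ",
               max(late_reps), " repetitions)")
  keep <- correct_flags %||% rep(TRUE, nrow(meta))
  seed <- region_beta_series(beta_set, seed_mask)
  win_z <- function(target_series, cond, reps) {
    sel <- which(meta$condition == cond & meta$repetition %in% reps & keep)
    if (per_block) {
      zs <- vapply(unique(meta$block[sel]), function(b) {
        s <- sel[meta$block[sel] == b]
        if (length(s) < 4L) return(NA_real_)
        tryCatch(beta_series_r(seed[s], target_series[s]),
                 error = function(e) NA_real_)
      }, 0)
      mean(zs, na.rm = TRUE)
    } else {
      if (length(sel) < 4L) return(NA_real_)
      tryCatch(beta_series_r(seed[sel], target_series[sel]),
               error = function(e) NA_real_)
    }
  }
  rows <- lapply(names(target_masks), function(nm) {
    ts <- region_beta_series(beta_set, target_masks[[nm]])
    zel <- win_z(ts, conditions[1], early_reps)
    zll <- win_z(ts, conditions[1], late_reps)
    zec <- win_z(ts, conditions[2], early_reps)
    zlc <- win_z(ts, conditions[2], late_reps)
    data.frame(target = nm,
               z_early_learning = zel, z_late_learning = zll,
               z_early_control = zec, z_late_control = zlc,
               contrast = (zll - zel) - (zlc - zec))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
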