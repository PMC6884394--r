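# Condition-mean activity per ROI: the conventional univariate complement to
# the pattern-similarity analysis. Cell estimates are formed from the same
# single-trial betas (mean over ROI voxels, then over correct trials).

#' Mean activity per condition x repetition x ROI
#'
#' @param beta_set A subject-level `trial_beta_set`.
#' @param roi_masks Named list of ROI masks (logical arrays or voxel indices).
#' @param correct_flags Logical vector aligned to `beta_set$meta`; error
#'   trials are excluded. Defaults to all trials.
#' @param subject Optional subject identifier recorded in the output.
#' @return Data frame: subject, condition, repetition, roi, mean_beta,
#'   n_trials (`NA` mean for empty cells).
#' @export
mean_activity <- function(beta_set, roi_masks, correct_flags = NULL,
                          subject = 1L) {
  meta <- beta_set$meta
  keep <- correct_flags %||% rep(TRUE, nrow(meta))
  if (length(keep) != nrow(meta))
    stop_input("`correct_flags` must align with trials")
  rows <- list()
  for (roi in names(roi_masks)) {
    cols <- roi_columns(beta_set, roi_masks[[roi]])
    series <- rowMeans(beta_set$betas[, cols, drop = FALSE])
    for (cond in unique(meta$condition)) {
      for (rep_ in sort(unique(meta$repetition))) {
        sel <- meta$condition == cond & meta$repetition == rep_ & keep
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subject, condition = cond, repetition = rep_, roi = roi,
          mean_beta = if (any(sel)) mean(series[sel]) else NA_real_,
          n_trials = sum(sel))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
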