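# Stage-resolved identity-specific pattern similarity.
#
# For one block and one implementation stage (two consecutive occurrences of
# each of the four stimuli, i.e. 8 trials), all pairwise Pearson correlations
# between single-trial beta patterns are computed over voxels. The statistic
# "delta" is the mean correlation over same-stimulus pairs minus the mean over
# different-stimulus pairs; identity-specific coding implies delta > 0.

#' Identity-specific pattern similarity for one block-stage
#'
#' @param trial_betas Trials x voxels matrix (one row per trial of the stage).
#' @param stimulus_labels Vector of stimulus ids, one per row; every label
#'   must occur exactly twice.
#' @param fisher_z If `TRUE`, correlations are Fisher z-transformed before
#'   averaging (default `FALSE`: plain means of correlations).
#' @return A `similarity_result` list: `mean_same_r`, `mean_diff_r`, `delta`,
#'   `n_same_pairs`, `n_diff_pairs`.
#' @export
stage_similarity <- function(trial_betas, stimulus_labels, fisher_z = FALSE) {
  if (!is.matrix(trial_betas)) trial_betas <- as.matrix(trial_betas)
  n <- nrow(trial_betas)
  if (length(stimulus_labels) != n)
    stop_input("one label per trial row is required")
  if (ncol(trial_betas) < 2L) stop_input("need at least 2 voxels")
  counts <- table(stimulus_labels)
  if (any(counts != 2L))
    stop_input("every stimulus label must occur exactly twice in a stage")
  v <- apply(trial_betas, 1L, stats::var)
  if (any(v <= 0))
    stop_input("constant beta pattern: correlation undefined")
  C <- stats::cor(t(trial_betas))
  if (fisher_z) C <- atanh(pmin(pmax(C, -1 + 1e-15), 1 - 1e-15))
  same <- outer(stimulus_labels, stimulus_labels, "==") & upper.tri(C)
  diffp <- (!outer(stimulus_labels, stimulus_labels, "==")) & upper.tri(C)
  res <- list(mean_same_r = mean(C[same]), mean_diff_r = mean(C[diffp]),
              delta = mean(C[same]) - mean(C[diffp]),
              n_same_pairs = sum(same), n_diff_pairs = sum(diffp))
  class(res) <- "similarity_result"
  res
}

# Map a region mask (logical array or voxel indices) to beta-set columns.
roi_columns <- function(beta_set, roi_mask) {
  vox <- if (is.logical(roi_mask)) which(as.vector(roi_mask)) else as.integer(roi_mask)
  cols <- match(vox, beta_set$mask_voxels)
  cols <- cols[!is.na(cols)]
  if (length(cols) == 0L) stop_input("ROI does not overlap the analyzed mask")
  cols
}

#' Block-wise similarity deltas for one ROI
#'
#' Computes the identity-specific pattern similarity separately for every
#' block and implementation stage. Degenerate cells (label counts disturbed by
#' correct-only filtering, or constant patterns) are returned as `NA`.
#'
#' @param beta_set A `trial_beta_set` (typically subject-level, see
#'   [combine_beta_sets()]).
#' @param roi_mask Logical array or voxel indices defining the ROI.
#' @param correct_only Restrict to correct trials (subjective rule); cells in
#'   which any stimulus then lacks exactly two trials are dropped.
#' @param correct_flags Logical vector aligned to `beta_set$meta` rows; needed
#'   when `correct_only = TRUE`.
#' @param fisher_z See [stage_similarity()].
#' @return Data frame: block, condition, stage, delta, mean_same_r,
#'   mean_diff_r.
#' @export
block_similarity <- function(beta_set, roi_mask, correct_only = FALSE,
                             correct_flags = NULL, fisher_z = FALSE) {
  cols <- roi_columns(beta_set, roi_mask)
  meta <- beta_set$meta
  keep <- rep(TRUE, nrow(meta))
  if (correct_only) {
    if (is.null(correct_flags) || length(correct_flags) != nrow(meta))
      stop_input("`correct_flags` aligned to trials is required")
    keep <- correct_flags
  }
  out <- list()
  for (b in sort(unique(meta$block))) {
    stages <- sort(unique(meta$stage[meta$block == b]))
    for (s in stages) {
      idx <- which(meta$block == b & meta$stage == s & keep)
      labels <- meta$stimulus_id[idx]
      delta <- same <- diffr <- NA_real_
      if (length(idx) && all(table(labels) == 2L) &&
          length(unique(labels)) > 1L) {
        res <- tryCatch(
          stage_similarity(beta_set$betas[idx, cols, drop = FALSE], labels,
                           fisher_z = fisher_z),
          error = function(e) NULL)
        if (!is.null(res)) {
          delta <- res$delta; same <- res$mean_same_r; diffr <- res$mean_diff_r
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        block = b, condition = meta$condition[meta$block == b][1],
        stage = s, delta = delta, mean_same_r = same, mean_diff_r = diffr)
    }
  }
  do.call(rbind, out)
}

#' Subject-level similarity table for one ROI
#'
#' Averages block-wise deltas within each condition x stage cell, optionally
#' adjusting for design bias measured in a white-matter control region (see
#' [wm_bias_adjust()]) and optionally aggregating stages (e.g. early =
#' mean of stages 1 and 2, late = mean of stages 3 and 4 for the 8-repetition
#' experiment).
#'
#' @param beta_set A subject-level `trial_beta_set`.
#' @param roi_mask ROI voxel mask or indices.
#' @param wm_mask Optional white-matter mask; when given, the `delta_wm_adjusted`
#'   column holds the bias-regressed estimate per cell.
#' @param aggregate_stages Optional named list mapping aggregate names to
#'   stage vectors, e.g. `list(early = 1:2, late = 3:4)`.
#' @param roi Label recorded in the output (ROI name).
#' @inheritParams block_similarity
#' @return Data frame: condition, stage, roi, delta, delta_wm_adjusted,
#'   n_blocks.
#' @export
subject_similarity <- function(beta_set, roi_mask, roi = "roi",
                               wm_mask = NULL, aggregate_stages = NULL,
                               correct_only = FALSE, correct_flags = NULL,
                               fisher_z = FALSE) {
  bs <- block_similarity(beta_set, roi_mask, correct_only, correct_flags,
                         fisher_z)
  wm <- if (!is.null(wm_mask))
    block_similarity(beta_set, wm_mask, correct_only, correct_flags, fisher_z)
  cells <- unique(bs[, c("condition", "stage")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- bs$condition == cells$condition[i] & bs$stage == cells$stage[i]
    d <- bs$delta[sel]
    adj <- NA_real_
    if (!is.null(wm)) {
      wsel <- wm$condition == cells$condition[i] & wm$stage == cells$stage[i]
      adj <- wm_bias_adjust(d, wm$delta[wsel])
    }
    rows[[i]] <- data.frame(condition = cells$condition[i],
                            stage = cells$stage[i], roi = roi,
                            delta = mean(d, na.rm = TRUE),
                            delta_wm_adjusted = adj,
                            n_blocks = sum(!is.na(d)))
  }
  out <- do.call(rbind, rows)
  if (!is.null(aggregate_stages)) {
    agg <- list()
    for (cond in unique(out$condition)) {
      for (nm in names(aggregate_stages)) {
        sel <- out$condition == cond & out$stage %in% aggregate_stages[[nm]]
        agg[[length(agg) + 1L]] <- data.frame(
          condition = cond, stage = nm, roi = roi,
          delta = mean(out$delta[sel]),
          delta_wm_adjusted = mean(out$delta_wm_adjusted[sel]),
          n_blocks = sum(out$n_blocks[sel]))
      }
    }
    out <- do.call(rbind, agg)
  }
  rownames(out) <- NULL
  out
}

#' White-matter bias regression
#'
#' The atomic-sequence scheme guarantees zero bias only in expectation; the
#' realized bias of an individual block's sequences is shared by every region,
#' including white matter where no stimulus information is expected. The ROI
#' block deltas are therefore regressed on the white-matter block deltas and
#' the regression intercept -- the ROI delta expected at zero measured bias --
#' is used as the adjusted subject-level estimate.
#'
#' @param roi_blockwise_deltas,wm_blockwise_deltas Numeric vectors, same block
#'   ordering.
#' @return Adjusted subject-level delta (scalar). With fewer than 3 complete
#'   pairs the regression is not attempted and the unadjusted mean is
#'   returned; zero variance in the WM deltas also falls back to the
#'   unadjusted mean, with a warning.
#' @export
wm_bias_adjust <- function(roi_blockwise_deltas, wm_blockwise_deltas) {
  if (length(roi_blockwise_deltas) != length(wm_blockwise_deltas))
    stop_input("block delta vectors must be aligned")
  ok <- stats::complete.cases(roi_blockwise_deltas, wm_blockwise_deltas)
  x <- wm_blockwise_deltas[ok]
  y <- roi_blockwise_deltas[ok]
  if (length(y) < 3L) return(mean(y))
  if (stats::var(x) == 0) {
    warning("white-matter deltas degenerate; returning unadjusted mean")
    return(mean(y))
  }
  unname(stats::coef(stats::lm(y ~ x))[1])
}

#' Offsets of a spherical searchlight
#'
#' Integer offsets of all lattice points within Euclidean distance `radius`
#' (in voxel units) of the origin, including the center (123 voxels at the
#' default radius 3).
#' @param radius Radius in voxels.
#' @export
searchlight_offsets <- function(radius = 3) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, ]
  as.matrix(g)
}

#' Searchlight map of identity-specific pattern similarity
#'
#' Computes, for every in-mask center voxel, the block-averaged similarity
#' delta on the voxels inside a sphere of `radius` voxels intersected with the
#' mask, separately per condition and stage. Centers whose sphere retains
#' fewer than 2 usable voxels are `NA`.
#'
#' @param beta_set A subject-level `trial_beta_set` fitted on (at least) the
#'   voxels of `mask`.
#' @param mask Logical 3D array: analysis mask (also constrains the spheres).
#' @param radius Sphere radius in voxel units (default 3).
#' @param conditions Conditions to map (default: all present).
#' @return Named list (condition) of named lists (stage) of 3D arrays with
#'   the delta map.
#' @export
searchlight_similarity <- function(beta_set, mask, radius = 3,
                                   conditions = NULL) {
  if (radius < 1) stop_input("`radius` must be >= 1")
  dims <- dim(mask)
  if (is.null(dims) || length(dims) != 3L)
    stop_input("`mask` must be a logical 3D array")
  centers <- which(mask)
  if (length(centers) == 0L) stop_input("mask is empty")
  col_of <- rep(NA_integer_, prod(dims))
  col_of[beta_set$mask_voxels] <- seq_along(beta_set$mask_voxels)
  if (anyNA(col_of[centers]))
    stop_input("mask contains voxels outside the fitted beta set")
  off <- searchlight_offsets(radius)
  meta <- beta_set$meta
  conditions <- conditions %||% unique(meta$condition)
  stages <- sort(unique(meta$stage))
  # pre-index block-stage trial groups
  groups <- list()
  for (b in sort(unique(meta$block))) for (s in stages) {
    idx <- which(meta$block == b & meta$stage == s)
    if (length(idx))
      groups[[length(groups) + 1L]] <- list(
        cond = meta$condition[idx[1]], stage = s, idx = idx,
        labels = meta$stimulus_id[idx])
  }
  maps <- stats::setNames(lapply(conditions, function(cc)
    stats::setNames(lapply(stages, function(s) array(NA_real_, dims)),
                    paste0("stage", stages))), conditions)
  coords <- arrayInd(centers, dims)
  for (ci in seq_along(centers)) {
    nb <- sweep(off, 2L, coords[ci, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] + (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    lin <- lin[mask[lin]]
    cols <- col_of[lin]
    cols <- cols[!is.na(cols)]
    if (length(cols) < 2L) next
    acc <- list()
    for (g in groups) {
      if (!(g$cond %in% conditions)) next
      d <- tryCatch(
        stage_similarity(beta_set$betas[g$idx, cols, drop = FALSE],
                         g$labels)$delta,
        error = function(e) NA_real_)
      key <- paste(g$cond, g$stage)
      acc[[key]] <- c(acc[[key]], d)
    }
    for (cc in conditions) for (s in stages) {
      key <- paste(cc, s)
      if (!is.null(acc[[key]]))
        maps[[cc]][[paste0("stage", s)]][centers[ci]] <-
          mean(acc[[key]], na.rm = TRUE)
    }
  }
  maps
}
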