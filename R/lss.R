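# Least-squares-separate (LSS) single-trial estimation.
#
# One GLM per implementation trial: a regressor for that trial, a regressor
# for all other implementation trials of the run, Fourier regressors per
# instruction phase, one feedback regressor, a run constant and DCT drifts.
# All trial-wise fits share the nuisance part of the design, so the package
# residualizes the trial regressors against the nuisance block once per run
# and solves every trial's 2x2 normal equations in closed form; this is
# algebraically identical to fitting each LSS design separately by OLS.

# Build the shared per-run regressors: the n_volumes x n_trials matrix of
# single-trial HRF regressors and the nuisance matrix (Fourier sets, feedback,
# constant, drifts) with column labels.
build_run_regressors <- function(run_events, config, n_volumes) {
  impl <- run_events[run_events$phase == "implementation", , drop = FALSE]
  if (nrow(impl) == 0L) stop_input("run has no implementation trials")
  trial <- hrf_regressor(impl$onset, config, n_volumes)
  colnames(trial) <- sprintf("trial%03d", seq_len(nrow(impl)))

  nuis <- list()
  # one Fourier set per run, its windows locked to every instruction-phase
  # onset (the first announcement of each block); the response shape is
  # shared across blocks
  ann <- run_events[run_events$phase == "announce", , drop = FALSE]
  if (nrow(ann)) {
    instr_onsets <- as.numeric(tapply(ann$onset, ann$block, min))
    fb <- build_fourier_basis(instr_onsets, config, n_volumes)
    colnames(fb) <- paste0("instr_", colnames(fb))
    nuis[[length(nuis) + 1L]] <- fb
  }
  fdb <- run_events[run_events$phase == "feedback", , drop = FALSE]
  if (nrow(fdb)) {
    col <- hrf_regressor(fdb$onset, config, n_volumes, collapse = TRUE)
    colnames(col) <- "feedback"
    nuis[[length(nuis) + 1L]] <- col
  }
  const <- matrix(1, n_volumes, 1, dimnames = list(NULL, "constant"))
  dct <- build_dct_highpass(n_volumes, config)
  nuis <- do.call(cbind, c(nuis, list(const), if (ncol(dct)) list(dct)))
  list(trial = trial, nuisance = nuis, meta = impl)
}

#' Build one LSS design matrix
#'
#' Returns the full design matrix for the GLM of a single implementation
#' trial: the target-trial regressor, the all-other-implementation-trials
#' regressor, the run's instruction-phase Fourier set, a feedback regressor,
#' the run constant, and DCT drift columns. Announcement displays carry no
#' regressor (absorbed by the baseline).
#'
#' @param run_events Events data frame of one run (see
#'   [generate_experiment_design()]).
#' @param trial_index Index of the target implementation trial within the run
#'   (1-based, in onset order).
#' @param config A [glm_config()].
#' @param n_volumes Number of volumes in the run.
#' @return List with `X` (design matrix), `labels` (column names) and
#'   `target_col` (index of the target-trial column).
#' @export
build_lss_design <- function(run_events, trial_index, config, n_volumes) {
  reg <- build_run_regressors(run_events, config, n_volumes)
  n_trials <- ncol(reg$trial)
  if (trial_index < 1L || trial_index > n_trials)
    stop_input("`trial_index` out of range (run has ", n_trials, " trials)")
  target <- reg$trial[, trial_index, drop = FALSE]
  others <- rowSums(reg$trial[, -trial_index, drop = FALSE])
  X <- cbind(target, others, reg$nuisance)
  colnames(X)[1:2] <- c("target_trial", "other_trials")
  list(X = X, labels = colnames(X), target_col = 1L)
}

# AR(1) prewhitening transform applied in place: y'_1 = sqrt(1 - rho^2) y_1,
# y'_t = y_t - rho y_{t-1}. Works column-wise on matrices.
ar1_whiten <- function(M, rho) {
  if (rho == 0) return(M)
  n <- nrow(M)
  W <- rbind(sqrt(1 - rho^2) * M[1, , drop = FALSE],
             M[-1, , drop = FALSE] - rho * M[-n, , drop = FALSE])
  dimnames(W) <- dimnames(M)
  W
}

# Pooled lag-1 residual autocorrelation across mask voxels. Residuals come
# from the model that mirrors the LSS nuisance structure (one regressor for
# all implementation trials plus the nuisance block); the near-saturated
# all-trials design would leave too few residual degrees of freedom and
# distort the autocorrelation.
estimate_ar1_rho <- function(Y, trial, nuisance) {
  X <- cbind(rowSums(trial), nuisance)
  qx <- qr(X)
  res <- qr.resid(qx, Y)
  n <- nrow(res)
  num <- sum(res[-1, ] * res[-n, ])
  den <- sum(res^2)
  rho <- if (den > 0) num / den else 0
  max(min(rho, 0.95), 0)
}

check_design_rank <- function(N, labels) {
  qn <- qr(N)
  if (qn$rank < ncol(N)) {
    ql <- qr(N, LAPACK = TRUE)  # pivoted QR names the collinear columns
    bad <- labels[ql$pivot[(qn$rank + 1L):ncol(N)]]
    stop_input("rank-deficient design; collinear columns: ",
               paste(bad, collapse = ", "))
  }
  qn
}

#' Fit the least-squares-separate single-trial model for one run
#'
#' Estimates one beta map per implementation trial. For each trial the model
#' contains the target-trial regressor, a single regressor for all other
#' implementation trials, the instruction-phase Fourier set, a feedback
#' regressor, the run constant and DCT drifts. With `ar1 = "estimate"` a
#' single AR(1) coefficient per run is pooled from full-model residuals and
#' data and design are prewhitened before the trial-wise fits.
#'
#' @param bold A `bold_run` (see [simulate_subject()]) or a voxels x time
#'   numeric matrix.
#' @param run_events Events data frame for this run.
#' @param config A [glm_config()].
#' @param mask Optional logical array/vector (or integer indices) selecting
#'   the voxels to analyze; every voxel inside the mask is analyzed
#'   regardless of signal level. Defaults to all voxels.
#' @return A `trial_beta_set`: list with `betas` (trials x voxels), `meta`
#'   (implementation-trial events aligned to rows), `mask_voxels` (column ->
#'   voxel index), `rho` (AR(1) coefficient used).
#' @export
fit_lss <- function(bold, run_events, config = glm_config(), mask = NULL) {
  data <- if (is.list(bold)) bold$data else bold
  if (!is.matrix(data)) stop_input("`bold` must contain a voxels x time matrix")
  if (!all(is.finite(data))) stop_input("BOLD data contain non-finite values")
  n_volumes <- ncol(data)
  if (is.null(mask)) {
    vox <- seq_len(nrow(data))
  } else if (is.logical(mask)) {
    vox <- which(as.vector(mask))
  } else {
    vox <- as.integer(mask)
  }
  if (length(vox) == 0L) stop_input("mask is empty")
  Y <- t(data[vox, , drop = FALSE])  # time x voxels

  reg <- build_run_regressors(run_events, config, n_volumes)
  trial <- reg$trial
  nuis <- reg$nuisance

  rho <- switch(config$ar1,
                off = 0,
                fixed = config$ar1_rho,
                estimate = estimate_ar1_rho(Y, trial, nuis))
  if (rho > 0) {
    Y <- ar1_whiten(Y, rho)
    trial <- ar1_whiten(trial, rho)
    nuis <- ar1_whiten(nuis, rho)
  }

  qn <- check_design_rank(nuis, colnames(nuis))
  Tt <- trial - qr.fitted(qn, trial)   # trial regressors residualized on nuisance
  Yt <- Y - qr.fitted(qn, Y)
  s <- rowSums(Tt)                      # residualized sum of all trials

  # per-trial 2x2 normal equations [a = target, b = sum of others]
  aa <- colSums(Tt^2)
  as_ <- as.numeric(crossprod(Tt, s))
  ab <- as_ - aa
  bb <- sum(s^2) - 2 * as_ + aa
  det <- aa * bb - ab^2
  if (any(det < 1e-10 * aa * bb))
    stop_input("rank-deficient design; collinear columns: target_trial, other_trials")
  aY <- crossprod(Tt, Yt)              # n_trials x n_vox
  bY <- matrix(colSums(s * Yt), nrow = nrow(aY), ncol = ncol(aY), byrow = TRUE) - aY
  betas <- (bb * aY - ab * bY) / det
  dimnames(betas) <- NULL

  structure(list(betas = betas, meta = reg$meta, mask_voxels = vox,
                 rho = rho, n_volumes = n_volumes),
            class = "trial_beta_set")
}

#' Combine per-run trial beta sets into one subject-level set
#'
#' @param beta_sets List of `trial_beta_set` objects with identical masks.
#' @export
combine_beta_sets <- function(beta_sets) {
  stopifnot(length(beta_sets) >= 1L)
  masks <- lapply(beta_sets, `[[`, "mask_voxels")
  if (!all(vapply(masks, identical, TRUE, masks[[1]])))
    stop_input("beta sets use different masks")
  structure(list(betas = do.call(rbind, lapply(beta_sets, `[[`, "betas")),
                 meta = do.call(rbind, lapply(beta_sets, `[[`, "meta")),
                 mask_voxels = masks[[1]],
                 rho = vapply(beta_sets, `[[`, 0, "rho")),
            class = "trial_beta_set")
}

#' Trial mixing matrix of the LSS estimator
#'
#' In the noiseless case the fitted single-trial betas are a fixed linear map
#' of the true per-trial amplitudes: `beta = M %*% amplitude`. `M` is computed
#' from the same residualized closed-form solution used by [fit_lss()] and is
#' the fast oracle behind [estimate_sequence_bias()].
#'
#' @param run_events Events data frame of one run (or block).
#' @param config A [glm_config()]; AR(1) options `"off"` and `"fixed"` are
#'   supported (there are no residuals to estimate from).
#' @param n_volumes Number of volumes.
#' @return n_trials x n_trials matrix `M`.
#' @export
lss_trial_mixing <- function(run_events, config = glm_config(), n_volumes) {
  reg <- build_run_regressors(run_events, config, n_volumes)
  trial <- reg$trial
  nuis <- reg$nuisance
  rho <- switch(config$ar1, off = 0, fixed = config$ar1_rho,
                estimate = stop_input(
                  "`ar1 = \"estimate\"` needs data; use \"off\" or \"fixed\""))
  trial_w <- if (rho > 0) ar1_whiten(trial, rho) else trial
  nuis_w <- if (rho > 0) ar1_whiten(nuis, rho) else nuis
  qn <- check_design_rank(nuis_w, colnames(nuis_w))
  Tt <- trial_w - qr.fitted(qn, trial_w)
  s <- rowSums(Tt)
  aa <- colSums(Tt^2)
  as_ <- as.numeric(crossprod(Tt, s))
  ab <- as_ - aa
  bb <- sum(s^2) - 2 * as_ + aa
  det <- aa * bb - ab^2
  aT <- crossprod(Tt, Tt)   # a'X for X = whitened trial regressors
  bT <- matrix(colSums(s * Tt), nrow(aT), ncol(aT), byrow = TRUE) - aT
  (bb * aT - ab * bT) / det
}
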