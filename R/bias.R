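# Design-induced bias of the stage-resolved similarity statistic.
#
# With overlapping BOLD responses, single-trial estimates of temporally close
# trials are correlated through the estimator, so the same/different-stimulus
# correlation contrast of a *fixed* trial sequence has nonzero expectation
# even for pure noise patterns. This module estimates that bias by Monte
# Carlo: every trial carries an independent random pattern (no identity
# structure), the noise-free data are pushed through the LSS estimator, and
# the stage-wise statistic is averaged. Because the estimator is linear, the
# noise-free betas are an exact linear mixing of the true trial patterns
# (see [lss_trial_mixing()]), which gives a fast equivalent route; the full
# route that simulates voxel data and calls [fit_lss()] is retained as a
# cross-check.

block_run_geometry <- function(block_design, config) {
  ev <- block_design$events
  if (is.null(ev$block)) ev$block <- 1L
  if (is.null(ev$run)) ev$run <- 1L
  run_len <- max(ev$onset + ev$duration) + RUN_TAIL_S
  n_vol <- as.integer(ceiling(run_len / config$tr_s))
  list(events = ev, n_volumes = n_vol)
}

#' Monte-Carlo estimate of the per-stage similarity bias of a block design
#'
#' @param block_design A `block_design` (see [generate_block_design()]).
#' @param glm A [glm_config()] with `ar1 = "off"` or `"fixed"`.
#' @param n_mc Number of Monte-Carlo pattern draws (>= 100).
#' @param n_voxels Number of voxels per simulated pattern (default 50).
#' @param method `"mixing"` uses the exact linear trial-mixing matrix;
#'   `"full"` simulates noise-free voxel data and runs [fit_lss()].
#' @param seed Optional integer seed.
#' @return List with `bias` (named per-stage mean delta), `se` (Monte-Carlo
#'   standard errors), `draws` (n_mc x stages matrix), `n_mc`.
#' @export
estimate_sequence_bias <- function(block_design, glm = glm_config(),
                                   n_mc = 200, n_voxels = 50,
                                   method = c("mixing", "full"),
                                   seed = NULL) {
  method <- match.arg(method)
  if (n_mc < 100) stop_input("`n_mc` must be >= 100")
  geo <- block_run_geometry(block_design, glm)
  impl <- geo$events[geo$events$phase == "implementation", ]
  stages <- sort(unique(impl$stage))
  n <- nrow(impl)
  if (method == "mixing") {
    cfg <- glm
    if (cfg$ar1 == "estimate") cfg$ar1 <- "off"
    M <- lss_trial_mixing(geo$events, cfg, geo$n_volumes)
  }
  with_seed(seed, {
    draws <- matrix(NA_real_, n_mc, length(stages),
                    dimnames = list(NULL, paste0("stage", stages)))
    for (m in seq_len(n_mc)) {
      P <- matrix(stats::rnorm(n * n_voxels), n, n_voxels)
      B <- if (method == "mixing") {
        M %*% P
      } else {
        gcfg0 <- glm
        reg <- build_run_regressors(geo$events, gcfg0, geo$n_volumes)
        fit_lss(t(reg$trial %*% P), geo$events, gcfg0)$betas
      }
      for (si in seq_along(stages)) {
        idx <- which(impl$stage == stages[si])
        draws[m, si] <- stage_similarity(B[idx, , drop = FALSE],
                                         impl$stimulus_id[idx])$delta
      }
    }
    list(bias = colMeans(draws),
         se = apply(draws, 2L, stats::sd) / sqrt(n_mc),
         draws = draws, n_mc = n_mc)
  })
}

#' Per-block bias across freshly randomized blocks, by sequencing scheme
#'
#' Generates `n_blocks` independent block designs under the given trial
#' ordering scheme and estimates each block's expected per-stage bias. The
#' spread of these per-block biases is what distinguishes the atomic scheme
#' (bias centered tightly on zero) from retrospectively splitting a single
#' fully randomized sequence into stage halves.
#'
#' @param n_blocks Number of fresh blocks.
#' @param scheme `"atomic"` or `"retrospective"`.
#' @param condition,experiment Block parameters (defaults: easy, exp1).
#' @param glm A [glm_config()].
#' @param n_mc Pattern draws per block.
#' @param n_voxels Voxels per pattern draw.
#' @param seed Optional integer seed.
#' @return List with `block_bias` (n_blocks x stages matrix of per-block mean
#'   deltas), `mean_bias`, `se_of_mean` (standard error of the grand mean,
#'   from the block-level spread), `block_variance` (variance of per-block
#'   bias per stage) and `block_mean_square` (mean squared per-block bias,
#'   i.e. spread around the zero-bias ideal).
#' @export
scheme_bias_profile <- function(n_blocks = 200, scheme = c("atomic", "retrospective"),
                                condition = "easy", experiment = "exp1",
                                glm = glm_config(), n_mc = 100,
                                n_voxels = 50, seed = NULL) {
  scheme <- match.arg(scheme)
  with_seed(seed, {
    bb <- NULL
    for (b in seq_len(n_blocks)) {
      blk <- generate_block_design(condition, experiment,
                                   stimulus_pool = 0:9, scheme = scheme)
      est <- estimate_sequence_bias(blk, glm, n_mc = n_mc,
                                    n_voxels = n_voxels, method = "mixing")
      bb <- rbind(bb, est$bias)
    }
    # the Monte-Carlo error of the grand mean is governed by the spread of
    # per-block biases (blocks are the independent unit, draws within a block
    # share its sequence)
    list(block_bias = bb,
         mean_bias = colMeans(bb),
         se_of_mean = apply(bb, 2L, stats::sd) / sqrt(n_blocks),
         block_variance = apply(bb, 2L, stats::var),
         block_mean_square = colMeans(bb^2),
         n_blocks = n_blocks, scheme = scheme)
  })
}
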