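test_that("canonical HRF has the expected double-gamma shape", {
  cfg <- glm_config()
  h <- canonical_hrf(cfg)
  dt <- cfg$tr_s / cfg$microtime
  expect_equal(h[1], 0)
  peak_t <- (which.max(h) - 1) * dt
  expect_gte(peak_t, 4); expect_lte(peak_t, 6)
  expect_gt(sum(h) * dt, 0)  # undershoot at ratio 1/6 does not cancel the peak
})

test_that("instruction Fourier basis is a zero-mean windowed harmonic set", {
  cfg <- glm_config()
  fb <- build_fourier_basis(20, cfg, 400)
  expect_equal(ncol(fb), 20)
  expect_lt(max(abs(colSums(fb))), 1e-10)
  # supports of phases >= 44 s apart do not overlap
  fb2 <- build_fourier_basis(20 + 44, cfg, 400)
  expect_equal(sum(abs(fb) * abs(fb2)), 0)
  expect_warning(build_fourier_basis(790, cfg, 400), "truncated")
})

test_that("DCT drift basis follows the floor(2*T/cutoff) convention", {
  expect_equal(ncol(build_dct_highpass(390, glm_config(hpf_cutoff_s = 128))), 12)
  X <- build_dct_highpass(390, glm_config(hpf_cutoff_s = 128))
  G <- crossprod(X)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_equal(ncol(build_dct_highpass(390, glm_config(hpf_cutoff_s = Inf))), 0)
})

test_that("the LSS design isolates exactly one trial per model", {
  d <- generate_experiment_design("exp1", seed = 2,
                                  blocks_per_condition_per_run = 1, n_runs = 1)
  ev <- d$events
  cfg <- default_glm_config("exp1")
  nv <- d$n_volumes[1]
  des5 <- build_lss_design(ev, 5, cfg, nv)
  des6 <- build_lss_design(ev, 6, cfg, nv)
  expect_equal(des5$labels[1:2], c("target_trial", "other_trials"))
  # target + others always sum to the same all-trials regressor
  expect_equal(des5$X[, 1] + des5$X[, 2], des6$X[, 1] + des6$X[, 2])
  expect_false(isTRUE(all.equal(des5$X[, 1], des6$X[, 1])))
  # nuisance block: the run Fourier set, feedback, constant, drifts
  K <- ncol(build_dct_highpass(nv, cfg))
  expect_equal(ncol(des5$X), 2 + 20 + 1 + 1 + K)
  expect_error(build_lss_design(ev, 999, cfg, nv), "out of range")
})

test_that("noiseless isolated trials are recovered exactly", {
  ev <- sparse_trial_events()
  cfg <- glm_config(hpf_cutoff_s = Inf, ar1 = "off")
  nv <- ceiling((max(ev$onset) + 35) / cfg$tr_s)
  reg <- rulemvpa:::build_run_regressors(ev, cfg, nv)
  set.seed(1)
  A <- matrix(rnorm(8 * 30, mean = 2), 8, 30)   # true amplitudes x voxels
  Y <- t(reg$trial %*% A + 5)                   # plus a baseline offset
  fit <- fit_lss(Y, ev, cfg)
  expect_lt(max(abs(fit$betas - A)), 1e-6)
  # prewhitening at a fixed rho leaves the exact solution unchanged
  fitw <- fit_lss(Y, ev, glm_config(hpf_cutoff_s = Inf, ar1 = "fixed",
                                    ar1_rho = 0.4))
  expect_lt(max(abs(fitw$betas - A)), 1e-6)
})

test_that("ar1 = off and a fixed rho of zero are identical", {
  ev <- sparse_trial_events(spacing_s = 4)
  nv <- ceiling((max(ev$onset) + 35) / 2)
  set.seed(2)
  Y <- matrix(rnorm(20 * nv), 20, nv)
  f1 <- fit_lss(Y, ev, glm_config(hpf_cutoff_s = Inf, ar1 = "off"))
  f2 <- fit_lss(Y, ev, glm_config(hpf_cutoff_s = Inf, ar1 = "fixed", ar1_rho = 0))
  expect_identical(f1$betas, f2$betas)
})

test_that("whitening with the true rho reduces beta variance under AR(1) noise", {
  ev <- sparse_trial_events(n_trials = 8, spacing_s = 3)
  cfg0 <- glm_config(hpf_cutoff_s = Inf, ar1 = "off")
  cfgw <- glm_config(hpf_cutoff_s = Inf, ar1 = "fixed", ar1_rho = 0.6)
  nv <- ceiling((max(ev$onset) + 35) / 2)
  reg <- rulemvpa:::build_run_regressors(ev, cfg0, nv)
  A <- matrix(1, 8, 1)
  set.seed(3)
  err0 <- errw <- matrix(NA_real_, 100, 8)
  for (i in 1:100) {
    noise <- rulemvpa:::ar1_noise(nv, 1, 1, 0.6)
    Y <- t(reg$trial %*% A + noise)
    err0[i, ] <- fit_lss(Y, ev, cfg0)$betas - 1
    errw[i, ] <- fit_lss(Y, ev, cfgw)$betas - 1
  }
  expect_lt(mean(apply(errw, 2, var)), mean(apply(err0, 2, var)))
})

test_that("collinear designs are rejected with named columns", {
  # with only two trials at the same onset, target and other regressors
  # coincide and the trial-wise normal equations are singular
  ev <- sparse_trial_events(n_trials = 2, stimuli = c(0, 0))
  ev$onset[2] <- ev$onset[1]
  nv <- ceiling((max(ev$onset) + 35) / 2)
  Y <- matrix(rnorm(10 * nv), 10, nv)
  expect_error(fit_lss(Y, ev, glm_config(hpf_cutoff_s = Inf, ar1 = "off")),
               "collinear")
})

test_that("the trial mixing matrix reproduces noiseless LSS fits", {
  blk <- generate_block_design("easy", "exp1", stimulus_pool = 0:3, seed = 9)
  geo <- rulemvpa:::block_run_geometry(blk, glm_config(ar1 = "off"))
  cfg <- glm_config(ar1 = "off")
  M <- lss_trial_mixing(geo$events, cfg, geo$n_volumes)
  reg <- rulemvpa:::build_run_regressors(geo$events, cfg, geo$n_volumes)
  set.seed(4)
  P <- matrix(rnorm(16 * 25), 16, 25)
  direct <- fit_lss(t(reg$trial %*% P), geo$events, cfg)$betas
  expect_lt(max(abs(M %*% P - direct)), 1e-8)
})
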