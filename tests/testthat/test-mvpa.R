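test_that("stage similarity matches the brute-force pairwise-Pearson oracle", {
  # the two-stimulus worked example
  B <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 5), c(4, 3, 2, 1), c(4, 3, 1, 2))
  labels <- c("S1", "S1", "S2", "S2")
  res <- stage_similarity(B, labels)
  o <- brute_delta(B, labels)
  expect_equal(res$delta, o$delta, tolerance = 1e-12)
  expect_equal(res$mean_same_r, o$mean_same, tolerance = 1e-12)
  expect_equal(res$n_same_pairs, 2)
  expect_equal(res$n_diff_pairs, 4)

  set.seed(10)
  for (i in 1:100) {
    B <- matrix(rnorm(8 * 50), 8, 50)
    labels <- sample(rep(1:4, 2))
    res <- stage_similarity(B, labels)
    o <- brute_delta(B, labels)
    expect_lt(abs(res$delta - o$delta), 1e-12)
    expect_equal(res$n_same_pairs, 4)
    expect_equal(res$n_diff_pairs, 24)
  }
})

test_that("perfectly repeated, orthogonalized patterns give unit same-correlation", {
  pat <- qr.Q(qr(matrix(rnorm(40 * 4), 40, 4)))  # orthonormal columns
  B <- t(pat[, c(1, 1, 2, 2, 3, 3, 4, 4)])
  res <- stage_similarity(B, rep(1:4, each = 2))
  expect_equal(res$mean_same_r, 1, tolerance = 1e-10)
  expect_gt(res$delta, 0)
})

test_that("similarity is invariant to a common voxel permutation", {
  set.seed(11)
  B <- matrix(rnorm(8 * 60), 8, 60)
  labels <- rep(1:4, 2)
  perm <- sample(60)
  expect_equal(stage_similarity(B, labels)$delta,
               stage_similarity(B[, perm], labels)$delta, tolerance = 1e-14)
})

test_that("degenerate similarity inputs are rejected", {
  B <- matrix(rnorm(6 * 20), 6, 20)
  expect_error(stage_similarity(B, c(1, 1, 1, 2, 2, 2)), "exactly twice")
  B2 <- matrix(rnorm(4 * 20), 4, 20)
  B2[2, ] <- 3  # constant pattern
  expect_error(stage_similarity(B2, c(1, 1, 2, 2)), "constant")
  expect_error(stage_similarity(matrix(1:4, 4, 1), c(1, 1, 2, 2)), "voxels")
})

test_that("white-matter bias adjustment uses the regression intercept", {
  roi <- c(0.1, 0.3, 0.2, 0.4, 0.25)
  expect_warning(a <- wm_bias_adjust(roi, rep(0.05, 5)), "degenerate")
  expect_equal(a, mean(roi))
  expect_equal(wm_bias_adjust(roi, roi), 0, tolerance = 1e-12)
  wm <- c(0.02, -0.01, 0.05, 0.0, 0.03)
  expect_equal(wm_bias_adjust(0.5 * wm + 0.2, wm), 0.2, tolerance = 1e-12)
  expect_error(wm_bias_adjust(1:4, 1:3), "aligned")
})

test_that("subject tables aggregate blocks and stages as specified", {
  # hand-built beta set: 2 blocks x 2 stages, 8 trials each, 30 voxels
  set.seed(12)
  meta <- expand.grid(t = 1:8, stage = 1:2, block = 1:2)
  meta$condition <- ifelse(meta$block == 1, "learning", "control")
  meta$stimulus_id <- c(replicate(4, sample(rep(1:4, 2))))
  meta$repetition <- 2 * meta$stage - 1 +
    ave(seq_len(nrow(meta)), meta$block, meta$stimulus_id, FUN = seq_along) %% 2
  meta$phase <- "implementation"
  betas <- matrix(rnorm(32 * 30), 32, 30)
  bs <- toy_beta_set(betas, meta)
  tab <- subject_similarity(bs, roi_mask = 1:30, roi = "test")
  expect_equal(nrow(tab), 4)  # 2 conditions x 2 stages
  # cell values equal the direct statistic on the corresponding trials
  for (i in seq_len(nrow(tab))) {
    sel <- meta$condition == tab$condition[i] & meta$stage == tab$stage[i]
    expect_equal(tab$delta[i],
                 stage_similarity(betas[sel, ], meta$stimulus_id[sel])$delta,
                 tolerance = 1e-12)
  }
  agg <- subject_similarity(bs, roi_mask = 1:30, roi = "test",
                            aggregate_stages = list(all = 1:2))
  for (cc in c("learning", "control"))
    expect_equal(agg$delta[agg$condition == cc],
                 mean(tab$delta[tab$condition == cc]))
})

test_that("correct-only filtering drops incomplete cells", {
  set.seed(13)
  meta <- data.frame(block = 1, condition = "learning", stage = 1,
                     stimulus_id = rep(1:4, 2), phase = "implementation",
                     repetition = rep(1:2, each = 4))
  betas <- matrix(rnorm(8 * 20), 8, 20)
  bs <- toy_beta_set(betas, meta)
  flags <- rep(TRUE, 8); flags[1] <- FALSE
  out <- block_similarity(bs, 1:20, correct_only = TRUE, correct_flags = flags)
  expect_true(is.na(out$delta[1]))
  out2 <- block_similarity(bs, 1:20)
  expect_false(anyNA(out2$delta))
})

test_that("searchlight geometry and local estimates are correct", {
  expect_equal(nrow(searchlight_offsets(3)), 123)
  expect_equal(nrow(searchlight_offsets(1)), 7)

  # one homogeneous signal region: the central searchlight approximates the
  # full-ROI delta
  set.seed(14)
  dims <- c(9L, 9L, 9L)
  mask <- array(TRUE, dims)
  nvox <- prod(dims)
  meta <- data.frame(block = 1, condition = "learning", stage = 1,
                     stimulus_id = rep(1:4, 2), phase = "implementation",
                     repetition = rep(1:2, each = 4))
  pat <- matrix(rnorm(4 * nvox), 4, nvox)
  betas <- pat[rep(1:4, 2), ] + 0.8 * matrix(rnorm(8 * nvox), 8, nvox)
  bs <- toy_beta_set(betas, meta, mask_voxels = seq_len(nvox))
  maps <- searchlight_similarity(bs, mask, radius = 3)
  center <- maps$learning$stage1[5, 5, 5]
  full <- stage_similarity(betas, meta$stimulus_id)$delta
  expect_false(is.na(center))
  expect_lt(abs(center - full), 0.15)
  # an edge voxel has fewer sphere voxels but still a value
  expect_false(is.na(maps$learning$stage1[1, 1, 1]))
})
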