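long_table <- function(Y, f1 = "A", f2 = "B") {
  n <- nrow(Y)
  cells <- expand.grid(b = 1:2, a = 1:2)  # last factor fastest
  cells <- cells[, c("a", "b")]
  out <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(subject = i, A = cells$a, B = cells$b, value = Y[i, ])))
  names(out)[2:3] <- c(f1, f2)
  out
}

test_that("rm_anova matches the classical error-strata oracle on 2x2 tables", {
  set.seed(20)
  for (rep_ in 1:5) {
    Y <- matrix(rnorm(6 * 4, mean = 0.3), 6, 4)
    tab <- long_table(Y)
    got <- rm_anova(tab, dv = "value", subject = "subject", within = c("A", "B"))
    oracle <- aov_rm_oracle(tab, "value", "subject", c("A", "B"))
    expect_equal(got$F[got$effect == "A"], unname(oracle["A"]), tolerance = 1e-8)
    expect_equal(got$F[got$effect == "B"], unname(oracle["B"]), tolerance = 1e-8)
    expect_equal(got$F[got$effect == "A:B"], unname(oracle["A:B"]),
                 tolerance = 1e-8)
    # 2-level factors admit no sphericity violation
    expect_true(all(got$gg_epsilon == 1))
    # partial eta^2 identity
    expect_equal(got$partial_eta_sq,
                 got$F * got$df_num / (got$F * got$df_num + got$df_den),
                 tolerance = 1e-12)
  }
})

test_that("the constant term equals the squared one-sample t", {
  set.seed(21)
  vals <- rnorm(10, mean = 0.5)
  tab <- data.frame(subject = 1:10, cond = "x", value = vals)
  got <- rm_anova(tab, dv = "value", subject = "subject", within = "cond")
  tt <- one_sample_t(vals)
  expect_equal(got$F[got$effect == "constant"], tt$t^2, tolerance = 1e-10)
  expect_equal(got$p_uncorrected[got$effect == "constant"], tt$p_two_sided,
               tolerance = 1e-10)
})

test_that("Greenhouse-Geisser epsilon is bounded and only shrinks p upward", {
  set.seed(22)
  # 4-level factor with correlated cells (epsilon < 1) and a real level
  # effect so that F > 1 and the correction can only be conservative
  n <- 12
  base <- rnorm(n)
  Y <- cbind(base + rnorm(n, sd = 0.2), base + 1 + rnorm(n, sd = 0.2),
             2 + rnorm(n), 3 + rnorm(n, sd = 3))
  tab <- do.call(rbind, lapply(1:n, function(i)
    data.frame(subject = i, rep = 1:4, value = Y[i, ])))
  got <- rm_anova(tab, dv = "value", subject = "subject", within = "rep")
  row <- got[got$effect == "rep", ]
  expect_gt(row$gg_epsilon, 1 / 3)
  expect_lte(row$gg_epsilon, 1)
  expect_lt(row$gg_epsilon, 1 - 1e-6)
  expect_gte(row$p_gg, row$p_uncorrected)
})

test_that("missing cells are refused with guidance", {
  tab <- data.frame(subject = c(1, 1, 2), A = c(1, 2, 1), value = rnorm(3))
  expect_error(rm_anova(tab, dv = "value", subject = "subject", within = "A"),
               "aggregate or impute")
})

test_that("linear-trend contrasts detect a built-in trend", {
  set.seed(23)
  n <- 15
  trend <- outer(rep(1, n), scale(1:4, scale = FALSE)[, 1]) * 0.5
  Y <- trend + matrix(rnorm(n * 4, sd = 0.3), n, 4)
  tab <- do.call(rbind, lapply(1:n, function(i)
    data.frame(subject = i, rep = 1:4, value = Y[i, ])))
  res <- rm_contrast(tab, dv = "value", subject = "subject", within = "rep",
                     weights = list(rep = poly_weights(4, 1)))
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, n - 1)
  expect_lt(res$p_uncorrected, 0.001)
})

test_that("one-sample t handles the textbook cases", {
  sym <- c(-2, -1, 1, 2)
  tt <- one_sample_t(sym)
  expect_equal(tt$t, 0)
  expect_equal(tt$p_two_sided, 1)
  vals <- c(1, 1, 1, 1, 2)
  tt2 <- one_sample_t(vals)
  expect_equal(tt2$t, mean(vals) / (sd(vals) / sqrt(5)), tolerance = 1e-12)
  expect_error(one_sample_t(1), "at least 2")
  expect_error(one_sample_t(c(3, 3, 3)), "zero variance")
})

test_that("max-statistic permutation p values behave as a valid FWE bound", {
  # all-zero maps: every corrected p is 1
  zero <- matrix(0, 10, 5)
  r0 <- maxstat_fwe(zero, n_permutations = 99, seed = 1)
  expect_true(all(r0$p_fwe == 1))

  # one voxel with a huge constant effect reaches the minimal p
  set.seed(2)
  X <- matrix(rnorm(20 * 6, sd = 0.1), 20, 6)
  X[, 3] <- 5
  r1 <- maxstat_fwe(X, n_permutations = 999, seed = 3)
  expect_equal(r1$p_fwe[3], 1 / 1000)
  expect_true(all(r1$p_fwe >= r1$p_uncorrected))

  # deterministic given the seed
  r2 <- maxstat_fwe(X, n_permutations = 999, seed = 3)
  expect_identical(r1$p_fwe, r2$p_fwe)
  expect_error(maxstat_fwe(list(array(0, c(2, 2, 2))),
                           mask = array(FALSE, c(2, 2, 2))), "empty")
})

test_that("the constant-term test keeps its nominal level on null tables", {
  set.seed(24)
  rej <- 0
  reps <- 500
  for (i in seq_len(reps)) {
    Y <- matrix(rnorm(15 * 4), 15, 4)
    tab <- long_table(Y)
    got <- rm_anova(tab, dv = "value", subject = "subject",
                    within = c("A", "B"))
    if (got$p_uncorrected[got$effect == "constant"] < 0.05) rej <- rej + 1
  }
  ci <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})
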