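# Group-level statistics: fully within-subject factorial ANOVA built from
# orthonormal contrast variables (so the Greenhouse-Geisser epsilon and
# partial eta squared fall out of the same decomposition), one-sample tests,
# and max-statistic sign-flip permutation FWE for maps.

# Orthonormal within-factor contrasts (polynomial) and the normalized unit
# vector used for factors not in an effect.
factor_contrast <- function(k) {
  if (k == 1L) return(matrix(1, 1, 0))
  cp <- stats::contr.poly(k)
  cp / rep(sqrt(colSums(cp^2)), each = k)
}
unit_column <- function(k) matrix(rep(1 / sqrt(k), k), k, 1)

# Arrange a long table into a subjects x cells matrix, cells ordered so the
# last factor varies fastest (matching the Kronecker product of contrasts).
cell_matrix <- function(table, dv, subject, within) {
  levs <- lapply(within, function(f) {
    x <- table[[f]]
    if (is.factor(x)) levels(x) else sort(unique(x))
  })
  names(levs) <- within
  cells <- expand.grid(rev(levs), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells <- cells[, rev(seq_along(within)), drop = FALSE]
  names(cells) <- within
  subjects <- sort(unique(table[[subject]]))
  Y <- matrix(NA_real_, length(subjects), nrow(cells))
  key_tab <- do.call(paste, c(lapply(within, function(f) as.character(table[[f]])),
                              sep = "\r"))
  key_cell <- do.call(paste, c(lapply(within, function(f) as.character(cells[[f]])),
                               sep = "\r"))
  for (i in seq_along(subjects)) {
    sel <- table[[subject]] == subjects[i]
    m <- match(key_cell, key_tab[sel])
    Y[i, ] <- table[[dv]][sel][m]
  }
  if (anyNA(Y))
    stop_input("missing cells in the repeated-measures table; ",
               "aggregate or impute upstream before calling rm_anova")
  list(Y = Y, levels = levs, cells = cells, subjects = subjects)
}

rm_effect_row <- function(Y, C, effect) {
  n <- nrow(Y)
  q <- ncol(C)
  Z <- Y %*% C
  zbar <- colMeans(Z)
  Zc <- sweep(Z, 2L, zbar)
  ss_eff <- n * sum(zbar^2)
  ss_err <- sum(Zc^2)
  df1 <- q
  df2 <- q * (n - 1L)
  F <- (ss_eff / df1) / (ss_err / df2)
  if (q == 1L) {
    eps <- 1
  } else {
    S <- crossprod(Zc) / (n - 1L)
    eps <- sum(diag(S))^2 / (q * sum(S^2))
    eps <- min(max(eps, 1 / q), 1)
  }
  data.frame(effect = effect, F = F, df_num = df1, df_den = df2,
             gg_epsilon = eps,
             p_uncorrected = stats::pf(F, df1, df2, lower.tail = FALSE),
             p_gg = stats::pf(F, df1 * eps, df2 * eps, lower.tail = FALSE),
             partial_eta_sq = F * df1 / (F * df1 + df2))
}

#' Repeated-measures factorial ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA computed from orthonormal contrast variables:
#' for each effect, the per-subject contrast scores are formed by the
#' Kronecker product of polynomial contrasts (factors in the effect) and
#' normalized unit vectors (factors averaged over); F is the ratio of the
#' between- to within-subject mean squares of those scores, the
#' Greenhouse-Geisser epsilon comes from the contrast covariance, and the
#' constant term tests the grand mean against zero (equal to the squared
#' one-sample t).
#'
#' @param table Long data frame with one row per subject x cell.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param within Character vector of within-subject factor columns.
#' @return Data frame with one row per effect (constant, main effects and all
#'   interactions): `F`, `df_num`, `df_den`, `gg_epsilon`, `p_uncorrected`,
#'   `p_gg`, `partial_eta_sq`.
#' @export
rm_anova <- function(table, dv = "value", subject = "subject", within) {
  cm <- cell_matrix(table, dv, subject, within)
  Y <- cm$Y
  n <- nrow(Y)
  k <- vapply(cm$levels, length, 0L)
  total_df <- prod(k) - 1L
  if (n < total_df + 2L)
    warning("few subjects relative to the design; F tests may be unstable")
  if (n < 2L) stop_input("need at least 2 subjects")
  effects <- list(constant = character(0))
  for (m in seq_along(within)) {
    for (comb in utils::combn(within, m, simplify = FALSE)) {
      effects[[paste(comb, collapse = ":")]] <- comb
    }
  }
  rows <- lapply(names(effects), function(nm) {
    inc <- effects[[nm]]
    mats <- lapply(within, function(f)
      if (f %in% inc) factor_contrast(k[[f]]) else unit_column(k[[f]]))
    C <- Reduce(kronecker, mats)
    rm_effect_row(Y, C, nm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-contrast repeated-measures test (e.g. a linear trend)
#'
#' Applies one contrast per factor (defaults: averaging) and t-tests the
#' resulting per-subject score against zero, reported as `F = t^2` with 1 and
#' n - 1 degrees of freedom to match the factorial output.
#'
#' @inheritParams rm_anova
#' @param weights Named list mapping factor names to contrast weight vectors
#'   (one weight per level, in level order). Factors not named are averaged
#'   over. Use e.g. polynomial weights for a linear trend.
#' @export
rm_contrast <- function(table, dv = "value", subject = "subject", within,
                        weights) {
  cm <- cell_matrix(table, dv, subject, within)
  k <- vapply(cm$levels, length, 0L)
  mats <- lapply(within, function(f) {
    if (f %in% names(weights)) {
      w <- weights[[f]]
      if (length(w) != k[[f]]) stop_input("wrong weight length for ", f)
      matrix(w / sqrt(sum(w^2)), ncol = 1)
    } else unit_column(k[[f]])
  })
  C <- Reduce(kronecker, mats)
  rm_effect_row(cm$Y, C, paste(names(weights), collapse = ":"))
}

#' Polynomial contrast weights
#' @param k Number of levels.
#' @param degree Polynomial degree (1 = linear).
#' @export
poly_weights <- function(k, degree = 1) stats::contr.poly(k)[, degree]

#' One-sample t test
#'
#' @param values Numeric vector (e.g. per-subject effects or paired
#'   differences).
#' @param mu Null value (default 0).
#' @return List with `t`, `df`, `p_two_sided`, `p_greater`, `p_less`, `mean`,
#'   `se`.
#' @export
one_sample_t <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop_input("need at least 2 values")
  if (stats::var(values) == 0) stop_input("zero variance")
  tt <- stats::t.test(values, mu = mu)
  t <- unname(tt$statistic)
  df <- unname(tt$parameter)
  list(t = t, df = df, p_two_sided = tt$p.value,
       p_greater = stats::pt(t, df, lower.tail = FALSE),
       p_less = stats::pt(t, df),
       mean = mean(values), se = stats::sd(values) / sqrt(n))
}

#' Max-statistic sign-flip permutation FWE for group maps
#'
#' One-sample group inference over voxels with family-wise error control by
#' the permutation distribution of the maximum t statistic under random sign
#' flips of whole subject maps. The corrected p at voxel v is
#' `(1 + #\{max-t(perm) >= t(v)\}) / (n_permutations + 1)`; per-voxel
#' uncorrected permutation p values from the same flips are also returned
#' (corrected >= uncorrected everywhere by construction).
#'
#' @param subject_maps Subjects x voxels matrix (maps already masked), or a
#'   list of 3D arrays plus `mask`.
#' @param mask Optional logical 3D array when `subject_maps` is a list of
#'   arrays.
#' @param n_permutations Number of random sign flips (default 1000).
#' @param seed Optional integer seed (results are deterministic given it).
#' @return List with `t` (observed t per voxel), `p_fwe`, `p_uncorrected`,
#'   `max_t_distribution`, `n_permutations`, and `mask`.
#' @export
maxstat_fwe <- function(subject_maps, mask = NULL, n_permutations = 1000,
                        seed = NULL) {
  if (is.list(subject_maps) && !is.matrix(subject_maps)) {
    if (is.null(mask)) stop_input("`mask` required with a list of maps")
    if (!any(mask)) stop_input("mask is empty")
    subject_maps <- do.call(rbind, lapply(subject_maps, function(a) a[mask]))
  }
  X <- as.matrix(subject_maps)
  n <- nrow(X)
  tstat <- function(M) {
    m <- colMeans(M)
    s <- sqrt(pmax(colSums(M^2) - n * m^2, 0) / (n - 1L))
    t <- m / (s / sqrt(n))
    # degenerate voxels: zero spread gives t = 0 (null) or +/-Inf (constant
    # nonzero effect), keeping the permutation comparisons well defined
    t[s == 0] <- sign(m[s == 0]) * Inf
    t[s == 0 & m == 0] <- 0
    t
  }
  t_obs <- tstat(X)
  with_seed(seed, {
    exceed <- numeric(length(t_obs))
    maxs <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      tb <- tstat(X * signs)
      maxs[b] <- max(tb)
      exceed <- exceed + (tb >= t_obs)
    }
    p_fwe <- vapply(t_obs, function(t0) (1 + sum(maxs >= t0)) /
                      (n_permutations + 1), 0)
    p_unc <- (1 + exceed) / (n_permutations + 1)
    list(t = t_obs, p_fwe = p_fwe, p_uncorrected = p_unc,
         max_t_distribution = maxs, n_permutations = n_permutations,
         mask = mask)
  })
}
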