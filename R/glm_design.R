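# Design-matrix construction for the single-trial GLM: canonical double-gamma
# HRF sampled at microtime resolution, event-locked Fourier basis for the
# instruction phase, and a discrete-cosine high-pass drift basis.

#' GLM configuration
#'
#' Bundles the timing and filtering parameters used to build design matrices
#' and fit the least-squares-separate (LSS) single-trial model.
#'
#' @param tr_s Repetition time in seconds (default 2).
#' @param hpf_cutoff_s High-pass filter cutoff in seconds. Use `128` for the
#'   shorter-block experiment, `256` for the longer one, or `Inf` to disable
#'   drift modelling. Must exceed `2 * tr_s`.
#' @param ar1 Autocorrelation handling: `"estimate"` pools a single lag-1
#'   coefficient per run from model residuals, `"off"` fits ordinary least
#'   squares, `"fixed"` uses `ar1_rho` as given.
#' @param ar1_rho Fixed AR(1) coefficient in `[0, 1)`; only read when
#'   `ar1 = "fixed"`.
#' @param fourier_span_s Length in seconds of the instruction-phase Fourier
#'   window (default 44).
#' @param fourier_n Number of Fourier regressors per instruction phase; must be
#'   even (default 20, i.e. an order-10 sine + cosine set).
#' @param microtime Number of microtime bins per TR at which regressors are
#'   built before resampling to the volume grid (default 16).
#' @param microtime_onset Microtime bin at which each volume is sampled
#'   (default 8, the middle bin).
#' @param hrf Double-gamma HRF parameters, see [hrf_params()].
#'
#' @return An object of class `glm_config`.
#' @export
glm_config <- function(tr_s = 2, hpf_cutoff_s = 128,
                       ar1 = c("estimate", "off", "fixed"), ar1_rho = NULL,
                       fourier_span_s = 44, fourier_n = 20,
                       microtime = 16, microtime_onset = 8,
                       hrf = hrf_params()) {
  ar1 <- match.arg(ar1)
  assert_scalar_number(tr_s, "tr_s", min = 1e-6)
  assert_scalar_number(hpf_cutoff_s, "hpf_cutoff_s", min = 0)
  if (is.finite(hpf_cutoff_s) && hpf_cutoff_s <= 2 * tr_s)
    stop_input("`hpf_cutoff_s` must exceed 2 * tr_s")
  if (fourier_n %% 2 != 0) stop_input("`fourier_n` must be even")
  if (ar1 == "fixed") {
    assert_scalar_number(ar1_rho, "ar1_rho", min = 0, max = 1 - 1e-9)
  }
  structure(list(tr_s = tr_s, hpf_cutoff_s = hpf_cutoff_s, ar1 = ar1,
                 ar1_rho = ar1_rho, fourier_span_s = fourier_span_s,
                 fourier_n = as.integer(fourier_n),
                 microtime = as.integer(microtime),
                 microtime_onset = as.integer(microtime_onset), hrf = hrf),
            class = "glm_config")
}

#' Canonical HRF parameters
#'
#' Double-gamma parameterisation: response peak at `peak_delay_s`, undershoot
#' peaking at `undershoot_delay_s`, unit dispersions, undershoot scaled by
#' `1 / ratio`, truncated at `length_s`.
#'
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       ratio = 6, length_s = 32) {
  list(peak_delay_s = peak_delay_s, undershoot_delay_s = undershoot_delay_s,
       peak_dispersion = peak_dispersion,
       undershoot_dispersion = undershoot_dispersion,
       ratio = ratio, length_s = length_s)
}

#' Sample the canonical double-gamma HRF at microtime resolution
#'
#' @param config A [glm_config()].
#' @return Numeric kernel sampled every `tr_s / microtime` seconds from 0 to
#'   the kernel length, scaled to unit peak.
#' @export
canonical_hrf <- function(config = glm_config()) {
  p <- config$hrf
  dt <- config$tr_s / config$microtime
  t <- seq(0, p$length_s, by = dt)
  # gamma densities with unit rate scaled by dispersion
  h <- stats::dgamma(t, shape = p$peak_delay_s / p$peak_dispersion,
                     rate = 1 / p$peak_dispersion) -
    stats::dgamma(t, shape = p$undershoot_delay_s / p$undershoot_dispersion,
                  rate = 1 / p$undershoot_dispersion) / p$ratio
  h / max(h)
}

# Indices (1-based, microtime grid) at which volumes are sampled.
microtime_sample_index <- function(n_volumes, config) {
  (seq_len(n_volumes) - 1L) * config$microtime + config$microtime_onset
}

# Convolve stick onsets with the canonical HRF and resample to the TR grid.
# Each stick contributes a copy of the kernel shifted to its onset bin, so the
# convolution is evaluated directly at the sampled microtime bins.
# Returns an n_volumes x length(onsets) matrix when collapse = FALSE, or a
# single summed column when collapse = TRUE.
hrf_regressor <- function(onsets, config, n_volumes, collapse = FALSE) {
  dt <- config$tr_s / config$microtime
  n_micro <- n_volumes * config$microtime
  h <- canonical_hrf(config)
  lh <- length(h)
  idx <- microtime_sample_index(n_volumes, config)
  bins <- floor(onsets / dt) + 1L
  if (any(bins < 1L | bins > n_micro))
    stop_input("event onset outside the run")
  one <- function(b) {
    col <- numeric(n_volumes)
    pos <- idx - b + 1L
    ok <- pos >= 1L & pos <= lh
    col[ok] <- h[pos[ok]]
    col
  }
  if (collapse) {
    out <- numeric(n_volumes)
    for (b in bins) out <- out + one(b)
    matrix(out, ncol = 1)
  } else {
    vapply(bins, one, numeric(n_volumes))
  }
}

# Same evaluation for a boxcar of given duration (used by the simulator for
# sustained instruction-phase activity): the boxcar is a sum of microtime
# sticks across its support.
hrf_boxcar <- function(onset_s, duration_s, config, n_volumes) {
  dt <- config$tr_s / config$microtime
  n_bins <- max(1L, round(duration_s / dt))
  on <- onset_s + (seq_len(n_bins) - 1L) * dt
  hrf_regressor(on, config, n_volumes, collapse = TRUE) * dt
}

#' Fourier basis for the instruction phases of a run
#'
#' An order-`fourier_n / 2` sine-plus-cosine set spanning `fourier_span_s`
#' seconds, time-locked to each instruction-phase onset and zero outside the
#' windows. The harmonics model the instruction-phase response directly (no
#' HRF convolution), so the response shape is unconstrained; one set of
#' coefficients is shared by all instruction phases of a run (the basis
#' functions superpose across onsets), which keeps early implementation
#' trials identifiable inside the window.
#'
#' @param onset_s Onset(s) of the instruction phase(s), seconds from run
#'   start.
#' @param config A [glm_config()].
#' @param n_volumes Number of volumes in the run.
#' @return Matrix with `n_volumes` rows and `fourier_n` columns, ordered
#'   sin(k), cos(k) for harmonics k = 1..order.
#' @export
build_fourier_basis <- function(onset_s, config, n_volumes) {
  span <- config$fourier_span_s
  order <- config$fourier_n %/% 2L
  dt <- config$tr_s / config$microtime
  # time of each sampled volume (middle microtime bin convention)
  tv <- (microtime_sample_index(n_volumes, config) - 1L) * dt
  if (any(onset_s + span > n_volumes * config$tr_s))
    warning("Fourier window overruns the run end; basis truncated")
  out <- matrix(0, n_volumes, config$fourier_n)
  for (on in onset_s) {
    u <- tv - on
    inside <- u >= 0 & u < span
    for (k in seq_len(order)) {
      ang <- 2 * pi * k * u[inside] / span
      out[inside, 2L * k - 1L] <- out[inside, 2L * k - 1L] + sin(ang)
      out[inside, 2L * k] <- out[inside, 2L * k] + cos(ang)
    }
  }
  colnames(out) <- as.vector(rbind(paste0("sin", seq_len(order)),
                                   paste0("cos", seq_len(order))))
  out
}

#' Discrete-cosine high-pass drift basis
#'
#' Standard DCT drift set: `K = floor(2 * n_volumes * tr_s / cutoff)` mutually
#' orthogonal cosine columns (the constant term is excluded; runs carry a
#' separate intercept).
#'
#' @param n_volumes Number of volumes.
#' @param config A [glm_config()].
#' @return Matrix with `n_volumes` rows and `K` columns (0 columns when the
#'   cutoff is infinite).
#' @export
build_dct_highpass <- function(n_volumes, config = glm_config()) {
  if (n_volumes < 2) stop_input("need at least 2 volumes")
  if (!is.finite(config$hpf_cutoff_s))
    return(matrix(numeric(0), n_volumes, 0))
  K <- floor(2 * n_volumes * config$tr_s / config$hpf_cutoff_s)
  if (K < 1) return(matrix(numeric(0), n_volumes, 0))
  n <- n_volumes
  t <- seq_len(n) - 1L
  out <- vapply(seq_len(K), function(k)
    sqrt(2 / n) * cos(pi * (2 * t + 1) * k / (2 * n)), numeric(n))
  colnames(out) <- paste0("dct", seq_len(K))
  out
}
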