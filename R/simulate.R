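# Ground-truthed synthetic BOLD simulation.
#
# The generator emulates the statistical structure the analysis assumes:
# trial-unique activations convolved with the canonical HRF at TR = 2 s and
# overlapping at 2-4 s SOAs; a block-local multivoxel rule-identity code in
# the signal prefrontal region (memorization conditions only); stimulus- and
# response-identity codes in the visual and motor regions in all conditions;
# declining mean amplitude over repetitions; sustained instruction-phase and
# event-related feedback activity; stationary AR(1) voxel noise; and a latent
# trial-amplitude coupling between the prefrontal seed and the striatum that
# strengthens from early to late trials in the learning condition only.

#' Simulation configuration
#'
#' All pattern parameters are standard deviations of voxel-wise Gaussian
#' draws, in the same arbitrary units as `amp_by_repetition`.
#'
#' @param sigma_identity SD of the block-local rule-identity code in the
#'   signal prefrontal region (absent in the control condition).
#' @param sigma_stim,sigma_resp SD of the stimulus-identity code (visual
#'   region) and response-identity code (motor region), present in all
#'   conditions.
#' @param trial_noise_sd SD of the i.i.d. per-trial pattern noise added in
#'   every responsive region.
#' @param amp_by_repetition Mean activation per stimulus repetition (length 8;
#'   the first 4 are used for the 4-repetition experiment). Declining by
#'   default.
#' @param amp_noise_sd SD of the per-trial, per-region amplitude jitter (the
#'   carrier of the connectivity coupling).
#' @param instruction_amp Amplitude of the sustained (boxcar) instruction-phase
#'   response added to gray-matter regions.
#' @param feedback_amp Amplitude of the event-related feedback response.
#' @param noise_sd Stationary SD of the AR(1) measurement noise.
#' @param ar1_rho AR(1) coefficient of the measurement noise, in `[0, 1)`.
#' @param coupling Named list per condition with elements `early` and `late`:
#'   correlation between the prefrontal and striatal amplitude jitters for
#'   trials in the early (repetitions 1-2) and late (repetitions 7-8)
#'   windows; intermediate repetitions use the early value.
#' @param behavior Behavioral generative model, see [behavior_model()].
#' @param tr_s Repetition time (default 2).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(sigma_identity = 1.0, sigma_stim = 1.0,
                              sigma_resp = 1.0, trial_noise_sd = 1.0,
                              amp_by_repetition = c(3.0, 2.4, 2.0, 1.7,
                                                    1.5, 1.35, 1.25, 1.2),
                              amp_noise_sd = 0.5,
                              instruction_amp = 2.0, feedback_amp = 1.5,
                              noise_sd = 1.0, ar1_rho = 0.3,
                              coupling = list(
                                easy = c(early = 0.1, late = 0.1),
                                difficult = c(early = 0.1, late = 0.1),
                                learning = c(early = 0.1, late = 0.6),
                                control = c(early = 0.1, late = 0.1)),
                              behavior = behavior_model(), tr_s = 2) {
  for (nm in c("sigma_identity", "sigma_stim", "sigma_resp", "trial_noise_sd",
               "amp_noise_sd", "noise_sd"))
    assert_scalar_number(get(nm), nm, min = 0)
  assert_scalar_number(ar1_rho, "ar1_rho", min = 0, max = 1 - 1e-9)
  structure(list(sigma_identity = sigma_identity, sigma_stim = sigma_stim,
                 sigma_resp = sigma_resp, trial_noise_sd = trial_noise_sd,
                 amp_by_repetition = amp_by_repetition,
                 amp_noise_sd = amp_noise_sd,
                 instruction_amp = instruction_amp,
                 feedback_amp = feedback_amp,
                 noise_sd = noise_sd, ar1_rho = ar1_rho,
                 coupling = coupling, behavior = behavior, tr_s = tr_s),
            class = "simulation_config")
}

#' Behavioral generative model
#'
#' Error probabilities and response times per condition and repetition, plus
#' the perseveration mechanism: after an erroneous execution the participant
#' adopts the executed response as their subjective rule with probability
#' `perseveration`, so later repetitions of that error are subjectively
#' consistent but objectively wrong.
#'
#' @param error_prob Named list (condition) of per-repetition error
#'   probabilities (length >= n repetitions).
#' @param perseveration Probability of adopting an erroneously executed
#'   response as the new subjective rule.
#' @param omission_prob Probability of a response omission.
#' @param rt_mean_ms Named list (condition) of per-repetition RT means.
#' @param rt_sd_ms RT standard deviation.
#' @export
behavior_model <- function(
    error_prob = list(
      easy      = c(0.25, 0.12, 0.08, 0.05, 0.05, 0.04, 0.04, 0.03),
      difficult = c(0.55, 0.35, 0.25, 0.18, 0.15, 0.12, 0.10, 0.10),
      learning  = c(0.25, 0.12, 0.08, 0.05, 0.05, 0.04, 0.04, 0.03),
      control   = c(0.03, 0.03, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02)),
    perseveration = 0.5, omission_prob = 0,
    rt_mean_ms = list(
      easy      = c(1350, 1150, 1000, 900, 850, 820, 800, 790),
      difficult = c(1750, 1500, 1300, 1150, 1050, 1000, 960, 940),
      learning  = c(1350, 1150, 1000, 900, 850, 820, 800, 790),
      control   = c(850, 820, 800, 790, 780, 775, 770, 765)),
    rt_sd_ms = 150) {
  list(error_prob = error_prob, perseveration = perseveration,
       omission_prob = omission_prob, rt_mean_ms = rt_mean_ms,
       rt_sd_ms = rt_sd_ms)
}

# Simulate executed responses and RTs for every implementation trial of a
# design, in event order. Returns the behavioral table.
simulate_behavior <- function(design, config) {
  bm <- config$behavior
  impl <- design$events[design$events$phase == "implementation", ]
  n <- nrow(impl)
  executed <- integer(n)
  rt <- numeric(n)
  belief <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    cond <- impl$condition[i]
    rep_ <- impl$repetition[i]
    key <- paste(impl$block[i], impl$stimulus_id[i])
    if (is.null(belief[[key]])) belief[[key]] <- impl$instructed_response[i]
    if (stats::runif(1) < bm$omission_prob) {
      executed[i] <- NA_integer_
      rt[i] <- NA_real_
      next
    }
    p_err <- bm$error_prob[[cond]][rep_]
    if (stats::runif(1) < p_err) {
      wrong <- setdiff(0:2, belief[[key]])
      ex <- wrong[sample.int(length(wrong), 1L)]
      if (stats::runif(1) < bm$perseveration) belief[[key]] <- ex
    } else {
      ex <- belief[[key]]
    }
    executed[i] <- ex
    rt[i] <- max(200, stats::rnorm(1, bm$rt_mean_ms[[cond]][rep_], bm$rt_sd_ms))
  }
  data.frame(run = impl$run, block = impl$block, condition = impl$condition,
             stimulus_id = impl$stimulus_id, repetition = impl$repetition,
             stage = impl$stage, onset = impl$onset,
             instructed_response = impl$instructed_response,
             executed_response = executed, rt_ms = rt)
}

rep_window <- function(rep_) ifelse(rep_ >= 7L, "late", "early")

# Draw the latent ground truth: per-trial amplitudes per region (with the
# configured prefrontal-striatal coupling) and block-local identity patterns.
draw_ground_truth <- function(design, atlas, config, behavior) {
  impl <- design$events[design$events$phase == "implementation", ]
  n <- nrow(impl)
  regions <- names(atlas$regions)
  nvox <- vapply(regions, function(r) sum(atlas_mask(atlas, r)), 0L)
  base <- config$amp_by_repetition[impl$repetition]
  u <- stats::rnorm(n)  # latent coupling factor
  amp <- matrix(NA_real_, n, length(regions),
                dimnames = list(NULL, regions))
  rho <- vapply(seq_len(n), function(i)
    config$coupling[[impl$condition[i]]][[rep_window(impl$repetition[i])]], 0)
  for (r in regions) {
    jitter <- switch(r,
      vlpfc_signal = u,
      striatum = rho * u + sqrt(1 - rho^2) * stats::rnorm(n),
      stats::rnorm(n))
    amp[, r] <- base + config$amp_noise_sd * jitter
  }
  patterns <- list()
  for (blk in design$blocks) {
    b <- as.character(blk$block)
    stim <- blk$stimulus_set
    patterns[[b]] <- list()
    if (config$sigma_identity > 0 && blk$condition != "control" &&
        "vlpfc_signal" %in% regions)
      patterns[[b]]$vlpfc_signal <- matrix(
        stats::rnorm(length(stim) * nvox[["vlpfc_signal"]],
                     sd = config$sigma_identity),
        length(stim), dimnames = list(as.character(stim), NULL))
    if (config$sigma_stim > 0 && "visual" %in% regions)
      patterns[[b]]$visual <- matrix(
        stats::rnorm(length(stim) * nvox[["visual"]], sd = config$sigma_stim),
        length(stim), dimnames = list(as.character(stim), NULL))
    if (config$sigma_resp > 0 && "motor" %in% regions)
      patterns[[b]]$motor <- matrix(
        stats::rnorm(3L * nvox[["motor"]], sd = config$sigma_resp),
        3L, dimnames = list(as.character(0:2), NULL))
  }
  trial_noise <- lapply(regions, function(r)
    matrix(stats::rnorm(n * nvox[[r]], sd = config$trial_noise_sd), n))
  names(trial_noise) <- regions
  list(amp = amp, latent = u, patterns = patterns, trial_noise = trial_noise,
       executed = behavior$executed_response)
}

# Instruction-phase boxcar span per block: from the "memorize" announcement
# onset to the end of the "implement" announcement.
instruction_spans <- function(run_events) {
  ann <- run_events[run_events$phase == "announce", ]
  blocks <- sort(unique(ann$block))
  t(vapply(blocks, function(b) {
    on <- sort(ann$onset[ann$block == b])
    c(onset = on[1], duration = on[length(on)] + ANNOUNCE_DUR_S - on[1])
  }, c(onset = 0, duration = 0)))
}

# Noiseless signal of one run over all grid voxels (voxels x time).
build_signal_run <- function(run, design, atlas, config, truth) {
  ev <- design$events[design$events$run == run, ]
  impl_all <- design$events[design$events$phase == "implementation", ]
  in_run <- impl_all$run == run
  impl <- impl_all[in_run, ]
  n_vol <- design$n_volumes[run]
  gcfg <- glm_config(tr_s = config$tr_s, hpf_cutoff_s = Inf)
  Tmat <- hrf_regressor(impl$onset, gcfg, n_vol)
  V <- prod(atlas$shape)
  Y <- matrix(0, n_vol, V)
  for (r in names(atlas$regions)) {
    vox <- which(atlas_mask(atlas, r))
    A <- matrix(truth$amp[in_run, r], nrow(impl), length(vox))
    A <- A + truth$trial_noise[[r]][in_run, , drop = FALSE]
    for (i in seq_len(nrow(impl))) {
      b <- as.character(impl$block[i])
      pat <- truth$patterns[[b]][[r]]
      if (is.null(pat)) next
      key <- if (r == "motor") {
        ex <- truth$executed[in_run][i]
        if (is.na(ex)) next else as.character(ex)
      } else as.character(impl$stimulus_id[i])
      A[i, ] <- A[i, ] + pat[key, ]
    }
    Y[, vox] <- Tmat %*% A
  }
  # sustained instruction activity in gray-matter regions
  gray <- setdiff(names(atlas$regions), "white_matter")
  gray_vox <- which(atlas$labels %in% atlas$regions[gray])
  if (config$instruction_amp != 0) {
    spans <- instruction_spans(ev)
    for (i in seq_len(nrow(spans))) {
      box <- hrf_boxcar(spans[i, "onset"], spans[i, "duration"], gcfg, n_vol)
      Y[, gray_vox] <- Y[, gray_vox] + config$instruction_amp * as.numeric(box)
    }
  }
  fdb <- ev[ev$phase == "feedback", ]
  if (nrow(fdb) && config$feedback_amp != 0) {
    fb <- hrf_regressor(fdb$onset, gcfg, n_vol, collapse = TRUE)
    Y[, gray_vox] <- Y[, gray_vox] + config$feedback_amp * as.numeric(fb)
  }
  Y
}

# Stationary AR(1) Gaussian noise, voxels in columns.
ar1_noise <- function(n_vol, n_vox, sd, rho) {
  innov <- matrix(stats::rnorm(n_vol * n_vox), n_vol, n_vox)
  if (rho > 0) {
    innov[-1, ] <- innov[-1, ] * sqrt(1 - rho^2)
    for (t in 2:n_vol) innov[t, ] <- innov[t, ] + rho * innov[t - 1L, ]
  }
  sd * innov
}

#' Simulate one subject's dataset
#'
#' Draws behavior, ground-truth amplitudes and identity patterns, and
#' assembles the BOLD runs (signal plus AR(1) noise) for a design on a
#' phantom atlas.
#'
#' @param design An `experiment_design` (its TR must match the config).
#' @param atlas A `phantom_atlas`.
#' @param config A [simulation_config()].
#' @param seed Optional integer seed; with a fixed seed the output is
#'   bit-identical across calls.
#' @return List with `runs` (list of `bold_run`: `data` voxels x time,
#'   `shape`, `tr_s`, `n_volumes`, `run`), `events`, `behavior` (scored
#'   table), `truth` (ground-truth sidecar), `design`, `atlas`.
#' @export
simulate_subject <- function(design, atlas, config = simulation_config(),
                             seed = NULL) {
  if (!isTRUE(all.equal(design$tr_s, config$tr_s)))
    stop_input("design and simulation TR differ")
  with_seed(seed, {
    behavior <- simulate_behavior(design, config)
    truth <- draw_ground_truth(design, atlas, config, behavior)
    runs <- vector("list", design$n_runs)
    for (r in seq_len(design$n_runs)) {
      n_vol <- design$n_volumes[r]
      Y <- build_signal_run(r, design, atlas, config, truth)
      Y <- Y + ar1_noise(n_vol, ncol(Y), config$noise_sd, config$ar1_rho)
      runs[[r]] <- structure(list(data = t(Y), shape = atlas$shape,
                                  tr_s = config$tr_s, n_volumes = n_vol,
                                  run = r),
                             class = "bold_run")
    }
    list(runs = runs, events = design$events,
         behavior = score_accuracy(behavior), truth = truth,
         design = design, atlas = atlas)
  })
}

#' Reconstruct the noiseless BOLD of a run from the ground-truth sidecar
#'
#' The ground truth (amplitudes, identity patterns, trial pattern noise,
#' executed responses) fully determines the noiseless signal; this function
#' regenerates it deterministically, which is the conservation check for the
#' simulator.
#'
#' @inheritParams simulate_subject
#' @param truth The `truth` element returned by [simulate_subject()].
#' @param run Run index.
#' @return Voxels x time matrix of the noiseless signal.
#' @export
reconstruct_noiseless <- function(design, atlas, config, truth, run) {
  t(build_signal_run(run, design, atlas, config, truth))
}

#' Write a BOLD run as NIfTI
#' @param bold A `bold_run`.
#' @param path Output path (`.nii.gz`).
#' @param voxel_size_mm Isotropic voxel size for the header.
#' @export
write_bold <- function(bold, path, voxel_size_mm = 3) {
  arr <- array(bold$data, dim = c(bold$shape, bold$n_volumes))
  img <- RNifti::asNifti(arr, pixdim = c(rep(voxel_size_mm, 3), bold$tr_s))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a BOLD run written by [write_bold()]
#' @param path NIfTI path.
#' @param run Run index to record.
#' @export
read_bold <- function(path, run = 1L) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  tr <- RNifti::pixdim(img)[4]
  structure(list(data = matrix(as.numeric(img), prod(d[1:3]), d[4]),
                 shape = d[1:3], tr_s = tr, n_volumes = d[4], run = run),
            class = "bold_run")
}

#' Simulate a cohort to disk
#'
#' Writes one directory per subject (`sub-01`, ...) containing
#' `run-<r>_bold.nii.gz`, `events.tsv`, `behavior.tsv` and
#' `ground_truth.json`, plus the shared `atlas.nii.gz` at the top level.
#' Per-subject seeds are derived deterministically from `master_seed`.
#'
#' @param n_subjects Number of subjects.
#' @param experiment `"exp1"` or `"exp2"`.
#' @param atlas A `phantom_atlas`.
#' @param config A [simulation_config()].
#' @param master_seed Integer master seed.
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param design_args Extra arguments for [generate_experiment_design()]
#'   (e.g. down-scaling overrides).
#' @return Invisibly, the vector of subject directories.
#' @export
simulate_cohort <- function(n_subjects, experiment, atlas,
                            config = simulation_config(), master_seed = 1L,
                            out_dir, overwrite = FALSE,
                            design_args = list()) {
  if (n_subjects < 1L) stop_input("`n_subjects` must be >= 1")
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop_input("`out_dir` exists and is not empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_atlas(atlas, file.path(out_dir, "atlas.nii.gz"))
  dirs <- character(n_subjects)
  for (i in seq_len(n_subjects)) {
    sd_i <- derive_seed(master_seed, i)
    design <- do.call(generate_experiment_design,
                      c(list(experiment = experiment, seed = sd_i,
                             tr_s = config$tr_s), design_args))
    sub <- simulate_subject(design, atlas, config, seed = sd_i + 1L)
    d <- file.path(out_dir, sprintf("sub-%02d", i))
    dir.create(d, showWarnings = FALSE)
    for (r in seq_len(design$n_runs))
      write_bold(sub$runs[[r]], file.path(d, sprintf("run-%d_bold.nii.gz", r)))
    utils::write.table(sub$events, file.path(d, "events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "n/a")
    utils::write.table(sub$behavior, file.path(d, "behavior.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "n/a")
    jsonlite::write_json(
      list(seed = sd_i, amp = sub$truth$amp, latent = sub$truth$latent,
           executed = sub$truth$executed),
      file.path(d, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    dirs[i] <- d
  }
  invisible(dirs)
}
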