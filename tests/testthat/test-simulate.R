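# Small atlas and design used throughout: 3 regions, 1 run, 2 blocks.
tiny_atlas <- function(seed = 1)
  make_phantom_atlas(shape = c(12L, 12L, 12L),
                     region_sizes = c(vlpfc_signal = 40L, visual = 40L,
                                      motor = 40L, white_matter = 40L),
                     seed = seed)

tiny_design <- function(seed = 1, experiment = "exp1")
  generate_experiment_design(experiment, seed = seed,
                             blocks_per_condition_per_run = 1, n_runs = 1)

test_that("phantom atlas packs disjoint regions and round-trips as NIfTI", {
  atlas <- make_phantom_atlas(seed = 3)
  sizes <- vapply(atlas_masks(atlas), sum, 0L)
  expect_equal(unname(sizes), rep(200L, 6))
  expect_equal(length(unique(names(sizes))), 6)
  # disjoint by construction: labeled voxels sum to total region size
  expect_equal(sum(atlas$labels > 0), 1200L)
  expect_error(make_phantom_atlas(shape = c(8L, 8L, 8L),
                                  region_sizes = c(a = 500L)),
               "infeasible")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "atlas.nii.gz")
  write_atlas(atlas, p)
  back <- read_atlas(p)
  expect_identical(back$labels, atlas$labels)
  expect_equal(back$regions, atlas$regions)
})

test_that("simulation is deterministic and its ground truth reconstructs the signal", {
  atlas <- tiny_atlas()
  design <- tiny_design()
  cfg <- simulation_config(noise_sd = 0.5)
  s1 <- simulate_subject(design, atlas, cfg, seed = 11)
  s2 <- simulate_subject(design, atlas, cfg, seed = 11)
  expect_identical(s1$runs[[1]]$data, s2$runs[[1]]$data)
  expect_identical(s1$behavior, s2$behavior)

  # noiseless simulation equals the reconstruction from the ground truth
  cfg0 <- simulation_config(noise_sd = 0)
  s0 <- simulate_subject(design, atlas, cfg0, seed = 12)
  rec <- reconstruct_noiseless(design, atlas, cfg0, s0$truth, run = 1)
  expect_lt(max(abs(s0$runs[[1]]$data - rec)), 1e-10)
})

test_that("with no signal structure, fitted betas equal the mixed trial noise exactly", {
  atlas <- tiny_atlas()
  design <- tiny_design()
  cfg <- simulation_config(sigma_identity = 0, sigma_stim = 0, sigma_resp = 0,
                           amp_noise_sd = 0, instruction_amp = 0,
                           feedback_amp = 0, noise_sd = 0, ar1_rho = 0,
                           amp_by_repetition = rep(0, 8))
  sub <- simulate_subject(design, atlas, cfg, seed = 13)
  gcfg <- glm_config(hpf_cutoff_s = 128, ar1 = "off")
  mask <- atlas_mask(atlas, "vlpfc_signal")
  fit <- fit_lss(sub$runs[[1]], design$events[design$events$run == 1, ],
                 gcfg, mask = mask)
  M <- lss_trial_mixing(design$events[design$events$run == 1, ], gcfg,
                        design$n_volumes[1])
  expected <- M %*% sub$truth$trial_noise$vlpfc_signal
  expect_lt(max(abs(fit$betas - expected)), 1e-8)
})

test_that("identity codes are block-local and absent in the control condition", {
  atlas <- tiny_atlas()
  design <- generate_experiment_design("exp2", seed = 9,
                                       blocks_per_condition_per_run = 2,
                                       n_runs = 1)
  cfg <- simulation_config()
  sub <- simulate_subject(design, atlas, cfg, seed = 14)
  pats <- sub$truth$patterns
  conds <- vapply(design$blocks, `[[`, "", "condition")
  for (i in seq_along(design$blocks)) {
    b <- as.character(design$blocks[[i]]$block)
    if (conds[i] == "control") {
      expect_null(pats[[b]]$vlpfc_signal)
    } else {
      expect_false(is.null(pats[[b]]$vlpfc_signal))
    }
    expect_false(is.null(pats[[b]]$visual))  # stimulus code in all conditions
  }
  # patterns in different blocks are independent draws
  lrn <- names(pats)[conds != "control"]
  rs <- c()
  for (i in seq_along(lrn)) for (j in seq_along(lrn)) if (i < j)
    for (k in 1:4)
      rs <- c(rs, cor(pats[[lrn[i]]]$vlpfc_signal[k, ],
                      pats[[lrn[j]]]$vlpfc_signal[k, ]))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("cohorts are written to disk deterministically", {
  atlas <- tiny_atlas()
  cfg <- simulation_config()
  d1 <- withr::local_tempdir()
  simulate_cohort(2, "exp1", atlas, cfg, master_seed = 5, out_dir = d1,
                  design_args = list(blocks_per_condition_per_run = 1,
                                     n_runs = 1))
  expect_true(all(file.exists(
    file.path(d1, "sub-01",
              c("run-1_bold.nii.gz", "events.tsv", "behavior.tsv",
                "ground_truth.json")))))
  expect_true(file.exists(file.path(d1, "atlas.nii.gz")))
  expect_error(simulate_cohort(2, "exp1", atlas, cfg, 5, out_dir = d1),
               "overwrite")
  d2 <- withr::local_tempdir()
  simulate_cohort(2, "exp1", atlas, cfg, master_seed = 5, out_dir = d2,
                  design_args = list(blocks_per_condition_per_run = 1,
                                     n_runs = 1))
  b1 <- read_bold(file.path(d1, "sub-02", "run-1_bold.nii.gz"))
  b2 <- read_bold(file.path(d2, "sub-02", "run-1_bold.nii.gz"))
  expect_equal(b1$data, b2$data)
})
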