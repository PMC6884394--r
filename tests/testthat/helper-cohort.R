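# Shared heavy fixtures for the acceptance-level checks: one default
# 8-repetition cohort (n = 20) reused by the recovery and connectivity
# checks, computed lazily on first use.

.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.cohort_cache$study))
    .cohort_cache$study <- run_group_study(20, "exp2", seed = 101)
  .cohort_cache$study
}

# One cohort of the null-signal calibration study: a reduced grid (two small
# regions) and a down-scaled 4-repetition design, no identity signal
# anywhere. Returns the constant-term p value of the condition x stage
# repeated-measures ANOVA on the signal-region deltas.
null_cohort_constant_p <- function(cohort_seed, n_subjects = 15) {
  atlas <- make_phantom_atlas(shape = c(10L, 10L, 8L),
                              region_sizes = c(vlpfc_signal = 40L,
                                               white_matter = 40L),
                              seed = cohort_seed)
  cfg <- simulation_config(sigma_identity = 0, sigma_stim = 0, sigma_resp = 0)
  gcfg <- glm_config(hpf_cutoff_s = 128, ar1 = "estimate")
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sd_i <- rulemvpa:::derive_seed(cohort_seed, i)
    design <- generate_experiment_design("exp1", seed = sd_i,
                                         blocks_per_condition_per_run = 2,
                                         n_runs = 1)
    sub <- simulate_subject(design, atlas, cfg, seed = sd_i + 1L)
    bset <- fit_lss(sub$runs[[1]], design$events, gcfg,
                    mask = atlas_mask(atlas, "brain"))
    tab <- subject_similarity(bset, atlas_mask(atlas, "vlpfc_signal"),
                              roi = "vlpfc_signal")
    tab$subject <- i
    rows[[i]] <- tab
  }
  tab <- do.call(rbind, rows)
  a <- rm_anova(tab, dv = "delta", subject = "subject",
                within = c("condition", "stage"))
  a$p_uncorrected[a$effect == "constant"]
}
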