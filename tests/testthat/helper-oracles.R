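# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the implementation.

# Same/different-stimulus correlation contrast by explicit double loop.
brute_delta <- function(betas, labels) {
  n <- nrow(betas)
  same <- c(); diffr <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- cor(betas[i, ], betas[j, ])
    if (labels[i] == labels[j]) same <- c(same, r) else diffr <- c(diffr, r)
  }
  list(mean_same = mean(same), mean_diff = mean(diffr),
       delta = mean(same) - mean(diffr),
       n_same = length(same), n_diff = length(diffr))
}

# Independent repeated-measures ANOVA oracle: classical univariate error
# strata via aov(). Returns F statistics named by effect.
aov_rm_oracle <- function(table, dv, subject, within) {
  table[[subject]] <- factor(table[[subject]])
  for (f in within) table[[f]] <- factor(table[[f]])
  rhs <- paste(within, collapse = " * ")
  err <- paste0("Error(", subject, "/(", rhs, "))")
  form <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- summary(stats::aov(form, data = table))
  out <- c()
  for (stratum in fit) {
    tab <- stratum[[1]]
    for (i in seq_len(nrow(tab))) {
      nm <- trimws(rownames(tab)[i])
      if (nm != "Residuals" && !is.na(tab[i, "F value"]))
        out[nm] <- tab[i, "F value"]
    }
  }
  out
}

# Events table of isolated implementation trials (spacing beyond the HRF
# length, so responses do not overlap), with 4 stimuli x 2 repetitions.
sparse_trial_events <- function(n_trials = 8, spacing_s = 40, t0 = 10,
                                stimuli = rep(0:3, 2)) {
  onsets <- t0 + (seq_len(n_trials) - 1) * spacing_s
  reps <- ave(seq_len(n_trials), stimuli[seq_len(n_trials)], FUN = seq_along)
  data.frame(onset = onsets, duration = 1, run = 1L, block = 1L,
             condition = "easy", phase = "implementation",
             stimulus_id = stimuli[seq_len(n_trials)],
             repetition = reps, stage = ceiling(reps / 2),
             instructed_response = rep(0:1, length.out = n_trials))
}

# A block-design-like object with a fixed SOA for every implementation trial.
fixed_soa_block <- function(soa_s = 2, seed = 1) {
  blk <- generate_block_design("easy", "exp1", stimulus_pool = 0:3, seed = seed)
  ev <- blk$events
  impl <- which(ev$phase == "implementation")
  start <- ev$onset[impl[1]]
  ev$onset[impl] <- start + (seq_along(impl) - 1) * soa_s
  fb <- which(ev$phase == "feedback")
  ev$onset[fb] <- max(ev$onset[impl]) + 2 + blk$end_delay_s
  blk$events <- ev
  blk$duration_s <- ev$onset[fb] + 2
  blk
}

# Minimal hand-built trial_beta_set for unit tests.
toy_beta_set <- function(betas, meta, mask_voxels = seq_len(ncol(betas))) {
  structure(list(betas = betas, meta = meta, mask_voxels = mask_voxels,
                 rho = 0), class = "trial_beta_set")
}
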