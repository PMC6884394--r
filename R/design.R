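# Experiment-design generation for the instruction-based learning paradigm.
#
# A design is a sequence of learning blocks, each consisting of an announced
# instruction phase (novel noun-response pairings), an implementation phase in
# which four nouns are each executed 4 or 8 times, and a feedback display.
# Implementation trial order is the concatenation of independently randomized
# "atomic" 8-trial sequences, one per implementation stage (a stage spans two
# consecutive repetitions of every stimulus). Randomizing each stage
# separately is what makes the stage-resolved pattern-similarity statistic
# unbiased in expectation despite overlapping BOLD responses.

SOA_LEVELS_S <- c(2, 2.5, 3, 3.5, 4)
DELAY_LEVELS_S <- c(2, 4)
ANNOUNCE_DUR_S <- 2
FEEDBACK_DUR_S <- 2
RUN_TAIL_S <- 20  # rest appended after the last event so the HRF can return

condition_levels <- function(experiment) {
  switch(experiment,
         exp1 = c("easy", "difficult"),
         exp2 = c("learning", "control"),
         stop_input("unknown experiment: ", experiment))
}

#' Generate an atomic 8-trial sequence
#'
#' An atomic sequence contains exactly two occurrences of each stimulus in
#' uniformly random order. One atomic sequence per implementation stage is the
#' randomization unit that guarantees, in expectation over sequences, an
#' unbiased stage-resolved similarity statistic.
#'
#' @param stimuli Vector of distinct stimulus ids (typically 4).
#' @param seed Optional integer seed.
#' @return Vector of `2 * length(stimuli)` stimulus ids.
#' @export
generate_atomic_sequence <- function(stimuli, seed = NULL) {
  if (length(stimuli) < 1L) stop_input("`stimuli` must be non-empty")
  if (anyDuplicated(stimuli)) stop_input("`stimuli` must be distinct")
  with_seed(seed, {
    s <- rep(stimuli, each = 2L)
    s[sample.int(length(s))]
  })
}

# Draw a stimulus -> response map using exactly n_responses distinct responses
# out of the three possible button responses (0, 1, 2), each used at least
# once.
draw_response_map <- function(stimuli, n_responses) {
  stopifnot(n_responses %in% c(2L, 3L), length(stimuli) >= n_responses)
  resp_set <- sort(sample(0:2, n_responses))
  repeat {
    m <- sample(resp_set, length(stimuli), replace = TRUE)
    if (length(unique(m)) == n_responses) break
  }
  names(m) <- as.character(stimuli)
  m
}

#' Generate one learning-block design
#'
#' Builds the full event timeline of a block (onsets relative to block start):
#' a pre-instruction delay, a 2 s "memorize" announcement, the instruction
#' items (4 items of 2 s each, or 10 items of 1 s each in the difficult
#' condition), a 2 s "implement" announcement, the implementation trials with
#' a random SOA from 2--4 s (0.5 s steps) inserted before each trial, an end
#' delay of 2 or 4 s, and a 2 s feedback display.
#'
#' @param condition One of `"easy"`, `"difficult"` (experiment 1) or
#'   `"learning"`, `"control"` (experiment 2).
#' @param experiment `"exp1"` or `"exp2"`.
#' @param stimulus_pool Integer ids available to this block; the block uses the
#'   first 4 (or 10 for the difficult condition) of them.
#' @param n_responses Number of distinct responses (2 or 3).
#' @param pre_delay_s,end_delay_s Delays before the instruction announcement
#'   and before feedback; drawn from 2/4 s when `NULL` (the experiment-level
#'   generator passes balanced values).
#' @param scheme `"atomic"` concatenates one independently randomized atomic
#'   sequence per stage; `"retrospective"` fully randomizes all repetitions of
#'   all stimuli in one shuffle and assigns stages retrospectively by
#'   occurrence order. The latter exists to demonstrate the bias it induces.
#' @param seed Optional integer seed.
#' @return A `block_design` list with fields `condition`, `stimulus_set`
#'   (implemented stimuli), `instructed_set`, `response_map`, `n_repetitions`,
#'   `response_cued` (TRUE for the control condition, whose response cues are
#'   displayed during implementation), and `events` (data frame).
#' @export
generate_block_design <- function(condition, experiment = c("exp1", "exp2"),
                                  stimulus_pool = 0:9, n_responses = 2L,
                                  pre_delay_s = NULL, end_delay_s = NULL,
                                  scheme = c("atomic", "retrospective"),
                                  seed = NULL) {
  experiment <- match.arg(experiment)
  scheme <- match.arg(scheme)
  if (!condition %in% condition_levels(experiment))
    stop_input(sprintf("condition '%s' is not valid for %s", condition, experiment))
  with_seed(seed, {
    n_rep <- if (experiment == "exp1") 4L else 8L
    n_instructed <- if (condition == "difficult") 10L else 4L
    item_dur <- if (condition == "difficult") 1 else 2
    if (length(stimulus_pool) < n_instructed)
      stop_input("`stimulus_pool` too small for this condition")
    instructed <- stimulus_pool[seq_len(n_instructed)]
    response_map <- draw_response_map(instructed, as.integer(n_responses))
    if (condition == "difficult") {
      # implemented subset: 4 of the 10 instructed nouns, requiring exactly
      # the block's number of distinct responses
      repeat {
        implemented <- sort(sample(instructed, 4L))
        if (length(unique(response_map[as.character(implemented)])) == n_responses)
          break
      }
    } else {
      implemented <- instructed
    }
    pre_delay_s <- pre_delay_s %||% sample(DELAY_LEVELS_S, 1L)
    end_delay_s <- end_delay_s %||% sample(DELAY_LEVELS_S, 1L)

    # implementation trial order
    if (scheme == "atomic") {
      order_ids <- unlist(lapply(seq_len(n_rep %/% 2L), function(s)
        generate_atomic_sequence(implemented)))
    } else {
      order_ids <- sample(rep(implemented, each = n_rep))
    }
    rep_count <- stats::setNames(integer(length(implemented)), as.character(implemented))
    repetition <- integer(length(order_ids))
    for (i in seq_along(order_ids)) {
      key <- as.character(order_ids[i])
      rep_count[key] <- rep_count[key] + 1L
      repetition[i] <- rep_count[key]
    }
    stage <- ceiling(repetition / 2)

    ev <- list()
    t <- pre_delay_s
    add <- function(phase, onset, dur, stim = NA_integer_, rep = NA_integer_,
                    stg = NA_integer_, resp = NA_integer_) {
      data.frame(onset = onset, duration = dur, condition = condition,
                 phase = phase, stimulus_id = stim, repetition = rep,
                 stage = stg, instructed_response = resp)
    }
    ev[[length(ev) + 1L]] <- add("announce", t, ANNOUNCE_DUR_S)
    t <- t + ANNOUNCE_DUR_S
    for (s in instructed) {
      resp <- if (condition == "control") NA_integer_ else
        unname(response_map[as.character(s)])
      ev[[length(ev) + 1L]] <- add("instruction", t, item_dur, stim = s, resp = resp)
      t <- t + item_dur
    }
    ev[[length(ev) + 1L]] <- add("announce", t, ANNOUNCE_DUR_S)
    t <- t + ANNOUNCE_DUR_S
    last_onset <- t
    for (i in seq_along(order_ids)) {
      soa <- sample(SOA_LEVELS_S, 1L)
      onset <- if (i == 1L) t + soa else last_onset + soa
      ev[[length(ev) + 1L]] <- add("implementation", onset, 1,
                                   stim = order_ids[i], rep = repetition[i],
                                   stg = as.integer(stage[i]),
                                   resp = unname(response_map[as.character(order_ids[i])]))
      last_onset <- onset
    }
    fb_onset <- last_onset + 2 + end_delay_s
    ev[[length(ev) + 1L]] <- add("feedback", fb_onset, FEEDBACK_DUR_S)
    events <- do.call(rbind, ev)
    structure(list(condition = condition, experiment = experiment,
                   stimulus_set = implemented, instructed_set = instructed,
                   response_map = response_map,
                   n_repetitions = n_rep, n_responses = as.integer(n_responses),
                   response_cued = identical(condition, "control"),
                   pre_delay_s = pre_delay_s, end_delay_s = end_delay_s,
                   scheme = scheme, events = events,
                   duration_s = fb_onset + FEEDBACK_DUR_S),
              class = "block_design")
  })
}

# Balanced 2 s / 4 s delay assignment: exactly half of each condition's blocks
# at each level (one random extra when the count is odd, which can only arise
# in down-scaled designs), in shuffled order.
balanced_delays <- function(n) {
  base <- rep(DELAY_LEVELS_S, n %/% 2L)
  if (n %% 2L) base <- c(base, sample(DELAY_LEVELS_S, 1L))
  sample(base)
}

#' Generate a complete experiment design
#'
#' Experiment 1: 36 blocks (18 easy, 18 difficult) over 3 runs of 12 blocks,
#' 6 per condition per run. Experiment 2: 24 blocks (12 intentional learning,
#' 12 control) over 3 runs of 8 blocks, 4 per condition per run. Conditions
#' are counterbalanced within run, every block draws a fresh stimulus set, the
#' 2 s / 4 s delays before instruction and before feedback are exactly
#' balanced per condition, and the number of distinct responses (2 vs 3)
#' alternates within condition.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param seed Optional integer seed; stored in the design.
#' @param blocks_per_condition_per_run,n_runs Optional down-scaling overrides
#'   (defaults reproduce the full paradigm sizes).
#' @param scheme Trial-ordering scheme, see [generate_block_design()].
#' @param tr_s Repetition time used to derive per-run volume counts
#'   (default 2).
#' @return An `experiment_design` list with `blocks` (list of
#'   `block_design`s with `$run` and `$block` indices), `events` (one data
#'   frame of all events, onsets in seconds from run start), `n_runs`,
#'   `run_length_s`, and `n_volumes` per run for a given TR.
#' @export
generate_experiment_design <- function(experiment = c("exp1", "exp2"),
                                       seed = NULL,
                                       blocks_per_condition_per_run = NULL,
                                       n_runs = 3L,
                                       scheme = c("atomic", "retrospective"),
                                       tr_s = 2) {
  experiment <- match.arg(experiment)
  scheme <- match.arg(scheme)
  with_seed(seed, {
    conds <- condition_levels(experiment)
    bpc <- blocks_per_condition_per_run %||% (if (experiment == "exp1") 6L else 4L)
    bpc <- as.integer(bpc)
    n_runs <- as.integer(n_runs)
    n_blocks_cond <- bpc * n_runs

    # per-condition balanced assignments, consumed in block order
    pre_delays <- lapply(conds, function(c) balanced_delays(n_blocks_cond))
    end_delays <- lapply(conds, function(c) balanced_delays(n_blocks_cond))
    n_resp_seq <- lapply(conds, function(c)
      rep_len(c(2L, 3L), n_blocks_cond))  # alternate deterministically
    names(pre_delays) <- names(end_delays) <- names(n_resp_seq) <- conds

    next_stim <- 0L
    used <- stats::setNames(rep(0L, length(conds)), conds)
    blocks <- list()
    events <- list()
    run_length <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      cond_order <- sample(rep(conds, bpc))
      t_run <- 0
      for (b in seq_along(cond_order)) {
        cond <- cond_order[b]
        used[cond] <- used[cond] + 1L
        k <- used[cond]
        n_instr <- if (cond == "difficult") 10L else 4L
        pool <- next_stim + seq_len(n_instr) - 1L
        next_stim <- next_stim + n_instr
        blk <- generate_block_design(cond, experiment, stimulus_pool = pool,
                                     n_responses = n_resp_seq[[cond]][k],
                                     pre_delay_s = pre_delays[[cond]][k],
                                     end_delay_s = end_delays[[cond]][k],
                                     scheme = scheme)
        blk$run <- r
        blk$block <- length(blocks) + 1L
        ev <- blk$events
        ev$onset <- ev$onset + t_run
        ev$run <- r
        ev$block <- blk$block
        t_run <- t_run + blk$duration_s
        blocks[[length(blocks) + 1L]] <- blk
        events[[length(events) + 1L]] <- ev
      }
      run_length[r] <- t_run + RUN_TAIL_S
    }
    events <- do.call(rbind, events)
    events <- events[, c("onset", "duration", "run", "block", "condition",
                         "phase", "stimulus_id", "repetition", "stage",
                         "instructed_response")]
    rownames(events) <- NULL
    design <- structure(list(experiment = experiment, n_runs = n_runs,
                             blocks = blocks, events = events,
                             run_length_s = run_length,
                             n_volumes = as.integer(ceiling(run_length / tr_s)),
                             tr_s = tr_s, seed = seed, scheme = scheme),
                        class = "experiment_design")
    validate_design(design)
    design
  })
}

#' Validate an experiment design against its structural invariants
#'
#' Checks block counts, within-run condition balance, strictly increasing
#' onsets, per-stage stimulus counts (exactly two occurrences of each
#' implemented stimulus per stage), the stage = ceiling(repetition / 2)
#' relation, and fresh stimulus sets across blocks.
#'
#' @param design An `experiment_design`.
#' @return The design, invisibly; errors describe any violated invariant.
#' @export
validate_design <- function(design) {
  ev <- design$events
  for (r in seq_len(design$n_runs)) {
    on <- ev$onset[ev$run == r]
    if (any(diff(on) <= 0)) stop_input("onsets not strictly increasing in run ", r)
  }
  impl <- ev[ev$phase == "implementation", ]
  if (!all(impl$stage == ceiling(impl$repetition / 2)))
    stop_input("stage != ceiling(repetition / 2)")
  for (blk in design$blocks) {
    bi <- impl[impl$block == blk$block, ]
    if (blk$scheme == "atomic") {
      tab <- table(bi$stage, bi$stimulus_id)
      if (!all(tab == 2L))
        stop_input("block ", blk$block, ": a stage is not an atomic sequence")
    }
    if (nrow(bi) != 4L * blk$n_repetitions)
      stop_input("block ", blk$block, ": wrong implementation trial count")
  }
  all_instr <- unlist(lapply(design$blocks, `[[`, "instructed_set"))
  if (anyDuplicated(all_instr)) stop_input("stimulus ids reused across blocks")
  counts <- table(vapply(design$blocks, `[[`, "", "condition"),
                  vapply(design$blocks, `[[`, 0L, "run"))
  if (length(unique(as.vector(counts))) != 1L)
    stop_input("conditions not counterbalanced across runs")
  invisible(design)
}

#' Write / read per-run events tables
#'
#' Tab-separated events files in a BIDS-like layout (onset and duration in
#' seconds, one file per run).
#' @param design An `experiment_design`.
#' @param dir Output directory.
#' @return `write_events_tsv` returns the file paths; `read_events_tsv`
#'   returns one events data frame.
#' @export
write_events_tsv <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(design$n_runs)
  for (r in seq_len(design$n_runs)) {
    paths[r] <- file.path(dir, sprintf("run-%d_events.tsv", r))
    utils::write.table(design$events[design$events$run == r, ], paths[r],
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
  }
  paths
}

#' @rdname write_events_tsv
#' @param path Path to one events TSV.
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
}

#' Count implementation trials (i.e. required LSS fits)
#'
#' @param design An `experiment_design`.
#' @param per Either `"run"` (vector, one count per run) or `"subject"`
#'   (total).
#' @export
count_lss_fits <- function(design, per = c("subject", "run")) {
  per <- match.arg(per)
  impl <- design$events[design$events$phase == "implementation", ]
  if (per == "subject") nrow(impl)
  else as.integer(table(factor(impl$run, levels = seq_len(design$n_runs))))
}
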