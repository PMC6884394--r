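test_that("atomic sequences contain each stimulus exactly twice, in random order", {
  s <- generate_atomic_sequence(1:4, seed = 42)
  expect_length(s, 8)
  expect_true(all(table(s) == 2))
  expect_identical(s, generate_atomic_sequence(1:4, seed = 42))
  expect_identical(generate_atomic_sequence("A"), c("A", "A"))
  expect_error(generate_atomic_sequence(c(1, 1, 2)), "distinct")

  set.seed(7)
  for (i in 1:10000) {
    s <- generate_atomic_sequence(0:3)
    if (any(tabulate(s + 1L, 4L) != 2L)) fail("unbalanced atomic sequence")
  }
  succeed()
})

test_that("block designs realize the paradigm structure for every condition", {
  easy <- generate_block_design("easy", "exp1", stimulus_pool = 0:3, seed = 1)
  ev <- easy$events
  expect_equal(sum(ev$phase == "implementation"), 16)
  expect_equal(sum(ev$phase == "instruction"), 4)
  expect_true(all(ev$duration[ev$phase == "instruction"] == 2))

  diff <- generate_block_design("difficult", "exp1", stimulus_pool = 0:9, seed = 2)
  expect_equal(sum(diff$events$phase == "instruction"), 10)
  expect_true(all(diff$events$duration[diff$events$phase == "instruction"] == 1))
  expect_length(diff$stimulus_set, 4)  # 4 implemented regardless of condition
  expect_true(all(diff$stimulus_set %in% diff$instructed_set))

  lrn <- generate_block_design("learning", "exp2", stimulus_pool = 0:3, seed = 3)
  impl <- lrn$events[lrn$events$phase == "implementation", ]
  expect_equal(nrow(impl), 32)
  expect_equal(as.vector(table(impl$stage)), rep(8, 4))
  expect_true(all(impl$stage == ceiling(impl$repetition / 2)))

  ctrl <- generate_block_design("control", "exp2", stimulus_pool = 0:3, seed = 4)
  expect_true(ctrl$response_cued)
  expect_false(lrn$response_cued)

  # SOAs in 0.5 s steps between 2 and 4 s
  soa <- diff(impl$onset[1:8])
  expect_true(all(soa >= 2 & soa <= 4 & (soa * 2) %% 1 == 0))

  expect_error(generate_block_design("control", "exp1", 0:3), "not valid")
  expect_error(generate_block_design("difficult", "exp1", 0:5), "too small")
})

test_that("experiment designs meet the block-count and balance invariants", {
  d1 <- generate_experiment_design("exp1", seed = 11)
  expect_equal(d1$n_runs, 3)
  expect_equal(length(d1$blocks), 36)
  expect_equal(count_lss_fits(d1, "run"), rep(192L, 3))
  expect_equal(count_lss_fits(d1), 576L)

  d2 <- generate_experiment_design("exp2", seed = 11)
  expect_equal(length(d2$blocks), 24)
  expect_equal(count_lss_fits(d2, "run"), rep(256L, 3))
  expect_equal(count_lss_fits(d2), 768L)

  # determinism, event by event
  expect_identical(d1$events, generate_experiment_design("exp1", seed = 11)$events)

  # delays balanced per condition across the design
  for (d in list(d1, d2)) {
    conds <- vapply(d$blocks, `[[`, "", "condition")
    pre <- vapply(d$blocks, `[[`, 0, "pre_delay_s")
    end <- vapply(d$blocks, `[[`, 0, "end_delay_s")
    for (cc in unique(conds)) {
      expect_equal(sum(pre[conds == cc] == 2), sum(pre[conds == cc] == 4))
      expect_equal(sum(end[conds == cc] == 2), sum(end[conds == cc] == 4))
    }
    nresp <- vapply(d$blocks, `[[`, 0L, "n_responses")
    for (cc in unique(conds))
      expect_equal(sum(nresp[conds == cc] == 2L), sum(nresp[conds == cc] == 3L))
  }

  # validate_design runs clean and catches a broken stage assignment
  expect_silent(validate_design(d1))
  broken <- d1
  broken$events$stage[broken$events$phase == "implementation"][1] <- 99L
  expect_error(validate_design(broken), "stage")
})

test_that("events tables round-trip through TSV", {
  d <- generate_experiment_design("exp1", seed = 5,
                                  blocks_per_condition_per_run = 1, n_runs = 1)
  dir <- withr::local_tempdir()
  paths <- write_events_tsv(d, dir)
  back <- read_events_tsv(paths[1])
  orig <- d$events[d$events$run == 1, ]
  rownames(orig) <- NULL
  expect_equal(back$onset, orig$onset)
  expect_equal(back$stimulus_id, orig$stimulus_id)
  expect_equal(back$phase, orig$phase)
})
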