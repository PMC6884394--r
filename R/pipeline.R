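# End-to-end orchestration: per-subject analysis (LSS -> similarity /
# univariate / connectivity / behavior) and cohort-level studies, either
# in memory or against a simulated cohort directory, plus YAML configuration
# and a TSV/JSON report writer.

#' Default GLM configuration per experiment
#'
#' The high-pass cutoff accommodates the different block lengths: 128 s for
#' the 4-repetition experiment, 256 s for the 8-repetition experiment.
#' @param experiment `"exp1"` or `"exp2"`.
#' @export
default_glm_config <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  glm_config(hpf_cutoff_s = if (experiment == "exp1") 128 else 256)
}

#' Analyze one simulated (or loaded) subject
#'
#' Fits the LSS model per run on all labeled atlas voxels, then computes the
#' ROI similarity table (with white-matter bias adjustment), the univariate
#' mean-activity table, the connectivity contrast (8-repetition designs
#' only), and the behavioral summary.
#'
#' @param sub A subject as returned by [simulate_subject()].
#' @param glm_config A [glm_config()]; defaults to the experiment-appropriate
#'   configuration.
#' @param subject Subject identifier recorded in the tables.
#' @param aggregate_stages Optional stage aggregation for the similarity
#'   table, e.g. `list(early = 1:2, late = 3:4)`.
#' @param correct_only Restrict the similarity analysis to correct trials.
#' @return List with `beta_set`, `similarity`, `univariate`, `connectivity`
#'   (or `NULL`), `behavior_summary`, `correct_flags`.
#' @export
analyze_subject <- function(sub, glm_config = NULL, subject = 1L,
                            aggregate_stages = NULL, correct_only = FALSE) {
  design <- sub$design
  atlas <- sub$atlas
  glm_config <- glm_config %||% default_glm_config(design$experiment)
  mask <- atlas_mask(atlas, "brain")
  sets <- lapply(seq_len(design$n_runs), function(r)
    fit_lss(sub$runs[[r]], design$events[design$events$run == r, ],
            glm_config, mask = mask))
  beta_set <- combine_beta_sets(sets)
  correct <- sub$behavior$correct_subjective

  rois <- atlas_masks(atlas)
  wm <- rois$white_matter
  sim_rows <- lapply(names(rois), function(nm)
    cbind(subject = subject,
          subject_similarity(beta_set, rois[[nm]], roi = nm,
                             wm_mask = if (!identical(nm, "white_matter")) wm,
                             aggregate_stages = aggregate_stages,
                             correct_only = correct_only,
                             correct_flags = correct)))
  similarity <- do.call(rbind, sim_rows)

  univariate <- mean_activity(beta_set, rois, correct_flags = correct,
                              subject = subject)
  connectivity <- NULL
  if (max(beta_set$meta$repetition) >= 8L &&
      all(c("vlpfc_signal", "striatum") %in% names(rois))) {
    conds <- condition_levels(design$experiment)
    connectivity <- cbind(subject = subject,
                          connectivity_change(beta_set, rois$vlpfc_signal,
                                              list(striatum = rois$striatum),
                                              correct_flags = correct,
                                              conditions = conds))
  }
  behavior_summary <- summarize_performance(
    cbind(subject = subject, sub$behavior))
  list(beta_set = beta_set, similarity = similarity, univariate = univariate,
       connectivity = connectivity, behavior_summary = behavior_summary,
       correct_flags = correct)
}

#' Run an in-memory cohort study
#'
#' Simulates `n_subjects` subjects (fresh design and data per subject, seeds
#' derived from `seed`) and stacks their similarity, univariate, connectivity
#' and behavioral tables for group inference.
#'
#' @param n_subjects Number of subjects.
#' @param experiment `"exp1"` or `"exp2"`.
#' @param atlas A `phantom_atlas` (default: [make_phantom_atlas()]).
#' @param config A [simulation_config()].
#' @param seed Integer master seed.
#' @param design_args Extra arguments to [generate_experiment_design()].
#' @param glm_config Optional [glm_config()] override.
#' @param keep_beta_sets Keep per-subject beta sets (memory-heavy; default
#'   drops them).
#' @inheritParams analyze_subject
#' @return List of stacked data frames: `similarity`, `univariate`,
#'   `connectivity`, `behavior`, plus `atlas` and the `seed`.
#' @export
run_group_study <- function(n_subjects, experiment = c("exp1", "exp2"),
                            atlas = NULL, config = simulation_config(),
                            seed = 1L, design_args = list(),
                            glm_config = NULL, aggregate_stages = NULL,
                            correct_only = FALSE, keep_beta_sets = FALSE) {
  experiment <- match.arg(experiment)
  atlas <- atlas %||% make_phantom_atlas(seed = derive_seed(seed, 0L))
  sim <- uni <- con <- beh <- list()
  bsets <- list()
  for (i in seq_len(n_subjects)) {
    s_design <- derive_seed(seed, 2L * i)
    s_data <- derive_seed(seed, 2L * i + 1L)
    design <- do.call(generate_experiment_design,
                      c(list(experiment = experiment, seed = s_design,
                             tr_s = config$tr_s), design_args))
    sub <- simulate_subject(design, atlas, config, seed = s_data)
    res <- analyze_subject(sub, glm_config = glm_config, subject = i,
                           aggregate_stages = aggregate_stages,
                           correct_only = correct_only)
    sim[[i]] <- res$similarity
    uni[[i]] <- res$univariate
    if (!is.null(res$connectivity)) con[[i]] <- res$connectivity
    beh[[i]] <- res$behavior_summary
    if (keep_beta_sets) bsets[[i]] <- res$beta_set
  }
  list(similarity = do.call(rbind, sim),
       univariate = do.call(rbind, uni),
       connectivity = if (length(con)) do.call(rbind, con),
       behavior = do.call(rbind, beh),
       beta_sets = if (keep_beta_sets) bsets,
       atlas = atlas, experiment = experiment, seed = seed)
}

#' Group one-sample tests of the similarity deltas
#'
#' One-sample t tests of the per-subject deltas against zero, per ROI x
#' condition (optionally per stage; default collapses stages by averaging
#' within subject first).
#'
#' @param similarity Stacked similarity table from [run_group_study()].
#' @param by_stage Keep stages separate instead of collapsing.
#' @param adjusted Use the white-matter-adjusted deltas where available.
#' @return Data frame: roi, condition (, stage), mean_delta, t, df,
#'   p_greater, p_two_sided, n.
#' @export
group_similarity_tests <- function(similarity, by_stage = FALSE,
                                   adjusted = FALSE) {
  dv <- if (adjusted && any(!is.na(similarity$delta_wm_adjusted)))
    "delta_wm_adjusted" else "delta"
  keys <- c("roi", "condition", if (by_stage) "stage")
  cells <- unique(similarity[, keys, drop = FALSE])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(similarity))
    for (k in keys) sel <- sel & similarity[[k]] == cells[[k]][i]
    per_subj <- tapply(similarity[[dv]][sel], similarity$subject[sel],
                       mean, na.rm = TRUE)
    tt <- one_sample_t(as.numeric(per_subj))
    cbind(cells[i, , drop = FALSE],
          data.frame(mean_delta = tt$mean, t = tt$t, df = tt$df,
                     p_greater = tt$p_greater, p_two_sided = tt$p_two_sided,
                     n = tt$df + 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a pipeline configuration from YAML
#'
#' Keys: `experiment`, `n_subjects`, `seed`, and optional `atlas`
#' (`shape`, `region_voxels`), `design` (overrides), `simulation` and `glm`
#' (argument lists for [simulation_config()] / [glm_config()]), `flags`
#' (`correct_only`, `fisher_z`).
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment) || is.null(cfg$n_subjects))
    stop_input("config must define `experiment` and `n_subjects`")
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Simulates the cohort, analyzes every subject, runs the group tests and
#' writes `similarity.tsv`, `univariate.tsv`, `connectivity.tsv`,
#' `behavior.tsv`, `group_similarity.tsv` and `report.json` (which records
#' the configuration and seed for provenance) into `out_dir`.
#'
#' @param config A list (see [read_pipeline_config()]) or a YAML path.
#' @param out_dir Output directory.
#' @return The group-study result list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atlas_args <- config$atlas %||% list()
  atlas <- make_phantom_atlas(
    shape = atlas_args$shape %||% c(24L, 24L, 24L),
    region_sizes = stats::setNames(
      rep(atlas_args$region_voxels %||% 200L, length(PHANTOM_REGIONS)),
      PHANTOM_REGIONS),
    seed = derive_seed(config$seed, 0L))
  sim_cfg <- do.call(simulation_config, config$simulation %||% list())
  glm_cfg <- if (!is.null(config$glm)) do.call(glm_config, config$glm)
  study <- run_group_study(
    n_subjects = config$n_subjects, experiment = config$experiment,
    atlas = atlas, config = sim_cfg, seed = config$seed,
    design_args = config$design %||% list(), glm_config = glm_cfg,
    correct_only = isTRUE(config$flags$correct_only))
  wt <- function(df, name) if (!is.null(df))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "n/a")
  wt(study$similarity, "similarity.tsv")
  wt(study$univariate, "univariate.tsv")
  wt(study$connectivity, "connectivity.tsv")
  wt(study$behavior, "behavior.tsv")
  group <- group_similarity_tests(study$similarity)
  wt(group, "group_similarity.tsv")
  jsonlite::write_json(
    list(config = config, seed = config$seed,
         package_version = as.character(utils::packageVersion("rulemvpa")),
         group_similarity = group),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(study)
}
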