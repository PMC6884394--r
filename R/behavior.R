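# Behavioral scoring.
#
# Because no trial-wise feedback is given, a participant who misremembers an
# instruction may settle on a self-generated rule and apply it consistently.
# Accuracy is therefore scored "subjectively": a response at repetition k > 1
# is correct when it matches the response executed at the preceding occurrence
# of the same stimulus within the same block; at repetition 1 (no preceding
# execution) it is scored against the instructed response. The conventional
# "objective" flag (always against the instructed response) is kept alongside.

#' Score a behavioral table with the subjective accuracy rule
#'
#' @param table Data frame with columns `block`, `condition`, `stimulus_id`,
#'   `repetition`, `instructed_response`, `executed_response` (`NA` =
#'   omission) and optionally `subject`, `rt_ms`.
#' @return The table with added logical columns `correct_subjective` and
#'   `correct_objective`. Omissions are incorrect under both rules. If the
#'   preceding occurrence was an omission, the subjective reference falls back
#'   to the last non-omitted execution of that stimulus, and to the instructed
#'   response if there is none.
#' @export
score_accuracy <- function(table) {
  req <- c("block", "stimulus_id", "repetition", "instructed_response",
           "executed_response")
  if (!all(req %in% names(table)))
    stop_input("missing columns: ", paste(setdiff(req, names(table)), collapse = ", "))
  subj <- if ("subject" %in% names(table)) table$subject else rep(1L, nrow(table))
  key <- paste(subj, table$block, table$stimulus_id, sep = "\r")
  table$correct_objective <- !is.na(table$executed_response) &
    table$executed_response == table$instructed_response
  table$correct_subjective <- NA
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(table$repetition[idx])]
    reps <- table$repetition[idx]
    if (!identical(as.integer(reps), seq_along(idx)))
      stop_input("repetitions of a stimulus within a block must form 1..n")
    ref <- table$instructed_response[idx[1]]
    for (j in seq_along(idx)) {
      ex <- table$executed_response[idx[j]]
      table$correct_subjective[idx[j]] <- !is.na(ex) && ex == ref
      if (!is.na(ex)) ref <- ex  # next trial is scored against this execution
    }
  }
  table
}

#' Summarize accuracy and response times per subject x condition x repetition
#'
#' Accuracy is the proportion of subjectively correct trials; RT is the mean
#' over correct trials only (`NA` when a cell has no correct trial).
#'
#' @param table A scored table (see [score_accuracy()]).
#' @return Data frame: subject, condition, repetition, accuracy,
#'   objective_accuracy, rt_ms, n_trials.
#' @export
summarize_performance <- function(table) {
  if (!"correct_subjective" %in% names(table)) table <- score_accuracy(table)
  if (!"subject" %in% names(table)) table$subject <- 1L
  has_rt <- "rt_ms" %in% names(table)
  cells <- unique(table[, c("subject", "condition", "repetition")])
  cells <- cells[order(cells$subject, cells$condition, cells$repetition), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$subject == cells$subject[i] &
      table$condition == cells$condition[i] &
      table$repetition == cells$repetition[i]
    corr <- table$correct_subjective[sel]
    rt <- if (has_rt && any(corr)) mean(table$rt_ms[sel][corr]) else NA_real_
    data.frame(subject = cells$subject[i], condition = cells$condition[i],
               repetition = cells$repetition[i],
               accuracy = mean(corr),
               objective_accuracy = mean(table$correct_objective[sel]),
               rt_ms = rt, n_trials = sum(sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
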