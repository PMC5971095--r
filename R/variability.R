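# Subject-level and item-level variability: nonstandard-parsing and
# nonstandard-assignment rates, and Shannon entropy of phoneme assignments.

#' Shannon entropy of a categorical count vector
#'
#' \eqn{H = \sum_i -p_i \log_2 p_i} with \eqn{p_i = n_i / \sum n}, in bits.
#' Zero-count categories contribute nothing (the \eqn{0 \log 0 = 0}
#' convention). `H = 0` means unanimity — every observation in one
#' category; the maximum for `k` observed categories is `log2(k)`,
#' attained at uniform counts.
#'
#' @param counts Non-negative numeric vector (possibly named by category)
#'   with a positive total.
#' @return Entropy in bits (full precision; round only for display).
#' @examples
#' entropy(c("ʧ" = 3, k = 11, s = 1, "ʃ" = 2, "θ" = 1))  # 1.68 at 2 dp
#' entropy(c(7))                                          # unanimity: 0
#' @export
entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0 || anyNA(counts) || any(counts < 0)) {
    stop_graphovar("counts must be non-negative and non-missing", "graphovar_bad_counts")
  }
  total <- sum(counts)
  if (total <= 0) {
    stop_graphovar("counts must have a positive total", "graphovar_bad_counts")
  }
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Per-subject entropy of phoneme assignment
#'
#' For each subject and each eligible grapheme the subject parsed out,
#' the entropy of that subject's phoneme distribution for the grapheme;
#' plus each subject's mean over those graphemes. High values mark
#' subjects who assign many different phonemes to the same grapheme.
#'
#' @param tally Output of [tally_assignments()].
#' @param eligible Grapheme labels to include (see [eligible_graphemes()]).
#' @param min_occurrences Drop (subject, grapheme) cells whose total count
#'   is below this; default 1 keeps every parsed-out cell, so eligibility
#'   is the only filter.
#' @return A list with `per_cell` (tibble `subject_id`, `grapheme`, `n_total`,
#'   `H`) and `subject_means` (tibble `subject_id`, `mean_H`, `n_graphemes`).
#' @export
subject_grapheme_entropy <- function(tally, eligible, min_occurrences = 1L) {
  cells <- tally[tally$grapheme %in% eligible, , drop = FALSE]
  if (nrow(cells) == 0) {
    return(list(
      per_cell = tibble(subject_id = character(), grapheme = character(),
                        n_total = integer(), H = numeric()),
      subject_means = tibble(subject_id = character(), mean_H = numeric(),
                             n_graphemes = integer())
    ))
  }
  per_cell <- dplyr::summarise(
    dplyr::group_by(cells, .data$subject_id, .data$grapheme),
    n_total = sum(.data$n), H = entropy(.data$n), .groups = "drop"
  )
  per_cell <- per_cell[per_cell$n_total >= min_occurrences, , drop = FALSE]
  subject_means <- dplyr::summarise(
    dplyr::group_by(per_cell, .data$subject_id),
    mean_H = mean(.data$H), n_graphemes = dplyr::n(), .groups = "drop"
  )
  list(per_cell = per_cell, subject_means = subject_means)
}

#' Across-subject entropy of phoneme assignment per grapheme
#'
#' For each eligible grapheme, the entropy of the distribution of phoneme
#' assignments pooled over all subjects (`p_i` = proportion of all
#' assignments of the grapheme that used phoneme `i`). `method =
#' "mean_subject"` instead averages each subject's own entropy for the
#' grapheme — both views are available; pooling is the default because the
#' quantity of interest is variability across the participant group.
#'
#' @inheritParams subject_grapheme_entropy
#' @param method `"pooled"` (default) or `"mean_subject"`.
#' @return A tibble `grapheme`, `n_total`, `H`, sorted by decreasing `H`.
#' @export
grapheme_entropy_across_subjects <- function(tally, eligible,
                                             method = c("pooled", "mean_subject")) {
  method <- match.arg(method)
  cells <- tally[tally$grapheme %in% eligible, , drop = FALSE]
  if (nrow(cells) == 0) {
    return(tibble(grapheme = character(), n_total = integer(), H = numeric()))
  }
  if (method == "pooled") {
    pooled <- dplyr::count(cells, .data$grapheme, .data$phoneme, wt = .data$n, name = "n")
    out <- dplyr::summarise(dplyr::group_by(pooled, .data$grapheme),
                            n_total = sum(.data$n), H = entropy(.data$n),
                            .groups = "drop")
  } else {
    per <- dplyr::summarise(dplyr::group_by(cells, .data$subject_id, .data$grapheme),
                            n_total = sum(.data$n), H = entropy(.data$n),
                            .groups = "drop")
    out <- dplyr::summarise(dplyr::group_by(per, .data$grapheme),
                            n_total = sum(.data$n_total), H = mean(.data$H),
                            .groups = "drop")
  }
  dplyr::arrange(out, dplyr::desc(.data$H), .data$grapheme)
}

#' Nonstandard-parsing and nonstandard-assignment rates
#'
#' Per-subject and per-nonword percentages of nonstandard parsings, the
#' per-subject percentage of nonstandard phoneme assignments, and overall
#' totals. Every percentage is stored with its numerator and denominator;
#' zero-denominator cells are reported as `NA`, not 0.
#'
#' @param classifications Output of [classify_parsings()].
#' @param tally Output of [tally_assignments()] over the same records, or
#'   `NULL` to skip assignment rates.
#' @param inv A [gpc_inventory()] (used to classify assignments).
#' @param eligible Optional grapheme labels: restrict assignment rates to
#'   these graphemes (the usual analysis restricts to the eligible set).
#' @return A list of class `graphovar_rates`: `subject_parsing`,
#'   `item_parsing`, `subject_assignment` (tibbles with `n_nonstandard`,
#'   `n_total`, `pct`) and `overall` (one-row tibble of the pooled counts
#'   and percentages).
#' @export
nonstandard_rates <- function(classifications, tally = NULL,
                              inv = default_inventory(), eligible = NULL) {
  cls <- as_tibble(classifications)
  an <- cls[cls$status != "unanalysable", , drop = FALSE]
  rate_by <- function(df, key) {
    out <- dplyr::summarise(dplyr::group_by(df, .data[[key]]),
                            n_nonstandard = sum(.data$status == "nonstandard"),
                            n_total = dplyr::n(), .groups = "drop")
    out$pct <- ifelse(out$n_total > 0, 100 * out$n_nonstandard / out$n_total, NA_real_)
    out
  }
  subject_parsing <- rate_by(an, "subject_id")
  item_parsing <- rate_by(an, "nonword")
  subject_assignment <- NULL
  overall_assign <- tibble(n_nonstandard_assignments = NA_integer_,
                           n_assignments = NA_integer_,
                           assignment_pct = NA_real_)
  if (!is.null(tally) && nrow(tally) > 0) {
    tl <- tally
    if (!is.null(eligible)) tl <- tl[tl$grapheme %in% eligible, , drop = FALSE]
    tl$assignment <- classify_assignment(tl$grapheme, tl$phoneme, inv)
    subject_assignment <- dplyr::summarise(
      dplyr::group_by(tl, .data$subject_id),
      n_nonstandard = sum(.data$n[.data$assignment == "nonstandard"]),
      n_total = sum(.data$n), .groups = "drop"
    )
    subject_assignment$pct <- ifelse(subject_assignment$n_total > 0,
                                     100 * subject_assignment$n_nonstandard /
                                       subject_assignment$n_total, NA_real_)
    overall_assign <- tibble(
      n_nonstandard_assignments = sum(subject_assignment$n_nonstandard),
      n_assignments = sum(subject_assignment$n_total),
      assignment_pct = 100 * sum(subject_assignment$n_nonstandard) /
        sum(subject_assignment$n_total)
    )
  }
  overall <- tibble(
    n_records = nrow(cls),
    n_unanalysable = sum(cls$status == "unanalysable"),
    n_analysable = nrow(an),
    n_nonstandard_parsings = sum(an$status == "nonstandard"),
    parsing_pct = if (nrow(an) > 0) 100 * sum(an$status == "nonstandard") / nrow(an)
                  else NA_real_
  )
  overall <- dplyr::bind_cols(overall, overall_assign)
  structure(list(subject_parsing = subject_parsing, item_parsing = item_parsing,
                 subject_assignment = subject_assignment, overall = overall),
            class = "graphovar_rates")
}

#' @export
print.graphovar_rates <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Nonstandard parsings: %d of %d analysable responses (%.1f%%)\n",
              o$n_nonstandard_parsings, o$n_analysable, o$parsing_pct))
  if (!is.na(o$n_assignments)) {
    cat(sprintf("Nonstandard assignments: %d of %d (%.1f%%)\n",
                o$n_nonstandard_assignments, o$n_assignments, o$assignment_pct))
  }
  cat(sprintf("Subject parsing rates: %.2f%% to %.2f%% across %d subjects\n",
              min(x$subject_parsing$pct), max(x$subject_parsing$pct),
              nrow(x$subject_parsing)))
  invisible(x)
}

#' Distinct responses per nonword
#'
#' The number of different reading-aloud responses each nonword evoked,
#' among analysable records. Transcriptions are normalized to canonical
#' phoneme sequences first, so dialectal spellings of the same phonemes
#' (`tʃ` vs `ʧ`, stress marks, slashes) are not counted as distinct.
#'
#' @param records A response-record table.
#' @param phonemes A [phoneme_set()].
#' @return A tibble `nonword`, `n_distinct`, `n_responses`.
#' @export
distinct_response_counts <- function(records, phonemes = default_phonemes()) {
  records <- as_tibble(records)
  an <- records[records$analysable, , drop = FALSE]
  an$norm <- vapply(an$transcription, function(t)
    paste(tokenize_phonemes(t, phonemes), collapse = " "), character(1),
    USE.NAMES = FALSE)
  dplyr::summarise(dplyr::group_by(an, .data$nonword),
                   n_distinct = dplyr::n_distinct(.data$norm),
                   n_responses = dplyr::n(), .groups = "drop")
}
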