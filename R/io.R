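# Table readers/writers and the end-to-end report.

#' Read a subject-by-nonword response table
#'
#' Reads a CSV or TSV file (by extension) with header columns `subject_id`,
#' `nonword`, `transcription`. Nonwords are uppercased; rows with an empty
#' or untokenizable transcription are flagged `analysable = FALSE`.
#' Duplicate (subject, nonword) rows are reported in a message and resolved
#' last-wins. Supply `col_map` to adapt a file whose columns are named
#' differently.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping required names to
#'   the file's names, e.g. `c(subject_id = "Subj", nonword = "Item",
#'   transcription = "IPA")`.
#' @param phonemes A [phoneme_set()].
#' @return A response-record tibble (see [response_records()]).
#' @export
read_responses <- function(path, col_map = NULL, phonemes = default_phonemes()) {
  if (!file.exists(path)) {
    stop_graphovar(paste0("response file not found: ", path), "graphovar_bad_file")
  }
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  tab <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  if (!is.null(col_map)) {
    for (want in names(col_map)) {
      if (!col_map[[want]] %in% names(tab)) {
        stop_graphovar(paste0("mapped column not in file: ", col_map[[want]]),
                       "graphovar_bad_file")
      }
      names(tab)[names(tab) == col_map[[want]]] <- want
    }
  }
  need <- c("subject_id", "nonword", "transcription")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_graphovar(paste0("response table lacks columns: ", paste(miss, collapse = ", ")),
                   "graphovar_bad_file")
  }
  dup <- duplicated(tab[, c("subject_id", "nonword")], fromLast = TRUE)
  if (any(dup)) {
    message(sum(dup), " duplicate (subject, nonword) row(s); keeping the last of each")
    tab <- tab[!dup, , drop = FALSE]
  }
  response_records(tab$subject_id, tab$nonword, tab$transcription, phonemes)
}

#' Write a response table
#'
#' @param records A response-record tibble.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path) {
  writer <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::write_csv else readr::write_tsv
  writer(records[, c("subject_id", "nonword", "transcription")], path)
  invisible(path)
}

#' Run the full variability analysis
#'
#' The end-to-end pipeline: classify every response as a standard or
#' nonstandard parsing, tally grapheme-phoneme assignments over
#' standard-parse responses, apply the per-subject eligibility rule,
#' classify assignments, and compute subject-level and item-level rate and
#' entropy tables plus distinct-response counts. Conservation invariants
#' (standard + nonstandard + unanalysable = total; tally totals =
#' grapheme incidences) are asserted before the report is returned.
#'
#' @param records A response-record table ([read_responses()] /
#'   [response_records()] / [simulate_responses()]`$responses`).
#' @param inv A [gpc_inventory()].
#' @param min_per_subject Eligibility threshold, see [eligible_graphemes()].
#' @param out_dir Optional directory: write every table as TSV (plus a
#'   provenance header file). Partial outputs are removed on failure.
#' @return A list of class `graphovar_report`: `provenance` (counts and
#'   bookkeeping: total, unavailable, analysable, eligible-grapheme count,
#'   maximal GPC data points), `classifications`, `rates`
#'   (a [nonstandard_rates()] object), `tally`, `eligible`,
#'   `subject_entropy`, `grapheme_entropy`, `distinct_counts`.
#' @export
run_report <- function(records, inv = default_inventory(), min_per_subject = 4L,
                       out_dir = NULL) {
  records <- as_tibble(records)
  cls <- classify_parsings(records, inv)
  stopifnot(sum(cls$status %in% c("standard", "nonstandard", "unanalysable")) == nrow(cls))
  tally <- tally_assignments(cls, inv)
  n_std <- sum(cls$status == "standard")
  incidences <- sum(cls$n_graphemes[cls$status == "standard"])
  stopifnot(sum(tally$n) == incidences)
  eligible <- eligible_graphemes(tally, min_per_subject)
  rates <- nonstandard_rates(cls, tally, inv, eligible = eligible)
  subj_H <- subject_grapheme_entropy(tally, eligible)
  graph_H <- grapheme_entropy_across_subjects(tally, eligible)
  distinct <- distinct_response_counts(records, inv$phonemes)
  subjects <- unique(records$subject_id)
  per_sg <- dplyr::count(tally[tally$grapheme %in% eligible, , drop = FALSE],
                         .data$subject_id, .data$grapheme, wt = .data$n, name = "n")
  max_freq <- if (nrow(per_sg)) {
    dplyr::summarise(dplyr::group_by(per_sg, .data$grapheme),
                     max_n = max(.data$n), .groups = "drop")
  } else tibble(grapheme = character(), max_n = integer())
  provenance <- tibble(
    package_version = as.character(utils::packageVersion("graphovar")),
    inventory = inv$name,
    min_per_subject = as.integer(min_per_subject),
    n_subjects = length(subjects),
    n_nonwords = dplyr::n_distinct(records$nonword),
    n_potential = length(subjects) * dplyr::n_distinct(records$nonword),
    n_records = nrow(records),
    n_unavailable = sum(cls$status == "unanalysable"),
    n_analysable = sum(cls$status != "unanalysable"),
    n_standard_parsings = n_std,
    n_assignments = sum(tally$n[tally$grapheme %in% eligible]),
    n_eligible_graphemes = length(eligible),
    max_gpc_per_subject = sum(max_freq$max_n),
    max_gpc_total = sum(max_freq$max_n) * length(subjects)
  )
  report <- structure(
    list(provenance = provenance, classifications = cls, rates = rates,
         tally = tally, eligible = eligible, subject_entropy = subj_H,
         grapheme_entropy = graph_H, distinct_counts = distinct),
    class = "graphovar_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop_graphovar(paste0("failed writing report: ", conditionMessage(e)),
                   "graphovar_bad_file")
  }
  tryCatch({
    put <- function(df, name) {
      f <- file.path(out_dir, paste0(name, ".tsv"))
      readr::write_tsv(df, f)
      written <<- c(written, f)
    }
    put(report$provenance, "provenance")
    put(report$classifications, "parse_classifications")
    put(report$rates$subject_parsing, "subject_parsing_rates")
    put(report$rates$item_parsing, "item_parsing_rates")
    if (!is.null(report$rates$subject_assignment)) {
      put(report$rates$subject_assignment, "subject_assignment_rates")
    }
    put(report$rates$overall, "overall_rates")
    put(report$tally, "assignment_tally")
    put(tibble(grapheme = report$eligible), "eligible_graphemes")
    put(report$subject_entropy$per_cell, "subject_grapheme_entropy")
    put(report$subject_entropy$subject_means, "subject_mean_entropy")
    put(report$grapheme_entropy, "grapheme_entropy")
    put(report$distinct_counts, "distinct_response_counts")
  }, error = on_fail)
  invisible(out_dir)
}

#' @export
print.graphovar_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("graphovar report (inventory '%s')\n", p$inventory))
  cat(sprintf("  %d subjects x %d nonwords = %d potential responses\n",
              p$n_subjects, p$n_nonwords, p$n_potential))
  cat(sprintf("  %d unavailable, %d analysable, %d standard parsings\n",
              p$n_unavailable, p$n_analysable, p$n_standard_parsings))
  cat(sprintf("  %d eligible graphemes (>= %d per subject); %d assignments analysed\n",
              p$n_eligible_graphemes, p$min_per_subject, p$n_assignments))
  print(x$rates)
  if (nrow(x$grapheme_entropy)) {
    top <- x$grapheme_entropy[1, ]
    cat(sprintf("  most variable grapheme: %s (H = %.3f bits, pooled)\n",
                top$grapheme, top$H))
  }
  invisible(x)
}
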