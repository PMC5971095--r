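# Classifying responses and tallying grapheme-phoneme assignments.
#
# A response is a standard parsing iff the number of phonemes in the
# response equals the number of graphemes in the stimulus's standard parse;
# otherwise it is a nonstandard parsing. Only standard-parse responses admit
# an unambiguous one-to-one grapheme-phoneme pairing, so only they feed the
# assignment tally.

#' Build a response-record table
#'
#' @param subject_id Subject identifiers.
#' @param nonword Nonword spellings (uppercased).
#' @param transcription IPA transcriptions of the spoken responses; `NA` or
#'   empty marks a missing response.
#' @param phonemes A [phoneme_set()] used to decide analysability: a record
#'   is analysable iff its transcription is present and tokenizes.
#' @return A tibble with columns `subject_id`, `nonword`, `transcription`,
#'   `analysable`.
#' @export
response_records <- function(subject_id, nonword, transcription,
                             phonemes = default_phonemes()) {
  out <- tibble(subject_id = as.character(subject_id),
                nonword = toupper(as.character(nonword)),
                transcription = as.character(transcription))
  out$analysable <- tokenizes_ok(out$transcription, phonemes)
  out
}

# standard-parse cache over the distinct nonwords of a record set;
# unparseable nonwords get NULL
parse_cache <- function(nonwords, inv) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  for (nw in unique(nonwords)) {
    assign(nw, tryCatch(standard_parse(nw, inv), graphovar_error = function(e) NULL),
           envir = cache)
  }
  cache
}

#' Classify each response as a standard or nonstandard parsing
#'
#' For each analysable record, counts the graphemes of the stimulus's
#' standard parse and the phonemes of the response; the record is a
#' `"standard"` parsing iff the two counts are equal, else `"nonstandard"`.
#' Records whose transcription is missing or fails tokenization, or whose
#' nonword does not parse under the inventory, are `"unanalysable"` and are
#' excluded from all denominators. The classification is invariant to
#' transcription formatting (slashes, stress marks, spacing).
#'
#' @param records A response-record table (see [response_records()] /
#'   [read_responses()]).
#' @param inv A [gpc_inventory()].
#' @return The records tibble with added columns `n_graphemes`,
#'   `n_phonemes` and `status` (`standard` / `nonstandard` / `unanalysable`).
#' @examples
#' recs <- response_records("s1", c("SPRAUK", "SHOIL"), c("/sprʌŋk/", "/ʃɔɪl/"))
#' classify_parsings(recs, default_inventory())[, c("nonword", "status")]
#' @export
classify_parsings <- function(records, inv = default_inventory()) {
  records <- as_tibble(records)
  cache <- parse_cache(records$nonword, inv)
  n_g <- integer(nrow(records)); n_p <- integer(nrow(records))
  status <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    p <- get(records$nonword[i], envir = cache)
    ph <- if (isTRUE(records$analysable[i])) {
      tryCatch(tokenize_phonemes(records$transcription[i], inv$phonemes),
               graphovar_error = function(e) NULL)
    } else NULL
    if (is.null(p) || is.null(ph)) {
      n_g[i] <- if (is.null(p)) NA_integer_ else nrow(p)
      n_p[i] <- NA_integer_
      status[i] <- "unanalysable"
    } else {
      n_g[i] <- nrow(p); n_p[i] <- length(ph)
      status[i] <- if (n_p[i] == n_g[i]) "standard" else "nonstandard"
    }
  }
  records$n_graphemes <- n_g
  records$n_phonemes <- n_p
  records$status <- status
  records
}

#' Align a standard-parse response grapheme-to-phoneme
#'
#' For a response classified as a standard parsing, each grapheme of the
#' stimulus is unambiguously associated with one phoneme of the response in
#' order, and vice versa.
#'
#' @param nonword Stimulus spelling.
#' @param transcription Response IPA string.
#' @param inv A [gpc_inventory()].
#' @return A tibble with columns `grapheme` (label) and `phoneme`, one row
#'   per grapheme, in stimulus order.
#' @examples
#' align_standard("GNEUTH", "/nuθ/", default_inventory())
#' @export
align_standard <- function(nonword, transcription, inv = default_inventory()) {
  p <- standard_parse(nonword, inv)
  ph <- tokenize_phonemes(transcription, inv$phonemes)
  if (length(ph) != nrow(p)) {
    stop_graphovar(
      sprintf("nonstandard parsing: %s has %d graphemes but the response has %d phonemes",
              toupper(nonword), nrow(p), length(ph)),
      "graphovar_nonstandard_parsing"
    )
  }
  tibble(grapheme = p$label, phoneme = as.character(unname(unclass(ph))))
}

#' Tally grapheme-phoneme assignments per subject
#'
#' Aggregates the one-to-one grapheme-phoneme pairs of every analysable
#' standard-parse record; nonstandard-parse and unanalysable records
#' contribute nothing. Summing a subject's counts over phonemes gives the
#' number of times that subject parsed the grapheme out.
#'
#' @param records A response-record table, or the output of
#'   [classify_parsings()] (classification is recomputed if absent).
#' @param inv A [gpc_inventory()].
#' @return A tibble `subject_id`, `grapheme`, `phoneme`, `n` (all `n >= 1`),
#'   with the subjects present in `records` kept in attribute `"subjects"`.
#' @export
tally_assignments <- function(records, inv = default_inventory()) {
  records <- as_tibble(records)
  if (!"status" %in% names(records)) records <- classify_parsings(records, inv)
  std <- records[records$status == "standard", , drop = FALSE]
  cache <- parse_cache(std$nonword, inv)
  labs <- vector("list", nrow(std))
  phs <- vector("list", nrow(std))
  for (i in seq_len(nrow(std))) {
    p <- get(std$nonword[i], envir = cache)
    ph <- tokenize_phonemes(std$transcription[i], inv$phonemes)
    labs[[i]] <- p$label
    phs[[i]] <- as.character(ph)
  }
  out <- if (nrow(std)) {
    long <- tibble(subject_id = rep(std$subject_id, lengths(labs)),
                   grapheme = unlist(labs), phoneme = unlist(phs))
    dplyr::count(long, .data$subject_id, .data$grapheme, .data$phoneme, name = "n")
  } else {
    tibble(subject_id = character(), grapheme = character(),
           phoneme = character(), n = integer())
  }
  attr(out, "subjects") <- unique(records$subject_id)
  out
}

#' Graphemes eligible for assignment analysis
#'
#' A grapheme is eligible iff it occurs at least `min_per_subject` times in
#' every subject's set of standard-parse responses — a universal quantifier:
#' one subject below threshold excludes the grapheme. The default of 4
#' ensures each grapheme has a reasonable chance of being read in different
#' ways by each subject.
#'
#' @param tally Output of [tally_assignments()].
#' @param min_per_subject Minimum per-subject occurrence count.
#' @param subjects Subjects under analysis; defaults to those recorded in
#'   the tally's `"subjects"` attribute. A subject with no occurrences of a
#'   grapheme counts as zero.
#' @return Character vector of eligible grapheme labels, sorted.
#' @export
eligible_graphemes <- function(tally, min_per_subject = 4L,
                               subjects = attr(tally, "subjects")) {
  if (is.null(subjects)) subjects <- unique(tally$subject_id)
  if (nrow(tally) == 0) return(character(0))
  per <- dplyr::count(tally, .data$subject_id, .data$grapheme, wt = .data$n, name = "n")
  per <- tidyr::complete(per, subject_id = subjects, grapheme = unique(tally$grapheme),
                         fill = list(n = 0L))
  ok <- dplyr::summarise(dplyr::group_by(per, .data$grapheme),
                         eligible = min(.data$n) >= min_per_subject, .groups = "drop")
  sort(ok$grapheme[ok$eligible])
}

#' Classify a phoneme assignment as standard or nonstandard
#'
#' An assignment is standard iff the phoneme equals the grapheme's standard
#' phoneme in the inventory.
#'
#' @param grapheme Grapheme label(s).
#' @param phoneme Assigned phoneme(s), same length (or length 1).
#' @param inv A [gpc_inventory()].
#' @return Character vector `"standard"` / `"nonstandard"`.
#' @examples
#' classify_assignment("AU", c("ɔː", "aʊ"), default_inventory())
#' @export
classify_assignment <- function(grapheme, phoneme, inv = default_inventory()) {
  std <- standard_phoneme(inv, grapheme)
  ifelse(phoneme == std, "standard", "nonstandard")
}
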