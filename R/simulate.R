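# Synthetic reader-response generator. Emulates the study conditions the
# analysis assumes: a panel of subjects each reading the same set of
# monosyllabic nonwords aloud, with per-subject propensities to perturb the
# standard graphemic parse (splitting a multi-letter grapheme into its
# letters, omitting a grapheme, inserting one) and per-subject categorical
# phoneme distributions per grapheme concentrated on the standard phoneme.
# Every latent choice is recorded in a ground-truth ledger.

#' Simulation parameters
#'
#' Defaults mirror the study conditions the analysis targets: 45 subjects by
#' 412 monosyllabic nonwords with about 2.3% of responses missing or
#' unanalysable; per-subject nonstandard-parse propensities spanning
#' 3.16-36.65% and per-subject nonstandard-assignment propensities spanning
#' 9-31% (both drawn uniformly from those ranges).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_nonwords Number of nonwords to generate when `nonwords` is NULL.
#' @param nonwords Optional character vector of nonword spellings.
#' @param p_missing Probability a response is missing/unanalysable.
#' @param parse_rate_range Range of the per-subject probability that a
#'   response's parse is perturbed.
#' @param assign_rate_range Range of the per-subject probability that a
#'   grapheme receives a nonstandard phoneme.
#' @param perturb_weights Named weights for the perturbation type given a
#'   perturbation occurs (`split`, `omit`, `insert`). Splitting a
#'   multi-letter vowel grapheme into its letters is the most prominent
#'   nonstandard-parsing mechanism, so it carries the largest weight.
#' @param n_alternatives Number of nonstandard alternative phonemes in each
#'   (subject, grapheme) assignment distribution; their relative weights are
#'   Dirichlet(1) draws.
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_subjects = 45L, n_nonwords = 412L, nonwords = NULL,
                              p_missing = 0.023,
                              parse_rate_range = c(0.0316, 0.3665),
                              assign_rate_range = c(0.09, 0.31),
                              perturb_weights = c(split = 0.5, omit = 0.3, insert = 0.2),
                              n_alternatives = 2L, seed = 1L) {
  if (n_subjects < 2) stop_graphovar("n_subjects must be >= 2", "graphovar_bad_params")
  probs <- c(p_missing, parse_rate_range, assign_rate_range)
  if (any(probs < 0) || any(probs > 1)) {
    stop_graphovar("probabilities must lie in [0, 1]", "graphovar_bad_params")
  }
  if (diff(parse_rate_range) < 0 || diff(assign_rate_range) < 0) {
    stop_graphovar("rate ranges must be increasing", "graphovar_bad_params")
  }
  if (!all(c("split", "omit", "insert") %in% names(perturb_weights)) ||
      any(perturb_weights < 0) || sum(perturb_weights) <= 0) {
    stop_graphovar("perturb_weights must be non-negative with names split, omit, insert",
                   "graphovar_bad_params")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nonwords = as.integer(n_nonwords), nonwords = nonwords,
                 p_missing = p_missing, parse_rate_range = parse_rate_range,
                 assign_rate_range = assign_rate_range,
                 perturb_weights = perturb_weights[c("split", "omit", "insert")],
                 n_alternatives = as.integer(n_alternatives),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Generate monosyllabic nonword spellings
#'
#' Builds nonwords from onset, vowel and coda grapheme blocks of the
#' inventory, including split-digraph forms (O.E style and -QUE style), and
#' keeps the distinct spellings that parse under the inventory. Used by
#' [simulate_responses()] when no nonword list is supplied. Uses the current
#' RNG state.
#'
#' @param n Number of distinct nonwords.
#' @param inv A [gpc_inventory()].
#' @return Character vector of length `n`.
#' @export
generate_nonwords <- function(n, inv = default_inventory()) {
  onsets <- c("B", "BL", "BR", "C", "CL", "CR", "CH", "D", "DR", "F", "FL", "FR",
              "G", "GL", "GN", "GR", "H", "K", "L", "M", "N", "P", "PH", "PL",
              "PR", "PS", "R", "S", "SC", "SCR", "SH", "SK", "SL", "SM", "SN",
              "SP", "SPR", "ST", "STR", "SW", "T", "TH", "TR", "TW", "V", "W",
              "WH", "Z")
  vowels <- c("A", "E", "I", "O", "U", "AI", "AU", "EA", "EE", "EU", "OA", "OI",
              "OO", "OU", "OW")
  open_vowels <- c("AI", "AU", "EA", "EE", "OA", "OI", "OO", "OW")
  codas <- c("B", "C", "CK", "D", "F", "FF", "G", "K", "L", "LL", "LF", "LK",
             "LP", "LT", "M", "MP", "N", "ND", "NT", "P", "S", "SH", "SK", "SP",
             "ST", "T", "TH", "Z")
  split_codas <- c("B", "C", "D", "F", "K", "L", "M", "N", "P", "S", "T", "V", "Z")
  heads <- c("A", "E", "I", "O", "U")
  out <- character(0)
  tries <- 0L
  while (length(out) < n && tries < 200L * n) {
    tries <- tries + 1L
    type <- sample(c("plain", "open", "split", "que"), 1,
                   prob = c(0.55, 0.10, 0.25, 0.10))
    w <- switch(type,
      plain = paste0(sample(onsets, 1), sample(vowels, 1), sample(codas, 1)),
      open = paste0(sample(onsets, 1), sample(open_vowels, 1)),
      split = paste0(sample(onsets, 1), sample(heads, 1), sample(split_codas, 1), "E"),
      que = paste0(sample(onsets, 1), sample(heads, 1), "QUE"))
    if (w %in% out) next
    ok <- !inherits(tryCatch(standard_parse(w, inv), graphovar_error = function(e) e),
                    "error")
    if (ok) out <- c(out, w)
  }
  if (length(out) < n) {
    stop_graphovar("could not generate enough distinct nonwords", "graphovar_bad_params")
  }
  out
}

# can tokens p1, p2 sit adjacent without the greedy tokenizer merging them?
merge_safe_matrix <- function(phonemes) {
  ipa <- phonemes$ipa
  m <- matrix(TRUE, length(ipa), length(ipa), dimnames = list(ipa, ipa))
  for (i in seq_along(ipa)) {
    for (j in seq_along(ipa)) {
      tok <- tokenize_phonemes(paste0(ipa[i], ipa[j]), phonemes)
      m[i, j] <- length(tok) == 2L && tok[1] == ipa[i] && tok[2] == ipa[j]
    }
  }
  m
}

#' Simulate reader responses with a ground-truth ledger
#'
#' For each (subject, nonword) pair: with probability `p_missing` the
#' response is missing; otherwise, with the subject's parse-perturbation
#' propensity the standard parse is perturbed (a multi-letter grapheme split
#' into its constituent letters, a grapheme omitted, or an extra glide/schwa
#' phoneme inserted), and each resulting grapheme receives a phoneme drawn
#' from the subject's categorical distribution for that grapheme — the
#' standard phoneme with probability one minus the subject's assignment
#' propensity, else one of a small set of same-class alternatives. The
#' emitted transcription is the IPA concatenation; adjacent phonemes that
#' the greedy tokenizer would merge into one (e.g. a stray `ə`+`ʊ`) are
#' resolved by falling back to a non-merging phoneme, so the emitted string
#' always re-tokenizes to exactly the intended phoneme count. Consequently
#' every parse-perturbed record is classified nonstandard by
#' [classify_parsings()] and every unperturbed record standard, by
#' construction.
#'
#' @param params A [simulation_params()] object.
#' @param inv A [gpc_inventory()].
#' @return A list of class `graphovar_simulation`: `responses` (a
#'   response-record table), `ledger` (one row per record: `perturbation`,
#'   `n_graphemes`, `n_phonemes`, `n_assignments`, `n_nonstandard_assign`),
#'   `subject_params` (per-subject generative propensities `parse_rate`,
#'   `assign_rate`), `nonwords`, and `params`.
#' @export
simulate_responses <- function(params = simulation_params(), inv = default_inventory()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  ns <- params$n_subjects
  subject_params <- tibble(
    subject_id = sprintf("S%02d", seq_len(ns)),
    parse_rate = runif(ns, params$parse_rate_range[1], params$parse_rate_range[2]),
    assign_rate = runif(ns, params$assign_rate_range[1], params$assign_rate_range[2])
  )
  nonwords <- params$nonwords
  if (is.null(nonwords)) nonwords <- generate_nonwords(params$n_nonwords, inv)
  nonwords <- toupper(nonwords)
  parses <- lapply(nonwords, standard_parse, inv = inv)
  names(parses) <- nonwords
  safe <- merge_safe_matrix(inv$phonemes)
  klass_of <- attr(inv$phonemes, "klass_of")
  by_class <- split(names(klass_of), klass_of)
  plain_letter <- local({
    # single-letter graphemes without positional/contextual restriction
    tab <- new.env(hash = TRUE, parent = emptyenv())
    function(letter) {
      d <- get0(letter, envir = tab, inherits = FALSE)
      if (is.null(d)) {
        idx <- which(inv$rules$pattern == letter & !inv$rules$is_split &
                       inv$rules$context == "" & inv$rules$position == "any")[1]
        if (is.na(idx)) stop_graphovar(paste0("no plain rule for letter ", letter),
                                       "graphovar_bad_inventory")
        d <- list(label = inv$rules$label[idx], phoneme = inv$rules$phoneme[idx],
                  klass = inv$rules$klass[idx])
        assign(letter, d, envir = tab)
      }
      d
    }
  })
  dist_cache <- new.env(hash = TRUE, parent = emptyenv())
  assign_dist <- function(subject, label, std) {
    key <- paste0(subject, "\r", label)
    d <- get0(key, envir = dist_cache, inherits = FALSE)
    if (is.null(d)) {
      pool <- setdiff(by_class[[klass_of[[std]]]], std)
      alts <- sample(pool, min(params$n_alternatives, length(pool)))
      wt <- rgamma(length(alts), 1)
      d <- list(alts = alts, probs = wt / sum(wt))
      assign(key, d, envir = dist_cache)
    }
    d
  }
  weights <- params$perturb_weights
  glides <- c("ə", "w", "j")
  nrec <- ns * length(nonwords)
  rec_subject <- character(nrec); rec_nonword <- character(nrec)
  rec_transcription <- rep(NA_character_, nrec); rec_analysable <- logical(nrec)
  led_perturbation <- character(nrec); led_n_graphemes <- integer(nrec)
  led_n_phonemes <- rep(NA_integer_, nrec); led_n_assignments <- integer(nrec)
  led_n_nonstd <- integer(nrec)
  r <- 0L
  for (s in seq_len(ns)) {
    sid <- subject_params$subject_id[s]
    q <- subject_params$parse_rate[s]
    a <- subject_params$assign_rate[s]
    for (nw in nonwords) {
      r <- r + 1L
      p <- parses[[nw]]
      G <- nrow(p)
      rec_subject[r] <- sid; rec_nonword[r] <- nw
      led_n_graphemes[r] <- G
      if (runif(1) < params$p_missing) {
        led_perturbation[r] <- "missing"
        next
      }
      glab <- p$label; gstd <- p$phoneme; gkl <- p$klass
      insert_at <- NA_integer_
      perturbation <- "none"
      if (runif(1) < q) {
        multi <- which(nchar(gsub(".", "", p$pattern, fixed = TRUE)) >= 2)
        feasible <- c(if (length(multi)) "split", if (G >= 2) "omit", "insert")
        type <- sample(feasible, 1, prob = weights[feasible])
        perturbation <- type
        if (type == "split") {
          k <- if (length(multi) == 1) multi else sample(multi, 1)
          chars <- strsplit(gsub(".", "", p$pattern[k], fixed = TRUE), "")[[1]]
          reps <- lapply(chars, plain_letter)
          r_lab <- vapply(reps, `[[`, "", "label")
          r_std <- vapply(reps, `[[`, "", "phoneme")
          r_kl <- vapply(reps, `[[`, "", "klass")
          # a split digraph's tail letter is word-final: letters keep their
          # span order, so head letters replace in place and a tail goes last
          if (!is.na(p$tail_start[k])) {
            nh <- nchar(sub("\\..*$", "", p$pattern[k]))
            hseq <- seq_len(nh)
            glab <- c(glab[seq_len(k - 1)], r_lab[hseq], glab[-seq_len(k)], r_lab[-hseq])
            gstd <- c(gstd[seq_len(k - 1)], r_std[hseq], gstd[-seq_len(k)], r_std[-hseq])
            gkl <- c(gkl[seq_len(k - 1)], r_kl[hseq], gkl[-seq_len(k)], r_kl[-hseq])
          } else {
            glab <- append(glab[-k], r_lab, after = k - 1)
            gstd <- append(gstd[-k], r_std, after = k - 1)
            gkl <- append(gkl[-k], r_kl, after = k - 1)
          }
        } else if (type == "omit") {
          k <- sample.int(length(glab), 1)
          glab <- glab[-k]; gstd <- gstd[-k]; gkl <- gkl[-k]
        } else {
          insert_at <- sample.int(length(glab) + 1L, 1) - 1L
        }
      }
      # draw assignments left to right, vetoing merges with the previous token
      ph <- character(0)
      n_nonstd <- 0L
      emit <- function(cand, std) {
        prev <- if (length(ph)) ph[length(ph)] else NULL
        ok <- function(x) is.null(prev) || safe[prev, x]
        if (!ok(cand)) {
          if (!is.null(std) && ok(std)) cand <- std
          else {
            pool <- by_class[[klass_of[[cand]]]]
            cand <- pool[which(vapply(pool, ok, logical(1)))[1]]
          }
        }
        cand
      }
      gi <- 0L
      for (k in seq_along(glab)) {
        if (!is.na(insert_at) && insert_at == k - 1L) {
          ph <- c(ph, emit(sample(glides, 1), NULL))
        }
        d <- NULL
        cand <- if (runif(1) < a) {
          d <- assign_dist(sid, glab[k], gstd[k])
          sample(d$alts, 1, prob = d$probs)
        } else gstd[k]
        cand <- emit(cand, gstd[k])
        if (cand != gstd[k]) n_nonstd <- n_nonstd + 1L
        ph <- c(ph, cand)
      }
      if (!is.na(insert_at) && insert_at == length(glab)) {
        ph <- c(ph, emit(sample(glides, 1), NULL))
      }
      rec_transcription[r] <- paste0("/", paste(ph, collapse = ""), "/")
      rec_analysable[r] <- TRUE
      led_perturbation[r] <- perturbation
      led_n_phonemes[r] <- length(ph)
      led_n_assignments[r] <- length(glab)
      led_n_nonstd[r] <- n_nonstd
    }
  }
  responses <- tibble(subject_id = rec_subject, nonword = rec_nonword,
                      transcription = rec_transcription, analysable = rec_analysable)
  ledger <- tibble(subject_id = rec_subject, nonword = rec_nonword,
                   perturbation = led_perturbation, n_graphemes = led_n_graphemes,
                   n_phonemes = led_n_phonemes, n_assignments = led_n_assignments,
                   n_nonstandard_assign = led_n_nonstd)
  structure(list(responses = responses, ledger = ledger,
                 subject_params = subject_params, nonwords = nonwords,
                 params = params),
            class = "graphovar_simulation")
}

#' @export
print.graphovar_simulation <- function(x, ...) {
  cat(sprintf("<simulation: %d subjects x %d nonwords, %d missing, seed %d>\n",
              nrow(x$subject_params), length(x$nonwords),
              sum(x$ledger$perturbation == "missing"), x$params$seed))
  invisible(x)
}

#' Recover generative parameters from a simulation
#'
#' Runs the full analysis pipeline on simulated responses and compares the
#' per-subject estimates with the generative propensities in the ground
#' truth: the estimated nonstandard-parsing rate against the subject's
#' parse-perturbation propensity and the estimated nonstandard-assignment
#' rate against the subject's assignment propensity, each with its binomial
#' standard error. Also checks exact classification consistency: the
#' pipeline's nonstandard-parse count must equal the ledger's perturbed
#' count, subject by subject.
#'
#' @param sim A `graphovar_simulation` from [simulate_responses()].
#' @param inv The [gpc_inventory()] used for the simulation.
#' @return A list of class `graphovar_recovery`: `parse` and `assignment`
#'   tibbles (per subject: `true`, `estimate`, `n`, `se`, `within_3se`) and
#'   a one-row `summary` (fractions of subjects within 3 SE, and
#'   `consistent` = TRUE when pipeline and ledger classifications agree
#'   exactly).
#' @export
recover_parameters <- function(sim, inv = default_inventory()) {
  stopifnot(inherits(sim, "graphovar_simulation"))
  cls <- classify_parsings(sim$responses, inv)
  an <- cls[cls$status != "unanalysable", , drop = FALSE]
  est_parse <- dplyr::summarise(dplyr::group_by(an, .data$subject_id),
                                n = dplyr::n(),
                                estimate = mean(.data$status == "nonstandard"),
                                .groups = "drop")
  led <- sim$ledger[sim$ledger$perturbation != "missing", , drop = FALSE]
  led_parse <- dplyr::summarise(dplyr::group_by(led, .data$subject_id),
                                ledger_rate = mean(.data$perturbation != "none"),
                                .groups = "drop")
  parse <- dplyr::left_join(est_parse, led_parse, by = "subject_id")
  parse <- dplyr::left_join(parse,
                            sim$subject_params[, c("subject_id", "parse_rate")],
                            by = "subject_id")
  parse$true <- parse$parse_rate
  parse$se <- sqrt(parse$true * (1 - parse$true) / parse$n)
  parse$within_3se <- abs(parse$estimate - parse$true) <= 3 * parse$se
  tl <- tally_assignments(cls, inv)
  tl$assignment <- classify_assignment(tl$grapheme, tl$phoneme, inv)
  est_assign <- dplyr::summarise(
    dplyr::group_by(tl, .data$subject_id),
    estimate = sum(.data$n[.data$assignment == "nonstandard"]) / sum(.data$n),
    n = sum(.data$n),
    .groups = "drop"
  )
  assignment <- dplyr::left_join(
    est_assign, sim$subject_params[, c("subject_id", "assign_rate")],
    by = "subject_id"
  )
  assignment$true <- assignment$assign_rate
  assignment$se <- sqrt(assignment$true * (1 - assignment$true) / assignment$n)
  assignment$within_3se <- abs(assignment$estimate - assignment$true) <= 3 * assignment$se
  led_nonstd <- dplyr::summarise(
    dplyr::group_by(led[led$perturbation == "none", , drop = FALSE], .data$subject_id),
    ledger_nonstd = sum(.data$n_nonstandard_assign),
    ledger_n = sum(.data$n_assignments), .groups = "drop"
  )
  est_counts <- dplyr::summarise(
    dplyr::group_by(tl, .data$subject_id),
    est_nonstd = sum(.data$n[.data$assignment == "nonstandard"]),
    est_n = sum(.data$n), .groups = "drop"
  )
  cons <- dplyr::left_join(led_nonstd, est_counts, by = "subject_id")
  led_counts <- dplyr::summarise(dplyr::group_by(led, .data$subject_id),
                                 n_perturbed = sum(.data$perturbation != "none"),
                                 .groups = "drop")
  est_nonstd_parse <- dplyr::summarise(dplyr::group_by(an, .data$subject_id),
                                       n_nonstandard = sum(.data$status == "nonstandard"),
                                       .groups = "drop")
  pc <- dplyr::left_join(led_counts, est_nonstd_parse, by = "subject_id")
  consistent <- all(pc$n_perturbed == pc$n_nonstandard) &&
    all(cons$ledger_nonstd == cons$est_nonstd) && all(cons$ledger_n == cons$est_n)
  summary <- tibble(
    prop_parse_within_3se = mean(parse$within_3se),
    prop_assign_within_3se = mean(assignment$within_3se),
    parse_mae = mean(abs(parse$estimate - parse$true)),
    assign_mae = mean(abs(assignment$estimate - assignment$true)),
    consistent = consistent
  )
  structure(list(parse = parse, assignment = assignment, summary = summary),
            class = "graphovar_recovery")
}

#' @export
print.graphovar_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<parameter recovery: %.0f%% of subjects within 3 SE on parse rate, ",
                     "%.0f%% on assignment rate; classification consistent: %s>\n"),
              100 * s$prop_parse_within_3se, 100 * s$prop_assign_within_3se,
              s$consistent))
  invisible(x)
}
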