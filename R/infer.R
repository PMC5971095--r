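# Diagnostic aligner: which graphemic parsing does a transcribed response
# imply? Headline counts never depend on this; parsings are classified
# standard/nonstandard purely by the phoneme-count rule.

#' Edit costs for response-to-parse alignment
#'
#' @param match Cost of a grapheme receiving its standard phoneme.
#' @param sub Cost of a nonstandard substitution where the phoneme's class
#'   (vowel/consonant) matches the grapheme's.
#' @param sub_cross Cost of a cross-class substitution (e.g. a vowel
#'   grapheme aligned with a consonant phoneme). Penalized above `sub` so
#'   that phonologically implausible alignments do not undercut parses in
#'   which every phoneme is licensed by a grapheme of the right class.
#' @param omit Cost of a grapheme with no phoneme (grapheme omission).
#' @param insert Cost of a phoneme with no grapheme (phoneme insertion).
#' @param ceiling Maximum total cost; alignments above it raise a
#'   `graphovar_no_alignment` error.
#' @return A named list of costs.
#' @export
infer_costs <- function(match = 0, sub = 1, sub_cross = 2, omit = 2, insert = 2,
                        ceiling = Inf) {
  stopifnot(match <= sub, sub <= sub_cross, omit > 0, insert > 0)
  list(match = match, sub = sub, sub_cross = sub_cross, omit = omit,
       insert = insert, ceiling = ceiling)
}

# Needleman-Wunsch over (grapheme, phoneme) positions for one candidate
# parse; minimizes (cost, structural edits) lexicographically.
align_parse_response <- function(parse, ph, ph_klass, costs) {
  G <- nrow(parse)
  P <- length(ph)
  cost <- matrix(Inf, G + 1L, P + 1L)
  strc <- matrix(Inf, G + 1L, P + 1L)
  move <- matrix(NA_character_, G + 1L, P + 1L)
  cost[1, 1] <- 0; strc[1, 1] <- 0
  for (i in seq_len(G)) {
    cost[i + 1L, 1] <- i * costs$omit; strc[i + 1L, 1] <- i; move[i + 1L, 1] <- "omit"
  }
  for (j in seq_len(P)) {
    cost[1, j + 1L] <- j * costs$insert; strc[1, j + 1L] <- j; move[1, j + 1L] <- "insert"
  }
  for (i in seq_len(G)) {
    std <- parse$phoneme[i]
    gkl <- parse$klass[i]
    for (j in seq_len(P)) {
      dc <- if (ph[j] == std) costs$match
            else if (ph_klass[j] == gkl) costs$sub else costs$sub_cross
      cand_cost <- c(cost[i, j] + dc, cost[i, j + 1L] + costs$omit,
                     cost[i + 1L, j] + costs$insert)
      cand_str <- c(strc[i, j], strc[i, j + 1L] + 1L, strc[i + 1L, j] + 1L)
      best <- order(cand_cost, cand_str)[1]
      cost[i + 1L, j + 1L] <- cand_cost[best]
      strc[i + 1L, j + 1L] <- cand_str[best]
      move[i + 1L, j + 1L] <- c("diag", "omit", "insert")[best]
    }
  }
  # backtrace
  ops <- list()
  i <- G + 1L; j <- P + 1L
  while (i > 1L || j > 1L) {
    m <- move[i, j]
    if (m == "diag") {
      i <- i - 1L; j <- j - 1L
      ops[[length(ops) + 1L]] <- tibble(
        op = if (ph[j] == parse$phoneme[i]) "match" else "substitute",
        grapheme = parse$label[i], phoneme = ph[j])
    } else if (m == "omit") {
      i <- i - 1L
      ops[[length(ops) + 1L]] <- tibble(op = "omit", grapheme = parse$label[i],
                                        phoneme = NA_character_)
    } else {
      j <- j - 1L
      ops[[length(ops) + 1L]] <- tibble(op = "insert", grapheme = NA_character_,
                                        phoneme = ph[j])
    }
  }
  edits <- dplyr::bind_rows(rev(ops))
  list(cost = cost[G + 1L, P + 1L], structural = strc[G + 1L, P + 1L], edits = edits)
}

#' Infer the graphemic parsing implied by a response
#'
#' Searches over candidate segmentations of the stimulus
#' (via [enumerate_parses()]) and, for each, computes the minimum-cost
#' grapheme-phoneme alignment allowing nonstandard substitutions, grapheme
#' omissions and phoneme insertions. The winning parse minimizes, in order:
#' total edit cost; number of structural edits (insertions plus omissions);
#' distance from the standard parse. The structural tie-break reflects the
#' interpretation that extra phonemes arise from a grapheme being parsed as
#' its constituent letters (each licensed by a grapheme) rather than from
#' free-floating insertions. This is a diagnostic; parse classification
#' itself uses only the phoneme-count rule ([classify_parsings()]).
#'
#' @inheritParams standard_parse
#' @param response An IPA string, or a phoneme vector from
#'   [tokenize_phonemes()].
#' @param costs Edit costs, see [infer_costs()].
#' @param max_count Maximum number of candidate parses examined.
#' @return A list of class `graphovar_inferred`: `parsing` (the winning
#'   `graphovar_parse`), `edits` (tibble of aligned operations in stimulus
#'   order), `cost`, `structural`, and `standard` (TRUE if the winner is the
#'   standard parse with zero cost).
#' @examples
#' inf <- infer_parse("SPRAUK", "/spɔːk/", default_inventory())
#' subset(inf$edits, op == "omit")
#' @export
infer_parse <- function(stimulus, response, inv = default_inventory(),
                        costs = infer_costs(), max_count = 200L) {
  ph <- if (is.character(response) && length(response) == 1L && is.null(attr(response, "source"))) {
    tokenize_phonemes(response, inv$phonemes)
  } else {
    as.character(response)
  }
  ph_klass <- phoneme_class(ph, inv$phonemes)
  cands <- enumerate_parses(stimulus, inv, max_count = max_count)
  std <- cands[[1]]
  std_sig <- paste(std$label, std$start, collapse = "|")
  best <- NULL
  best_key <- c(Inf, Inf, Inf, Inf)
  for (k in seq_along(cands)) {
    p <- cands[[k]]
    al <- align_parse_response(p, ph, ph_klass, costs)
    shared <- sum(paste(p$label, p$start) %in% paste(std$label, std$start))
    key <- c(al$cost, al$structural, nrow(std) - shared, k)
    if (is.null(best) || order_keys(key, best_key) < 0) {
      best <- c(al, list(parsing = p))
      best_key <- key
    }
  }
  if (best$cost > costs$ceiling) {
    stop_graphovar(sprintf("no alignment of %s with the response within cost ceiling %s",
                           toupper(stimulus), format(costs$ceiling)),
                   "graphovar_no_alignment")
  }
  structure(list(parsing = best$parsing, edits = best$edits, cost = best$cost,
                 structural = best$structural,
                 standard = best$cost == 0 &&
                   paste(best$parsing$label, best$parsing$start, collapse = "|") == std_sig),
            class = "graphovar_inferred")
}

# lexicographic comparison of numeric keys: -1 if a < b, 0 if equal, 1 if a > b
order_keys <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  0L
}

#' @export
print.graphovar_inferred <- function(x, ...) {
  cat(sprintf("<inferred parse %s: cost %g, %d structural edit(s)%s>\n",
              format(x$parsing), x$cost, x$structural,
              if (x$standard) ", standard" else ""))
  invisible(x)
}
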