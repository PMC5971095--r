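#' Construct a grapheme-phoneme correspondence (GPC) inventory
#'
#' A GPC inventory is a set of rules, each mapping one grapheme — a letter
#' pattern, possibly discontinuous — to its standard phoneme. Discontinuous
#' split digraphs are written with a gap marker, e.g. `O.E` (as in STOLE) or
#' `A.UE` (as in PLAQUE): the head letters precede the gap and the silent
#' tail (`E` or `UE`) is anchored at the end of the word. A rule may be
#' restricted by position (`onset` = word-initial, `coda` = word-final,
#' `any`) and by letter context (`next=E,I,Y` or `prev=Q` style conditions),
#' so that e.g. G and G (before E) are different graphemes.
#'
#' @param rules A data frame with columns `pattern`, `position`, `context`,
#'   `phoneme` and optionally `precedence` (integer rank used as final
#'   tie-break in parsing) and `label` (display name; defaults to the pattern,
#'   annotated with the context where present).
#' @param name Identifier for the inventory.
#' @param phonemes A [phoneme_set()] used to validate the standard phonemes.
#' @param check_letters If `TRUE`, warn when a single letter A-Z has no rule
#'   (letter strings containing it cannot be parsed).
#' @return An object of class `gpc_inventory`.
#' @seealso [load_inventory()], [standard_parse()]
#' @export
gpc_inventory <- function(rules, name = "custom", phonemes = default_phonemes(),
                          check_letters = FALSE) {
  rules <- as_tibble(rules)
  need <- c("pattern", "position", "context", "phoneme")
  miss <- setdiff(need, names(rules))
  if (length(miss)) {
    stop_graphovar(paste0("rule table lacks columns: ", paste(miss, collapse = ", ")),
                   "graphovar_bad_inventory")
  }
  rules$pattern <- toupper(rules$pattern)
  rules$position[is.na(rules$position) | !nzchar(rules$position)] <- "any"
  rules$context[is.na(rules$context)] <- ""
  if (!all(rules$position %in% c("onset", "coda", "any"))) {
    stop_graphovar("position must be one of onset, coda, any", "graphovar_bad_inventory")
  }
  if (any(!grepl("^[A-Z]+(\\.[A-Z]+)?$", rules$pattern))) {
    bad <- rules$pattern[!grepl("^[A-Z]+(\\.[A-Z]+)?$", rules$pattern)]
    stop_graphovar(paste0("malformed pattern(s): ", paste(bad, collapse = ", ")),
                   "graphovar_bad_inventory")
  }
  is_split <- grepl(".", rules$pattern, fixed = TRUE)
  tails <- sub("^[A-Z]+\\.", "", rules$pattern[is_split])
  if (length(tails) && !all(tails %in% c("E", "UE"))) {
    stop_graphovar("split-grapheme tails must be E or UE", "graphovar_bad_inventory")
  }
  key <- paste(rules$pattern, rules$position, rules$context, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- rules$pattern[duplicated(key)]
    stop_graphovar(paste0("duplicate rule for (pattern, position, context): ",
                          paste(unique(dup), collapse = ", ")),
                   "graphovar_duplicate_rule")
  }
  # validates every standard phoneme against the phoneme inventory
  rules$klass <- phoneme_class(rules$phoneme, phonemes)
  if (!"precedence" %in% names(rules)) rules$precedence <- seq_len(nrow(rules))
  rules$precedence <- as.integer(rules$precedence)
  if (!"label" %in% names(rules)) rules$label <- NA_character_
  auto <- is.na(rules$label) | !nzchar(rules$label)
  rules$label[auto] <- rules$pattern[auto]
  rules$head <- ifelse(is_split, sub("\\..*$", "", rules$pattern), rules$pattern)
  rules$tail <- ifelse(is_split, sub("^[A-Z]+\\.", "", rules$pattern), "")
  rules$is_split <- is_split
  rules <- rules[order(rules$precedence), ]
  if (check_letters) {
    covered <- unique(unlist(strsplit(rules$pattern[!is_split & nchar(rules$pattern) == 1], "")))
    missing_letters <- setdiff(LETTERS, covered)
    if (length(missing_letters)) {
      warn(paste0("no single-letter rule for: ", paste(missing_letters, collapse = ", "),
                  "; strings using these letters may fail to parse"))
    }
  }
  structure(list(rules = rules, name = name, phonemes = phonemes),
            class = "gpc_inventory")
}

#' @export
print.gpc_inventory <- function(x, ...) {
  cat(sprintf("<gpc_inventory '%s': %d rules (%d split digraphs), %d phonemes>\n",
              x$name, nrow(x$rules), sum(x$rules$is_split), nrow(x$phonemes)))
  invisible(x)
}

#' Load a GPC rule file
#'
#' Reads a tab-separated rule file with columns `pattern`, `position`,
#' `context`, `phoneme`, `precedence`, `label` (one rule per line) and
#' validates it: duplicate (pattern, position, context) triples and unknown
#' phonemes are rejected with an informative error.
#'
#' @param path Path to the rule file. Defaults to the inventory shipped with
#'   the package, a DRC-style English GPC table covering all single letters,
#'   common multi-letter graphemes, and the split digraphs `A.E`...`U.E`
#'   plus the longer-tailed `A.UE`, `AI.E`, `OU.E`, ... family.
#' @param name Inventory identifier; defaults to the file name.
#' @param phonemes A [phoneme_set()].
#' @return A [gpc_inventory()].
#' @export
load_inventory <- function(path = NULL, name = NULL, phonemes = default_phonemes()) {
  if (is.null(path)) path <- system.file("extdata", "gpc_rules.tsv", package = "graphovar")
  if (!file.exists(path)) {
    stop_graphovar(paste0("rule file not found: ", path), "graphovar_bad_file")
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) stop_graphovar(paste0("cannot read rule file: ", conditionMessage(e)),
                                       "graphovar_bad_file")
  )
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    stop_graphovar(sprintf("rule file format error at line %d: %s",
                           prob$row[1] + 1L, prob$expected[1]),
                   "graphovar_bad_file")
  }
  gpc_inventory(tab, name = name, phonemes = phonemes, check_letters = TRUE)
}

#' Default English GPC inventory
#'
#' Loads (and caches) the rule table shipped with the package.
#' @return A [gpc_inventory()].
#' @export
default_inventory <- function() {
  if (is.null(the$inventory)) the$inventory <- load_inventory()
  the$inventory
}

#' Standard phoneme of a grapheme
#'
#' The standard phoneme assignment of a grapheme is the phoneme most often
#' corresponding to it in the monosyllabic words of English, position and
#' context taken into account; the inventory stores one such phoneme per
#' rule. Pure lookup by grapheme label (e.g. `"AU"`, `"O.E"`,
#' `"G(before E)"`).
#'
#' @param inv A [gpc_inventory()].
#' @param grapheme Grapheme label(s).
#' @return Character vector of phonemes.
#' @examples
#' standard_phoneme(default_inventory(), c("AU", "SH", "OI"))
#' @export
standard_phoneme <- function(inv, grapheme) {
  idx <- match(grapheme, inv$rules$label)
  if (anyNA(idx)) {
    stop_graphovar(paste0("grapheme not in inventory: ",
                          paste(grapheme[is.na(idx)], collapse = ", ")),
                   "graphovar_missing_grapheme")
  }
  inv$rules$phoneme[idx]
}

#' Derive standard phoneme assignments from a lexicon by majority
#'
#' Re-estimates each grapheme's standard phoneme as the phoneme that occurs
#' most often for that grapheme across a lexicon of monosyllabic words,
#' counting by word type (each spelling once), with position and context
#' taken into account via the inventory's rules. Words whose standard parse
#' length differs from their pronunciation length cannot be aligned
#' one-to-one and are skipped (reported in attribute `"skipped"`).
#'
#' Majority ties break deterministically: first by the tied phoneme's summed
#' count across all graphemes in the lexicon, then lexicographically by ipa;
#' a `graphovar_tie` warning reports each tie so resolved.
#'
#' @param lexicon A data frame with columns `spelling` and `ipa`.
#' @param inv A [gpc_inventory()] supplying the graphemic parses.
#' @return A new [gpc_inventory()] with updated standard phonemes (and
#'   phoneme classes); the input is unchanged. Graphemes never observed in
#'   the lexicon keep their current standard phoneme.
#' @export
derive_standard_assignments <- function(lexicon, inv) {
  lexicon <- as_tibble(lexicon)
  if (!all(c("spelling", "ipa") %in% names(lexicon))) {
    stop_graphovar("lexicon must have columns spelling, ipa", "graphovar_bad_file")
  }
  lexicon <- dplyr::distinct(lexicon, spelling = toupper(.data$spelling),
                             .keep_all = TRUE)
  if (nrow(lexicon) == 0) stop_graphovar("empty lexicon", "graphovar_empty_lexicon")
  pairs <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(lexicon))) {
    sp <- lexicon$spelling[i]
    al <- tryCatch({
      p <- standard_parse(sp, inv)
      ph <- tokenize_phonemes(lexicon$ipa[i], inv$phonemes)
      if (nrow(p) != length(ph)) NULL else tibble(grapheme = p$label, phoneme = ph)
    }, graphovar_error = function(e) NULL)
    if (is.null(al)) skipped <- c(skipped, sp) else pairs[[length(pairs) + 1L]] <- al
  }
  if (!length(pairs)) {
    stop_graphovar("no lexicon word could be aligned under this inventory",
                   "graphovar_empty_lexicon")
  }
  tab <- dplyr::count(dplyr::bind_rows(pairs), .data$grapheme, .data$phoneme, name = "n")
  global <- dplyr::count(dplyr::bind_rows(pairs), .data$phoneme, wt = NULL, name = "g")
  tab <- dplyr::left_join(tab, global, by = "phoneme")
  rules <- inv$rules
  for (g in unique(tab$grapheme)) {
    sub <- tab[tab$grapheme == g, ]
    best <- sub[sub$n == max(sub$n), ]
    if (nrow(best) > 1) {
      best <- best[order(-best$g, best$phoneme), ]
      warn(sprintf("tie for grapheme %s between %s; resolved to %s",
                   g, paste(sub$phoneme[sub$n == max(sub$n)], collapse = ", "),
                   best$phoneme[1]),
           class = "graphovar_tie")
    }
    rules$phoneme[rules$label == g] <- best$phoneme[1]
  }
  rules$klass <- phoneme_class(rules$phoneme, inv$phonemes)
  out <- gpc_inventory(rules[setdiff(names(rules), c("head", "tail", "is_split", "klass"))],
                       name = paste0(inv$name, "+lexicon"), phonemes = inv$phonemes)
  attr(out, "skipped") <- skipped
  out
}
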