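# Graphemic parsing: segmenting a letter string into an ordered sequence of
# graphemes that covers every letter exactly once. Split digraphs (O.E, A.UE,
# ...) own two letter spans: a head and a word-final silent tail.

VOWEL_LETTERS <- c("A", "E", "I", "O", "U")

check_stimulus <- function(stimulus) {
  if (length(stimulus) != 1 || is.na(stimulus)) {
    stop_graphovar("stimulus must be a single string", "graphovar_no_parse")
  }
  s <- toupper(stimulus)
  if (!grepl("^[A-Z]+$", s)) {
    stop_graphovar(paste0("stimulus must be letters A-Z only: '", stimulus, "'"),
                   "graphovar_no_parse")
  }
  s
}

context_ok <- function(context, letters, start, end) {
  if (!nzchar(context)) return(TRUE)
  m <- regmatches(context, regexec("^(next|prev)=([A-Z,]+)$", context))[[1]]
  if (length(m) == 0) {
    stop_graphovar(paste0("malformed context condition: '", context, "'"),
                   "graphovar_bad_inventory")
  }
  set <- strsplit(m[3], ",", fixed = TRUE)[[1]]
  at <- if (m[2] == "next") end + 1L else start - 1L
  at >= 1L && at <= length(letters) && letters[at] %in% set
}

position_ok <- function(position, start, end, n) {
  switch(position, any = TRUE, onset = start == 1L, coda = end == n)
}

# one parsed grapheme occurrence (plain list; assembled into a tibble at the end)
occ <- function(rules, i, start, end, tail_start = NA_integer_, tail_end = NA_integer_) {
  list(label = rules$label[i], pattern = rules$pattern[i], phoneme = rules$phoneme[i],
       klass = rules$klass[i], start = start, end = end,
       tail_start = tail_start, tail_end = tail_end)
}

new_parsing <- function(rows, stimulus) {
  start <- vapply(rows, `[[`, 0L, "start")
  ord <- order(start)
  cols <- list(
    label = vapply(rows, `[[`, "", "label")[ord],
    pattern = vapply(rows, `[[`, "", "pattern")[ord],
    phoneme = vapply(rows, `[[`, "", "phoneme")[ord],
    klass = vapply(rows, `[[`, "", "klass")[ord],
    start = start[ord],
    end = vapply(rows, `[[`, 0L, "end")[ord],
    tail_start = vapply(rows, `[[`, NA_integer_, "tail_start")[ord],
    tail_end = vapply(rows, `[[`, NA_integer_, "tail_end")[ord]
  )
  out <- tibble::new_tibble(cols, nrow = length(rows))
  structure(out, stimulus = stimulus,
            class = c("graphovar_parse", class(tibble())))
}

#' @export
format.graphovar_parse <- function(x, ...) paste(x$label, collapse = "+")

#' @export
print.graphovar_parse <- function(x, ...) {
  cat(sprintf("<parse of %s: %s (%d graphemes)>\n",
              attr(x, "stimulus"), format(x), nrow(x)))
  invisible(x)
}

# precomputed matching tables for the contiguous (non-split) rules
contig_rules <- function(inv) {
  rules <- inv$rules[!inv$rules$is_split, , drop = FALSE]
  list(rules = rules,
       chars = strsplit(rules$pattern, "", fixed = TRUE),
       lens = nchar(rules$pattern),
       specificity = (rules$position != "any") + nzchar(rules$context))
}

# All structurally valid split-digraph bindings for a word: a head vowel
# pattern, 1-2 intervening consonant letters, and a word-final E/UE tail.
split_bindings <- function(letters, inv, block_ge = TRUE) {
  n <- length(letters)
  rules <- inv$rules[inv$rules$is_split, , drop = FALSE]
  if (nrow(rules) == 0 || n < 3) return(list())
  # prefer longer heads, then longer tails, then rule precedence
  rules <- rules[order(-nchar(rules$head), -nchar(rules$tail), rules$precedence), ]
  out <- list()
  for (i in seq_len(nrow(rules))) {
    tail_chars <- strsplit(rules$tail[i], "")[[1]]
    tl <- length(tail_chars)
    tail_start <- n - tl + 1L
    if (tail_start < 2L || !identical(letters[tail_start:n], tail_chars)) next
    head_chars <- strsplit(rules$head[i], "")[[1]]
    hl <- length(head_chars)
    for (k in 1:2) {
      head_end <- tail_start - k - 1L
      head_start <- head_end - hl + 1L
      if (head_start < 1L) next
      if (!identical(letters[head_start:head_end], head_chars)) next
      interv <- letters[(head_end + 1L):(tail_start - 1L)]
      if (any(interv %in% VOWEL_LETTERS)) next
      # GE owns a word-final E after a single-letter head (DONGE = D,O,N,GE)
      if (block_ge && rules$tail[i] == "E" && hl == 1L &&
          letters[tail_start - 1L] == "G") next
      out[[length(out) + 1L]] <- list(rules = rules, i = i, head_start = head_start,
                                      head_end = head_end, tail_start = tail_start,
                                      tail_end = n)
    }
  }
  out
}

bind_occ <- function(b) {
  occ(b$rules, b$i, b$head_start, b$head_end, b$tail_start, b$tail_end)
}

# indices of contiguous rules matching at position `pos` within [pos, seg_end]
matches_at <- function(letters, pos, seg_end, n, ct) {
  hits <- integer(0)
  for (i in seq_along(ct$lens)) {
    end <- pos + ct$lens[i] - 1L
    if (end > seg_end) next
    if (!identical(letters[pos:end], ct$chars[[i]])) next
    if (!position_ok(ct$rules$position[i], pos, end, n)) next
    if (!context_ok(ct$rules$context[i], letters, pos, end)) next
    hits <- c(hits, i)
  }
  hits
}

#' Standard graphemic parse of a letter string
#'
#' Computes the single, deterministic standard parse. First any applicable
#' split-vowel pattern (a vowel head, one or two intervening consonant
#' letters, and a word-final silent E or UE) is bound, preferring the
#' longest head; the remaining letters are then segmented left to right by
#' maximal munch. When several rules match at a position, the most specific
#' wins (a position- or context-restricted rule beats an unrestricted one),
#' then the longer pattern, then the lower precedence rank — so GNEUTH
#' parses as GN,EU,TH and SCROME as S,C,R,O.E,M.
#'
#' @param stimulus Letter string (A-Z; lowercase is uppercased).
#' @param inv A [gpc_inventory()].
#' @return A `graphovar_parse`: a tibble with one row per grapheme occurrence
#'   (columns `label`, `pattern`, `phoneme`, `klass`, letter spans), in
#'   stimulus order. Split graphemes carry a second span (`tail_start`,
#'   `tail_end`). The spans cover every letter exactly once.
#' @examples
#' standard_parse("SHOIL", default_inventory())
#' format(standard_parse("SCROME", default_inventory()))
#' @export
standard_parse <- function(stimulus, inv = default_inventory()) {
  s <- check_stimulus(stimulus)
  letters <- strsplit(s, "")[[1]]
  n <- length(letters)
  rows <- list()
  bound <- rep(FALSE, n)
  bind <- split_bindings(letters, inv)
  if (length(bind)) {
    b <- bind[[1]]
    rows[[1]] <- bind_occ(b)
    bound[c(b$head_start:b$head_end, b$tail_start:b$tail_end)] <- TRUE
  }
  ct <- contig_rules(inv)
  pos <- 1L
  while (pos <= n) {
    if (bound[pos]) { pos <- pos + 1L; next }
    seg_end <- pos
    while (seg_end < n && !bound[seg_end + 1L]) seg_end <- seg_end + 1L
    p <- pos
    while (p <= seg_end) {
      hits <- matches_at(letters, p, seg_end, n, ct)
      if (!length(hits)) {
        stop_graphovar(
          sprintf("no grapheme rule covers letter '%s' at position %d of %s",
                  letters[p], p, s),
          "graphovar_no_parse"
        )
      }
      best <- hits[order(-ct$specificity[hits], -ct$lens[hits],
                         ct$rules$precedence[hits])][1]
      rows[[length(rows) + 1L]] <- occ(ct$rules, best, p, p + ct$lens[best] - 1L)
      p <- p + ct$lens[best]
    }
    pos <- seg_end + 1L
  }
  new_parsing(rows, s)
}

# all segmentations of the unbound stretches into contiguous graphemes
enum_segments <- function(letters, bound, n, ct) {
  segs <- list()
  pos <- 1L
  while (pos <= n) {
    if (bound[pos]) { pos <- pos + 1L; next }
    seg_end <- pos
    while (seg_end < n && !bound[seg_end + 1L]) seg_end <- seg_end + 1L
    segs[[length(segs) + 1L]] <- c(pos, seg_end)
    pos <- seg_end + 1L
  }
  per_seg <- lapply(segs, function(se) {
    res <- list()
    recurse <- function(p, acc) {
      if (p > se[2]) { res[[length(res) + 1L]] <<- acc; return(invisible()) }
      hits <- matches_at(letters, p, se[2], n, ct)
      # distinct graphemes at this span: dedupe same (pattern, length)
      if (length(hits)) hits <- hits[!duplicated(ct$rules$pattern[hits])]
      for (h in hits) {
        recurse(p + ct$lens[h], c(acc, list(occ(ct$rules, h, p, p + ct$lens[h] - 1L))))
      }
    }
    recurse(se[1], list())
    res
  })
  if (!length(per_seg)) return(list(list()))
  combos <- per_seg[[1]]
  for (k in seq_along(per_seg)[-1]) {
    combos <- unlist(lapply(combos, function(a) lapply(per_seg[[k]], function(b) c(a, b))),
                     recursive = FALSE)
    if (!length(combos)) return(list())
  }
  combos
}

#' Enumerate all graphemic parses of a letter string
#'
#' All distinct segmentations of the stimulus into inventory graphemes,
#' with and without each applicable split-digraph binding. The standard
#' parse is listed first; the rest are ordered by grapheme count and then
#' lexicographically, so the output is deterministic.
#'
#' @inheritParams standard_parse
#' @param max_count Maximum number of parses to return; if the enumeration
#'   is cut short the result carries attribute `truncated = TRUE`.
#' @return A list of `graphovar_parse` objects (at least one, else a
#'   `graphovar_no_parse` error).
#' @examples
#' length(enumerate_parses("OOSH", default_inventory()))
#' @export
enumerate_parses <- function(stimulus, inv = default_inventory(), max_count = 100L) {
  s <- check_stimulus(stimulus)
  letters <- strsplit(s, "")[[1]]
  n <- length(letters)
  ct <- contig_rules(inv)
  bindings <- c(list(NULL), split_bindings(letters, inv, block_ge = FALSE))
  parses <- list()
  for (b in bindings) {
    bound <- rep(FALSE, n)
    pre <- list()
    if (!is.null(b)) {
      bound[c(b$head_start:b$head_end, b$tail_start:b$tail_end)] <- TRUE
      pre <- list(bind_occ(b))
    }
    for (seg in enum_segments(letters, bound, n, ct)) {
      parses[[length(parses) + 1L]] <- new_parsing(c(pre, seg), s)
    }
  }
  if (!length(parses)) {
    stop_graphovar(paste0("no parse exists for ", s), "graphovar_no_parse")
  }
  sig <- vapply(parses, function(p) paste(p$label, p$start, collapse = "|"), character(1))
  parses <- parses[!duplicated(sig)]
  sig <- sig[!duplicated(sig)]
  std <- tryCatch(standard_parse(s, inv), graphovar_error = function(e) NULL)
  std_sig <- if (is.null(std)) "" else paste(std$label, std$start, collapse = "|")
  ord <- order(sig != std_sig, vapply(parses, nrow, integer(1)), sig)
  parses <- parses[ord]
  truncated <- length(parses) > max_count
  if (truncated) parses <- parses[seq_len(max_count)]
  attr(parses, "truncated") <- truncated
  parses
}
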