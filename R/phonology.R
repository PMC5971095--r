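#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats runif rgamma setNames
#' @importFrom utils head
NULL

the <- new.env(parent = emptyenv())

stop_graphovar <- function(message, class, ...) {
  abort(message, class = c(class, "graphovar_error"), ...)
}

#' Construct a phoneme inventory
#'
#' A phoneme inventory is the closed alphabet over which IPA transcriptions
#' are tokenized. Each phoneme is a short unicode string (one or two base
#' characters, plus an optional length mark) classed as vowel or consonant.
#' Aliases allow alternative spellings of the same phoneme (for example the
#' two-glyph affricates `tʃ`/`dʒ` for `ʧ`/`ʤ`); they are normalized to the
#' canonical form during tokenization.
#'
#' @param ipa Character vector of canonical phoneme strings (unique).
#' @param klass Character vector, `"vowel"` or `"consonant"`, same length.
#' @param aliases Named character vector mapping alias spelling to canonical
#'   ipa, or `NULL`.
#' @return An object of class `phoneme_set`: a tibble with columns `ipa` and
#'   `klass`, carrying the alias map and a prebuilt longest-match table as
#'   attributes.
#' @seealso [default_phonemes()], [tokenize_phonemes()]
#' @export
phoneme_set <- function(ipa, klass, aliases = NULL) {
  if (length(ipa) == 0) stop_graphovar("phoneme inventory is empty", "graphovar_bad_inventory")
  if (anyDuplicated(ipa)) {
    stop_graphovar(
      paste0("duplicate phoneme entries: ", paste(unique(ipa[duplicated(ipa)]), collapse = ", ")),
      "graphovar_bad_inventory"
    )
  }
  if (!all(klass %in% c("vowel", "consonant"))) {
    stop_graphovar("phoneme klass must be 'vowel' or 'consonant'", "graphovar_bad_inventory")
  }
  if (!is.null(aliases)) {
    bad <- setdiff(unname(aliases), ipa)
    if (length(bad)) {
      stop_graphovar(paste0("alias targets not in inventory: ", paste(bad, collapse = ", ")),
                     "graphovar_bad_inventory")
    }
    clash <- intersect(names(aliases), ipa)
    if (length(clash)) {
      stop_graphovar(paste0("alias spelling collides with canonical phoneme: ",
                            paste(clash, collapse = ", ")), "graphovar_bad_inventory")
    }
  }
  out <- tibble(ipa = as.character(ipa), klass = as.character(klass))
  # longest-match table: every recognizable spelling -> canonical ipa
  pat <- c(setNames(out$ipa, out$ipa), aliases)
  lk <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(pat)) assign(names(pat)[i], pat[[i]], envir = lk)
  attr(out, "aliases") <- aliases
  attr(out, "patterns") <- pat
  attr(out, "lookup") <- lk
  attr(out, "max_pattern_chars") <- max(nchar(names(pat)))
  attr(out, "klass_of") <- setNames(out$klass, out$ipa)
  class(out) <- c("phoneme_set", class(out))
  out
}

#' Load a phoneme inventory from a tab-separated file
#'
#' The file has one phoneme per line with columns `ipa`, `klass` and
#' `aliases` (comma-separated alternative spellings, may be empty).
#'
#' @param path Path to the TSV resource. Defaults to the inventory shipped
#'   with the package: a General-English monosyllable set of 24 consonants
#'   and 22 vowels (short vowels, long vowels and diphthongs).
#' @return A [phoneme_set()].
#' @export
load_phonemes <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "phonemes.tsv", package = "graphovar")
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("ipa", "klass")
  if (!all(need %in% names(tab))) {
    stop_graphovar("phoneme file must have columns ipa, klass", "graphovar_bad_file")
  }
  aliases <- NULL
  if ("aliases" %in% names(tab)) {
    has <- !is.na(tab$aliases) & nzchar(tab$aliases)
    if (any(has)) {
      spl <- strsplit(tab$aliases[has], ",", fixed = TRUE)
      aliases <- setNames(rep(tab$ipa[has], lengths(spl)), trimws(unlist(spl)))
    }
  }
  phoneme_set(tab$ipa, tab$klass, aliases)
}

#' Default phoneme inventory
#'
#' Loads (and caches) the phoneme inventory shipped with the package.
#' @return A [phoneme_set()].
#' @export
default_phonemes <- function() {
  if (is.null(the$phonemes)) the$phonemes <- load_phonemes()
  the$phonemes
}

#' Class of a phoneme
#'
#' @param phoneme Character vector of canonical phoneme strings.
#' @param phonemes A [phoneme_set()].
#' @return `"vowel"` or `"consonant"` for each element.
#' @export
phoneme_class <- function(phoneme, phonemes = default_phonemes()) {
  kl <- attr(phonemes, "klass_of")[phoneme]
  if (anyNA(kl)) {
    stop_graphovar(paste0("unknown phoneme: ",
                          paste(phoneme[is.na(kl)], collapse = ", ")),
                   "graphovar_unknown_symbol")
  }
  unname(kl)
}

# strip slashes, brackets, stress marks and whitespace from a transcription
clean_transcription <- function(x) {
  gsub("[/\\[\\]ˈˌ'\\s]+", "", x, perl = TRUE)
}

#' Tokenize an IPA transcription into phonemes
#'
#' Greedy longest-match tokenization over the phoneme inventory. Slashes,
#' brackets, stress marks and whitespace are stripped first; the length mark
#' `ː` binds to the preceding vowel because long vowels are inventory members
#' in their own right. Alias spellings (for example `tʃ`) are normalized to
#' their canonical form (`ʧ`), so the multiset of phonemes is independent of
#' the transcription dialect.
#'
#' Greedy longest match means a diphthong such as `aɪ` is always one phoneme,
#' never a sequence of two, matching how phonemes are counted throughout the
#' analysis. An unknown symbol aborts tokenization (classed condition
#' `graphovar_unknown_symbol`) rather than being skipped: silently dropping
#' symbols would corrupt phoneme counts, the core measure.
#'
#' @param transcription A single IPA string, for example `"/sprɔːk/"`.
#' @param phonemes A [phoneme_set()].
#' @return Character vector of canonical phonemes, with the cleaned source
#'   string as attribute `"source"`.
#' @examples
#' tokenize_phonemes("/nuθ/")
#' length(tokenize_phonemes("/sprʌŋk/"))
#' @export
tokenize_phonemes <- function(transcription, phonemes = default_phonemes()) {
  if (length(transcription) != 1 || is.na(transcription)) {
    stop_graphovar("transcription must be a single non-missing string",
                   "graphovar_unknown_symbol")
  }
  s <- clean_transcription(transcription)
  if (!nzchar(s)) {
    stop_graphovar("empty transcription after cleaning", "graphovar_unknown_symbol")
  }
  lk <- attr(phonemes, "lookup")
  maxlen <- attr(phonemes, "max_pattern_chars")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    hit <- NA_character_
    for (len in seq(min(maxlen, n - i + 1L), 1L)) {
      cand <- paste(chars[i:(i + len - 1L)], collapse = "")
      canon <- get0(cand, envir = lk, inherits = FALSE)
      if (!is.null(canon)) {
        hit <- canon
        i <- i + len
        break
      }
    }
    if (is.na(hit)) {
      stop_graphovar(
        sprintf("unknown symbol '%s' at offset %d in '%s'", chars[i], i, s),
        "graphovar_unknown_symbol"
      )
    }
    out <- c(out, hit)
  }
  attr(out, "source") <- s
  out
}

# Does tokenization succeed? (vectorized convenience for flagging records)
tokenizes_ok <- function(transcription, phonemes = default_phonemes()) {
  vapply(transcription, function(t) {
    if (is.na(t) || !nzchar(trimws(t))) return(FALSE)
    !inherits(tryCatch(tokenize_phonemes(t, phonemes), error = function(e) e), "error")
  }, logical(1), USE.NAMES = FALSE)
}
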