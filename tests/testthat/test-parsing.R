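inv <- default_inventory()

test_that("multi-letter and context-dependent graphemes parse as units", {
  expect_identical(format(standard_parse("OOSH", inv)), "OO+SH")
  expect_identical(format(standard_parse("SNOWL", inv)), "S+N+OW+L")
  expect_identical(format(standard_parse("THUSE", inv)), "TH+U.E+S")
  expect_identical(format(standard_parse("SPRAUK", inv)), "S+P+R+AU+K")
  expect_identical(format(standard_parse("B", inv)), "B")
  expect_identical(format(standard_parse("shoil", inv)), "SH+OI+L")  # case-folded
})

test_that("split vowel graphemes bind across one or two consonants", {
  # multiletter vowel graphemes with a silent word-final tail
  cases <- c(TWOLE = "O.E", GWENE = "E.E", TRURE = "U.E", THAQUE = "A.UE",
             WAICE = "AI.E", HAUVE = "AU.E", STRIQUE = "I.UE", HIECE = "IE.E",
             WOUGE = "OU.E", CRUSQUE = "U.UE", FRUGUE = "U.UE", PSEUCE = "EU.E",
             SUILE = "UI.E", STOARSE = "OA.E", SCROME = "O.E")
  for (w in names(cases)) {
    p <- standard_parse(w, inv)
    expect_true(cases[[w]] %in% p$pattern, label = paste(w, "binds", cases[[w]]))
  }
  # ...but a word-final GE keeps the E: DONGE is D,O,N,GE, not D,O.E,N,G
  expect_identical(format(standard_parse("DONGE", inv)), "D+O+N+GE")
  expect_identical(paste(standard_parse("DONGE", inv)$phoneme, collapse = ""), "dɒnʤ")
})

test_that("standard pronunciations of the narrated nonwords come out right", {
  pron <- function(w) paste(standard_parse(w, inv)$phoneme, collapse = "")
  expect_identical(pron("SHOIL"), "ʃɔɪl")
  expect_identical(pron("GNEUTH"), "nuθ")
  expect_identical(pron("PSIRP"), "sɜːp")
  expect_identical(pron("CLALF"), "klælf")
  expect_identical(pron("SCROME"), "skrəʊm")
  expect_identical(pron("GANC"), "gæŋk")
})

test_that("parse spans cover every letter exactly once", {
  set.seed(7)
  words <- generate_nonwords(40, inv)
  for (w in words) {
    p <- standard_parse(w, inv)
    covered <- c()
    for (i in seq_len(nrow(p))) {
      covered <- c(covered, p$start[i]:p$end[i])
      if (!is.na(p$tail_start[i])) covered <- c(covered, p$tail_start[i]:p$tail_end[i])
    }
    expect_identical(sort(covered), seq_len(nchar(w)), label = w)
    # split tails are word-final
    expect_true(all(is.na(p$tail_end) | p$tail_end == nchar(w)), label = w)
  }
})

test_that("the standard parse is among the enumerated parses", {
  set.seed(11)
  words <- generate_nonwords(25, inv)
  for (w in words) {
    sigs <- vapply(enumerate_parses(w, inv, max_count = 500L),
                   function(p) paste(p$label, p$start, collapse = "|"), character(1))
    std <- standard_parse(w, inv)
    expect_true(paste(std$label, std$start, collapse = "|") %in% sigs, label = w)
  }
})

test_that("enumeration finds alternative segmentations and truncates", {
  sigs <- vapply(enumerate_parses("OOSH", inv),
                 function(p) paste(p$pattern, collapse = "+"), character(1))
  expect_true("OO+SH" %in% sigs)
  expect_true("O+O+S+H" %in% sigs)
  expect_identical(sigs[1], "OO+SH")  # standard parse first
  one <- enumerate_parses("A", inv)
  expect_length(one, 1)
  expect_identical(format(one[[1]]), "A")
  trunc <- enumerate_parses("OOSH", inv, max_count = 2L)
  expect_length(trunc, 2)
  expect_true(attr(trunc, "truncated"))
})

test_that("enumeration matches the brute-force segmentation oracle", {
  toy <- toy_inventory()
  pats <- toy$rules$pattern
  set.seed(3)
  strs <- unique(replicate(300, paste(sample(c("B", "R", "E", "C"),
                                             sample(1:6, 1), replace = TRUE),
                                      collapse = "")))
  for (s in strs) {
    got <- sort(vapply(enumerate_parses(s, toy, max_count = 1000L),
                       function(p) paste(p$pattern, collapse = "+"), character(1)))
    want <- sort(vapply(brute_parses(s, pats), paste, character(1), collapse = "+"))
    expect_identical(got, want, label = s)
  }
})

test_that("letters with no covering rule raise a NoParse error", {
  toy <- toy_inventory()
  expect_error(standard_parse("BRX", toy), class = "graphovar_no_parse")
  expect_error(enumerate_parses("BRX", toy), class = "graphovar_no_parse")
  expect_error(standard_parse("", inv), class = "graphovar_no_parse")
  expect_error(standard_parse("SP AUK", inv), class = "graphovar_no_parse")
})
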