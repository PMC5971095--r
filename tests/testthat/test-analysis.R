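inv <- default_inventory()

test_that("parsings are classified purely by the phoneme-count rule", {
  recs <- response_records(
    "s1", c("SPRAUK", "SPRAUK", "SPRAUK", "SHOIL"),
    c("/sprʌŋk/", "/spɔːk/", "/spraʊ/", "/ʃɔɪl/")
  )
  cls <- classify_parsings(recs, inv)
  expect_identical(cls$n_graphemes, c(5L, 5L, 5L, 3L))
  expect_identical(cls$n_phonemes, c(6L, 4L, 4L, 3L))
  expect_identical(cls$status, c("nonstandard", "nonstandard", "nonstandard", "standard"))
})

test_that("classification ignores transcription formatting", {
  a <- classify_parsings(response_records("s1", "SHOIL", "/ʃɔɪl/"), inv)
  b <- classify_parsings(response_records("s1", "SHOIL", " ˈʃɔɪl "), inv)
  expect_identical(a$status, b$status)
  expect_identical(a$n_phonemes, b$n_phonemes)
})

test_that("missing and untokenizable responses are unanalysable, not nonstandard", {
  recs <- response_records("s1", c("SHOIL", "SHOIL", "SHOIL"),
                           c("/ʃɔɪl/", NA, "/ʃ4l/"))
  expect_identical(recs$analysable, c(TRUE, FALSE, FALSE))
  cls <- classify_parsings(recs, inv)
  expect_identical(cls$status, c("standard", "unanalysable", "unanalysable"))
  # partition: standard + nonstandard + unanalysable = total
  expect_identical(sum(table(cls$status)), 3L)
})

test_that("standard-parse responses align grapheme-to-phoneme one-to-one", {
  al <- align_standard("SHOIL", "/ʃɔɪl/", inv)
  expect_identical(al$grapheme, c("SH", "OI", "L"))
  expect_identical(al$phoneme, c("ʃ", "ɔɪ", "l"))
  al2 <- align_standard("GNEUTH", "/nuθ/", inv)
  expect_identical(al2$grapheme, c("GN", "EU", "TH"))
  expect_identical(al2$phoneme, c("n", "u", "θ"))
  expect_error(align_standard("SPRAUK", "/sprʌŋk/", inv),
               class = "graphovar_nonstandard_parsing")
})

test_that("assignment tallies reproduce known per-grapheme counts", {
  tl <- tally_assignments(subject9_records(), inv)
  ch <- tl[tl$grapheme == "CH", ]
  expect_identical(setNames(ch$n, ch$phoneme)[c("ʧ", "k", "s", "ʃ", "θ")],
                   c("ʧ" = 3L, k = 11L, s = 1L, "ʃ" = 2L, "θ" = 1L))
  ie <- tl[tl$grapheme == "I.E", ]
  expect_identical(setNames(ie$n, ie$phoneme)[c("aɪ", "ɛ", "i", "ɪ")],
                   c("aɪ" = 1L, "ɛ" = 1L, i = 2L, "ɪ" = 3L))
})

test_that("tally conserves grapheme incidences and skips nonstandard parses", {
  recs <- response_records("s1", c("SHOIL", "SHOIL", "SPRAUK"),
                           c("/ʃɔɪl/", "/sɔɪl/", "/spɔːk/"))
  cls <- classify_parsings(recs, inv)
  tl <- tally_assignments(cls, inv)
  expect_identical(sum(tl$n), sum(cls$n_graphemes[cls$status == "standard"]))
  expect_false("AU" %in% tl$grapheme)  # only from the nonstandard SPRAUK record
  empty <- tally_assignments(response_records(character(), character(), character()), inv)
  expect_identical(nrow(empty), 0L)
})

test_that("grapheme eligibility requires the minimum for every subject", {
  tl <- tibble::tibble(
    subject_id = c("a", "a", "b", "b", "a", "b"),
    grapheme = c("L", "L", "L", "CH", "CH", "X"),
    phoneme = c("l", "r", "l", "ʧ", "ʧ", "z"),
    n = c(3L, 2L, 100L, 4L, 3L, 9L)
  )
  attr(tl, "subjects") <- c("a", "b")
  # L: a has 5, b has 100 -> eligible at 4; CH: a has 3 -> excluded;
  # X: absent for a (counts 0) -> excluded
  expect_identical(eligible_graphemes(tl, 4L), "L")
  # brute-force recount agrees
  brute <- sapply(unique(tl$grapheme), function(g) {
    all(sapply(c("a", "b"), function(s) sum(tl$n[tl$grapheme == g & tl$subject_id == s]) >= 4))
  })
  expect_identical(sort(names(brute)[brute]), eligible_graphemes(tl, 4L))
  # threshold is a knob
  expect_true("X" %in% eligible_graphemes(tl, 0L))
})

test_that("assignments classify against the grapheme's standard phoneme", {
  expect_identical(classify_assignment("AU", "ɔː", inv), "standard")
  expect_identical(classify_assignment("AU", c("aʊ", "ʌ", "ɑː"), inv),
                   rep("nonstandard", 3))
  expect_identical(classify_assignment("CH", "ʧ", inv), "standard")
  expect_error(classify_assignment("NOPE", "x", inv),
               class = "graphovar_missing_grapheme")
})
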