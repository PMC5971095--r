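inv <- default_inventory()

test_that("entropy reproduces the worked per-grapheme values", {
  expect_equal(round(entropy(c(3, 11, 1, 2, 1)), 2), 1.68)
  expect_equal(round(entropy(c(1, 1, 2, 3)), 2), 1.84)
  expect_identical(entropy(c(x = 7)), 0)            # unanimity
  expect_identical(entropy(c(a = 5, b = 5)), 1)     # uniform over two
  expect_error(entropy(numeric()), class = "graphovar_bad_counts")
  expect_error(entropy(c(0, 0)), class = "graphovar_bad_counts")
  expect_error(entropy(c(-1, 2)), class = "graphovar_bad_counts")
})

test_that("entropy matches the direct formula, is permutation- and scale-invariant", {
  set.seed(13)
  for (i in 1:300) {
    k <- sample(1:8, 1)
    counts <- sample(0:20, k, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    H <- entropy(counts)
    expect_equal(H, entropy_direct(counts))
    expect_equal(entropy(counts[sample.int(length(counts))]), H)
    expect_equal(entropy(counts * 7), H)
    expect_gte(H, 0)
    expect_lte(H, log2(max(1, sum(counts > 0))) + 1e-12)
  }
})

test_that("uniform counts maximize entropy over integer compositions", {
  # brute force over all compositions of 12 into k parts, k <= 4
  # (12 is divisible by each k, so the uniform composition is attainable)
  for (k in 2:4) {
    grid <- expand.grid(rep(list(0:12), k))
    grid <- grid[rowSums(grid) == 12, , drop = FALSE]
    H <- apply(grid, 1, entropy)
    best <- grid[which.max(H), ]
    expect_true(all(best == 12 / k))
    expect_equal(max(H), entropy(rep(12 / k, k)))
  }
})

test_that("per-subject entropy cells match cell-wise recomputation", {
  tl <- tally_assignments(rbind(subject9_records("s9"),
                                records_for("CHOM", rep("/ʧɒm/", 18), "s42"),
                                records_for("BIDE", rep("/baɪd/", 7), "s42")), inv)
  rep_ <- subject_grapheme_entropy(tl, eligible = c("CH", "I.E"))
  h <- function(s, g) rep_$per_cell$H[rep_$per_cell$subject_id == s &
                                        rep_$per_cell$grapheme == g]
  expect_equal(round(h("s9", "CH"), 2), 1.68)
  expect_equal(round(h("s9", "I.E"), 2), 1.84)
  expect_identical(h("s42", "CH"), 0)   # consistent reader
  expect_identical(h("s42", "I.E"), 0)
  means <- rep_$subject_means
  expect_identical(means$mean_H[means$subject_id == "s42"], 0)
  # oracle: every cell equals entropy() of its counts
  for (i in seq_len(nrow(rep_$per_cell))) {
    cell <- rep_$per_cell[i, ]
    counts <- tl$n[tl$subject_id == cell$subject_id & tl$grapheme == cell$grapheme]
    expect_equal(cell$H, entropy(counts))
  }
})

test_that("across-subject grapheme entropy pools assignments", {
  tl <- tibble::tibble(
    subject_id = c("a", "b", "a", "b"),
    grapheme = c("CH", "CH", "L", "L"),
    phoneme = c("ʧ", "k", "l", "l"),
    n = c(5L, 5L, 9L, 3L)
  )
  attr(tl, "subjects") <- c("a", "b")
  out <- grapheme_entropy_across_subjects(tl, eligible = c("CH", "L"))
  expect_identical(out$H[out$grapheme == "L"], 0)   # everyone agrees
  expect_identical(out$H[out$grapheme == "CH"], 1)  # disjoint equal halves
  # mean-over-subjects view differs: each subject is internally consistent
  alt <- grapheme_entropy_across_subjects(tl, eligible = c("CH", "L"),
                                          method = "mean_subject")
  expect_identical(alt$H[alt$grapheme == "CH"], 0)
})

test_that("rate reports carry consistent numerators and denominators", {
  recs <- rbind(
    records_for("SPRAUK", c("/sprɔːk/", "/spɔːk/", "/sprʌŋk/"), "s1"),
    records_for("SHOIL", c("/ʃɔɪl/", "/sɔɪl/"), "s1"),
    records_for("SPRAUK", c("/sprɔːk/", "/sprɔːk/"), "s2"),
    records_for("SHOIL", c("/ʃɔɪl/", NA), "s2")
  )
  cls <- classify_parsings(recs, inv)
  tl <- tally_assignments(cls, inv)
  rates <- nonstandard_rates(cls, tl, inv)
  o <- rates$overall
  expect_identical(o$n_records, 9L)
  expect_identical(o$n_unanalysable, 1L)
  expect_identical(o$n_analysable, 8L)
  expect_identical(o$n_nonstandard_parsings, 2L)
  expect_equal(o$parsing_pct, 100 * 2 / 8)
  # conservation across groupings
  expect_identical(sum(rates$subject_parsing$n_nonstandard), o$n_nonstandard_parsings)
  expect_identical(sum(rates$item_parsing$n_nonstandard), o$n_nonstandard_parsings)
  expect_identical(sum(rates$subject_parsing$n_total), o$n_analysable)
  expect_true(all(rates$subject_parsing$pct >= 0 & rates$subject_parsing$pct <= 100))
  # assignment side: SH->s is the one nonstandard assignment
  expect_identical(o$n_nonstandard_assignments,
                   sum(rates$subject_assignment$n_nonstandard))
  expect_equal(o$assignment_pct,
               100 * o$n_nonstandard_assignments / o$n_assignments)
})

test_that("an all-standard table reports zero rates everywhere", {
  recs <- rbind(records_for("SHOIL", rep("/ʃɔɪl/", 3), "s1"),
                records_for("SHOIL", rep("/ʃɔɪl/", 3), "s2"))
  cls <- classify_parsings(recs, inv)
  rates <- nonstandard_rates(cls, tally_assignments(cls, inv), inv)
  expect_true(all(rates$subject_parsing$pct == 0))
  expect_true(all(rates$item_parsing$pct == 0))
  expect_identical(rates$overall$assignment_pct, 0)
})

test_that("distinct responses are counted on normalized transcriptions", {
  recs <- records_for("CHOM", c("/ʧɒm/", "tʃɒm", "/kɒm/", "/ʃɒm/", "/kɒm/"))
  out <- distinct_response_counts(recs)
  expect_identical(out$n_distinct, 3L)  # ʧɒm == tʃɒm after normalization
  expect_identical(out$n_responses, 5L)
  same <- distinct_response_counts(records_for("SHOIL", rep("/ʃɔɪl/", 4)))
  expect_identical(same$n_distinct, 1L)
})
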