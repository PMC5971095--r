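# shared fixtures, built in code

# a 10-grapheme toy inventory over the letters B, R, E, C (position-free)
toy_inventory <- function() {
  gpc_inventory(
    data.frame(
      pattern = c("B", "R", "E", "C", "BR", "RE", "EC", "CE", "EE", "CC"),
      position = "any", context = "",
      phoneme = c("b", "r", "ɛ", "k", "p", "iː", "æ", "s", "i", "g")
    ),
    name = "toy"
  )
}

# exhaustive segmentation oracle: every way of cutting `s` into pieces that
# are all members of `patterns`
brute_parses <- function(s, patterns) {
  n <- nchar(s)
  if (n == 1L) {
    return(if (s %in% patterns) list(s) else list())
  }
  res <- list()
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
    bounds <- c(0L, cuts, n)
    pieces <- substring(s, head(bounds, -1L) + 1L, bounds[-1L])
    if (all(pieces %in% patterns)) res[[length(res) + 1L]] <- pieces
  }
  res
}

# response records for one subject over one nonword, one row per response
records_for <- function(nonword, transcriptions, subject = "s1") {
  response_records(rep(subject, length(transcriptions)),
                   rep(nonword, length(transcriptions)), transcriptions)
}

# one subject's CH and I.E distributions, mirroring a highly variable reader:
# CH as ʧ(3) k(11) s(1) ʃ(2) θ(1); I.E as aɪ(1) ɛ(1) i(2) ɪ(3)
subject9_records <- function(subject = "s9") {
  ch <- c(rep("/ʧɒm/", 3), rep("/kɒm/", 11), "/sɒm/", rep("/ʃɒm/", 2), "/θɒm/")
  ie <- c("/baɪd/", "/bɛd/", rep("/bid/", 2), rep("/bɪd/", 3))
  rbind(records_for("CHOM", ch, subject), records_for("BIDE", ie, subject))
}

# independent entropy recomputation, straight from the formula
entropy_direct <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  sum(-p * log2(p))
}
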