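---
title: "Quantifying variability in nonword reading aloud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying variability in nonword reading aloud}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphovar)
```

## The model

When a skilled reader pronounces a letter string they have never seen, the
nonlexical route of a dual-route reading model runs three stages:
*graphemic parsing* (segment the letters into graphemes), *phoneme
assignment* (give each grapheme a phoneme), and *phoneme blending* (fuse
the phonemes into a syllable). Different readers can parse the same string
differently, and even readers who parse alike can assign different
phonemes; blending, by contrast, essentially never fails in healthy adults
and is represented only trivially here. `graphovar` operationalizes both
variable stages and measures them.

**Definitions used throughout.** A grapheme is the written representation
of one phoneme. Consequently a response is a *standard parsing* exactly
when the number of phonemes in the response equals the number of graphemes
in the stimulus's standard parse; any mismatch (an inserted, omitted, or
letter-split grapheme) makes it *nonstandard*. This count-based criterion
is deliberately the only criterion: it needs no judgement call about which
parse a reader "really" intended, and it makes the headline rates exactly
reproducible. The diagnostic aligner (`infer_parse()`, below) narrates
*which* parse a response suggests, but never feeds the counts. A phoneme
assignment is *standard* when it equals the inventory's standard phoneme
for that grapheme — the phoneme most often corresponding to it in English
monosyllables, with position and context taken into account (G and
G-before-E are different graphemes).

## The phoneme inventory and tokenizer

Transcriptions are IPA strings over a closed General-English monosyllable
inventory (24 consonants, 22 vowels including long vowels and diphthongs),
shipped as `inst/extdata/phonemes.tsv` and overridable. Tokenization is
greedy longest-match, so a diphthong (/aɪ/) or affricate (/ʧ/) is always
one phoneme; the inventory is prefix-ambiguous only between a
multi-character phoneme and its first character, so longest-match resolves
every case. The length mark ː binds to the preceding vowel because long
vowels are inventory members in their own right. Two-glyph affricate
spellings (tʃ, dʒ) and a few other dialectal variants are aliases
normalized to canonical forms, making phoneme counts independent of
transcription dialect. Unknown symbols abort tokenization — the record is
flagged unanalysable — rather than being skipped, because silent skipping
would corrupt phoneme counts, the core measure. One consequence of a
closed alphabet: a few adjacent canonical phonemes concatenate to the
spelling of a longer member (ə+ʊ spells əʊ); joined tokens are therefore a
tokenizer fixed point, and the strict string round trip holds for
merge-free sequences. The synthetic generator actively avoids emitting
merging pairs so that its intended phoneme counts always survive
re-tokenization.

## The GPC inventory and the standard parse

The shipped rule table (`inst/extdata/gpc_rules.tsv`) is a DRC-style
English grapheme-phoneme correspondence set: all single letters,
the common multi-letter consonant and vowel graphemes, contextual rules
(C before E/I/Y, G before E, N before C/K/Q, U after Q), positional rules
(GN/PS/KN/WR word-initial, GE/CK/NG word-final), and the split digraphs
A.E/E.E/I.E/O.E/U.E plus the longer-tailed A.UE, I.UE, U.UE, AI.E, AU.E,
EU.E, IE.E, OA.E, OU.E, UI.E. Since no published study prints its complete
inventory, this table documents its own resolution of the underdetermined
cases rather than claiming fidelity to any unpublished set; every analysis
accepts a custom inventory via `load_inventory()`.

`standard_parse()` is deterministic:

1. **Split-vowel pre-binding.** Any pattern "vowel head + 1-2 intervening
   consonant letters + word-final silent E/UE" is bound first, preferring
   the longest head (so WAICE binds AI.E, not I.E). Allowing up to two
   intervening consonants is the smallest rule that covers both O.E in
   TWOLE (one consonant) and U.UE in CRUSQUE (two).
2. **Maximal munch** left to right over the remaining letters. Among rules
   matching at a position, the more *specific* rule (position- or
   context-restricted) wins, then the longer pattern, then the explicit
   precedence rank from the rule file — making parsing reproducible
   bit-for-bit from configuration.

Two interacting conventions deserve note. A word-final GE after a
single-letter vowel head blocks split binding, so DONGE parses D, O, N, GE
(/dɒnʤ/) while WOUGE, whose head OU is multi-letter, parses W, OU.E, G.
And specificity precedes length so that the coda rule GE (length 2) beats
the contextual rule G-before-E (length 1) at a word-final GE, while
contextual single-letter rules still beat their plain counterparts
elsewhere. These choices jointly reproduce every standard parse the
package's tests assert (SHOIL, GNEUTH, PSIRP, CLALF, DONGE, SCROME, GANC,
and the full split-digraph family).

`enumerate_parses()` lists *all* segmentations (split bindings optional,
including G-blocked ones, since those are structurally possible readings),
standard parse first, deterministically ordered and truncated at
`max_count` with a flag. It is validated exhaustively against a
brute-force segmentation oracle for all strings of length ≤ 6 over a toy
inventory.

## The diagnostic aligner

`infer_parse()` finds the parse a response implies: over candidate
segmentations it runs a dynamic-programming alignment with edit costs
match = 0, nonstandard same-class substitution = 1, cross-class
substitution = 2, grapheme omission = 2, phoneme insertion = 2
(configurable via `infer_costs()`, with an optional cost ceiling). Ties in
total cost break by *fewer structural edits* (insertions + omissions),
then by closeness to the standard parse. Two of these choices were
genuinely open and are worth recording:

* **Cross-class substitutions cost more.** With class-blind substitution,
  a response like /səʊwəθ/ to PSOATH is explained most cheaply by an
  all-single-letter parse with phonologically absurd pairings (S→/əʊ/,
  O→/w/). Penalizing vowel-grapheme/consonant-phoneme pairings keeps the
  winning alignments interpretable.
* **Structural-edit tie-break before closeness-to-standard.** The same
  response costs 4 either as the standard parse PS, OA, TH with two
  inserted phonemes or as PS, O, A, TH with one insertion and two
  substitutions. Preferring fewer structural edits selects the second —
  the reading in which the vowel digraph was parsed as its letters, each
  phoneme licensed by a grapheme — which matches how such responses
  pattern empirically (letter-split vowel graphemes are the dominant
  nonstandard-parsing mechanism).

The aligner is a diagnostic only; no headline count depends on it.

## Tallies, eligibility, rates, entropy

Only standard-parse responses admit an unambiguous one-to-one
grapheme-phoneme pairing, so only they feed `tally_assignments()`; this
also means each grapheme's per-subject occurrence denominator counts
standard-parse records only. A grapheme enters the assignment analysis
only if it occurs at least `min_per_subject` (default 4) times for
*every* subject — a universal quantifier, so a single sparse subject
excludes the grapheme. The default 4 gives each grapheme a reasonable
chance of being read in different ways; it is a config knob for
sensitivity analysis.

Entropy is Shannon's H = Σ −pᵢ log₂ pᵢ in bits, with 0·log 0 = 0;
values are kept at full precision internally and rounded (2 dp) only for
display. Subject-level entropy is computed per (subject, grapheme) cell;
by default every parsed-out cell of an eligible grapheme counts
(`min_occurrences = 1`), with the threshold exposed as a knob. For
across-subject grapheme entropy two readings were possible: pooling all
subjects' assignments into one distribution, or averaging each subject's
own entropy. Both are implemented
(`grapheme_entropy_across_subjects(method =)`); pooled is the default and
the headline, since the quantity of interest is variability across the
participant group, and the two differ tellingly (a grapheme read
consistently but differently by two subjects has pooled H = 1, mean
per-subject H = 0).

Rate reports always carry numerators and denominators; zero-denominator
cells are reported as missing, never as 0%. Conservation identities
(standard + nonstandard + unanalysable = total records; tally total =
standard-parse grapheme incidences; per-subject and per-item numerators
sum to the overall numerator) are asserted by `run_report()` on every run.

## The synthetic generator

`simulate_responses()` emulates the study conditions the analysis assumes:
45 subjects × 412 monosyllabic nonwords, with 2.3% of responses missing.
Per-subject parse-perturbation propensities are uniform on
[0.0316, 0.3665] and per-subject nonstandard-assignment propensities
uniform on [0.09, 0.31] — the empirical ranges such panels exhibit. Given
a perturbation, its type is split / omit / insert with weights .5 / .3 /
.2: splitting a multi-letter (especially vowel) grapheme into its letters
is the dominant mechanism in real data, grapheme omission next, insertion
least; the weights are the package's own calibration of that ordering.
Perturbations operate on the *parse*, not the phoneme string, so the
ground-truth ledger is interpretable in grapheme terms, and each resulting
grapheme's phoneme is drawn from the subject's cached categorical
distribution (standard phoneme with probability 1 − a; otherwise one of
`n_alternatives` same-class alternatives with Dirichlet(1) weights).
Nonwords are generated from onset/vowel/coda blocks of the inventory,
including split-digraph and -QUE forms, all verified to parse.

By construction (and by test): a fixed seed gives byte-identical output;
every perturbed record classifies nonstandard and every unperturbed record
standard, exactly; and the pipeline recovers the generative per-subject
rates within binomial error (the acceptance suite checks 3-SE coverage of
at least 95% across ten seeds at full scale).

**What the generator does not emulate.** Items are exchangeable: there are
no item-difficulty effects, so per-item nonstandard rates vary only by
binomial noise and virtually no item is read in the standard way by all 45
subjects — unlike real panels, where item difficulty spreads per-item
rates from 0% to above 90% and a tail of easy items is read unanimously.
There are likewise no lexical-analogy or frequency effects, no correlation
between a subject's parsing and assignment propensities, and no
perseveration across trials. Passing recovery tests therefore validates
the *pipeline's accounting*, not the cognitive realism of the generator.

## Numerical and operational choices

* Problem sizes: unit tests run on toy tables and small simulations
  (typically 4-6 subjects × 20-40 nonwords); the end-to-end checks run the
  full 45 × 412 design, ten seeds for the recovery study — the scale the
  generator's defaults describe.
* Letter X maps to /z/ (as in xylophone): a GPC rule maps one grapheme to
  one phoneme and /ks/ is two. QU is Q→/k/ plus a contextual U-after-Q→/w/.
* One published 36-grapheme eligibility list contains a duplicated "O" and
  an ambiguous "O. E"; since the intended distinct items cannot be
  recovered, the shipped inventory simply covers O, O.E and the context
  variants and lets eligibility be recomputed from data.
* "Most often" in the standard-assignment definition is implemented as
  *type* counts (each lexicon spelling once), the default in
  `derive_standard_assignments()`; majority ties break by the phoneme's
  global count, then lexicographically, with a classed warning.
* Records that fail tokenization count as unavailable, never as
  nonstandard, keeping them out of every denominator.
* Plug-in entropy is biased downward at small cell counts (tested at
  n = 4 vs n = 100); reported H values at the eligibility threshold are
  therefore conservative.

## Limitations

The count-based standardness criterion cannot distinguish a nonstandard
parse with a compensating assignment error from a standard one (a
response with the right phoneme count is always "standard parsing"), and
equal-length alternative parses are invisible to it; the aligner exists
precisely to explore such cases, without affecting the counts. The
shipped inventory is one defensible English GPC set, not the only one;
all headline rates are inventory-relative, and analyses of real data
should report the inventory used alongside the rates.
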