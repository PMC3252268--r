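---
title: "Scoring AU-rich elements: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring AU-rich elements: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arescore)
```

## The model

AU-rich elements destabilise mRNAs through three sequence features that this
package quantifies jointly: the number of AUUUA pentamers, their mutual
proximity, and an AU-rich context. The score of a sequence is additive:

* **Basal score** — `pentamer_value` (default 1) for every AUUUA occurrence,
  including overlapping ones. The UUAUUUA(U/A)(U/A) nonamer is deliberately
  *not* a separate feature: it is two overlapping pentamers, or a pentamer in
  AU context, and is already rewarded through the terms below.
* **Proximity bonuses** — for each pair of *neighbouring* pentamers the gap
  is the number of nucleotides strictly between them
  (`next_start − prev_start − 5`). A negative gap means overlap and earns
  1.5; gaps of 0–3, 4–6 and 7–9 nt earn 0.75, 0.4 and 0.2; nothing beyond.
  Restricting to neighbouring pairs makes the bands contiguous and mutually
  exclusive, and a tandem run of *k* overlapping pentamers earns exactly
  *k − 1* overlap bonuses rather than a quadratic all-pairs sum.
* **AU-block bonus** — 0.3 per pentamer located inside an AU-block.

All constants live in `score_config()` and may be changed; the defaults
encode the standard setting above.

### AU-block semantics

A sliding window of `block_word` = 20 nt moves along the sequence. A block
*opens* at the start of the first window whose A+U fraction reaches
`block_start_au` = 0.80 and *extends* while each subsequent window stays at
or above `block_end_au` = 0.55; it *closes* at the end (start + 20 − 1) of
the last qualifying window. The hysteresis (open high, sustain lower) means a
block captures the AU-rich shoulder around a strong core rather than
fragmenting at every local dip.

Three boundary questions have no single canonical answer; the package fixes
them as follows and treats them as part of its contract:

* **Closing coordinate.** The block ends at the *end* of the last qualifying
  window, not at its start. This makes a pure-AU sequence one block covering
  the whole sequence, which is the intuitive reading; blocks from separate
  window runs that overlap or touch after this extension are merged, so the
  reported blocks are disjoint and maximal.
* **Membership.** A pentamer earns the block bonus only when its full 5-nt
  span lies inside one block, and at most once. Partial overlap earns
  nothing; this is the conservative reading of "within a block".
* **Alphabet.** T and U are identical and case is ignored; IUPAC ambiguity
  letters count as non-AU in windows and never match the pentamer.
  Coordinates are 1-based inclusive in every user-facing structure.

## Transcriptome-wide use

`score_batch()` drops sequences shorter than `min_len` = 10 nt before
scoring — very short annotated 3′UTRs are mostly annotation noise — and
`collapse_by_gene()` keeps, per gene, the transcript with the highest score
(score ties broken by the lexicographically smallest transcript id, a
deterministic rule chosen so repeated runs agree). The length filter is
applied before collapsing.

## Null sequence sets

Two nulls calibrate "how much ARE is expected by chance":

* `composition_matched_set()` pools every nucleotide of the input, applies
  one seeded uniform permutation, and re-cuts sequences at the original
  lengths. Composition and length multiset are conserved *exactly* — a
  permutation guarantees this, while i.i.d. resampling would only match in
  expectation — so any score enrichment in the real set reflects sequence
  *arrangement*, the thing AREs are.
* `concatemer_set()` builds sequences of prescribed lengths by concatenating
  randomly drawn real sequences and truncating the tail. This stricter null
  preserves local sequence structure and asks whether a *set* of UTRs is more
  ARE-rich than typical UTR sequence of the same size. Truncating the tail
  (rather than the head, or both ends) is an arbitrary but documented choice.

Both require an explicit integer seed and restore the caller's RNG state.

## Statistics

* **Enrichment** (`enrichment_at_threshold()`): the 2×2 table of scores
  ≥/< a threshold in real versus control sequences, with Pearson χ² (no
  continuity correction), two-sided Fisher's exact test, and the Φ
  coefficient `(ad − bc)/√((a+b)(c+d)(a+c)(b+d))`. When a margin is zero, χ²
  and Φ are undefined and reported as `NA`; Fisher's test is still returned.
  Thresholds of 4 (ARE-bearing) and 10 (strong AREs) are conventional
  operating points, not magic numbers.
* **ROC** (`roc_auc()`): every unique observed score is swept as a
  threshold, predicting the positive class (labile) at score ≥ threshold.
  The trapezoid area equals the tie-adjusted Mann–Whitney U divided by
  n₁n₂ — the probability that a random positive outscores a random negative —
  and the test suite asserts that identity on random instances.
* **Censored Spearman** (`spearman_censored()`): half-lives beyond the
  measurement window are only known to exceed it. Such entries are treated
  as mutually tied at the largest rank (average ranks), which uses their
  ordering information without inventing magnitudes. This is a choice —
  other treatments (dropping them, imputing the limit) are possible — and it
  is switchable by simply not passing the censoring flags. Because of this
  choice, correlations computed on censored data are comparable only between
  analyses using the same rule.
* **Half-life fitting** (`fit_half_life()`): ordinary least squares on
  log abundance versus time; t½ = ln 2/|slope|. A non-negative slope or a
  fitted t½ beyond `censor_limit` = 240 min returns a censored result. OLS on
  the log scale corresponds to multiplicative measurement error, the
  dominant error mode of qPCR quantification.

## The synthetic transcriptome

`generate_synthetic_transcriptome()` emulates a compact metazoan 3′UTR
complement: log-normal lengths with median 207 nt and σ(log) = 0.7 (a fly-like
median; the heavy tail supplies the long UTRs where strong AREs tend to sit),
background A+U fraction 0.60, and a planted fraction (default 5 %) of
sequences carrying a class-II-like ARE cassette: 4–7 pentamers separated by
gaps of −1 to 3 nt (−1 is the only self-overlap AUUUA admits, on the shared
A) inside a 90 %-AU pad of 20 nt per side. The truth table records each
cassette's position and pentamer count, so tests can verify detection against
construction rather than against the scorer itself.

What the generator does *not* emulate: dinucleotide composition, codon- or
UTR-specific base biases, repeat structure, alternative polyadenylation, and
any correlation between length and composition. Passing enrichment tests on
this material therefore demonstrates that the pipeline detects planted
arrangement signal at realistic sizes and noise — not that any particular
real transcriptome is enriched.

## Problem sizes and determinism

The validation suite runs the scorer against a literal brute-force
re-implementation (exhaustive 5-mer enumeration plus a per-window state
machine) on 1000 random sequences of 20–500 nt and demands exact equality;
Fisher p-values are checked against full hypergeometric enumeration for
every 2×2 table with N ≤ 40; enrichment power is assessed on 20 independent
2000-gene synthetic transcriptomes (and calibration on 20 null-vs-null
pairs, at threshold 2 so the high-score cell stays populated on unplanted
sequences); half-life recovery uses 100 simulated four-point time courses
per true half-life at 5 % multiplicative noise. These sizes keep the full
suite at a few minutes on a single core while leaving the random-instance
counts large enough that a rule discrepancy would be found with
near-certainty. Every stochastic step takes an explicit seed, and a fixed
seed reproduces results byte for byte.

## Known limitations

* The score is a heuristic for *potential* ARE strength; it does not model
  ARE-binding-protein expression or competition, and a high score does not
  guarantee regulation in any particular cell type.
* Pentamer counting is exact-match; degenerate pentamers (AUUUG, GUUUA) and
  purely U-rich class-III-like elements contribute nothing.
* The AU-block rule is window-based; AU content just below the sustain
  threshold across a long stretch yields no block at all.
* Censored Spearman treats all censored values as exchangeable; with many
  censored observations the coefficient is dominated by the tie group and
  its magnitude should be interpreted cautiously.
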