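---
title: "Mosaic matching: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaic matching: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the classifier implemented by `mosaicmatch` — its
model and assumptions, the parameters that matter, the numerical choices
made where the design was open, what the synthetic test data does and
does not show, and the package's known limitations.

## The classification model

The classifier assigns protein (or translated DNA) queries to protein
domain families without alignment. Its unit of evidence is the
oligopeptide word: a window of `k = 18` consecutive residues. Words are
long enough that a shared word, or a near-neighbourhood in word space, is
strong evidence of homology, and short enough that 100-bp reads still
contain a dozen of them — which is why the approach keeps its sensitivity
on fragments where profile HMMs, built for full domains, lose theirs.

Three ingredients make word neighbourhoods meaningful:

1. **Evolutionary alphabet ordering.** Words are compared
   lexicographically, so only a shared *prefix* brings words together.
   To make prefixes tolerant of conservative substitutions, the 20
   amino-acid letters are re-ordered along the shortest cyclic path
   through pairwise distances `d_ij = 1 - cos(s_i, s_j)` between the
   column vectors of a substitution scoring matrix. Biochemically similar
   residues (e.g. the aliphatic block `MLIV`) become adjacent letters, so
   a conservative substitution perturbs a word's dictionary position as
   little as possible. The shipped ordering is the fixed constant
   `ATSPGNDEQKRHYWFMLIVC`; it is deliberately *not* recomputed at build
   time so that databases are bit-stable. `alphabet_distance()` and
   `shortest_cyclic_order()` are provided to derive orderings from
   user-supplied matrices (an exact Held–Karp solver up to 12 letters for
   validation, and a nearest-neighbour + 2-opt heuristic for 20).

2. **Sorted dictionary with LCP nearest neighbours.** All reference
   words are encoded base-20 (first residue most significant, so numeric
   order equals lexicographic order), sorted, deduplicated and indexed by
   their hexamer prefix. A query word either matches exactly or is
   located at its insertion position; the two flanking words are its
   nearest neighbours under the longest-common-prefix distance (word
   length minus LCP). Ambiguous words (one 18-mer, several families) are
   removed outright — they carry no usable evidence. Singleton words,
   whose label differs from both sorted neighbours, are removed *after*
   PSSM training, because they are exactly the negative examples the
   training needs.

3. **Learned positional scoring.** Whether a nearest-neighbour match is
   trustworthy is decided by 12 learned 20×20 scoring matrices, one per
   suffix position (the hexamer prefix is mostly identical between
   neighbours and carries little signal, so it is not scored). Training
   data come for free from the dictionary: every adjacent pair is an
   example, labelled +1 if the family labels agree and -1 otherwise. The
   ridge objective and its solution are linear; the regularization
   parameter is chosen by classification accuracy on the held-out pairs.

Word-level scores are combined by the mosaic rule: per family, each
residue keeps the maximum positional score over all covering matches
from either direction, and the maxima are summed. Overlapping words
therefore do not double-count a residue, and a single well-matching word
cannot be outvoted by many mediocre ones at the same position.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `word_length` | 18 residues | evidence unit; fixed by the dictionary design |
| `prefix_length` | 6 residues | block index; suffix (12) must fit exact integer doubles (20^12 < 2^53) |
| `lambda_grid` | 10 points, 1e-2..1e4 (log) | ridge strengths spanning under- to over-shrinkage for count-scale one-hot features |
| `masker` | entropy, window 12, 2.2 bits | low-complexity filter approximating SEG-style masking; lowercase input is honoured as pre-masked |
| `levels` | default 0.1%, sensitive 1% | per-sequence false-positive rates of the two calibrated thresholds |
| `n_random` | 1e5 per length | calibration sample; 1e5 resolves the 0.1% quantile with ~100 expected exceedances |
| `lengths` | 32..1024 aa (powers of 2) | calibration grid; thresholds interpolate log-linearly between grid points |
| `min_orf` | 60 nt, inclusive | shortest translated ORF; six frames, stop-free runs, no start codon required |

## Numerical and procedural choices

Several points are underdetermined by the method description and were
fixed as package design choices:

* **Training-pair membership.** A dictionary location is *mixed* when
  its two incident adjacent pairs carry opposite signs; a pair trains
  iff either endpoint is mixed. This reading concentrates training on
  family boundaries (where discrimination matters) and guarantees both
  classes are present; all remaining pairs validate λ. Ties in
  validation accuracy prefer the larger λ. A prediction of exactly 0
  counts as negative. There is no intercept; targets are ±1.
* **Solver.** The normal equations are solved on the *observed*
  substitution features only (unobserved one-hot columns receive weight
  exactly 0 under ridge) via one symmetric eigendecomposition of the
  Gram matrix shared across the λ grid. The test suite proves
  equivalence with a dense normal-equations solve to 1e-6.
* **Exact matches** score only against the matched word; flanking
  neighbours are consulted only for inexact matches. When the two
  neighbours share a family, their positional scores combine by
  per-position maximum; when they differ, each contributes a separate
  match (no cross-family maximum).
* **Reverse coordinate mapping.** A reversed word's suffix corresponds
  to the *first* 12 residues of the original window; scores are mapped
  back accordingly before the mosaic step.
* **Empty prefix blocks.** When no stored word shares the query's
  hexamer, the neighbours flanking the global insertion position are
  used (flag `empty_block = "global"`; `"skip"` declares no match). On
  small databases this keeps every window scored; the learned scores and
  the calibrated thresholds absorb the extra noise.
* **Singleton removal** is a single pass on the original sorted
  neighbourhood. No cascade is needed: a retained word's label-sharing
  neighbour is by construction never a singleton, so removal cannot
  create new singletons (this invariant is property-tested).
* **Quantile convention.** The threshold at FPR f is the upper order
  statistic `s[(n - floor(f n))]` of the sorted max-score sample, so at
  most `floor(f n)` calibration sequences strictly exceed it — realized
  FPR on the calibration sample never exceeds nominal. FPR is defined
  per sequence (any family above threshold makes the sequence a false
  positive); a per-family definition would scale with database size.
* **Interpolation** of thresholds is piecewise linear in log2(length),
  matching the geometric calibration grid, clamped flat outside
  [32, 1024].
* **Degenerate inputs.** Words containing non-standard residues (X, B,
  Z, U, *, gaps) are rejected, never substituted — one wrong residue
  would relocate the word arbitrarily in the dictionary. Sequences
  shorter than 18 residues yield no words; empty dictionaries yield
  no-match lookups; ties in best-hit mode resolve to the smaller family
  index.
* **Determinism.** All randomness flows from explicit seeds; databases
  serialize to deterministic plain text (`%.17g` doubles), so identical
  content produces identical bytes and save/load round-trips exactly.
  Processing is sequential; output order always equals input order.

## The synthetic data model

`generate_families()` draws one ancestor per family i.i.d. from the
bundled background frequencies (UniProtKB/Swiss-Prot average
composition) and derives members by i.i.d. substitutions at a fixed
per-residue rate, with the replacement drawn uniformly from the 19 other
letters so the realized substitution fraction matches the nominal rate.
The reference study conditions used by the acceptance checks are 10
families × 50 members of 300 aa at a 5% rate — within-family identity of
roughly 90%, enough variation that word matching must rely on
near-neighbourhoods rather than exact hits. DNA test data are produced
by back-translation with uniform synonymous codons (the classifier has
no codon-usage assumption) and uniform fragment sampling at fixed
coverage, without sequencing errors.

What this emulates: a reference collection whose families are
well-populated and internally variable, and short reads that subsample
genes uniformly. What it does not emulate: real domain length variation,
insertions/deletions (there is no gap model to stress), shared motifs
between families, low-complexity sequence, codon bias, or sequencing
errors. Passing the end-to-end bar (TPR at least 0.90 and PPV at least
0.95 on held-out mutated members at the default threshold) therefore
demonstrates a correct implementation of the pipeline under its own
model, not field performance on natural sequence collections, which
depends on database coverage of family variation.

The false-positive calibration check is the more transferable result: on
an independent sample of 100,000 random 128-aa sequences, the realized
per-sequence FPR of the default and sensitive thresholds must fall
within a four-sigma binomial band of their nominal 0.1% and 1% — this is
exactly the property the calibration procedure promises, and it holds
regardless of how realistic the reference families are.

## Problem sizes

The shipped tests build databases of 4 × 10 × 120 aa (unit tests; random
calibration at 2,000 sequences per length) and 10 × 50 × 300 aa
(acceptance checks; calibration and validation at 100,000 sequences for
lengths 32–1024). These sizes were chosen so the whole suite exercises
every code path, including full-scale calibration statistics, while a
complete run stays within a coffee break on a single core. Dictionary
sizes grow linearly with reference residues; the ridge fit cost is
dominated by one eigendecomposition of the active-feature Gram matrix
(at most 4800 × 4800).

## Limitations

* No gap model: a single insertion/deletion shifts all downstream words;
  sensitivity on indel-rich divergence relies on the flanking words
  only.
* Families represented by a handful of sequences yield few words and
  weak training signal; the method wants databases that represent
  within-family variation (profile methods degrade more gracefully
  there).
* The normal-mode codon-usage ORF pre-filter is a transparent log-odds
  screen and ships disabled; with no codon table it is a no-op.
* Only the standard genetic code is supported; no E-values are computed
  — significance is purely threshold-based.
* The entropy masker is a simple approximation of dedicated
  low-complexity filters; pre-masked (lowercase) input is recommended
  when exact SEG behaviour matters.
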