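---
title: "isomiRpipe: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isomiRpipe: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRpipe)
```

This vignette is the package's own account of what it computes and why:
the isomiR model and its naming convention, the statistical surrogate used
for differential expression, the integration rules, what the synthetic
generator does and does not emulate, and the numerical choices a
maintainer would want written down.

## The isomiR model

A precursor hairpin produces a family of mature products. We model every
read as `templated core + optional non-templated 3' tail`, where the core
must match the precursor *exactly and contiguously*. Single-nucleotide
polymorphic or edited variants (internal mismatches, A-to-I) are
deliberately out of scope: allowing internal mismatches would conflate
sequencing error with biology at the read lengths involved, and the
class system covered here — reference form, templated 5'/3'/5'3' end
variants, non-templated 3' additions — captures the dominant variant mass
in mammalian small-RNA libraries.

Coordinates are 0-based half-open everywhere (files and API), matching
BED-style genomics tooling; the reference interchange format is a
precursor FASTA plus a TSV of arm intervals, with a converter from
miRBase-style GFF3 (`gff3ToCoordsTable`). DNA input is accepted and stored
as RNA, since mature sequences are conventionally printed in RNA letters.
The package is agnostic to the miRBase release behind the annotation.

### Offset sign convention

With `s, e` the read's templated start/end on the precursor and `[a, b)`
the arm interval: `offset5 = s - a` and `offset3 = (s + read length) - b`.
So `+1` at the 5' end means one nucleotide trimmed, and a 2-nt tail on an
otherwise exact read gives `offset3 = +2`. This is the only convention
consistent with names like `miR-27b-3p_t_+1_0` for the variant
`UCACAGUGGCUAAGUUCUGC` of `UUCACAGUGGCUAAGUUCUGC`. Offsets are printed
with an explicit `+`/`-` and a bare `0`; `parseName()` is an exact inverse
of `nameCall()` and rejects anything outside that grammar rather than
guessing.

### Classifier windows and tie-break

Defaults (`classifierConfig()`): `maxOffset = 5` nt applied separately to
the 5' offset and to the *templated* 3' displacement, `maxTail = 3` nt
(mono- to tri-nucleotide tails are the biologically common case; total 3'
offset may thus reach 8), read lengths 16–28 nt around the canonical
19–25 nt mature range. Published variant tables rarely exceed |offset| 3
and tail 2, so the windows leave headroom without admitting junk.

Two rules make "non-templated" well defined and the output deterministic:

* **Maximal prefix.** The templated core is extended as far as the
  precursor allows before a tail is declared; a declared tail therefore
  never begins with the next templated base (unless the match reaches the
  precursor's end). A read ending in `CG` over a `CG` flank is a templated
  3'-extension, not a tail.
* **Tie-break.** Among admissible placements: longest templated match,
  then smallest `|offset5| + |offset3|`, then shortest tail, then
  lexicographically smallest parent name. Each read is counted once,
  never fractionally. This is this package's choice — upstream tools do
  not document one — and it is what makes quantification reproducible and
  testable; the test suite checks it against an independent brute-force
  enumeration oracle on tens of thousands of random instances.

Unassigned reads are tallied per reason (`length`, `no_match`,
`offset_too_large`, `tail_too_long`) rather than dropped silently.

## Differential expression

The DE stage is a deliberately transparent negative-binomial Wald
surrogate rather than a wrapper around a full shrinkage estimator: with
the intended use (testing planted effects in simulation, and small-cohort
contrasts with raw-p calling), a documented closed-form procedure is
easier to reason about and to verify. The steps per two-group contrast:

1. **Normalization.** Median-of-ratios to the geometric-mean
   pseudo-reference over features positive in all samples, rescaled to
   geometric mean 1. On a simulated 1:2:4 depth gradient with 5000
   features the factors come back within 5%, and they agree with the
   standard median-of-ratios implementation in DESeq2 (used as an
   independent cross-check in the tests, never as the implementation).
2. **Dispersion.** Method of moments on normalized counts: within each
   group `alpha_g = (s^2_g - m_g * mean(1/sf)) / m_g^2`, pooled with
   `n_g - 1` weights and floored at `1e-8`. No shrinkage across features.
3. **Effect and test.** `log2FC = log2(m_test / m_ref)`, with a 0.5
   pseudo-count entering only when a group mean is exactly zero — this
   keeps the estimate exactly invariant to rescaling any sample's column.
   The standard error is the NB delta method,
   `Var(m_g) = (m_g * sum(1/sf_j) + n_g * alpha * m_g^2) / n_g^2`, and the
   Wald statistic `log2FC / se` is referred, two-sided, to a
   **t distribution with `n1 + n2 - 2` degrees of freedom**.

The t reference is a small-sample calibration choice: the per-feature
moment dispersion has roughly `n1 + n2 - 2` degrees of freedom, so a
normal reference is anticonservative at `n = 6` per group (analytically
`P(|t10| > 1.96)` is about 0.078). With the t reference the observed null
type-I error over 2000 simulated features at `n = 6` per group, mean 500,
dispersion 0.1, lands between 0.03 and 0.07 — the calibration band the
test suite enforces.

Features with total raw count below 10 across the contrast samples are
flagged `filtered` and not tested. Calling uses raw `p < 0.05` (a BH
column is emitted but not used), with `|log2FC| >= 1` added for
gene-level matrices; small invasive-biopsy cohorts are commonly reported
on raw p at the miR level, and the package follows that practice rather
than silently imposing FDR control. Samples are treated as independent
groups; a paired (same-subject) design is *not* modeled — with paired
biopsies across time points this leaves power on the table, and is a
known limitation.

Recovery behaviour, as enforced by the tests: with sign-balanced planted
effects (10% of features DE) the mean bias of the estimates stays below
0.1 across `lfc ∈ {0, 1, 2} × dispersion ∈ {0.05, 0.2}` at n = 6/group,
and the per-replicate mean estimate over 100 planted `log2FC = 2`
features is within ±0.3 in at least 95% of 40 seeded replicates. The
per-replicate *mean* is the right unit here: a single feature's estimate
has delta-method sd ≈ 0.26 under these conditions, so no estimator could
put individual features within ±0.3 at 95%. Note that one-sided planting
(all effects up) biases median-of-ratios normalization itself — a
property of the normalization model, not a bug — which is why the
generator plants balanced effects.

## Integration rules

* Target scores live on a 0–100 scale and are kept at **score ≥ 80**,
  inclusive.
* A pair is `negative` iff the fold-change signs oppose. "Correlation"
  here is sign opposition of contrast fold changes, not a Pearson/Spearman
  coefficient on expression vectors. A zero product cannot normally occur
  (gene calling requires |log2FC| ≥ 1; exact zeros are measure-zero for
  miRs), but a defensive rule classifies it `positive` with a warning.
* **Seed inheritance.** Variants with `offset5 == 0` (reference, 3'-only,
  purely tailed) share the parent's seed and inherit the parent arm's
  target rows when they have none of their own; 5'-shifted variants have
  a different seed and must bring their own rows.
* **TF expansion.** A literature-curated TF→miR-family regulation applies
  to every DE feature whose parent arm belongs to the family, since all
  variants are transcribed from the same gene. Non-curated records are
  ignored by default.
* **Circuit.** Only negative pairs are wired (the regulatory reading of
  miR action); positive pairs are reported but not wired. isomiR features
  collapse into family nodes labelled by parent arm, with multiplicity
  recorded. Edges are never invented: every edge traces to an input
  relation, and exports (DOT, edge-list TSV) are lossless.

## The synthetic generator

`makeReference()` draws precursors whose arms (19–25 nt) are embedded in
G/C-only flanks and spacers, so an A/U tail can never be templated and
every planted variant is classifiable by construction; arm starts are
constrained to begin with two distinct bases so that ±1-offset variants
of the same arm cannot align ambiguously. `defaultIsoProfile()` emits 50%
reference form, templated ±1-nt end variants, and adenine-heavy tails
(A, 2A, 3A, with minor U/AU) — the composition skew reported for
mammalian libraries. Copy numbers are NB with variance
`mu + dispersion * mu^2`; `noise = FALSE` yields `round(mu)` exactly, so
quantification can be compared with the truth table bit for bit.
`simulateStudy()` couples the read-level simulation to a gene matrix with
planted anti-correlated (regulator, gene) pairs, decoy target rows below
the score threshold, and a planted two-step TF motif (TF gene targeted by
an up-regulated family, regulating a down-regulated family that targets a
second TF gene) for circuit checks.

What the generator does **not** emulate: sequencing error and quality
variation, adapter remnants, multi-mapping across paralogous precursors,
compositional (TMM-style) biases, and subject-level pairing. Passing the
simulation tests therefore demonstrates the pipeline's correctness on
clean, in-model data — not robustness to those artefacts on real
libraries.

Problem sizes used by the test suite were chosen to make the statistical
checks sharp while keeping a full run inside a few minutes on one CPU:
10,000+ random instances for oracle equivalence, 2000 features for the
null-calibration check, 40 replicates × 1000 features (100 planted) for
recovery, and studies of 4–6 precursors × 8–12 samples end to end.

## Degenerate inputs and edge rules

* Empty FASTQ → all-zero column with a warning, not an error.
* No feature positive in all samples → normalization refuses with advice
  to pre-filter.
* A contrast group emptied by filtering → explicit error.
* Sequences shorter than 8 nt have no seed; `seedOf()` errors.
* `parseName` reports malformed names (unknown type token, `+0`, a
  templated name with two zero offsets) with a position, instead of
  treating them as reference names.

## Known limitations

Paired designs and time-course models are not implemented; dispersion is
estimated per feature without shrinkage, which costs power at very small
n relative to empirical-Bayes methods; polymorphic isomiRs are excluded
by design; and target/TF tables are consumed as given — no network-based
prediction is attempted. The curated receptive-endometrium pairing table
shipped in `inst/extdata` is a fixture for the integration machinery, not
a re-derivation of those pairs from raw data.
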