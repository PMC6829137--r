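---
title: "Family-level TE expression quantification: models, parameters, and design"
author: "tefamquant developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-level TE expression quantification: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tefamquant)
```

## The quantification model

Short reads from transposable elements (TEs) frequently map to several
near-identical loci. Locus-level counting must discard those reads;
family-level counting keeps them whenever all of a read's annotated hits
fall within one family, because family membership — defined by sequence
similarity — is exactly the equivalence class within which the mapping
ambiguity lives.

The classifier works against a merged annotation built in three steps:

* **Disjoin.** Structural TE annotations nest (a young insertion lands
  inside an older element). Each base pair is attributed to exactly one
  element: a contained element claims its own span and punches a hole in
  its container, recursively. For the rare *partial* (non-nested) overlaps
  the winner is chosen deterministically — most deeply nested span first,
  then earlier start, then longer span, then lexicographically smaller
  element ID. Total covered bp is conserved (a tested invariant).
* **Exon masking.** TE base pairs under any gene exon are removed, so a
  read wholly inside an exon can never count as TE evidence. What remains
  of a TE inside a gene abuts the exon — reads straddling that boundary are
  the *ambiguous* class.
* **Allowlisting.** Features on unplaced contigs are dropped.

Each read (all reported alignments, spliced blocks included) collects the
set of gene exons and TE segments it overlaps by at least 1 bp, and resolves
to exactly one category: `gene_unique`, `u_te.fam` (unique, one family,
optionally one element), `m_te.fam` (multi-mapper, all annotated hits in one
family), `u_te.g`/`m_te.g` (hits both a gene and one family), or
`unassigned`. Three corner rules deserve note, all tested:

* a multi-mapper whose annotated hits are genes only is `unassigned`
  (gene assignment is defined for unique mappers only);
* alignments overlapping *no* feature never disqualify a multi-mapper whose
  annotated hits are single-family — the single-family rule constrains the
  hit set, not unannotated positions;
* a unique read spanning two members of one family is family-unique but
  earns no element-level credit.

Ambiguous reads are tallied per library (they are real signal about
gene/TE entanglement) but excluded from every downstream statistic,
including the RPM denominator.

## Normalization and expression calls

RPM divides each feature's count by the library's *assigned* reads
(gene-unique + family counts) times 10⁻⁶, so per library the RPM mass over
the assigned universe is exactly 10⁶ (tested to 10⁻⁶ relative). The percent
of TE-derived reads is additionally offered with the ambiguous categories
included in numerator and denominator — the convention used when plotting
per-category contributions — since the two denominators answer different
questions.

Expression calls use `min_rpm = 1` throughout, in three modes mirroring
common designs: **atlas** (RPM strictly > 1 in ≥ 3 libraries — for large
mixed atlases), **replicate-mean** (mean RPM ≥ 1 within a condition — for
designs with biological replicates), and **single** (RPM ≥ 1 — for panels
without replicates). Calling is monotone in the threshold (tested).

Tissue specificity is τ = Σᵢ(1 − xᵢ/max x)/(N−1) on log₂(1+RPM)-transformed
profiles; τ = 0 is constitutive, τ = 1 single-condition. τ is undefined
(NA) for all-zero profiles rather than 0, because "not expressed anywhere"
is not "constitutively expressed".

## The dip test and its calling convention

Expression segregation across recombinant inbred lines (RILs) is screened
with Hartigan & Hartigan's dip statistic: the sup-distance between the
empirical CDF and the nearest unimodal CDF. The implementation is built
from the CDF-band geometry — at the i-th order statistic the ecdf occupies
the band [(i−1)/n, i/n]; the greatest convex minorant is fitted through the
lower band corners, the least concave majorant through the upper corners,
and the modal interval shrinks iteratively while one-sided hull deviations
accumulate; the dip is half the final maximum, with exact floor 1/(2n)
(constant samples attain it; any two distinct points give exactly 0.25).
Slope comparisons are cross-multiplied so ties never divide by zero. The
implementation was validated at 10⁻¹² agreement against an independent
reference implementation on thousands of random samples; nine frozen
reference values are asserted in the test suite.

P-values are Monte-Carlo: the proportion of uniform(0,1) samples of the
same size whose dip is at least the observed one. The null table for a
given n is computed once and shared across features (`dip_null()`),
which is statistically identical to per-test simulation and dramatically
cheaper. Under the standard null — *the distribution is unimodal* — small
p-values reject unimodality. The operational rule in parts of the TE
literature inverts this reading and labels a family "unimodal" when
p < 0.05; both conventions are exposed (`call_convention = "standard"`
(default) vs `"p_lt_alpha"`), so results can either be statistically
conventional or reproduce that operational rule, explicitly.

## Differential expression stand-in

The DE layer is a deliberately simple, fully specified negative-binomial
test rather than a dependency on a heavyweight estimator: median-of-ratios
size factors (tested against an established implementation at 10⁻¹⁰),
per-feature method-of-moments dispersion pooled across both groups with a
Poisson fallback when under-dispersed, a Wald test on
log₂((mean_B + pc)/(mean_A + pc)) with a delta-method standard error, and
Benjamini–Hochberg adjustment (tested against the literal step-up
definition on a full grid of p-vectors up to length 6). The scientific
contract is the thresholds — FDR < 0.05 (strict) and fold change ≥ 2
(inclusive) — not any particular shrinkage scheme; simulated 4-fold changes
with 6 vs 6 replicates at moderate dispersion are recovered in ≥ 90% of
seeds (tested over 200 seeds).

The pseudocount (default 0.5, configurable) guards fold changes and
mid-parent ratios against zeros; the source methods are silent on zero
handling, so a conventional half-count was chosen once.

Hybrid trios are classified from the two F1-vs-parent contrasts:
`above_both` if the F1 is significantly *up* versus each parent,
`below_both` if *down* versus each, else `additive_range`; the mid-parent
deviation log₂((F1 + pc)/((P1+P2)/2 + pc)) is reported on the log scale
(a distribution "centered at 0" is the additive expectation). On simulated
trios with strong effects (4× beyond both parents) class recovery exceeds
95%.

## What the simulator emulates — and what it does not

`simulate_annotation()` / `simulate_library()` generate the structures the
method actually has to disambiguate: families from one to twenty members
across LTR/TIR/Helitron/LINE/SINE orders, nested insertions, TEs straddling
exon boundaries (the ambiguous-read source), genes with introns, and reads
that are unique, multi-mapped within a family, or gene/TE-ambiguous.
Defaults are desk-scale: 2 × 100 kb chromosomes, 12 three-exon genes,
38 TEs in 6 families, 60 bp reads, 85% gene reads, 30% of family reads
multi-mapped, 5% ambiguous. No nucleotide sequences exist — alignments are
*placed* with full-match CIGARs inside the assignable segments of expressed
elements, so every read's intended category is exact by construction and
the classifier can be checked read-for-read (a green end-to-end test
establishes that classification logic, not an aligner, is correct).

Consequently the simulator does **not** emulate: sequencing error or
quality, alignment ambiguity beyond the family structure (reads are never
placed at near-miss paralogous positions), splicing in reads (spliced
*parsing* is tested separately), fragment-length effects, or
genome-scale family-size distributions (real genomes have
families with thousands of members; the classifier is O(overlaps) and
indifferent, but the fixtures stay tiny by design). Green tests therefore
establish correctness of the algebra and the statistics, not performance on
a real genome.

The RIL panel generator tags each expressed element with a parent of
origin; every line inherits each non-shared element independently with
probability 0.5. Per-element gamma noise (CV 0.4 by default) models
biological variability — without it, a family with k expressed members
would produce a k+1-point lattice across the panel that the dip test
correctly flags as multimodal, which is an artifact of noise-free
simulation, not of the method. A single segregating element then yields a
bimodal RPM distribution with presence in about half the lines; several
additive members yield a unimodal one (both recovered in the acceptance
suite at the stated rates over 25 seeds each — enough that the Binomial
pass probabilities at the 90%/80% thresholds are dominated by the intended
signal, not seed luck). The panel defaults to count/RPM emission because
the segregation statistics consume RPM matrices; `emit = "sam"` produces
full per-line alignment files (tested for consistency with the count
matrix) at a cost that makes it sensible only for small panels.

## Numerical and degenerate-input choices

* Coordinates are 1-based, fully closed everywhere (the GFF3 and SAM
  convention); no off-by-one conversion exists anywhere in the package.
* `prop_unique` is NA (not 0) when a family has no reads; τ is NA for
  all-zero profiles; per-library percent TE is NA with zero assigned reads.
* Ranking ties in top-k family contributions break lexicographically by
  family code, for deterministic output.
* All simulation entry points take an explicit integer seed, use a local
  RNG scope (the caller's `.Random.seed` is untouched), and are
  byte-deterministic; pipeline outputs carry a provenance header
  (version, config hash, seed) and rerunning a fixed config is
  byte-identical (tested).
* An NH tag disagreeing with the observed alignment count warns and the
  observed count wins; unmapped records are skipped; no MAPQ or duplicate
  filtering is applied (none is specified for the method).

## Known limitations

* The NB stand-in has no dispersion shrinkage, so its p-values are
  anti-conservative at very low replicate numbers; with the 2-fold/FDR
  thresholds and ≥ 3 replicates it recovers strong effects reliably, which
  is the regime the method targets.
* Family-level attribution inherits the annotation's family definitions;
  mis-classified families in the input GFF3 propagate.
* Reads from family members absent in the reference but present in the
  sample genotype map where the reference allows — family-level counts
  absorb some of this, locus-level columns do not.
* The ambiguous class is resolved by exclusion, not apportionment; genes
  heavily overlapped by expressed TEs lose unique signal by construction.
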