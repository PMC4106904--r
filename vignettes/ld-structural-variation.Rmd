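---
title: "Detecting structural variation from short-range LD deviations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structural variation from short-range LD deviations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldsv)
library(dplyr)
```

## The idea

Structural rearrangements — duplications, deletions, inversions — perturb
the local statistical association between nearby markers. A duplication or
an inversion suppresses effective recombination and drags linkage
disequilibrium (LD) up; assembly errors, genotyping artefacts around
breakpoints, or recurrent rearrangement push it down. `ldsv` turns this
observation into a scan statistic over ordinary SNP-array data: no
sequencing, no intensity files, just phased biallelic genotypes.

The unit of evidence is a single SNP together with its *right window*: all
polymorphic SNPs within 100 kb downstream on the same chromosome. For each
such pair the squared correlation

$$r^2 = \frac{(p_{11} - p_1 q_1)^2}{p_1 p_2\, q_1 q_2}$$

is computed from phased haplotype counts, where $p_1, p_2$ are the minor
and major allele frequencies at the first SNP, $q_1, q_2$ at the second,
and $p_{11}$ the joint minor–minor haplotype frequency. Because finite
samples inflate $r^2$ (independent loci show $E[r^2] \approx 1/n$ for $n$
haplotypes), every value is corrected; the default is $r^2_{adj} = r^2 -
1/n$. The exact algebraic form of the correction in the literature varies,
so the normalized Hill–Weir form $(r^2 - 1/n)/(1 - 1/n)$ and an identity
pass-through are selectable via `adjust_r2()`. Corrected values are
deliberately **not** floored at zero: near linkage equilibrium the scan
still needs to distinguish "below expectation" from "at expectation".

## Expected means and the deviation test

Within one population and one chromosome, all window pairs are sorted by
distance and averaged in twenty 5-kb bins, giving the *expected means* —
the LD-decay baseline for that chromosome. Each SNP's neighbour pairs are
then compared against the expected mean of their own distance bin:

* the SNP is **directional** when all its deviations are strictly positive
  (or all strictly negative); a deviation of exactly zero, or any mix of
  signs, disqualifies it;
* its p-value comes from a *paired t-test* of the observed adjusted
  $r^2$ values against their binned expected means — algebraically the
  two-sided one-sample t-test of the deviations against zero with
  `n_neighbors - 1` degrees of freedom;
* SNPs with fewer than 15 window neighbours are *untestable*: they sit in
  sparsely covered regions where the "all above / all below" statement
  would rest on too few pairs;
* if a neighbour pair falls in a distance bin with no pairs at all (which
  can only happen when a profile is supplied externally), the SNP is
  untestable with an explicit reason rather than silently compared to 0.

Degenerate cases follow the limit behaviour of the t statistic:
zero-variance deviations with nonzero mean give p = 0 (maximally
significant), and all-exactly-zero deviations give direction `mixed` with
p = 1.

P-values are corrected by the Benjamini–Hochberg step-up rule at
$\alpha = 0.05$: sort the $m$ p-values, find the largest $k$ with
$p_{(k)} \le \alpha k / m$, declare the $k$ smallest significant.
`bh_adjust()` implements exactly this rule (ties share a fate;
significance is monotone in p). The family is **per population per
chromosome** by default — the pipeline runs breed by breed and chromosome
by chromosome, so the chromosome is the natural testing family — with a
genome-per-population option (`bh_scope = "genome"`).

A **structural variant (SV)** is then a maximal run of at least 3
consecutive post-QC SNPs, spanning at least 1 kb between first and last
member, all BH-significant with the same direction. A direction flip or
any non-qualifying SNP terminates a run. The span is the distance between
the member SNP positions (not a padded interval); runs shorter than 1 kb
are discarded. `validate_svs()` re-checks every emitted call against this
definition directly, independently of the caller's internals, and the test
suite keeps it always on.

## Quality control

Markers are filtered per population, in a fixed order with first-failure
attribution: call rate (default `max_missing = 0.10`), exact
Hardy–Weinberg test (`hwe_alpha = 1e-3`), then minor allele frequency
(`maf_min = 0.05`). Three choices deserve a note:

* The MAF cutoff is a **proportion** (5%), which also removes monomorphic
  markers. Array QC conventions sometimes print this ambiguously as a
  percentage; the threshold is configurable for anyone wanting the
  literal 0.0005.
* The HWE test is the **exact conditional test** (sum of all heterozygote
  configurations, given the allele counts, with probability at most that
  of the observed one), not the chi-square approximation: array panels
  contain many markers with rare genotype classes where the asymptotic
  test misbehaves. The significance level, not stated by most array
  pipelines either, defaults to 1e-3 and is configurable.
* HWE is never tested on pooled populations — pooling breeds induces
  Wahlund-effect departures that have nothing to do with genotyping
  quality.

## The synthetic cohort

Real array cohorts of this kind are rarely redistributable, so the package
ships a seeded generator used by every end-to-end test. It is a
founder-copy model: a small set of founder haplotypes is drawn SNP-wise
(founder-panel allele frequencies kept at or above `maf_floor` by
construction), and each sample haplotype mosaics across founders, switching
with probability $1 - e^{-\rho \cdot gap}$ between adjacent SNPs. This
yields LD that decays smoothly with physical distance at a scale set by
$\rho$.

Defaults are calibrated once to the regime reported for dense bovine
array data, the setting this method was developed in: 200 diploid
animals, 2000 SNPs at 4 kb mean spacing (about 25 right-neighbours within
100 kb, comfortably above the 15-neighbour rule), 4 founders and
$\rho = 7.5 \times 10^{-6}$, giving mean adjusted $r^2$ of roughly 0.3–0.4
in the first 5-kb bin, falling to roughly 0.05–0.1 at 100 kb — the
magnitudes published LD-decay curves for such panels show.

Two kinds of segments can be planted as ground truth:

* `high_ld`: two complementary template haplotypes are built from the
  segment, and each haplotype's segment is overwritten (with probability
  `strength`) by the template matching its own allele at an *anchor*
  column — the most informative SNP in the right half of the segment.
  Anchoring keeps every planted column polymorphic and preserves the
  anchor's natural decaying LD into the right flank, so the elevated LD
  fades into the background rather than collapsing at the boundary, as
  around a real recombination-suppressed rearrangement. At strength 1 all
  within-segment pairs reach $r^2 = 1$.
* `low_ld`: each segment column is independently permuted across
  haplotypes with probability `strength`, destroying association while
  preserving allele frequencies (and hence HWE and MAF).

The reference scenario (`default_scenario()`) plants one segment of each
kind, 130 kb long (~30 SNPs), at strength 0.9. The 130-kb length is
deliberate: the deviation unit is a SNP *plus its full 100-kb window*, so
a deviating region must exceed the window for any member SNP's entire
neighbourhood to lie inside it; regions at or below window size are only
detectable when their boundary pairs happen to cooperate. Under these
conditions the scan recovers both planted segments, with the correct
direction, in essentially all seeded replicates, and independence panels
(`planted = FALSE`) yield no calls in almost all replicates.

What the generator does *not* emulate: mutation, gene conversion,
ascertainment bias of array SNP selection, population admixture and
relatedness structure, genotyping error, and phasing error. Passing the
recovery tests therefore demonstrates the scan's correctness and its
behaviour under calibrated LD decay — not robustness to phasing artefacts
or demographic confounding in real cohorts.

## Merging, regions and downstream summaries

Calls from many populations are grouped into **regions** by
single-linkage merging of intervals sharing at least one base pair
(`merge_regions()`): transitive chains collapse into one region, giving
the unique minimal disjoint cover of all calls. Regions carry the union of
member populations and member SNP positions. The one-base-pair criterion
(rather than a reciprocal-overlap fraction) matches the package's
region-consistency semantics — two breeds "share" a region as soon as any
segment of it is declared in both — and `overlap_count()` applies the same
criterion when counting hits against external interval sets (e.g. CNV
region catalogues); users comparing against studies that use reciprocal
criteria should treat those fractions as upper bounds.

`population_stats()`, `sv_per_mb()` and `maf_spectrum()` produce the
standard per-population summary table, per-chromosome densities and MAF
histograms. `sv_pca()` runs covariance PCA (column mean-centring, no
scaling — a `scale.` flag is available) on the populations × chromosomes
SV-count matrix from `sv_count_matrix()`; eigenvector signs are fixed by
making each component's largest-magnitude loading positive, which makes
results bit-reproducible. `tidy()`/`glance()` methods expose scores and
variance fractions.

## Numerical choices collected

* Bins are half-open left, closed right: $((b-1)\,5000,\ b \cdot 5000]$,
  so every distance in 1..100000 maps to exactly one of 20 bins.
* Minor-allele ties at frequency 0.5 break toward allele 1 (the ALT
  allele); $r^2$ itself is invariant to the choice.
* Pairs are formed left-to-right only; the neighbour count that the
  15-neighbour rule tests is the right-window count (a two-sided variant
  is out of scope of the default scan).
* The BH mask marks `p <= p_(k)`; no tie can straddle the threshold
  because a tied value at $k{+}1$ would itself satisfy the step-up
  inequality.
* "Adjacent" SNPs means consecutive in the post-QC map of that
  population, so QC-removed markers do not interrupt runs.
* The exact HWE p-value guards its configuration comparison with a
  relative tolerance of 1e-9 against floating-point ties between
  configurations of mathematically equal probability.

## Problem sizes used in validation

The shipped validation uses panels of 60–100 SNPs for the
oracle-equivalence checks (where a naive quadratic transcription of the
definition is feasible), the 200-animal / 2000-SNP reference scenario with
20 seeded replicates for recovery and null control, and 200 random
interval fixtures per merging/overlap oracle. These sizes were chosen so
the whole suite re-runs quickly on a laptop while leaving each statistical
check enough resolution (e.g. ~34,000 testable SNP tests pooled across
null replicates for the FDR bound).

## Known limitations

* The method detects *LD-deviant segments*; calling them structural
  variations is an interpretation. Low-recombination regions,
  selection, and assembly errors can produce the same signature.
* Windows are one-sided; a variant's last ~window of SNPs tend to be
  `mixed` and are recovered only via members further left.
* Phasing is trusted as given. Phasing errors deflate LD and would bias
  the scan toward `below` calls.
* Expected means are estimated from the same data being scanned; a
  chromosome dense in true variants has a biased baseline. At realistic
  variant densities this is second-order, but it is the reason profiles
  are per-chromosome rather than genome-wide.
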