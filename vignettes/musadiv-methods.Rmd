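---
title: "Methods: dominant-marker diversity, AMOVA and volatilome analytics in musadiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-marker diversity, AMOVA and volatilome analytics in musadiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musadiv)
```

`musadiv` analyses dominant DNA fingerprints (RAPD / ISSR / band-scored
SSR) and GC–MS volatile profiles of banana germplasm panels. This
vignette is the package's own account of the statistical models it
implements, the conventions it had to choose where the field admits
several, and the limits of what its tests demonstrate.

## 1. The dominant-marker model

A dominant band locus shows a band whenever at least one of a
genotype's $m$ allele copies carries the presence allele. Under
random union of alleles the absence phenotype requires all $m$ copies
null, so from an observed band frequency $\bar p$ the estimators are

$$q = (1-\bar p)^{1/m}, \qquad p = 1 - q .$$

`estimate_allele_freqs()` defaults to the diploid Hardy–Weinberg scheme
($m = 2$, the convention of standard dominant-marker software even for
polyploid panels) and offers `scheme = "ploidy_aware"` for an explicit
$m$; banana panels mix diploids, triploids and tetraploids, and the
cube/fourth-root estimators can differ appreciably at high band
frequency. All per-locus statistics then follow the two-allele forms:
$Na$ (alleles with positive frequency), $Ne = 1/(p^2+q^2)$,
$I = -(p\ln p + q\ln q)$ with $0\ln 0 \equiv 0$, $He = 2pq$, and the
small-sample-corrected $uHe = \frac{2N}{2N-1} He$, where $N$ counts
genotypes actually scored at the locus (missing cells are excluded
locus-wise everywhere).

Conventions chosen where the literature offers alternatives:

* **PIC.** For dominant loci we take $PIC = 2\bar p(1-\bar p)$ (the De
  Riek convention, ceiling 0.5); the codominant form $1-\sum p_i^2$ is
  available via `method = "one_minus_sum_sq"` but is not the default.
* **Resolving power.** $RP = \sum_b I_b$ with band informativeness
  $I_b = 1 - 2|0.5 - \bar p_b|$ (Prevost & Wilkinson).
* **Marker index.** $MI = \overline{PIC} \times EMR$, with the
  effective multiplex ratio $EMR = n_{poly}\,(n_{poly}/n_{loci})$.
* **Amplicon accounting.** An *amplicon* is a 1-cell of the band
  matrix; a locus is *polymorphic* when its scored cells contain both
  0 and 1 (strict criterion — with ~20-genotype panels the 95% rule
  would discard real variation). Polymorphism % is the ratio of 1-cells
  at polymorphic loci to all 1-cells of the primer. These counting
  semantics make per-primer rows internally consistent: a primer with
  one fixed-present locus in a 20-genotype panel contributes exactly 20
  monomorphic amplicons.

Panel mean rows average each statistic arithmetically across a marker
system's primers; mean polymorphism % averages the per-primer
percentages recomputed from counts (not the ratio of summed counts).

## 2. Similarity, UPGMA and group cuts

Between two fingerprint lanes the package uses the
shared-amplification-product coefficient

$$S = \frac{2a}{n_a + n_b},$$

with $a$ the jointly present bands and $n_a, n_b$ the per-lane band
counts over loci scored in both lanes — the Dice / Nei–Li coefficient.
Joint absences carry no signal for dominant data (absence of a band is
not evidence of shared ancestry) and are excluded by construction;
Jaccard and simple matching are available behind the `coefficient`
argument for comparison but are not defaults. Similarity is converted
to distance as $D = 1 - S$ before clustering and ordination.

UPGMA is implemented directly rather than through `stats::hclust`
because deterministic output requires a defined tie-break: when two
cluster pairs are equidistant (within $10^{-12}$), the pair whose
(label, label) pair — each cluster labelled by its alphabetically first
member — is lexicographically smallest merges first. Trees are
therefore invariant to input row order. Heights follow the cophenetic
convention (the full merge distance); `write_newick()` halves them into
ultrametric branch lengths, quoting labels that contain spaces or
Newick metacharacters.

`cut_at_similarity(tree, s)` groups leaves whose cophenetic distance is
**at most** $1-s$. The inclusive boundary is deliberate: at $s = 0$ all
leaves form one group even when the deepest merge sits exactly at
distance 1 (possible with Dice distances), and at $s = 1$ only exact
duplicates — merged at height 0 — share a group.

`cophenetic_correlation()` reports the Pearson correlation between
tree-implied and observed distances as a fit diagnostic; it errors on
constant distance matrices, where the correlation is undefined.

## 3. Ordination

`pcoa()` performs classical principal coordinates analysis: Gower
double-centering $B = -\frac12 J D^2 J$, symmetric eigendecomposition,
coordinates scaled by the square roots of positive eigenvalues. Dice
distances are generally non-Euclidean, so negative eigenvalues occur;
they are reported, but excluded from both the coordinates and the
variance-explained denominator, which keeps cumulative percentages
monotone and ending at exactly 100. Eigenvalues below
$10^{-8} \max|\lambda|$ are treated as null. Axis orientation is fixed
by making each axis's largest-magnitude loading positive, so runs are
bit-reproducible.

## 4. AMOVA and permutation testing

The squared inter-genotype distance is the band-mismatch count over
jointly scored loci — the squared Euclidean distance on 0/1 vectors and
the standard AMOVA metric for binary data. For $N$ genotypes in $k$
populations:

$$SS_{total} = \frac1N \sum_{i<j} d^2_{ij}, \qquad
  SS_{within} = \sum_{p} \frac{1}{n_p} \sum_{i<j \in p} d^2_{ij},$$

$SS_{among}$ by subtraction, $df = (k-1,\ N-k)$,
$n_0 = (N - \sum n_p^2/N)/(k-1)$, $\sigma^2_w = MS_{within}$,
$\sigma^2_a = (MS_{among}-MS_{within})/n_0$ and
$\Phi_{ST} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)$. Choices:

* Significance by whole-genotype label permutation with the add-one
  estimator $p = (1+\#\{\Phi^* \ge \Phi\})/(1+n_{perm})$, which cannot
  report $p = 0$. Default 999 permutations; `n_perm = 0` skips the test
  for simulation loops (a p-value always uses at least 99).
* A negative $\sigma^2_a$ (when $MS_{among} < MS_{within}$) is reported
  as-is with a note rather than truncated — the unbiased-estimator
  convention, and the reason $\Phi$ can be slightly negative on
  unstructured data.
* If all genotypes are identical, $\Phi$ is undefined and reported as 0
  with a warning.
* The design is strictly one-level (no regional hierarchy), matching
  small germplasm panels.

Per-population summaries use the dominant estimator within each
population: gene diversity is the locus mean of $1-(p^2+q^2)$ with the
small-sample factor $n/(n-1)$ for $n \ge 2$ (skipped, with a flag, for
singleton populations), heterozygosity the locus mean of $2pq$
(Lynch–Milligan-style expected value — observed heterozygosity is not
recoverable from dominant bands).

## 5. Bayesian-clustering summaries

The package never runs admixture MCMC; it post-processes plain-text
run summaries. `evanno_delta_k()` implements the second-difference
statistic $\Delta K = |L''(K)|/sd(K)$ on replicate LnP(D) means; it
requires a contiguous K range of length $\ge 4$ and $\ge 2$ replicates
per K, flags zero-sd K values as undefined rather than dividing by
zero, and is invariant to constant shifts of all log-probabilities.
`classify_membership()` assigns each genotype to its argmax cluster,
calling it `unassigned` below the membership threshold `C`
(default 0.44), `pure` at or above `purity_threshold` (default 0.7) and
`admixture` in between. The purity rule is this package's explicit
convention — membership thresholds alone cannot separate pure from
admixed genotypes deterministically — and both thresholds are plain
arguments.

## 6. Volatilome analytics

Kovats retention indices use the linear temperature-programmed
convention on a strictly monotone C8–C20 n-alkane ladder:
$RI = 100n + 100\,(n'-n)\frac{rt - RT_n}{RT_{n'} - RT_n}$ for
bracketing alkanes $n < n'$, exact ($100n$) at every anchor, and an
error outside the ladder span. RI matching defaults to a tolerance of
15 index units, typical for semi-standard non-polar columns, and
reports signed deviations.

Class composition restricts chemical classes to a closed nine-class
vocabulary (ester, aromatic aldehyde, alcohol, hydrocarbon, ketone,
ether, carboxylic acid, diverse functional group, chlorine-containing).
Reported percentages are rounded **half-up** to integers
(`round_half_up()`), the convention of published composition tables
(30/54 = 55.6 prints as 56); exact percentages always sum to 100 and
are also returned. Per-cultivar totals are cross-checked against a
stored totals row when the input provides one; mismatches are reported
and warned about, never silently corrected.

The packaged 54-compound table
(`inst/extdata/banana_volatiles.csv`) is a transcription of a published
nine-cultivar screening. A few presence cells in its final sections are
typographically truncated in the source; those cells were filled so
that every per-class and per-cultivar count matches the table's own
printed class headers and totals row (which reconcile exactly), and are
flagged in the `ambiguous` column. Aggregate statistics are insensitive
to the flagged cells by construction; analyses of individual flagged
compounds should treat them with caution.

Cultivar clustering reuses the fingerprint machinery: the cultivar ×
compound presence matrix is treated exactly like a band matrix
(Dice similarity, UPGMA), so a compound absent everywhere has no
effect, and a cultivar with no compounds is an error (its similarity is
undefined).

## 7. The synthetic-data generator

`simulate_structured_bands()` draws, per locus, an ancestral band-allele
frequency $p_0 \sim U(0.1, 0.9)$ and per population
$p_k \sim \mathrm{Beta}\!\big(p_0\tfrac{1-F}{F},\,(1-p_0)\tfrac{1-F}{F}\big)$
— the Balding–Nichols model, giving a single interpretable
differentiation knob with $\mathrm{E}[p_k] = p_0$ and
$\mathrm{Var}[p_k] = F\,p_0(1-p_0)$; $F = 0$ short-circuits to
$p_k = p_0$ exactly, and $F \ge 0.95$ is rejected as degenerate. A
genotype of ploidy $m$ expresses the band with probability
$1-(1-p_k)^m$. Defaults mirror the study conditions the package is
designed around: 20 genotypes in 4 subpopulations, a 34-primer panel
(11 RAPD + 11 ISSR primers at the published per-primer locus counts,
12 SSR primers with 1–5 loci), $F = 0.23$, and genome groups sampled
triploid-heavy from AA/AB/AAA/AAB/ABB/AAAB. One seed drives every draw,
so whole pipelines replay bit-exactly.

**Dominant masking inflates band-level $\Phi_{ST}$.** The band
phenotype frequency $\pi_k = 1-(1-p_k)^m$ is a concave transform of
$p_k$, and $\Phi_{ST}$ computed from band mismatches estimates the
differentiation of $\pi$, not of $p$, and sits materially above $F$
for ploidy $\ge 2$ (the test suite asserts only that it increases
with $F$). For parameter-recovery tests the generator therefore supports
`ploidy = 1` — per-allele band expression, the codominant-equivalent
scoring under which $\Phi_{ST}$ recovers $F$ within ±0.05 (asserted in
the test suite for $F$ = 0.05 / 0.15 / 0.25 as means of 10 seeds at
4 × 25 genotypes × 300 loci). Real cultivar maps keep the
biological 2–4 ploidy constraint; `ploidy = 1` exists for calibration
and testing.

What the generator does **not** emulate: linkage between loci, locus
dropout correlated with fragment size, scoring error, or the marginal
band-frequency spectrum of any particular real panel (the fingerprints
behind the published summary tables are unpublished, and no claim of
spectrum match is made). Green tests therefore demonstrate correctness
of the estimators under the stated model, not robustness to artefacts
real gels can contain.

`simulate_structure_runs()` builds a mean LnP(D) curve that is piecewise
linear with slope 40 before the true K and 2 after it, so the only
nonzero second difference sits at the kink; replicate noise is Gaussian
with configurable sd. At noise sd 0.5 and 5 replicates, $\Delta K$
selects the true K in at least 90% of seeded runs (asserted over 50
seeds in the test suite).
`simulate_volatile_table()` draws retention times uniformly over the GC
window, computes experimental RIs from a monotone ladder spanning the
window (so the simulated table is self-consistent under
`kovats_ri()`), perturbs reference RIs with $N(0,5)$ library error,
and defaults to the 54-compound, 56%-ester class profile.

## 8. Numerical conventions and problem sizes

* File dialect everywhere: comma-separated UTF-8, `NA` for missing,
  fixed column order, floats as `%.4f` in pipeline artifacts; locus ids
  encode `PRIMER|SYSTEM|band`, so per-primer statistics need no side
  table. Band labels stay text (mixed `0.75 Kb` / `750 bp` labelling in
  the wild; no unit parsing).
* Validation errors name the offending genotype/locus/cultivar.
* UPGMA tie tolerance $10^{-12}$; PCoA eigenvalue cutoff
  $10^{-8}\max|\lambda|$; Q-matrix rows must sum to 1 within $10^{-6}$.
* The test suite checks oracle equivalence (Dice, UPGMA, AMOVA sums of
  squares, PCoA reconstruction) against independent brute-force
  implementations at $n \le 10$, parameter recovery at 4 × 25 genotypes
  × 300 loci over 10 seeds, and delta-K selection over 50 seeded runs —
  sizes chosen to hold Monte-Carlo error well below the asserted
  tolerances while keeping the default suite in seconds.

## 9. Known limitations

* Dominant-marker allele frequencies assume Hardy–Weinberg within
  populations; clonally propagated cultivars violate this to an unknown
  degree, a limitation shared by all dominant-marker diversity studies.
* SSR loci are treated as dominant bands; the codominant allele-size
  information a true SSR assay carries is summarised only through the
  external Bayesian-clustering route.
* AMOVA is one-level; hierarchical designs (regions over populations)
  are out of scope.
* The volatile module summarises presence/absence, not peak areas or
  odour-activity values.
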