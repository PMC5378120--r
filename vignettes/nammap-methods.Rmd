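---
title: "Linkage maps and diversity statistics for selfed-RIL NAM panels: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage maps and diversity statistics for selfed-RIL NAM panels: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nammap)
```

`nammap` analyses nested association mapping (NAM) panels of selfed
recombinant inbred lines (RILs): many biparental populations sharing one
reference parent, each genotyped at a sparse set of biallelic markers
after four to six rounds of single-seed descent (SSD). This vignette
explains the models, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the design choices made where
the method descriptions in the field leave room.

## The selfing recursion: the package's probabilistic core

Every statistical step rests on the exact genetics of repeated selfing
from a fully heterozygous F1.

For a single locus, heterozygosity halves each generation:
at F_k the genotype frequencies are
$(\tfrac{1-h}{2},\, h,\, \tfrac{1-h}{2})$ with $h = (1/2)^{k-1}$ —
at F4, `r paste(selfingGenotypeFrequencies(4), collapse = " / ")`.
`selfingGenotypeFrequencies()` iterates this with integer numerators
over the denominator $4^{k-1}$, so the returned doubles are exact
(all values are dyadic rationals).

For two loci, `twoLocusSelfingDistribution(r, k)` tracks the ten
unordered diplotypes over the four two-locus haplotypes through $k-1$
selfing rounds. Meiosis from a double heterozygote emits parental
haplotypes with probability $(1-r)/2$ each and recombinants with $r/2$
each; one selfing round squares the gamete distribution and re-collapses
to diplotypes. The transition matrix entries are quadratic polynomials
in $r$, so the coefficients are fitted once and likelihood evaluations
cost three small matrix-vector products. `k = Inf` uses the closed-form
inbred limit, the Haldane–Waddington recombinant-class frequency
$R_\infty = 2r/(1+2r)$; the recursion at $k = 200$ agrees with it to
below $10^{-6}$ (tested).

Two-point estimation (`estimateRf`, `estRfMatrix`) maximises the
multinomial likelihood of the observed 9-class contingency table over
$r \in [0, 0.5]$ under this recursion, reporting the linkage LOD
$\log_{10} L(\hat r) - \log_{10} L(0.5)$. The matrix version scores all
pairs on an $r$-grid (step 0.005) via nine cross-product count matrices,
then refines linked pairs (grid LOD ≥ 3 by default) by Brent search to
tolerance $10^{-6}$; distant pairs keep grid resolution, which is
irrelevant downstream because grouping only consumes pairs with
rf ≤ 0.3 and LOD ≥ 3. Markers scored without a single heterozygote —
a common scoring failure in which heterozygotes are miscategorised with
one homozygote class — use a collapsed AA-versus-non-AA likelihood for
rf estimation and are excluded from the distortion and translocation
analyses. Fully inbred populations drop heterozygote calls and use the
inbred-limit model throughout.

## Map construction

`buildGeneticMap()` chains validation → pairwise estimation → grouping
→ ordering → splitting. The parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `maxMissing` | 0.10 | markers with missing fraction **strictly above** this are dropped (ties kept) |
| `lodMin`, `rfMax` | 3.0, 0.3 | both must hold on every link of the single-linkage closure |
| `rippleWindow` | 3 | window for progressive rippling after greedy seriation |
| `gapCm` | 35 | split linkage groups at adjacent gaps ≥ this (inclusive) |

Ordering is greedy seriation under the minimum-SARF criterion (SARF =
sum of adjacent recombination fractions): seed with the closest pair,
insert the (marker, position) pair that minimises SARF, ties broken by
marker name for determinism, then ripple until no window permutation
strictly improves. The objective never increases during rippling.
Positions are cumulative Kosambi distances of the adjacent per-meiosis
$\hat r$ — the per-meiosis fraction, not the F_k-inflated recombinant
frequency, is what a map function expects, and the estimator already
works on the per-meiosis scale. Chromosome labels come from the
majority a-priori assignment of the member markers.

## Consensus maps

Per chromosome, component linkage groups from all populations are first
oriented: any component whose mean Spearman correlation of shared-marker
ranks against all others is negative is reversed; components sharing no
markers with any other are discarded. Merging solves a linear program
over consensus positions $x$: each component adds order constraints
$x_{i+q} \ge x_i$ for pairs up to $K$ apart in its order, and L1
objective terms $|(x_j - x_i) - d_{ij}|$ for its adjacent pairs, each
component weighted equally. Cycles in the union order graph (genuine
order conflicts) are removed as a feedback arc set weighted by the
number of supporting components (`igraph::feedback_arc_set`); exact
minimal removal is NP-hard and not attempted. The candidate maps for
$K = 1, 2, 3$ are scored by per-component RMSE — root-mean-square of
consensus position minus the affinely rescaled component position over
shared markers — and the lowest mean RMSE wins, ties by lower SD of
RMSE, then lower $K$. On identical inputs all candidates are exact and
$K = 1$ is returned.

The L1 objective is linearised in epigraph form
($e_t \ge \pm((x_j - x_i) - d_t)$) and solved by a small two-phase dense
simplex written for this package (Bland's anti-cycling rule throughout).
These systems are tiny but extremely degenerate — many duplicated terms
and zero-distance ties — and the general-purpose simplex routines
available to the package returned spurious infeasibility on exactly
those instances; Bland's rule guarantees termination, and the solver is
cross-checked in the tests against frozen instances with hand-verifiable
optima.

## Map comparison

The marker-distance ratio (MDR) of a biparental linkage group against
the consensus divides the two mean marker distances over the **shared**
markers only: span of the shared markers divided by interval count, in
each map's own coordinates. Groups of length 0 cM are excluded (they
artificially compress the ratio range). Within each chromosome, ratios
beyond the Tukey fences $Q_1 - 1.5\,\mathrm{IQR}$ / $Q_3 +
1.5\,\mathrm{IQR}$ are outliers; quantiles use linear interpolation
(type 7), a choice documented here because fence membership can flip
with the quantile method. A high outlier counts as an *expanded*
linkage group only when it rests on at least six shared markers.

Order congruence is the Spearman correlation of shared-marker positions
(average ranks on ties), classified on $|\rho_s|$ **after** orientation:
$|\rho_s| \le 0.6$ incongruent, $0.6 < |\rho_s| \le 0.7$ near
incongruent, else congruent; fewer than seven shared markers is classed
insufficient. The boundary assignment (0.6 inclusive to incongruent) is
a package decision — the published intervals overlap at 0.6. A
perfectly reversed group ($\rho_s = -1$) is a flip handled by
orientation, not a rearrangement.

## Segregation distortion

`imputeGenotypes()` is a forward–backward HMM per individual and linkage
group: initial probabilities are the generation-k marginals, transitions
are conditionals of the two-locus recursion at
$r = $ `kosambiInverse(adjacent distance)`, emissions give the observed
state $1 - \texttt{errorProb}$ (others `errorProb`/2, uniform when
missing). The hard call is the maximal-posterior state, left missing
below `minProb = 0.95` (max-marginal behaviour). The defaults interact:
with `errorProb = 1e-4` an isolated double flip between 1 cM flanks is
*not* corrected — the prior probability of a double recombination
(~4 × 10⁻⁴) exceeds the error probability, and because neither state
reaches 0.95 the call is withheld rather than trusted. Correction of
such flips requires an error-tolerant setting (e.g. `errorProb = 0.02`);
both behaviours are asserted in the tests.

`segregationScan()` runs a χ² goodness-of-fit of the hard-call counts
against the generation expectation (df 2; fully inbred populations test
AA:BB = 1:1, df 1) with Benjamini–Hochberg adjustment across the
population's markers; direction uses the homozygote counts only.
Markers with fewer than 20 informative calls are flagged underpowered.
The nonindependence of neighbouring tests (they share imputation
information) is inherited from the max-marginal design; no correction
beyond BH is applied. `qcAlleleRatio()` flags populations whose mean
reference-homozygote ratio reaches 0.54 or whose other-parent ratio
falls to 0.37 — such populations are retained but excluded from panel
aggregates. `sdlHotspots()` projects significant markers onto the
consensus and reports per-marker and per-10 cM-bin population counts
(binning added for sparse-marker robustness; both are returned).

## Translocations

Two callers, merged by union per (population, chromosome pair):

* *mapped* — markers whose a-priori assignment disagrees with their
  linkage group's majority label; one minority marker suffices by
  default (`minMinority` configurable, the published procedure does not
  state a minimum); mirror-image pairs are flagged reciprocal.
* *estRF* — marker pairs on different chromosomes with two-point LOD
  **strictly greater** than 7.0, aggregated per chromosome pair with the
  maximum LOD. The more conservative LOD > 10 screening stage described
  alongside it is available by setting `lodThreshold = 10`; the package
  exposes both rather than resolving the textual ambiguity.

`ancestralEnrichment()` tests carrier-versus-non-carrier distribution
across ancestral groups by χ², switching to a Monte-Carlo p-value
(10⁴ resamples of the table margins) whenever an expected cell falls
below 5 — with nine groups and few carriers that is the norm; both
p-values are reported.

## Crossover counts and QTL

`countCrossovers()` sums obligate junctions over consecutive non-missing
genotypes in map order: AA↔AB and AB↔BB count 1, AA↔BB counts 2 (the
intercross convention; with codes 1/2/3 the contribution is |g₁ − g₂|).
Counts are computed on imputed hard calls by preference, since raw
mis-scored calls inflate obligate junctions. `qtlScan()` regresses the
trait on the expected reference-allele dosage from the posteriors
(Haley–Knott), with $\mathrm{LOD} = (n/2)\log_{10}(RSS_0/RSS_1)$;
putative QTL are local maxima at LOD ≥ 2, peaks within 10 cM merged.
The additive effect is the slope per reference allele (positive =
reference allele increases crossovers); the confidence interval is the
1.5-LOD drop. `multipleQtlModel()` refits all putative QTL jointly and
retains those whose drop-one LOD clears either the fixed threshold 2.0
or, optionally, the 95th percentile of permutation genome-wide maxima —
the published analysis names a data-derived threshold without defining
it, so both rules are provided. `projectCommonQtl()` counts, per
consensus marker, the populations whose QTL interval contains it;
maximal runs with ≥ 4 populations form common QTL.

## The synthetic panel generator

`simulateSsdPopulation()` builds each line from an F1 heterozygote of
the two founders and applies $k-1$ selfing rounds with exactly one
offspring kept per line (the SSD bottleneck). Per chromosome and
meiosis, crossover counts are Poisson with mean length/100 — no
interference, i.e. Haldane — with uniform positions. Maps are
nevertheless computed with Kosambi, mirroring the analysis practice;
parameter-recovery tests therefore compare recombination fractions, not
cM, and simulated maps are expected to be mildly compressed relative to
the simulated lengths.

Structural variants are expressed as a *realized geometry*
(`realizeGeometry()`): a carrier cross simulates all meioses with the
translocated block's markers relocated to the recipient chromosome at
the insertion point (recipient markers shifted; reciprocal events swap
equal-length intervals) and inverted blocks' positions reflected in
place, while the markers keep their native chromosome in the metadata
(the array-annotation analogue). Rearranged blocks therefore
cosegregate with their physical location — exactly the signature the
detectors consume (inter-chromosome linkage, minority assignments,
reversed local order). Per-haplotype segregation of the carrier state
itself is not tracked: it alters none of the observable statistics this
pipeline measures, and unbalanced-gamete loss, if wanted, is expressible
through a selection locus.

Selection loci act as relative zygote survival weights per selfing
round (rejection sampling; a configuration whose surviving offspring
set is empty errors out). A crossover modifier adds
`effect × dosage(non-reference allele)` to every per-chromosome Poisson
mean of the parent's meioses. Observation noise sets calls missing at
`missingRate` and flips survivors to a uniformly different code at
`errorRate`; the truth record (pre-noise calls, realised crossovers per
lineage, geometry, planted variants) rides along in the returned
object. Default study conditions mirror the motivating panel: 94
individuals, F4, `wheatGenomeSpec()` with 8–31 markers on A/B
chromosomes and 3–6 on D, genetic lengths 110–160 cM; missing and error
rates (2 %, 0.5 %) are free parameters chosen as plausible for KASP-like
scoring, since no error model is published.

What the generator does **not** emulate: crossover interference,
sequence-level mutation/ascertainment, shared founder haplotypes across
populations (each cross is simulated independently), residual
heterozygosity structure beyond the selfing recursion, and
marker-intensity artefacts richer than symmetric miscalls. Passing
tests therefore validate the estimators against their own model class,
not against every failure mode of real array data.

## Statistical power at the study's scale — a known limitation

With 94 F4 lines, sparse markers and obligate-junction crossover
counts, the crossover-QTL stage has intrinsically low power, and the
package's validation quantifies rather than hides this. A crossover-rate
modifier expresses itself on the trait scale only weakly, for two
compounding reasons measured with the simulator:

* *dilution* — the F1 is uniformly heterozygous, so between-line dosage
  contrast exists only in later selfing generations, by which time most
  of the genome is fixed and extra crossovers in homozygous tracts
  create no junctions (visible fraction of realised crossovers
  ~5–10 %);
* *saturation* — strong modifiers decorrelate adjacent markers and push
  every line's obligate count toward the same ceiling (~0.985 junctions
  per interval), erasing the contrast again.

Across modifier strengths the trait-scale additive effect peaks near
0.5 obligate crossovers per allele, i.e. a median LOD around 0.4 at
n = 94: majority recovery of a planted modifier at LOD ≥ 2 is not
achievable under this design, and the corresponding acceptance test
records that honestly as a failure with these measured rates. The QTL
machinery itself is validated at n = 1200, where the same effect gives
LOD ≈ 5 and reliable localisation. This mirrors the published caveat
that obligate-count traits carry reduced statistical power.

## Problem sizes in the test suite

The suites run at the study's population size (n = 94, F4) with
genomes scaled to the question: single chromosomes for ordering and
distortion power (200 replicates), three chromosomes for translocation
power and two for QTL calibration (100–200 replicates), 21 sparse
chromosomes for the translocation null, a 5 × 12-marker genome at
n = 500 for full map reconstruction, and the full
`wheatGenomeSpec()` for end-to-end runs. These sizes are the package's
validation design; all complete in a few minutes on one CPU.
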