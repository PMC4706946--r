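---
title: "Cluster models, flagging criteria and QC for exome-array genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster models, flagging criteria and QC for exome-array genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exocall)
```

# The problem

Two-channel genotyping arrays summarize each sample-variant pair as a point
in normalized polar coordinates: the allelic angle theta (0 for a pure
A-allele signal, 1 for pure B) and the total intensity R. Across samples, a
well-behaved variant shows up to three clusters — AA near theta 0.1, AB near
0.5, BB near 0.9 — and genotype calling is cluster assignment. The approach
degrades exactly where exome arrays matter most: rare variants. With one or
two minor-allele carriers there is no heterozygote cluster to anchor, so a
few drifted homozygotes can be mistaken for one; degraded assays scatter
low-intensity points across the theta range; and a cluster boundary fitted
too tightly no-calls perfectly good samples. Cohorts from populations poorly
represented in the array design aggravate all of this because most designed
variants are monomorphic in-sample.

`exocall` implements the full workflow used to handle this in practice —
call, compute per-variant cluster statistics, flag suspicious variants under
criterion tables, repair what can be repaired, run sample/variant QC, and
validate against sequencing — together with a simulator that plants the
pathologies, so every stage is testable without any proprietary data or
software.

# The caller

## Model

Per variant, the caller fits a three-component constrained mixture on theta.
Components are anchored at configurable prior centers (defaults 0.10 / 0.50
/ 0.90) with an anchor deviation of 0.06; fitting is a classification EM
with **uniform class priors** — component size never down-weights a class,
because a genuine rare heterozygote cluster of three points must be able to
claim its members against a 500-point homozygote cluster. Points are
weighted by R in the mean and deviation updates (low-intensity points carry
less information about cluster position). Ordering AA < AB < BB is enforced
at every iteration; empty components snap back to their anchors so they can
still capture points in later iterations; components ending with fewer than
`min_points` (default 2) members are marked unpopulated. Initialization is
fixed at the anchors, so the fit is deterministic — there is no RNG anywhere
in the caller.

Calling assigns each sample the populated cluster with the highest posterior
under a per-cluster bivariate normal on (theta, R) with independent axes and
uniform priors. A sample is no-called (NC) when the best cluster's
Mahalanobis distance exceeds `d_max` (default 4.0), the posterior falls
below `p_min` (default 0.7), or the intensity is missing. Array software
does not document its no-call rule; these two thresholds are this package's
own, exposed in `caller_config()`.

R is simulated lognormal but modeled normal per cluster; at the default
sdlog of 0.1 the skew is negligible against a 4-deviation cut.

## Reclustering

Real workflows repair flagged variants by manual inspection. `exocall`
replaces that with a deterministic pipeline, and explicitly does not claim
parity with human decisions:

1. **Low-R masking** — points with R below `r_frac` (0.4) times the
   variant's median R are dropped from the fit; after repair they will
   generally no-call, which is the intended outcome for low-intensity
   contamination.
2. **Trimming** — after a refit, points more than `trim_sd` (3.0) deviations
   from their component center are removed and the model refit once.
3. **Spur dissolution** — a populated component holding under
   `dissolve_frac` (10 %) of calls, sitting more than 0.10 from its anchor,
   next to a populated neighbour at least 3 times its size, is read as a
   drifted pseudo-heterozygote spur: its points are merged into the
   neighbour, whose deviation is widened so the absorbed points sit within
   `0.9 * d_max` — the programmatic analogue of dragging a cluster boundary
   over misassigned points. The anchor-offset condition protects genuine
   rare heterozygote clusters, which sit *at* their anchor.
4. **Boundary widening** — if the repaired model still no-calls more than
   `nc_widen_threshold` (5 %) of the points that passed the low-R mask,
   deviations are inflated by `boundary_widen` (1.5), kept only when that
   reduces the no-call rate, at most twice. Masked low-R points are excluded
   from this rate on purpose: they are intended no-calls, not evidence of a
   tight boundary (counting them would re-admit junk as genotype calls).

The repaired variant is re-called and re-measured. If any
irreparable-geometry rule still fires — cluster separation, AB frequency,
AB R mean, heterozygote excess — the variant is **zeroed** (excluded
downstream). Otherwise it is **reclustered**. If the incoming flags were
frequency-only (the combined MAF/call-rate rows) and no geometry rule fires,
nothing is touched (**unchanged**): a clean rare variant flagged for being
rare needs no repair. The choice of which rules block restoration is this
package's own; the T Mean / T Dev rows are deliberately not in the blocking
set because successful spur absorption legitimately widens a cluster.

# Flagging criteria

The two built-in criterion tables each hold 17 rules in four categories
(general clustering errors and per-cluster AA / AB / BB errors). They differ
only in four combined frequency rows: the stricter set flags any imperfect
call rate on rare or single-class variants (`MAF < 0.0001 & Call Freq != 1`,
`AA Freq = 1 & Call Freq < 1`, `AB Freq = 0 & MAF > 0`,
`BB Freq = 1 & Call Freq < 1`), while the adjusted set relaxes the call-rate
cutoffs to 0.99 and the missing-heterozygote MAF bound to 0.0002 — designed
for cohorts where two thirds of the array is monomorphic, so that "rare and
imperfectly called" stops flagging half the chip. By construction every
adjusted flag set is a subset of its stricter counterpart, which the test
suite asserts across simulated cohorts.

Conventions, all configurable:

* rulesets are data (YAML/JSON), not code; users can define new columns;
* the call-frequency band `0.95~0.99` is half-open `[0.95, 0.99)`, so a call
  frequency of exactly 0.99 falls through to the combined rules; T Mean
  bands are closed;
* equality-against-constant predicates (`AB Freq = 0`, `AA Freq = 1`,
  `MAF > 0`, `Call Freq != 1`) are evaluated on integer counts, never on
  floating-point frequencies;
* the `AB R Mean` row has no published cutoff; the default predicate is
  `ab_r_mean < 0.3`;
* absent metric fields (an unpopulated cluster has no T Mean) never satisfy
  a predicate;
* flag totals are **redundancy-counted**: a variant hit by three rules
  contributes three, and the unique-variant count is reported alongside.
  The package defines a criterion table's total as the sum of its per-rule
  counts.

The cluster-separation and heterozygote-excess formulas are surrogates for
undocumented proprietary statistics (see the README for the closed forms);
they are calibrated so the conventional thresholds (0.4; 0.1 / -0.9) behave
sensibly on simulated geometry, and they are *not* claimed to reproduce
array-software values on real exports.

# The QC cascade

Sample QC runs first, in a fixed order, each sample recording its first
failure: relatedness (one member of each pair with PI_HAT > 0.1875 — the
midpoint between second- and third-degree expectations — dropping the
lower-call-rate member), the X-heterozygosity sex check
(`F = 1 - O(het)/E(het)`; female below 0.2, male above 0.8), then the sample
call-rate filter (< 0.99). Variant QC follows on the surviving samples:
call rate < 0.95 (which also removes fully missing variants), the
Hardy-Weinberg exact test (p < 1e-6; computed on females only for X
variants), minor allele count (mac 0 reported as `monomorphic`, mac 1 as
`low_mac` under the default `mac_min = 2`), and duplicate records at the
same position with the same alleles (higher call rate wins; ties resolved
by position then id).

The HWE test enumerates every heterozygote count compatible with the
observed allele counts via a numerically stable recurrence from the modal
configuration and sums the probabilities not exceeding the observed one
(with a 1e-7 relative tie tolerance). The test suite checks it against an
independent log-factorial enumeration for every genotype triple with total
up to 200, at 1e-12.

Two guards are deliberately stricter than common defaults: the relatedness
screen requires at least 1,000 polymorphic autosomal markers and the sex
check at least 20 polymorphic X markers, otherwise they are skipped with a
warning. Method-of-moments PI_HAT at a few hundred markers has a standard
deviation near 0.1, so the 0.1875 threshold would mass-exclude unrelated
samples; real workflows run these screens on tens of thousands of markers,
and small simulated panels must not pretend otherwise.

# Concordance evaluation

Array calls are compared with sequencing-derived truth genotypes on the
site intersection (matched by chromosome and position; swapped ref/alt
orientations are retained with the truth dosage mirrored; strand-ambiguous
A/T and C/G sites and off-target-flagged sites are excluded and counted).
Per variant, pairs with a no-call or missing genotype on either side leave
both numerator and denominator. Three metrics:

* **overall** — fraction of matching pairs, stratified by the array
  cohort's MAF: common (>= 5 %), less common (1-5 %), rare (< 1 %);
* **non-reference** — restricted to pairs whose truth genotype carries a
  non-reference allele, stratified by truth-cohort MAC (default 2-5);
* **heteroallele accuracy** — among truth heterozygotes, the fraction the
  array calls heterozygous, same stratification.

Stratum summaries are mean and SD **across variants**, not pooled pairs.
MAF classes come from the array cohort and MAC strata from the truth cohort;
both choices are arguments.

# The simulator

The generator emulates, directly in (theta, R) space: the three-cluster
geometry (centers 0.10/0.50/0.90); an exome-chip MAF spectrum for an
under-represented population (66.7 % monomorphic, 14.66 % at (0, 0.001],
3.21 % at (0.001, 0.005], 1.50 % at (0.005, 0.01], 2.98 % at (0.01, 0.05],
10.95 % above 0.05), with the MAF uniform within its interval; Hardy-
Weinberg genotypes at the variant's true MAF; X-chromosome dosage (males
hemizygous, represented as homozygous calls drawn from homozygote
clusters); planted duplicate pairs (genotypes copied) and parent-offspring
pairs (one transmitted allele per variant); and three planted
misclassification modes:

* `ab_misassign` — a fraction (default 2 %, minimum 2) of the
  majority-homozygote samples drifts to theta about 0.18 off its anchor
  (i.e. ~0.28 or ~0.72), where the caller reads it as a heterozygote
  cluster; the drift lands inside the T Mean 0.2-0.3 / 0.7-0.8 flag bands.
* `low_r_wide_theta` — 10 % of samples have R multiplied by 0.3 and theta
  noise inflated by sd 0.15: low-intensity scatter.
* `short_boundary` — intensities untouched; the stored cluster model's
  deviations are shrunk by 0.66, producing spurious no-calls. Under the
  two-dimensional no-call rule the expected call rate is
  `1 - exp(-8 s^2)`; `s = 0.66` places it near 0.97, inside the 0.95-0.99
  call-frequency flag band, which is how such variants are detected in
  practice.

Default geometry deviations are 0.015 on theta. The value must sit clearly
below the `T Dev > 0.025` criterion: a clean cluster's *sample* deviation
straddles its true value, so a true deviation at the threshold would flag
half of all clean variants by sampling noise alone and the criterion would
not discriminate.

Determinism: one global integer seed; every stochastic operation consumes a
named substream derived from it, so regenerating any one component (or
adding error modes) does not perturb the others, and an identical
configuration yields a bit-identical bundle.

What the simulator does **not** emulate — and what passing tests therefore
do not establish about real data: raw two-channel fluorescence and
normalization, batch and plate effects, population structure and departures
from HWE, genotyping-chemistry artifacts correlated across variants,
cryptic relatedness beyond the planted pairs, and the empirical intensity
distributions of any particular cohort (the geometry defaults are the
package's own, not estimates).

# Numerical and design notes

* Deviations are floored (theta 0.01, R 0.02) so degenerate single-point
  clusters cannot produce zero-variance components; theta-mean ties after
  ordering enforcement are separated by 1e-6.
* The exact-test tie tolerance (1e-7, relative) makes the "configurations
  no more likely than observed" set robust to floating-point noise.
* IBD Z estimates are clipped to [0, 1] and renormalized; pairs are
  evaluated on the variants both members have called.
* `--geno`-style filtering follows the prose convention "call rate < 0.95"
  (an exclusion floor on the call rate, not a missingness ceiling).
* Monomorphic exclusion is implemented as `mac < mac_min` with
  `mac_min = 2`, covering both monomorphic variants and singletons.
* Sample QC precedes variant QC; within each, filters run in the documented
  order and record first failures only, so reason counts partition the
  exclusions.
* PED/MAP, minimal GT-only VCF (4.2), a long-format final-report TSV and a
  JSON cluster-file dialect are the interchange formats; binary `.egt` and
  `.bed` are out of scope, and reading an `.egt` raises a pointed error.
  Coordinates are 1-based everywhere.

# Problem sizes

The test suite and acceptance script run at desk scale by design: cohorts
of 100-500 samples and 30-600 variants for caller and rules behaviour,
5,000 markers for relatedness recovery, 20-seed sweeps for the
reclustering-improvement and ruleset-containment properties, and exhaustive
HWE validation for all genotype totals up to 200. These sizes are chosen so
each statistical property is tested well inside its sampling noise; none of
the package's thresholds depend on them.

# Limitations

The caller is a surrogate, not a reimplementation, of proprietary array
clustering; flag counts on real exports will differ from array-software
output, and the cluster-separation / heterozygote-excess values are not
comparable across tools. The deterministic repair pipeline encodes one
reasonable reading of manual reclustering; variants a human would rescue by
eye (e.g. asymmetric but genuine clusters far off anchor) may be zeroed.
Relatedness beyond first degree is neither simulated nor specially handled;
the sex check assumes a two-state declared sex; and no linkage
disequilibrium pruning precedes IBD estimation.
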