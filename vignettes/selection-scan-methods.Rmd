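---
title: "Methods: two-population selection-signature scanning in fstscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-population selection-signature scanning in fstscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Two closed populations (in the motivating setting, two beef cattle breeds
genotyped on a ~50K SNP BeadChip across the 29 bovine autosomes) share an
ancestor but have been bred separately. Most of their genome differs only
by drift; loci targeted by divergent artificial selection show locally
elevated allele-frequency differentiation (a selective sweep) or locally
divergent linkage-disequilibrium structure. `fstscan` implements two
complementary detectors for such loci and a simulator that generates data
with known truth for calibrating them.

# The Fst model

For a biallelic SNP with within-population frequencies $f_1, f_2$ of the
same allele and sample sizes $n_1, n_2$ individuals, the pooled frequency
is the chromosome-count weighted mean

$$f_p = \frac{f_1\,(2n_1) + f_2\,(2n_2)}{2(n_1+n_2)},$$

the total expected heterozygosity is $H_t = 2 f_p (1-f_p)$, the
within-population expected heterozygosity is
$H_s = w_1\, 2f_1(1-f_1) + w_2\, 2f_2(1-f_2)$ with $w_i =
2n_i/(2n_1+2n_2)$, and

$$F_{st} = \frac{H_t - H_s}{H_t}.$$

Two choices deserve comment:

* **$H_s$ weighting.** Using the same chromosome-count weights as $f_p$
  makes $H_t \ge H_s$ a consequence of the concavity of $2p(1-p)$, so
  $F_{st} \in [0,1]$ always. Equal weighting is available via
  `hs_weighting = "equal"`.
* **No finite-sample correction.** This is the plain heterozygosity-ratio
  (Nei/Gst-style) estimator computed from sample frequencies; with several
  hundred samples per population the sampling bias is of order $10^{-3}$
  and is dwarfed by drift. Monomorphic pooled loci ($H_t = 0$) give `NA`
  and are excluded from smoothing.

Genome-wide, the mean of per-locus $F_{st}$ summarizes background
differentiation; the conventional reading multiplies it by 100 to give the
percentage of genetic variation explained by population differences.

# Data editing

The QC pipeline mirrors standard array editing: restriction to autosomes
1–29 (`n_autosomes` configurable), then removal of SNPs that are
(1) monomorphic in *both* populations separately, (2) missing in more than
2.5 % of all samples, or (3) of pooled minor allele frequency below 1 %.
Each SNP is counted once, under the first filter that triggers, so the
report reconciles exactly (input = retained + removals). Filter order
affects only that attribution, not the retained set.

Remaining missing calls are replaced by the homozygote of the allele that
is most frequent *within the sample's own population* at that locus — the
literal "most frequent allele" reading; an exact 50/50 tie imputes
`allele_a`, deterministically. Heterozygosity summaries (observed
heterozygote fraction and $2f(1-f)$) are computed after filtering but
before imputation, with missing calls excluded from denominators, so
imputation cannot inflate them. Missingness is assessed across both
populations pooled; a per-population variant of the MAF/missingness
denominators was considered and rejected because editing precedes the
pooled-frequency Fst computation.

# LOWESS smoothing and the control chart

Raw per-SNP Fst is extremely noisy. Each chromosome's track is smoothed
with a locally weighted regression (LOWESS): at every SNP a polynomial of
degree 1 is fitted by weighted least squares to the nearest
$q = \lceil S\,n\rceil$ SNPs (by physical distance), with tricube weights
$(1-(d/h)^3)^3$, $h$ the neighborhood radius. The span is chosen per
chromosome as $S = 20/n$ so that **every local fit spans 20 SNPs**
regardless of chromosome length. Defaults follow the common LOWESS
conventions (degree 1, zero robustness iterations); both are exposed in
`fst_scan()`, as is an SNP-rank abscissa (`x_axis = "snp_index"`) for
sensitivity analysis — physical bp is the default because it is the
natural metric of the genome scan. The smoother is implemented in the
package (the contract requires an exact nearest-$q$ neighborhood, pure
tricube weights and a configurable degree) and is cross-checked in the
tests against both an independent weighted-least-squares oracle and the
classic `stats::lowess` implementation.

Smoothed values are then monitored with a control chart: limits at
mean ± 3·SD (sample SD, $n-1$) of the smoothed values, by default per
chromosome (each chromosome gets its own limits; `scope = "genome"` pools
the moments instead). Strict inequalities are used — a value exactly on a
limit is in control. Contiguous runs above the UCL collapse into peaks
(summit = maximum smoothed value); runs that rise above 90 % of the
mean-to-UCL distance without crossing it are reported as *borderline*
peaks, the signature of a sweep that has not reached fixation. The 90 %
fraction is a package convention (configurable), not part of the original
procedure, which never quantified "borderline". Only upper-limit
exceedances are treated as selection signatures downstream; low outliers
remain in the data model.

Note a calibration fact quantified by the acceptance tests: the smoothed
track of a null genome is right-skewed (Fst is a squared-difference
statistic), so the fraction of SNPs outside its own ±3 SD limits exceeds
the Gaussian nominal 0.27 %, by roughly 3–4×. The chart is a
signal-flagging device, not an exact-level test.

# Regional LD comparison

The second detector asks a different question: do the two populations
organize the *same* local haplotype structure? For each window of 20 SNPs
(matching the LOWESS window) and each population, the package forms the
Pearson correlation matrix of genotype dosages (composite LD — signed,
phase-free). Columns fixed within a population get zero off-diagonal
correlation and a unit diagonal, preserving trace $= k$. The window score
is

$$\mathrm{raw} = \sum_{i=1}^{k} \left|\lambda^{(A)}_{(i)} -
\lambda^{(B)}_{(i)}\right|,$$

the L1 distance between the ordered eigenvalue spectra. Raw scores are
standardized genome-wide (z-score by default, so the 3-SD significance
threshold is literal; a rank-based inverse-normal transform is available
and gives exact-level calls), assigned to the window's central SNP
(index $\lceil k/2\rceil$ from the window start), and flagged one-sided:
only elevated LD divergence marks differential selection. Windows slide
one SNP at a time and never span chromosomes.

Because the statistic depends only on the spectrum, it is invariant to a
simultaneous sign flip of a SNP's correlations (re-polarizing an allele is
a diagonal ±1 similarity transform). This matters for the simulator
design below.

# The simulator

`simulate_dataset()` generates the study conditions: two populations of
364 and 410 individuals (the sampled breed sizes) typed on 29 autosomes ×
~1,724 SNPs (~50K total) with

1. ancestral allele frequencies uniform on [0.05, 0.95] (array SNPs are
   ascertained to be common);
2. independent Wright–Fisher drift in each population: `t_gens = 100`
   generations of binomial resampling of $2 N_e$ chromosomes with
   `n_e = 800`. These defaults were chosen so the background genome-wide
   mean Fst is ≈ 0.03, the drift-level differentiation typical of related
   cattle breeds. Analytically, each branch accumulates fixation
   $F_T = 1-(1-\tfrac{1}{2N_e})^{T}$ and the two-deme pooled-heterozygosity
   Fst has expectation $\approx F_T/(2-F_T)$ — about $F_T/2$, not $F_T$ —
   which the property tests verify against an independent frequency-level
   simulation;
3. planted sweeps: at the sweep SNP the **ancestral minor allele** of the
   target population follows the deterministic logistic trajectory
   $p' = p(1+s)/(1+sp)$ for `t_gens` generations (a sweep drives a
   low-frequency favored variant upward; selecting an allele already near
   fixation would produce no signal), and flanking SNPs are pulled toward
   the swept frequency with weight $e^{-d/\mathrm{decay}}$ — a
   phenomenological hitch-hiking model, not a recombination-explicit one;
4. haplotypes emitted as a first-order Markov walk along each chromosome
   with adjacent-allele correlation `rho = 0.3` (typical adjacent-SNP LD
   on a 50K array); joint probabilities are Fréchet-clamped so marginal
   frequencies are exact. Two haplotypes per individual are summed to
   dosages;
5. LD-divergent regions: within the region the target population's
   Markov coupling is **attenuated to zero** while marginals are
   untouched, so the region is invisible to Fst but visible to the
   spectral statistic. A sign-flip mode also exists but is a pure gauge
   transform of the correlation matrix — its spectrum is unchanged (the
   2×2 case $r=-0.5$ vs $+0.5$ scores exactly 0) — so it cannot be used
   for varLD power studies; attenuation is therefore the default;
6. iid missing calls at rate 0.002.

Everything is driven by one mandatory seed; identical configurations give
identical datasets. The generator does **not** model recombination maps,
demography (bottlenecks, migration), ascertainment bias beyond the MAF
bounds, or genotyping error structure, so passing recovery tests show the
detectors work against drift + Markov-LD backgrounds — not that they are
calibrated for every real-data pathology.

# Numerical and edge-case conventions

* Coordinates are 1-based closed throughout; BED export converts.
* Allele orientation is fixed at read time (first-observed allele in
  PED/MAP, REF/ALT in VCF) and never re-polarized; Fst and the LD spectra
  are invariant to it. PED round-trips are exact up to this orientation;
  VCF round-trips are exact.
* Duplicate map positions are tolerated with a warning; duplicates are
  jittered +1 bp before smoothing.
* Chromosomes with fewer SNPs than the window fall back to a global
  regression (scan) or are skipped (varLD), with warnings.
* A zero-SD chromosome collapses its control limits to the mean and flags
  nothing.
* All randomness (simulator, tests) flows through explicit seeds.

# Problem sizes used in the tests

The shipped suite runs module tests at toy sizes (tens of samples,
hundreds of SNPs) and the end-to-end properties at a reduced genome —
null calibration on 25 × 2,000 SNPs, drift recovery on 10 × 2,000, and a
50-replicate sweep/LD recovery experiment at 5 chromosomes × 2,000 SNPs
with full sample sizes — sizes chosen to exercise every code path at
realistic density while keeping the suite fast enough to run routinely.

# Known limitations

* Exactly two populations; multi-population designs are out of scope.
* The Fst estimator carries no finite-sample correction by design
  (it reproduces the printed pooled-heterozygosity form).
* The 3-SD chart and z-score threshold are descriptive flagging rules on
  skewed statistics; their false-positive rates under the null run above
  the Gaussian nominal level (quantified in the acceptance tests). Use
  the rank-normal varLD mode when exact-level calls are needed.
* Phased-haplotype statistics (EHH/iHS/ROH) and database/network
  annotation are outside the package's scope; gene annotation requires a
  user-supplied local GFF3/BED on matching coordinates.
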