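---
title: "Methods: CNVR construction, admixture and differentiation from CNV calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNVR construction, admixture and differentiation from CNV calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvadmix)
```

This vignette is the package's account of its methods: the models and
rules each stage implements, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where a published analysis
protocol leaves the details open.

## Coordinates and formats

Every interval inside the package is 0-based half-open `[start, end)`;
BED output uses the same convention; segment TSV input is declared
1-based inclusive (the usual array-caller convention) and converted on
read. Half-open arithmetic makes "any-base overlap" unambiguous:
abutting intervals share no base and never merge. Human-readable
reports are 1-based inclusive.

Array CNV callers differ in whether segment coordinates are
probe-midpoint or probe-boundary based; the declared input dialect is a
convention the caller's output must be mapped onto, not a
reconstruction of any specific tool's semantics.

## Segment quality filters

A segment is kept iff it is autosomal, has `n_probes >= 5`, its largest
inter-probe gap is `< 10` kb, `lod >= 10`, and its span is `< 1` Mb
(`filter_policy()`). Three details are deliberate:

* **Gap aggregation.** "Probes less than 10 kb apart" is enforced on
  the *maximum* inter-probe gap within the segment — the conservative
  reading; a mean-gap rule would admit segments with one large gap.
* **Boundary inclusivity** follows the printed comparators literally:
  LOD exactly 10 is kept, a segment of exactly 1 Mb is rejected.
* **Rule order** (autosome, probes, gap, LOD, size) only affects which
  tag a multiply-violating segment gets in the report, never the kept
  set.

Rejected segments are tagged with the first violated rule, and per-rule
counts are reported, so filter behaviour is auditable.

## CNVR construction

Within each chromosome, kept segments are merged by single linkage on
any-base overlap; each connected component's union span is a candidate
CNVR. Candidates carried by fewer than `min_freq` (default 5 %) of all
manifest samples are discarded. Choices made where the procedure is
underdetermined:

* **Per-sample state conflicts.** When one sample contributes several
  member segments with different states, the widest segment's state
  wins; ties go to the state most deviant from 2, then to the loss
  state. Any deterministic rule would do; this one prefers the
  strongest signal.
* **Threshold population.** The frequency threshold is computed over
  the whole cohort, not per population: its purpose is suppressing
  singleton/rare calls, which is a cohort-level property. It is applied
  after merging, on carrier sample counts.
* **Frequency matrices.** Within-population deletion (state < 2) and
  duplication (state > 2) carrier fractions use the population's full
  sample count as denominator, including non-carriers.

CNVRs are classified `del`, `dup`, or `gain_loss` according to whether
losses, gains, or both occur among their non-normal states.

## Biallelic recoding

Diploid copy-number states map to unordered haploid copy-count pairs:
0 → 0/0, 1 → 0/1, 2 → 1/1, 3 → 1/2, 4 → 2/2. The true allelic
configuration at CN = 2 (1/1 vs 0/2) is unknowable from diploid dosage;
the printed convention is adopted verbatim, making the map total and
invertible. Genotype-confidence masking keeps calls with confidence
strictly below 0.1 and discards those strictly above; the boundary
value itself is retained (both printed clauses exclude it; retention
keeps data).

## Population structure

A supervised random-forest classifier (population ~ CNVR states) yields
a proximity matrix — the fraction of trees in which two samples share a
terminal node — and an out-of-bag confusion matrix. The forest is the
`randomForest` CART/Gini implementation, features per node
`mtry_rule(p) = max(1, floor(sqrt(p)))` (23 at the full 567-CNVR map),
50,000 trees at full scale. Missing states are imputed to the locus
modal state first (trees need complete features). `1 - proximity` is
embedded by classical (Torgerson) MDS: double-centre the squared
distances, eigendecompose, scale the top eigenvectors by the square
roots of their (positive) eigenvalues. Proximity-derived distances are
generally non-Euclidean, so negative eigenvalues are truncated and the
captured fraction of positive-eigenvalue mass is reported. Tests use
200–5,000 trees; the ensemble is stable at that scale (entrywise
proximity correlation > 0.9 across seeds on separable data), and
accuracy is assessed out-of-bag, not by resubstitution.

## Admixture by EM

The admixture model: each of an individual's two allele copies at locus
*l* is drawn from ancestral component *k* with probability `q_ik`, then
is allele *a* with probability `p_lka`. `fit_admixture()` maximises the
observed-data likelihood by EM — responsibilities of components for
each observed copy, then closed-form `Q` and `P` updates — which is the
point-estimation counterpart of Bayesian admixture clustering on the
identical likelihood, without priors. MCMC burn-in/iteration settings
of sampler-based tools have no EM analogue and are not modelled.

Numerical choices: `Q` rows initialise from a flat Dirichlet; `P` from
observed allele frequencies perturbed by seeded log-normal noise (so
restarts differ); both are floored at 1e-12 and renormalised each
update to keep the likelihood finite; missing copies contribute
nothing; loci observed in no individual are dropped with a warning.
Convergence is declared when the log-likelihood gain falls below `tol`
(default 1e-5, `max_iter` 500); the best of `n_restarts` (default 10)
seeded restarts is returned. The log-likelihood is non-decreasing every
iteration by construction, and the test suite asserts it on every fit.
Components are identifiable only up to permutation; label switching is
resolved only afterwards by `align_components()`, which exhaustively
searches component assignments (K is small) to maximise the summed mean
ancestry of the chosen reference populations. The default fit is
unsupervised — ancestral-role samples are not constrained to pure
ancestry — with `fixed_Q` available to pin known ancestral rows to unit
vectors.

## Weir–Cockerham F_ST

Multi-allelic loci are handled by per-allele indicator decomposition:
each allele is scored as presence/absence, the 1984 variance components
*a*, *b*, *c* are computed per locus and allele (heterozygosity = the
two haploid copies differ in carrying that allele), and
θ = Σa / Σ(a+b+c) over all loci and alleles (ratio of sums, the
Arlequin-comparable estimator). Individuals missing a locus are
excluded locus-wise; loci with fewer than two genotyped individuals in
either population are skipped; monomorphic loci contribute zero to both
sums. Small negative estimates are a normal property of the estimator
and are not truncated. Fixed-difference populations give θ = 1 exactly;
the estimate is verified against an independently coded brute-force
evaluation in the tests.

## Ancestry-informative CNVRs

The published binning criteria for ancestry informativeness live in
supplementary material that is not available; `classify_aic()`
implements a documented reconstruction with both thresholds exposed:
with `f_og`, `f_ind`, `f_afr` the carrier frequencies in the admixed
group, the Indian ancestor and the (mean- or max-summarised) African
ancestors, a CNVR is `unique` if `f_og >= rare` while both ancestors
are below `rare` (default 0.05, the same floor used for CNVR
construction); otherwise `indian_close` / `african_close` when the
frequency distance to one ancestor is below `delta` (default 0.2) and
to the other is not; `unassigned` otherwise. Gain–loss CNVRs are
excluded as ambiguous; deletion CNVRs are scored on deletion
frequencies and duplication CNVRs on duplication frequencies.
`og_specific_cnvrs()` implements the absence-based notion separately:
regions called in the target population and in no designated ancestral
population (and, for the strictly private subset, in no other
population at all).

## Enrichment

Genes are reduced to their longest transcript (ties: smaller start,
then transcript id) and mapped to CNVRs by any-base overlap. Gene-set
over-representation uses the exact hypergeometric upper tail
`P(X >= k)` with Bonferroni correction, by default within each set
category separately (matching per-category reporting conventions), with
a global option. The background universe is the full annotation table:
multi-resource backgrounds of web enrichment services are not
reproducible, so externally published enrichment p-values cannot be
compared directly and are not targets of this package.

## The synthetic-data generator

`simulate_cnv_study()` emulates the study design the package is
organised around: ancestral populations differentiated under a
Balding–Nichols model (per locus, base frequency p ~ U(0.05, 0.95);
component frequency ~ Beta(p(1−θ)/θ, (1−p)(1−θ)/θ)), and an admixed
population whose individuals draw each allele copy's component from a
per-individual Dirichlet ancestry vector. Deletion loci contribute
haploid copy 0 against reference 1; duplication loci contribute haploid
copy 2 — so diploid states stay in the 0–4 alphabet. Segments are
emitted per non-normal state over the true locus interval, with probe
counts, gaps, LODs and confidences drawn to pass the default filters;
decoy segments violating exactly one filter each are added at
configurable rates and labelled only in the truth object.

Defaults chosen once as the study conditions: two components at
θ = 0.2 (the magnitude of differentiation seen between continental
panels), 30 + 30 ancestral + 40 admixed samples, 500 loci, admixed
Dirichlet α = (4.13, 5.87) so mean ancestry mirrors a majority-African
admixed group (58.7 % African), deletion:duplication locus ratio 7:1
(the deletion excess typical of SNP-array CNV calls), 2 kb mean probe
spacing, locus sizes 10–100 kb. Loci are placed non-overlapping with at
least one probe-spacing separation, so CNVR ground truth is
unambiguous. One global seed fans out to per-step seeds through a
stage-name hash, making each step independently reproducible and full
runs byte-identical.

What the generator does **not** emulate: linkage disequilibrium between
loci, overlapping or nested CNV loci, probe-intensity noise, batch
effects, and caller-specific breakpoint uncertainty. Passing the
recovery tests therefore shows the estimators are correct *under the
model's assumptions* — independent loci, known segment boundaries,
well-calibrated filters — not that they are robust to the artefacts of
a real array experiment.

## Problem sizes used by the test suite

The packaged tests run the full-scale logic at reduced size, chosen so
each check remains decisive: CNVR reconstruction on 200 noise-free loci
× 60 samples; F_ST recovery at 25 samples/population × 500 loci for
θ ∈ {0.05, 0.16, 0.3} (tolerance ±0.03); EM ancestry recovery of
Q = (0.6, 0.4) with 40 admixed + 2 × 30 ancestral individuals × 1,000
loci (tolerance ±0.05); forests of 200–5,000 trees; hypergeometric
enumeration exhaustive up to N = 12 and a 1,000-replicate null
calibration. These sizes are the package's own desk-scale choices; all
thresholds were fixed by the study conditions above, not by the
observed test outcomes.

## Known limitations

* CNV calling itself (from intensities) is out of scope; the pipeline
  starts at segment calls.
* The biallelic recoding discards allelic-configuration ambiguity at
  CN = 2 and CN = 4 by convention.
* EM gives point estimates only — no credible intervals, no
  correlated-frequency prior, no K-selection heuristic.
* The AIC binning rule is a reconstruction; its thresholds (`delta`,
  `rare`) should be treated as analysis parameters, not constants.
* With strongly non-Euclidean proximity matrices, low-dimensional MDS
  captures a modest share of the positive eigenvalue mass; the reported
  `positive_mass` should be checked before interpreting distances.
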