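---
title: "Methods: summary-data MR, colocalization and perturbation overlap for lipidomic exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-data MR, colocalization and perturbation overlap for lipidomic exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmr)
```

# Scope

`lipidmr` implements an inference stack for asking whether circulating lipid
species causally influence a disease outcome, using only GWAS summary
statistics, a genotype reference panel, a cell-perturbation lipidomics
experiment and a cohort table.  The stack has five statistical layers:

1. **Two-sample summary-data MR** with correlated instruments: per-instrument
   Wald ratios combined by generalized least squares (GSMR-style), HEIDI
   outlier filtering for pleiotropic instruments, and IVW / MR-Egger
   sensitivity estimators.
2. **Bayesian colocalization** per region via Wakefield approximate Bayes
   factors, with region construction around exposure index SNPs, interval
   merging, and 95% credible sets.
3. **Lipid nomenclature**: a deterministic grammar for species names
   (`PC(16:0/20:4)`, `SM 40:2;O2`, `PC(O-16:0/20:3)`), cross-panel mapping,
   and class enrichment by Fisher's exact test.
4. **Perturbation analysis**: differential lipid abundance with a batch
   covariate, a cortisol-reversal summary, and a within-batch permutation
   overlap test against the MR hit list.
5. **Cohort association**: outlier trimming, covariate residualization,
   Pearson correlation, and instrument-based polygenic scoring.

Every layer is exercisable on synthetic data with known ground truth; the
generators are first-class, tested code.

# The MR model

For instrument $j$ let $\hat b_{zx,j}$ (s.e. $s_{x,j}$) be its marginal
effect on the exposure and $\hat b_{zy,j}$ (s.e. $s_{y,j}$) its marginal
effect on the outcome (log-odds scale for case–control outcomes).  Under the
instrumental-variable assumptions each Wald ratio
$\hat\beta_j = \hat b_{zy,j} / \hat b_{zx,j}$ estimates the causal effect
$b_{xy}$ (log-odds of outcome per 1 SD of exposure).  Its delta-method
variance is

$$ v_j = \frac{\hat b_{zy,j}^2}{\hat b_{zx,j}^2}\left(
   \frac{s_{x,j}^2}{\hat b_{zx,j}^2} + \frac{s_{y,j}^2}{\hat b_{zy,j}^2}
   \right), $$

with the continuity limit $v_j = s_{y,j}^2/\hat b_{zx,j}^2$ at
$\hat b_{zy,j} = 0$ so the weight never degenerates.

## Instrument selection

Instruments are selected by: (i) harmonizing exposure and outcome alleles
(strand flips renamed; effect/other swaps negate the outcome beta and map
eaf to 1−eaf; palindromic A/T and C/G variants dropped unconditionally
because strand and swap are indistinguishable); (ii) greedy p-value-ordered
LD clumping at $r^2 < 0.1$ within a 10 Mb window, at the relaxed association
threshold $p < 10^{-6}$; (iii) requiring at least 10 instruments (3 in
relaxed mode).  Ties in p are broken by position then variant id so results
are deterministic.  Window semantics are pairwise distance
$|pos_i - pos_j| \le w$; the clumping p-values come from the exposure GWAS
only (exposure-driven instrument selection).

## HEIDI outlier filtering

Pleiotropic instruments have ratios inconsistent with the rest.  Each
instrument's ratio is compared to a reference by
$z_j = (\hat\beta_j - \hat\beta_{ref}) / \sqrt{v_j + v_{ref} -
2 r_{j,ref}\sqrt{v_j v_{ref}}}$; instruments with two-sided $p < 0.01$ are
removed, and the filter iterates (reference recomputed) until no removal, at
most 10 rounds, never below 2 survivors.

*Reference choice.* The reference is the instrument whose ratio is closest
to the inverse-variance-weighted **median** ratio (ties by exposure p).  The
alternative — the instrument with the smallest exposure p — fails
catastrophically when that instrument is itself pleiotropic: every clean
instrument then deviates from a biased reference and is removed en masse.
The median anchor is robust to any contamination below 50%, in the spirit
of the weighted-median MR estimator, while preserving the pairwise-z test
and its threshold.

## GLS combination and weighting

Surviving ratios are combined by generalized least squares with
$V_{jk} = r^{*}_{jk}\sqrt{v_j v_k}$, where $r^{*}_{jk}$ is the reference-panel
LD correlation aligned to each instrument's exposure-increasing allele
($r^{*}_{jk} = r_{jk}\,\mathrm{sign}(\hat b_{zx,j})\,
\mathrm{sign}(\hat b_{zx,k})$).  This alignment is what makes the fit exactly
invariant under simultaneous allele flips of any instrument in both GWAS
tables — a property the test suite asserts.

The GLS (and IVW) weights are **iterated modified second-order weights**:
after a first pass with the delta-method variances, the variance is
re-evaluated at the predicted outcome effect,

$$ v_j(b) = b^2 \frac{s_{x,j}^2}{\hat b_{zx,j}^2} +
            \frac{s_{y,j}^2}{\hat b_{zx,j}^2}, $$

and the estimate is re-fit (three updates).  Observed-value weights are
correlated with the estimation noise in $\hat b_{zy,j}$ — instruments whose
outcome effect is under-estimated get spuriously small variances and excess
weight — which attenuates $b_{xy}$ towards zero and erodes interval
coverage.  Evaluating the variance at $b\,\hat b_{zx,j}$ removes that
coupling (cf. modified second-order weights in the MR literature on exact
Q statistics).  The delta-method variances are retained unchanged inside
HEIDI, where only ratio *differences* are tested.  Because `ivw_fit()`
shares this weighting core with a diagonal $V$, GSMR with identity LD
reproduces fixed-effect IVW to numerical precision.

If the instrument correlation matrix is ill-conditioned (condition number
above $10^{10}$), the later member of the most-correlated pair is dropped
with a warning — the same intent as LD pruning, keeping the pipeline total.
The conditioning test uses the correlation matrix, not $V$, so
heterogeneous variances alone never trigger it.

## Sensitivity estimators

`ivw_fit()` reports Cochran's Q at the final weights, from which a
multiplicative random-effects standard error can be derived by the caller
(fixed-effect is the default).  `egger_fit()` orients instruments to
non-negative exposure effects and regresses $\hat b_{zy}$ on $\hat b_{zx}$
with an intercept by weighted least squares, weights $1/s_{y}^2$ treated as
*known* inverse variances (no residual-variance rescaling).  The intercept
estimates directional pleiotropy; with known weights its z-test is exactly
normal under the generative model, which is what the prescribed normal
p-value assumes — an estimated-sigma combined with a normal reference would
be anti-conservative at typical instrument counts.

## Panel runs, FDR, masking, concordance

`run_panel()` fits every testable exposure, applies Benjamini–Hochberg FDR
across the exposures actually tested (skipped exposures do not enter $m$),
and attaches IVW/Egger sensitivity fits on each exposure's GSMR-surviving
instruments.  `mask_locus()` removes variants in a 1-based inclusive
interval (as in sensitivity reruns excluding the chromosome-11 fatty-acid
desaturase cluster, chr11:61,067,099–62,134,286) before re-selection.
`concordance()` joins two panel results on exposure name and reports the
sign-agreement fraction and Pearson correlation of estimates.

# Colocalization

For one region and two traits, per-variant Wakefield log approximate Bayes
factors are $\tfrac12[\log(1-r) + r z^2]$ with $r = W/(W + se^2)$.  Prior
effect variances default to $W = 0.15^2$ for quantitative and $0.2^2$ for
binary traits; per-variant priors are $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$.  The five hypothesis masses (no signal, trait-1 only,
trait-2 only, two distinct variants, one shared variant) are accumulated
entirely in log space; the H3 mass $S_1 S_2 - S_{12}$ is computed by a
log-space complement and clamped at zero with a warning if cancellation
makes it negative.  Per-variant H4 posteriors give the 95% credible set
(descending posteriors, ties by ascending position, minimal prefix reaching
0.95) and candidate variants (posterior > 0.01).  Evidence tiers are
PPH4 > 0.8 (strong) and > 0.5 (suggestive).

Regions are built from exposure signals only: index SNPs clumped at
$r^2 < 0.1$ within 500 kb, each giving a ±250 kb region clipped at 1.
Merging performs interval union over the integer line: overlapping,
touching, or integer-adjacent intervals merge (no uncovered base between
them), and each merged locus records its members and best member tier.
Variants present in only one trait's table are dropped (intersection
analysis) and counted.

# Lipid nomenclature and enrichment

The grammar accepts `CLASS(chains)`, `CLASS chains`, ether prefixes `O-`
and `P-`, `;`-separated modifiers (e.g. hydroxylation `;O2`), and class
synonyms (DG≡DAG, TG≡TAG).  A single chain at class level is a sum
composition (total carbons:double bonds) for multi-chain classes.  Mapping
matches on (class, ether prefix, chain multiset, modifiers); chain order is
ignored because sn-position is not comparable across panels.
Sum-composition matching (a resolved species matches a sum species whose
totals agree) is opt-in per call and flagged in the output, because such
matches are ambiguous; one-to-many matches are reported, never silently
resolved.  Class enrichment uses `stats::fisher.test` on the
hit-by-class 2×2 table; the test suite cross-checks it against a full
hypergeometric enumeration oracle.

# Perturbation analysis

Features missing in more than 50% of samples (strictly) are dropped;
remaining missing values are imputed as zero (below detection).  Analysis
is on the absolute quantification (pmol) scale without further
transformation; log2 fold-changes of condition means are attached for
reporting only.  Each feature is fit by least squares on condition
indicators plus batch indicators; contrasts are condition differences with
known-design standard errors and t-based p-values, BH-corrected within each
contrast.  Any rank deficiency of the condition+batch design is a
confounded design and raises an error naming the aliased columns.

The overlap permutation test shuffles condition labels independently
**within each batch** (preserving per-batch condition multisets — asserted
per repeat in the tests), refits all features, ranks by contrast p
ascending (ties: larger |estimate|, then feature name), keeps the top N
(N = the observed count of q < 0.05 features), maps them to the GWAS panel
naming (sum-composition matching enabled) and counts hits.  The empirical
p-value is `count/n_perm` exactly; `add_one = TRUE` gives the conservative
`(count+1)/(n_perm+1)`.  Because overlaps are small integers, ties make the
test mildly conservative — visible in the calibration check as a mean
empirical p slightly above 0.5.

# Cohort association

Lipid values are trimmed once at mean ± 5 sd computed on the input (strict
outside, no re-iteration — a second pass removes nothing on clean data,
which the tests assert empirically), log-transformed (natural log; the
correlation is base-invariant after linear adjustment) and residualized on
age, sex, center, batch and BMI; symptom scores are residualized on age,
sex and wave.  The Pearson correlation of the residuals is tested by the t
transform on n−2 df.  Aliased covariate columns are dropped with a warning.
The polygenic score is the dosage-weighted sum of effect-allele-aligned
instrument betas; mediation testing is deliberately out of scope.
Symptom scores are not trimmed, only lipid values.

# Synthetic data: what it emulates and what it does not

Summary statistics are simulated **directly at the marginal level** in
standardized-genotype space: exposure effects are planted one per LD block
with equal explained variance summing to $h^2$; marginal effects are
$R\beta$ with $R$ the block LD; estimation noise is drawn with the same
within-block correlation at standard errors $1/\sqrt{2n\,\mathrm{maf}
(1-\mathrm{maf})}$.  The reference panel doubles as the population, so the
LD used by the estimators is the LD that generated the data.  This gives
desk-scale speed with exact control of the LD-induced correlation of
estimation noise, at the price of not modeling reference-panel error,
case–control ascertainment (outcomes are simulated on the continuous
log-odds scale), winner's curse beyond the selection actually performed,
or real human LD maps and population structure.  Passing tests therefore
demonstrate internal statistical correctness under the stated model, not
robustness to those real-data complications.

Default study conditions (chosen once, used by the tests and the
acceptance script):

* **LD panel**: 30 blocks × 10 variants, AR-1 latent correlation 0.8,
  2,000 diploid individuals, MAF ~ U(0.1, 0.5).  Dosages are two
  independently thresholded latent-Gaussian haplotypes.
* **GWAS pair**: 30 causal variants, $h^2 = 0.05$ (per-instrument
  $z \approx 9$, comfortably past the $10^{-6}$ threshold so selection
  effects are negligible — a realistic strength for lipid-species GWAS of
  a few thousand samples scaled to $n_{exposure} = 50{,}000$), outcome at
  $n_{outcome} = 200{,}000$ equivalents, causal effects
  $b_{xy} \in \{-0.2, 0, 0.1\}$.
* **Pleiotropy (HEIDI efficacy)**: 20% of instruments carry *directional*
  direct effects of fixed per-allele magnitude 0.06 (≈0.8 SD shift in the
  Wald ratio), signed consistently on the exposure-increasing allele.
  Directional pleiotropy is the canonical threat an outlier filter
  targets; randomly signed effects cancel in a third of replicates and
  make paired bias comparisons uninformative.
* **Colocalization regions**: 2 blocks × 50 variants, latent correlation
  0.95; causal z drawn from U(8, 12) for both traits; the distinct-variant
  case plants trait 2's causal variant in the other, LD-independent block.
* **PBMC experiment**: 5 conditions (control, cortisol, cortisol + extract
  at 3 doses) × 4 batches × 1 sample = 20 samples; 500 features; 132
  features downregulated by cortisol, 75 of them reversed at the top
  extract dose; mean absolute effect 4 pmol against residual sd 1 and
  per-feature batch offsets of sd 2; log-normal baselines.  Missingness is
  injected with an exact per-feature count `round(frac_missing × n)` on a
  random non-planted feature subset, so the >50% filter rule is exercised
  deterministically.
* **Planted overlap**: 200 features, 40 cortisol-down features which *are*
  the MR hit set.  Because all planted features share one label pattern,
  their permuted test statistics co-move; requiring the full planted set
  makes the observed overlap exceed anything label shuffling can assemble.
* **Cohort**: n = 970, planted partial correlation −0.08 between the
  lipid's non-covariate component and the latent symptom scale, polygenic
  heritability $h^2 = 0.02$ (so the score–lipid correlation is
  $\approx \sqrt{0.02} = 0.14$); symptom scores are a rounded non-negative
  transform of the latent scale, which attenuates the correlation by a few
  percent — well inside the ±0.06 sampling band at this n.

Problem sizes in the test suite (e.g. 200–500 replicates per calibration,
200 inner permutations in the calibration loop, 80–200 features in the
permutation matrices) were chosen as the smallest sizes at which the
binomial/sampling error bands stated by each check are meaningful.

# Numerical choices

* Log-sum-exp throughout the colocalization sums; H3 via log-space
  complement with clamping.
* GLS via Cholesky of $V$; correlation-matrix conditioning guard at
  $10^{10}$ with deterministic later-member dropping.
* Recomputed p-values (when a table lacks them) are clamped at the
  smallest positive double so extreme z-scores cannot underflow out of
  (0, 1]; supplied p-values are trusted.
* Deterministic tie-breaks everywhere: clumping and pruning (p, position,
  id), credible sets (posterior, position), permutation top-N (p,
  |estimate|, name).
* Every generator takes an explicit seed, restores the caller's RNG state,
  and is bit-reproducible for identical (config, seed); the pipeline
  manifest records seeds and stage counts, and the test suite checks
  output-file hashes across reruns.

# Known limitations

* Only exposure→outcome MR is implemented; no bi-directional analysis,
  no MR-PRESSO/weighted-median/mode estimators, no multivariable MR, no
  Steiger filtering.
* The HEIDI variant is the pairwise-z formulation described above; other
  formulations (multi-SNP heterogeneity) exist.
* Colocalization assumes at most one causal variant per trait per region
  (single-signal ABF); no SuSiE-style multi-signal analysis or conditional
  analysis.
* No genome-build liftover, rsID resolution, VCF-encoded summary
  statistics, or allele-frequency consistency filtering between panels.
* Sum-composition lipid matches are inherently ambiguous and only reported
  when explicitly enabled; fatty-acyl isomer annotations (n-3 vs n-6) are
  carried as opaque suffixes, not resolved.
* The permutation overlap test's empirical p is discrete; with few
  attainable overlap values it is conservative.
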