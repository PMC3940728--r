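---
title: "Methods: heritability, quasi-Poisson association and permutation-based significance for longitudinal count phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heritability, quasi-Poisson association and permutation-based significance for longitudinal count phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`countgwas` re-implements, as a tested and reusable pipeline, a
developmental genetic analysis of bounded, overdispersed count
phenotypes — the kind produced by brief behavioural screening
instruments (integer scores 0–24) administered at several ages in a
birth cohort. The pipeline estimates SNP heritability per age and
genetic correlations across ages by GREML, scans the most heritable
ages genome-wide with per-SNP quasi-Poisson regression, applies
genomic control, reduces the panel to independent index variants by LD
clumping, and assesses familywise significance and candidate-gene
co-location with a jointly permuted multi-phenotype null. Because
cohort genotype–phenotype data of this kind are access-restricted, the
package ships a synthetic-data module that reproduces the statistical
structure every downstream stage assumes, so the whole pipeline is
testable without any external download.

## The synthetic cohort

### Genotypes

Genotypes are simulated per LD block from a thresholded latent
Gaussian. Within a block of `block_size` SNPs, each haplotype draws a
latent vector with exchangeable correlation `within_block_rho` (one
shared factor plus independent noise); each coordinate is thresholded
at the normal quantile of that SNP's allele frequency, and two
haplotypes are summed to a dosage in {0, 1, 2}. MAFs are uniform on
`maf_range`; positions are uniform on the chromosome. This model was
chosen over haplotype-copying simulators because the pipeline needs
*tunable, analytically checkable* r² — the adjacent-SNP dosage r²
implied by a given `within_block_rho` can be computed independently by
direct Monte-Carlo integration of the thresholded bivariate normal,
which is exactly how the generator is tested. It does not attempt
realistic human haplotype structure, recombination hotspots, or allele
frequency spectra; consequences for interpretation are discussed under
*Limitations*.

### Count phenotypes

Scores at age $t$ follow a mixed Poisson model on the log scale:

$$ y_{it} \sim \mathrm{Poisson}\!\left(u_{it}\,
   e^{\beta_0 + \mathbf{x}_i'\boldsymbol\gamma + g_{it} + e_{it}}\right),
   \qquad u_{it} \sim \Gamma(\theta, \theta), $$

i.e. marginally negative binomial with size $\theta$ given the latent
terms. The genetic values $g_{it}$ are built from `n_causal` causal
SNPs shared across ages; per-age effect vectors are correlated across
ages through a matrix square root of the target genetic correlation
matrix $R_g$, and residual liabilities $e_{it}$ are multivariate
normal with correlation $R_e$. Per age, the realized (not merely
expected) variances are rescaled so that on the latent log scale

$$ \frac{\operatorname{var}(g_t)}{\operatorname{var}(g_t) +
   \operatorname{var}(e_t)} = h^2_t, \qquad
   \operatorname{var}(g_t) + \operatorname{var}(e_t) =
   \texttt{latent\_sd}^2 . $$

The gamma frailty was preferred over a lognormal frailty because the
negative-binomial margin has closed-form moments, which the unit tests
exploit (`theta -> Inf` must give variance/mean → 1). Clipping at the
instrument maximum of 24 is **off by default**: truncation distorts
the count model that the downstream calibration tests assume. It is
enabled (`clip_to_range = TRUE`) when the goal is to emulate the
bounded instrument itself, and the distributional checks against the
target score summaries are run in that mode.

### Default calibration

The defaults (`baseline_log_mean = -0.45`, `latent_sd = 1.5`,
`dispersion_theta = 30`, per-age $h^2$ = 0.24/0.16/0.08/0.45 at ages
8/11/14/17, adjacent-age $r_g$ 0.82–0.95 decaying to 0.51 across the
full span, $r_e$ 0.35–0.56) were moment-tuned once, jointly, so that a
clipped run at $n = 5000$ reproduces the target phenotype summary:
median score 1, SD ≈ 3.7–4.1, range 0–24. Most marginal
overdispersion then comes from the lognormal latent term rather than
the frailty, hence the large default $\theta$; the frailty models
occasion-specific noise.

One structural attenuation is worth understanding because it shapes
what the tests can and cannot show:

* **Correlation attenuation.** $R_g$ and $R_e$ act on the latent log
  scale. Poisson sampling noise and the frailty are independent across
  ages, so observed-scale cross-age Spearman correlations are lower
  than the latent correlations — about 0.33–0.37 for adjacent ages
  under the defaults, at the low end of the 0.38–0.58 range the real
  instrument shows. Raising them further would require latent
  correlations above 1; the band tested is [0.3, 0.7].
* **Heritability attenuation.** For the same reason, the heritability
  of the *observed* (rank-transformed) counts is roughly half the
  configured latent $h^2$. The per-age $h^2$ ranking is preserved, so
  pipeline stages that rank ages by estimated heritability behave
  correctly, but parameter-recovery validation of the REML machinery
  is run on Gaussian liabilities generated by `simulate_liabilities()`,
  which realizes the variance components exactly on the scale the
  model assumes. Both generators share the causal-architecture code.

## GREML heritability and genetic correlations

The genetic relationship matrix is the standard allele-frequency
standardized form,

$$ A_{jk} = \frac{1}{m_{jk}} \sum_i
   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)}, $$

with per-pair marker counts $m_{jk}$ over SNPs non-missing in both
individuals, and monomorphic SNPs excluded. Phenotypes enter REML as
covariate-adjusted, rank-based inverse-normal transformed residuals:
least-squares residuals on age, sex and two ancestry covariates,
ranked with ties averaged, mapped through the normal quantile of the
Blom plotting position $(r - 3/8)/(n + 1/4)$. The Blom offset is the
most common default; it is not prescribed by the analysis being
reproduced and the transform is a separate function, so it is easy to
swap.

`reml_univariate()` fits $y = \mu + g + e$,
$\operatorname{cov}(g) = A\sigma^2_g$,
$\operatorname{cov}(e) = I\sigma^2_e$, by average-information REML.
With a single GRM, $V = \sigma^2_g A + \sigma^2_e I$ is diagonal after
one symmetric eigendecomposition of $A$, so every iteration is $O(n)$;
`grm_precompute()` caches the decomposition when many traits are
analysed against one GRM. The first step is an EM update (as in
standard GREML practice), subsequent steps are AI with EM fallback on
a singular AI matrix, and every step is halved until the restricted
log-likelihood is non-decreasing and $V$ stays positive definite.
Convergence requires both $|\Delta \ell| < 10^{-6}$ and a maximum
component change below $10^{-6}$; non-convergence is an error carrying
the iteration trajectory. Variance components are constrained
non-negative by default (floored at $10^{-8}$ of the phenotypic
variance). A GRM with numerically no eigenvalue spread (e.g. the
identity) cannot separate the components; the fit is then flagged
`identifiable = FALSE` with $\sigma^2_g$ pinned at the boundary rather
than returning an arbitrary ridge point.

Standard errors come from the inverse AI matrix with the delta method
for $h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$. The test of
$\sigma^2_g = 0$ is a likelihood ratio against the closed-form null
fit, referenced by default to $\chi^2_1$ — matching how such analyses
conventionally report the LRT — although the boundary-correct
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture (which halves the
p-value) is available via `lrt_mixture = TRUE`.

`reml_bivariate()` fits the two-trait model with genetic and residual
covariances; after the same rotation, $V$ is similar to $n$
independent 2×2 blocks, so the six-parameter AI iteration stays
$O(n)$ per step. It is initialized from the univariate fits and a
proportional split of the phenotypic covariance. If the AI iteration
stalls, the restricted likelihood is maximized directly with L-BFGS-B
— a pragmatic fallback chosen over a full bivariate EM because the EM
offers no constraint handling advantage for covariance parameters,
while the AI matrix at the optimum still provides the SEs (delta
method for $r_g = \sigma_{g12}/\sqrt{\sigma^2_{g1}\sigma^2_{g2}}$ and
$r_e$). Covariances are kept inside the correlation bound during
updates. When either trait's genetic variance estimate falls below 1%
of its phenotypic variance, $r_g$ is undefined for practical purposes
and is returned as `NA` with a warning rather than a number. The fit
uses individuals observed for both traits; partially overlapping
samples are not supported (the synthetic cohort has complete overlap).

## Per-SNP association and genomic control

Counts are analysed untransformed — so effects are directly
interpretable as changes in log counts per effect allele — by
quasi-Poisson regression: a Poisson log-link IRLS fit with dispersion
$\hat\varphi = X^2_{\mathrm{Pearson}}/(n - p)$ estimated afterwards
and SEs inflated by $\sqrt{\hat\varphi}$. The IRLS starts at
$\beta = 0$ except intercept $= \log(\bar y + 0.5)$, converges on a
relative deviance change of $10^{-8}$, and caps at 50 iterations. The
Wald statistic is referenced to the standard normal (not $t$): the
intended sample sizes are in the thousands. A perfect fit
($\hat\varphi = 0$) yields zero SEs; the Wald columns are then
reported `NA` — flagged non-inferential — rather than infinite. The
design per scan is intercept, age at measurement, sex, two ancestry
covariates, and allele dosage, with per-age listwise deletion (and
per-SNP deletion of missing dosages). The motivating property, which
the acceptance suite demonstrates, is that under an overdispersed null
($\varphi \approx 2$) naive Poisson inference is anti-conservative
while the quasi-Poisson type-I error stays at its nominal level.

Genomic control estimates
$\lambda_{GC} = \mathrm{median}(W^2)/0.4549364$ (the $\chi^2_1$
median) per scan and divides every squared Wald statistic by
$\max(\lambda, 1)$. The floor at 1 — never *inflating* significance
when a scan is deflated — is the common conservative default; the
analysis being reproduced did not need to state its convention since
its observed $\lambda \ge 1.03$, and the floor can be disabled.
Because the correction is a single constant per scan, p-value ordering
is preserved exactly.

## LD clumping to index variants

"Pruning to independent index variants" is implemented as
p-value-ordered greedy clumping (PLINK-clump-like): repeatedly take
the smallest-p unassigned SNP as an index and assign to it every
unassigned SNP within ±`window_kb` (default 500 kb) whose dosage r²
with it exceeds `r2_max` (default 0.3). Ties in p are broken by
smaller genomic coordinate, then SNP ID, making the output invariant
to input row order. Every SNP ends up an index or assigned to exactly
one index (a partition), a property the tests check against an
independent brute-force re-execution of the definition on random
instances. r² is the squared Pearson correlation of dosage vectors
(composite LD) — the data are dosages, not phased haplotypes. Clumped
regions span the member SNP positions only (1-based inclusive); gene
overlap converts the span to 0-based half-open and requires at least
one shared base against BED-convention gene intervals. The index set
is selected once, on the most strongly associated observed scan, and
reused across permutations; regions are built from all QC-passing
SNPs while permutation scans run on index SNPs only.

## The permutation null and co-location

To control familywise error across correlated repeated-measure scans,
each permutation relabels whole per-individual phenotype records —
scores *and* ages-at-measurement at every time-point travel together —
against the genotype-linked record (genotypes, sex, ancestry
covariates). Sex and ancestry stay with the genotype because they are
genotype-linked; a `scores_only` mode is available. Per-age score
multisets and within-individual cross-age structure are preserved
exactly; only the genotype–phenotype pairing is broken. For each
permutation the index SNPs are re-scanned at every configured age with
the full quasi-Poisson model (exact, rather than a residualized
score-test shortcut), genomic control is re-estimated within each
permuted scan — the thresholds are GC-corrected p-values, so permuted
statistics must be on the same scale — and the minimum GC-corrected
p-value over all index SNPs and scans is recorded.

For thresholds $\tau$: `k_exceed` counts permutations whose minimum is
$\le \tau$; `k_coloc` counts those where additionally the clumped
region of at least one passing SNP overlaps a candidate gene. The
primary co-location probability is the **joint** event `k_coloc / S`,
not the probability conditional on exceedance — the reading consistent
with a co-location p-value smaller than the exceedance p-value; the
conditional ratio is reported alongside. Empirical p-values are
`k / S` as conventionally printed, with the `(k+1)/(S+1)` small-sample
versions also reported; SEs are binomial,
$\sqrt{\hat p (1 - \hat p)/S}$. Per-permutation sub-seeds are derived
from the master seed by a counter scheme, so chunked execution (for
long runs) reproduces a single run bit-for-bit after
`combine_permutation_results()`.

## Quality control and file formats

SNP-level QC removes markers with MAF < 1%, call rate < 95%,
Hardy–Weinberg equilibrium $P < 5\times10^{-7}$ (one-degree-of-freedom
chi-square goodness of fit on hard calls; monomorphic SNPs return
$p = 1$), or imputation $R^2 \le 0.8$. Thresholds phrased as "<" are
strict removals, so boundary SNPs are retained. The chi-square rather
than exact HWE test is used because at the $5\times10^{-7}$ regime the
two agree in ordering deep in the tail; the test function is separate
and swappable. The filters are a conjunction (order-independent); the
per-SNP report gives the first failed criterion in the fixed
precedence maf → call_rate → hwe → impute_r2. Sample-level QC (sex
checks, heterozygosity, relatedness) is out of scope: it concerns real
cohort data the package never touches.

I/O covers PLINK .bed/.bim/.fam (v1.0 SNP-major, two-bit codes,
checked against a hand-decoded fixture), a documented tab-separated
dosage dialect ("NA" missing, 6 significant digits), wide phenotype
TSVs, 4+-column BED gene sets (0-based half-open), and the GCTA
binary GRM layout (float32 lower triangle + id file + per-pair N).

## Problem sizes used in validation

The validation suites use sizes at which the statistical properties
are well-resolved while remaining desk-scale: GREML recovery at
$n = 2000$, $m = 5000$ (one panel, replicate phenotype draws — the
standard simulation design for estimator validation); quasi-Poisson
calibration over 1000 null SNPs at $n = 2000$; genomic control on a
10,000-SNP null scan; clumping against brute force on 200 random
20-SNP instances; the permutation machinery on a 500-individual,
~200-index-SNP, two-age null genome with $S = 200$; and the
end-to-end pipeline at $n = 500$, $m = 800$, $S = 40$, run twice to
confirm byte-identical reports.

The scan-calibration suites simulate the *bounded* instrument
(`clip_to_range = TRUE`). This is not incidental: unbounded
lognormal-latent counts occasionally produce one extreme score that
enters every SNP's regression as a shared leverage point and inflates
$\lambda_{GC}$ scan-wide (values up to ~1.5 were observed in
development), whereas the clipped scores the instrument actually
yields give $\lambda_{GC}$ stably within a few percent of 1 — the
same mild-inflation regime real scans of this type report.

## Known limitations

* The LD model is exchangeable within blocks and independent across
  blocks; there is no recombination map, so clumped-region widths are
  not comparable to real genomic regions.
* The count model is a stand-in: the score-generating distribution of
  real screening instruments is not published, and the
  negative-binomial/lognormal mixture is chosen for closed-form
  moments, not psychometric fidelity (no item-level structure, no
  informative missingness).
* Latent-scale correlation and heritability targets attenuate on the
  observed scale (see above); passing tests demonstrate internal
  consistency of the estimators, not that real-data estimates at
  these magnitudes would be recovered from counts.
* The cohort is unrelated by construction; relatedness pruning,
  multi-component GREML and mixed-model association are out of scope.
* Bivariate REML requires complete overlap of the two traits'
  samples.
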