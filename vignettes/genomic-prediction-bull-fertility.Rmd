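---
title: "Kernel-based genomic prediction of bull fertility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-based genomic prediction of bull fertility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sirefert)
```

## The problem

Sire conception rate (SCR) is a service-sire fertility phenotype: each bull's
record is a percent deviation in conception rate from a population mean fixed
at zero, so a bull at −4 sires 4% fewer conceptions than average. Records are
computed upstream from cow field data and arrive with very different
precisions — a bull with 8,000 breedings is measured far more reliably than
one with 50. SCR only becomes available once a bull is already on the market,
which is exactly too late for selection decisions; predicting it from SNP
genotypes available at birth is therefore the practical goal.

Two features make this trait awkward for off-the-shelf genomic prediction:

* the record-level precision varies by two orders of magnitude across bulls,
  so residuals are strongly heteroscedastic;
* a handful of loci with large *recessive* effects segregate in some breeds
  (recessive-allele frequencies near 0.3), and purely additive whole-genome
  models capture them poorly.

`sirefert` implements the whole analysis chain for this setting: genotype QC,
kernel construction, a Bayesian kernel regression with reliability weights
and recessive-indicator fixed effects, repeated cross-validation, and a
single-marker recessive scan — plus a synthetic-data generator so the entire
chain is testable without proprietary cohort data.

## The model

The core model is the kernel regression

$$\mathbf{y} = \mathbf{X b} + \mathbf{K\boldsymbol\alpha} + \mathbf{e},$$

with $\mathbf{y}$ the SCR records, $\mathbf{b}$ fixed effects (a general
intercept, plus optional recessive-homozygote indicators for known major
markers), and $\mathbf{K}$ an $n \times n$ kernel over individuals. The RKHS
coefficients solve the penalized problem
$\ell(\boldsymbol\alpha \mid \lambda) =
(\mathbf{y}-\mathbf{K}\boldsymbol\alpha)'(\mathbf{y}-\mathbf{K}\boldsymbol\alpha)
+ \lambda\,\boldsymbol\alpha'\mathbf{K}\boldsymbol\alpha$, which in the
Bayesian reading corresponds to
$\boldsymbol\alpha \sim N(\mathbf 0, \mathbf{K}^{-1}\sigma_g^2)$,
$\mathbf{e} \sim N(\mathbf 0, \mathbf{R}^{-1}\sigma_e^2)$ and
$\lambda = \sigma_e^2/\sigma_g^2$. $\mathbf{R} = \mathrm{diag}(r_i)$ holds
the record reliabilities, so record $i$ has residual variance
$\sigma_e^2 / r_i$: high-reliability records pull the fit harder. In terms of
the genetic values $\mathbf{g} = \mathbf{K}\boldsymbol\alpha$ this is the
familiar mixed model $\mathbf g \sim N(\mathbf 0, \mathbf K \sigma_g^2)$.

The kernel is the linear (additive genomic relationship) kernel
$\mathbf{K}_L = \mathbf{SS}'/p$, with $\mathbf S$ the centered and
standardized genotype matrix
($s_{ij} = (g_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$) and $p$ the SNP count. With
this kernel the model is GBLUP; we keep the RKHS formulation because it is
the form the variance components are sampled in.

Known major loci enter a second model variant as fixed covariates coded 0/1
for *carrying two copies of the recessive allele* — a deliberately
non-additive coding that lets a recessive subfertility effect be captured
directly instead of being diluted through the additive kernel.

## Sampling scheme and numerical choices

`rkhs_fit()` runs a Gibbs sampler over $(\mathbf b, \mathbf g, \sigma_g^2,
\sigma_e^2)$:

* **Spectral reparameterization.** The prior
  $\boldsymbol\alpha \sim N(\mathbf 0,\mathbf K^{-1}\sigma_g^2)$ notationally
  requires $\mathbf K^{-1}$, but a centered kernel is always singular (the
  row sums of $\mathbf S$ vanish, so $\mathbf K$ has a null eigenvalue). We
  therefore eigendecompose $\mathbf K = \mathbf U\,\mathrm{diag}(d)\,
  \mathbf U'$ once per fit, drop eigenvalues below $10^{-8}\,d_{\max}$, and
  sample the independent coordinates $\mathbf z$ of
  $\mathbf g = \mathbf U \mathbf z$, $z_j \sim N(0, d_j\sigma_g^2)$. The
  coordinates are updated single-site with an incrementally maintained
  residual (the update loop is compiled code); the fixed effects are drawn
  jointly from their multivariate-normal full conditional under a flat
  prior.
* **Variance components.** Scaled-inverse-chi-square full conditionals with
  prior degrees of freedom 5 for both components; "auto" prior scales put
  the prior mode at half the training phenotypic variance for each
  component, the convention of the Bayesian whole-genome regression software
  family this package follows. Defaults: 30,000 iterations, 5,000 burn-in,
  thinning 5 — all configurable through `rkhs_control()`.
* **Held-out individuals.** Records flagged `train = FALSE` (or with `NA`
  phenotypes) contribute no likelihood; their $g_i$ is still sampled through
  the kernel, which is how cross-validation folds and yet-to-be-phenotyped
  candidates are predicted.
* **Reproducibility.** One seeded R-level RNG drives the whole chain, with
  draws consumed in a fixed order, so a fit is bit-reproducible given
  `rkhs_control(seed = )`.
* **Oracle.** `blup_closed_form()` solves the same model deterministically
  from known variance components via
  $\hat{\mathbf b} = (\mathbf X'\mathbf V^{-1}\mathbf X)^{-1}
  \mathbf X'\mathbf V^{-1}\mathbf y$ and
  $\hat{\mathbf g} = \sigma_g^2\,\mathbf K_{\cdot,t}\mathbf V^{-1}
  (\mathbf y-\mathbf X\hat{\mathbf b})$ with
  $\mathbf V = \mathbf K_{tt}\sigma_g^2 + \mathrm{diag}(\sigma_e^2/r_i)$.
  The test suite holds the sampler to this oracle (genetic-value correlation
  above 0.999 with variances fixed at truth) and holds the oracle itself to
  a literal joint normal-equations solve.

## Quality control

`qc_filter()` applies the standard panel filters: individuals with call rate
below 95% are removed first, then — with frequencies recomputed on retained
animals — SNPs that are monomorphic, have minor allele frequency below 1%
(strictly; MAF exactly 0.01 is kept), or have call rate below 99%. The
individual-first order is the common practice and makes SNP statistics
reflect the analyzed cohort; each SNP is attributed to the first rule it
violates so the report's removal lists are disjoint and sum to the total.
Remaining missing dosages are mean-imputed at standardization time
(standardized value exactly 0), the neutral choice for panels that arrive
essentially complete after upstream imputation.

Two open choices are worth stating explicitly:

* **Recessive allele identity.** For a designated major marker the package
  defaults to treating the cohort *minor* allele as recessive — deleterious
  recessives are typically rare — with an explicit per-SNP override
  (`recessive_allele =`) for loci whose recessive allele is known.
* **Majors in the kernel.** The major markers stay in the polygenic kernel
  as well as appearing as fixed effects; `exclude_majors_from_kernel = TRUE`
  removes them. Keeping them is the default because a two-SNP change in a
  dense panel is numerically negligible and avoids a special-cased kernel.

## Cross-validated evaluation

`cross_validate()` runs repeated $k$-fold cross-validation (default 5 folds,
10 repetitions) of the `"polygenic"` and `"polygenic_majors"` variants.
Design choices:

* One predictive correlation and one MSEP per repetition, computed over the
  pooled out-of-fold predictions — this yields exactly one point per
  repetition for boxplot-style summaries, rather than a per-fold average.
* Fold assignments are shared between variants within a repetition, so the
  comparison is paired.
* Metrics are unweighted by reliability by default (`weighted_metrics =`
  switches to reliability-weighted versions).
* If a training fold contains no recessive homozygote for a major marker,
  that indicator column is inestimable and is dropped for that fold with a
  message.
* Folds are unstratified uniform partitions; SCR has no grouping structure
  that would call for stratification.

## The recessive scan

`scan_recessive()` is a deliberately simplified single-marker scan: per SNP,
a weighted least-squares regression of the phenotype on the
recessive-homozygote indicator (reliabilities as weights), a t-based
two-sided p-value, and a Bonferroni threshold over the tested SNPs. SNPs
with fewer than 5 recessive homozygotes (configurable) are reported but
skipped, with the reason recorded. The scan does not adjust for polygenic
background or relatedness — it is the screening computation used to
(re)discover planted loci in synthetic data and to rank candidate recessive
regions, not a full mixed-model association study. Under the null its
type-I rate is calibrated (the suite checks 5% ± 2%), but on structured real
populations stratification could inflate it; a GRM-adjusted scan is out of
scope here.

## What the synthetic generator emulates — and what it does not

`simulate_population()` generates the data-generating structure the model
assumes:

* HWE genotypes with uniform allele frequencies on `maf_range`, spread
  round-robin over 29 autosomes;
* an infinitesimal polygenic value $u = S\beta$ with i.i.d. normal SNP
  effects, rescaled so $\mathrm{var}(u) = \sigma_g^2 = h^2\sigma_p^2$;
* planted recessive loci (defaults: two loci, recessive-allele frequencies
  0.29 and 0.31, effect −8 phenotype units each) that deviate *only*
  recessive homozygotes;
* breedings uniform on 50–8,110 mapped to reliabilities by
  $r = n/(n + k)$ with $k = 200$ — the functional form is a standard
  repeatability-style mapping chosen because it is monotone in breedings and
  bounded in (0, 1); $k = 200$ places typical reliabilities in the
  0.2–0.98 range actually spanned by such records;
* heteroscedastic residuals $e_i \sim N(0, \sigma_e^2/r_i)$, the literal
  consequence of $\mathbf e \sim N(\mathbf 0,\mathbf R^{-1}\sigma_e^2)$;
* centering so the mean deviation is exactly 0, matching the SCR scale; the
  default phenotypic SD of 5% puts simulated records roughly in the −22 to
  +10 range once recessive homozygotes are included.

A subtlety on heritability semantics: $h^2$ fixes the split
$\sigma_g^2 = h^2\sigma_p^2$, $\sigma_e^2 = (1-h^2)\sigma_p^2$ of the *base*
variances, but the realized noise variance is inflated by
$\mathbb{E}[1/r] \approx 1.13$ under the default breedings distribution, so
the realized ratio $\mathrm{var}(u)/\mathrm{var}(y)$ sits slightly below the
nominal $h^2$ (about 0.32 for $h^2 = 0.35$). The generator documents rather
than hides this: it is exactly the attenuation real weighted evaluations
face.

What the generator deliberately does **not** emulate: linkage
disequilibrium (SNPs are independent, so a planted locus is tagged only by
itself), pedigree and family structure, selection, genotyping/imputation
error beyond uniform missingness, and the upstream national-evaluation
machinery that produces SCR from cow field data — the generator draws the
deviations directly. Consequently, passing tests demonstrate that the
estimators are correct under the assumed statistical structure; they do not
demonstrate field-data performance, where LD between markers and causal
variants, relatedness between training and test bulls, and non-genetic
trends all move the numbers. In particular, simulated major-marker gains are
larger than what field data typically show, because the planted loci are
tagged exactly and their carriers are identified without error.

## Problem sizes used in the checks

The test suite and the acceptance script exercise the chain at a deliberate
desk scale chosen to keep every statistical check sharp: populations of
500 bulls × 2,000 SNPs for variance-component recovery and cross-validation
(cross-validation chains shortened to 3,000 iterations, which suffices for
posterior-mean prediction), 1,000 × 500 for scan calibration and power, and
100 × 5,000 for the kernel's HWE diagonal. These sizes reproduce the
qualitative structure of a ~1,100-bull, high-density-panel analysis while
keeping the full suite in the minutes range on one CPU.

## Known limitations

* Only the linear kernel is provided; Gaussian or averaged multi-kernel
  variants are out of scope.
* No REML path: variance components come from the Gibbs sampler (or are
  supplied to the closed-form solver).
* The scan is marginal and unadjusted; see above.
* PLINK I/O covers bed/bim/fam v1 (SNP-major) and the additive-dosage text
  format; long-format or sample-major variants are not read.
* One record per individual; repeated records should be collapsed to the
  most reliable one upstream, mirroring how SCR records are used.
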