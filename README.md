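# sirefert

Genomic prediction of dairy bull fertility from dense SNP genotypes.

Sire conception rate (SCR) is a service-sire fertility phenotype expressed
as a percent deviation from a population mean set to zero: a bull at −4
sires 4% fewer conceptions than average. SCR records only exist once a bull
is already in service, so predicting them from genotypes available at birth
is what makes early selection (or early culling of predicted subfertile
calves) possible. Two things make the trait statistically awkward: record
precision varies enormously with the number of breedings behind each
record, and some breeds segregate large-effect *recessive* subfertility
loci that additive whole-genome models capture poorly.

`sirefert` implements the full analysis chain for this setting, for
quantitative geneticists and breeding-program analysts:

* **Genotype QC** — monomorphism, minor-allele-frequency (< 1%) and
  call-rate (SNP < 99%, individual < 95%) filters with a full removal
  report (`qc_filter()`);
* **Kernel construction** — the linear kernel / additive genomic
  relationship matrix `K = SS'/p` from centered, standardized genotypes
  (`standardize_genotypes()`, `build_linear_kernel()`);
* **Model fitting** — Bayesian RKHS/GBLUP regression by Gibbs sampling,

  ```
  y = Xb + K alpha + e,   alpha ~ N(0, K^-1 sigma_g^2),
  e ~ N(0, R^-1 sigma_e^2),   lambda = sigma_e^2 / sigma_g^2,
  ```

  with `R = diag(r_i)` the record reliabilities (so record `i` has residual
  variance `sigma_e^2 / r_i`) and known recessive major markers optionally
  fitted as 0/1 recessive-homozygote fixed effects (`rkhs_fit()`,
  `code_recessive()`), plus a deterministic weighted-BLUP oracle
  (`blup_closed_form()`);
* **Evaluation** — repeated 5-fold cross-validation with paired fold
  assignments, scored by predictive Pearson correlation and mean squared
  error of prediction (`cross_validate()`);
* **Recessive scan** — a single-marker weighted recessive-contrast genome
  scan with Manhattan-table output (`scan_recessive()`);
* **Synthetic data** — a generator planting polygenic background,
  recessive major loci and reliability-driven heteroscedastic noise
  (`simulate_population()`), so the whole chain runs and is tested without
  proprietary cohort data;
* **I/O** — PLINK bed/bim/fam (v1 binary) and additive-dosage text
  readers/writers, tab-separated phenotype/kernel/result tables, and a
  pipeline runner with JSON run manifests (`run_pipeline()`, thin CLI at
  `inst/cli/sirefert.R`).

## Worked example

Simulate a 300-bull cohort with two planted recessive loci (effect −8 SCR
units, recessive-allele frequencies 0.29/0.31), run QC, fit the model, scan
for recessive effects, and cross-validate both model variants:

```r
library(sirefert)

pop <- simulate_population(sim_config(n_individuals = 300, n_snps = 1000,
                                      seed = 42))
pop
#> Simulated population: 300 bulls, 1000 SNPs
#>   sigma_g2 = 8.750, sigma_e2 = 16.250 (h2 = 0.35)
#>   major recessive loci: snp000017, snp000298 ( 43 recessive homozygote calls )
#>   SCR range: -22.8 to 20.4; breedings 90 to 8078

qc <- qc_filter(pop$genotypes)
K  <- build_linear_kernel(standardize_genotypes(qc$genotypes))
fit <- rkhs_fit(pop$phenotypes$scr, K, weights = pop$phenotypes$reliability,
                control = rkhs_control(n_iter = 6000, burn_in = 1000, seed = 1))
summary(fit)
#> Fixed effects (posterior mean and sd):
#>             estimate    sd
#> (Intercept)  -0.0498 0.266
#>
#> Variance components: sigma_g2 = 15.431 (sd 4.060), sigma_e2 = 20.135 (sd 3.558)
#> lambda (sigma_e2/sigma_g2) = 1.447; variance ratio = 0.434
#> 300 of 300 records in likelihood; 1000 draws kept; 1 eigenvalue(s) dropped

scan_recessive(qc$genotypes, pop$phenotypes$scr, pop$phenotypes$reliability)
#> Recessive-effect genome scan: 1000 SNPs, 818 tested
#>   Bonferroni threshold (alpha = 0.05): 6.11e-05
#>   top signals:
#>     snp_id chromosome position n_recessive_homozygotes effect_estimate      p_value
#>  snp000298          8    11000                      22       -8.679132 1.252953e-11
#>  snp000017         17     1000                      21       -5.956694 7.658571e-06
#>  ...

cv <- cross_validate(qc$genotypes, pop$phenotypes,
                     major_snp_ids = pop$major_locus_ids,
                     k = 5, reps = 10, seed = 7)
cv
#> 5-fold cross-validation, 10 repetitions
#>   polygenic          correlation 0.105 (sd 0.046)   MSEP 36.80 (sd 0.71)
#>   polygenic_majors   correlation 0.461 (sd 0.016)   MSEP 29.04 (sd 0.59)
#>   relative gain in predictive correlation: 341%
```

Reading the output: the scan recovers both planted loci as its top two
signals, with the strongest surviving the Bonferroni threshold and an
effect estimate near the planted −8. The fitted variance components imply a
shrinkage ratio `lambda` of about 1.4; the genomic variance ratio (0.43) is
inflated above the generating polygenic heritability because the recessive
loci sit in the kernel too. Cross-validation shows the practical point:
fitting the two known recessive markers as fixed effects raises the
out-of-sample predictive correlation from 0.11 to 0.46 and cuts MSEP from
36.8 to 29.0 in this simulated cohort — the planted loci are tagged
exactly, so simulated gains run larger than field gains.

The same chain is scriptable from a shell:

```sh
Rscript inst/cli/sirefert.R simulate --out run --set n_individuals=300 --set seed=42
Rscript inst/cli/sirefert.R qc --out run --set genotypes=run.raw
Rscript inst/cli/sirefert.R cv --out run --set genotypes=run.qc.raw --set pheno=run.pheno.tsv
```

Each stage writes a JSON run manifest (config, seeds, input digests,
package version) alongside its outputs.

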