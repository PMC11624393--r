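#' Configuration for the synthetic bull-fertility population generator
#'
#' Collects and validates the parameters of the data-generating model used
#' throughout the package's tests and examples: a polygenic additive
#' background over biallelic SNPs in Hardy-Weinberg equilibrium, a small
#' number of planted large-effect recessive loci, and heteroscedastic
#' residual noise driven by record reliability. Phenotypes mimic sire
#' conception rate (SCR): percent deviations from a population mean of zero.
#'
#' @param n_individuals Number of bulls. Default 1102, the size of cohorts
#'   this analysis is designed for.
#' @param n_snps Number of autosomal SNPs.
#' @param n_chromosomes Number of chromosomes SNPs are spread over
#'   (round-robin). Default 29, the bovine autosome count.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-SNP counted-allele
#'   frequencies are drawn uniformly from this interval.
#' @param heritability Narrow-sense heritability of the polygenic component,
#'   in `[0, 1)`: the fraction `sigma_g2 / (sigma_g2 + sigma_e2)` where
#'   `sigma_e2` is the base residual variance before reliability scaling.
#' @param n_major_loci Number of planted recessive major loci.
#' @param major_recessive_allele_freqs Recessive-allele frequency of each
#'   major locus. Defaults 0.29 and 0.31, the frequencies of the two known
#'   major fertility markers in Brown Swiss.
#' @param major_effect_sizes Phenotype-unit deviation added to recessive
#'   homozygotes at each major locus (negative = subfertility).
#' @param phenotypic_sd Target phenotypic standard deviation (percent units)
#'   of the polygenic + base-residual part. Default 5, which puts simulated
#'   SCR deviations roughly in the -22 to +10 range once recessive
#'   homozygotes are included.
#' @param breedings_range Integer pair; breedings per record are drawn
#'   uniformly from this range. Default 50 to 8110.
#' @param reliability_shape Positive `k` of the reliability mapping
#'   `r = n_breedings / (n_breedings + k)`. Default 200.
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param seed Integer seed; all simulation randomness derives from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 200, n_snps = 1000, seed = 42)
#' pop <- simulate_population(cfg)
#' pop
sim_config <- function(n_individuals = 1102, n_snps = 10000,
                       n_chromosomes = 29, maf_range = c(0.05, 0.5),
                       heritability = 0.35, n_major_loci = 2,
                       major_recessive_allele_freqs = c(0.29, 0.31),
                       major_effect_sizes = c(-8, -8),
                       phenotypic_sd = 5,
                       breedings_range = c(50L, 8110L),
                       reliability_shape = 200,
                       missing_rate = 0, seed = 1L) {
  stopifnot(n_individuals >= 1, n_snps >= 1, n_chromosomes >= 1,
            length(maf_range) == 2, length(breedings_range) == 2,
            reliability_shape > 0)
  if (n_major_loci > n_snps)
    stop("n_major_loci exceeds n_snps")
  if (heritability < 0 || heritability > 1)
    stop("heritability must lie in [0, 1]")
  if (any(maf_range <= 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair in (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (n_major_loci > 0) {
    if (length(major_recessive_allele_freqs) != n_major_loci ||
        length(major_effect_sizes) != n_major_loci)
      stop("major_recessive_allele_freqs and major_effect_sizes must have length n_major_loci")
    if (any(major_recessive_allele_freqs <= 0) ||
        any(major_recessive_allele_freqs > 0.5))
      stop("major recessive-allele frequencies must lie in (0, 0.5]")
  }
  if (breedings_range[1] < 1 || breedings_range[1] > breedings_range[2])
    stop("breedings_range must be an increasing pair of positive integers")
  structure(list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes), maf_range = as.numeric(maf_range),
    heritability = heritability, n_major_loci = as.integer(n_major_loci),
    major_recessive_allele_freqs = as.numeric(major_recessive_allele_freqs)[seq_len(n_major_loci)],
    major_effect_sizes = as.numeric(major_effect_sizes)[seq_len(n_major_loci)],
    phenotypic_sd = phenotypic_sd,
    breedings_range = as.integer(breedings_range),
    reliability_shape = reliability_shape,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Draws allele dosages `Binomial(2, p_j)` independently per SNP, with
#' counted-allele frequencies `p_j` uniform on `maf_range`. Major loci are
#' assigned their configured recessive-allele frequencies (the counted allele
#' of a major locus *is* its recessive allele). SNPs are assigned round-robin
#' to chromosomes with positions increasing within each chromosome. Missing
#' calls are masked uniformly at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()]; the ids of the planted major loci are
#'   attached as `attr(, "major_locus_ids")`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  p <- config$n_snps
  set.seed(config$seed)
  freqs <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  major_idx <- integer(0)
  if (config$n_major_loci > 0) {
    major_idx <- sort(sample.int(p, config$n_major_loci))
    freqs[major_idx] <- config$major_recessive_allele_freqs
  }
  dosage <- matrix(stats::rbinom(n * p, 2L, rep(freqs, each = n)), nrow = n)
  if (config$missing_rate > 0)
    dosage[stats::runif(n * p) < config$missing_rate] <- NA_integer_
  ind_ids <- sprintf("bull%05d", seq_len(n))
  sids <- sprintf("snp%06d", seq_len(p))
  chr <- as.character(((seq_len(p) - 1L) %% config$n_chromosomes) + 1L)
  pos <- ((seq_len(p) - 1L) %/% config$n_chromosomes + 1L) * 1000L
  dimnames(dosage) <- list(ind_ids, sids)
  map <- data.frame(snp_id = sids, chromosome = chr, position = pos,
                    allele_counted = "A", allele_other = "B",
                    stringsAsFactors = FALSE)
  g <- genotype_matrix(dosage, map)
  attr(g, "major_locus_ids") <- sids[major_idx]
  g
}

#' Simulate reliability-weighted fertility phenotypes on a genotype matrix
#'
#' Builds a polygenic value `u = S beta` (infinitesimal model: i.i.d. normal
#' effects on centered, standardized genotypes, rescaled so `var(u)` equals
#' the genetic variance implied by the heritability), adds the configured
#' deviation for individuals carrying two copies of a major locus's recessive
#' allele, draws breedings uniformly on `breedings_range`, maps them to
#' reliabilities `r = n/(n + k)`, draws residuals `N(0, sigma_e2 / r)`, and
#' centers the result so the population mean deviation is exactly 0.
#'
#' @param genotypes A [genotype_matrix()], typically from
#'   [simulate_genotypes()]. Major loci are taken from its
#'   `"major_locus_ids"` attribute.
#' @param config The same [sim_config()] used to generate `genotypes`.
#' @return A list of class `"sim_population"` with elements `genotypes`,
#'   `phenotypes` (data frame: `id`, `scr`, `n_breedings`, `reliability`),
#'   `true_polygenic_values`, `true_major_indicator` (n x n_major 0/1),
#'   `true_variance_components` (`sigma_g2`, `sigma_e2`), `major_locus_ids`.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  if (config$heritability >= 1)
    stop("heritability = 1 implies zero residual variance; the generator requires heritability < 1")
  n <- nrow(genotypes$dosage)
  major_ids <- attr(genotypes, "major_locus_ids")
  if (is.null(major_ids)) major_ids <- character(0)
  sigma_p2 <- config$phenotypic_sd^2
  sigma_g2 <- config$heritability * sigma_p2
  sigma_e2 <- (1 - config$heritability) * sigma_p2
  set.seed(config$seed + 1L)        # distinct stream from the genotype draw
  u <- numeric(n)
  if (sigma_g2 > 0) {
    # SNPs that happen to be monomorphic in a small sample carry no
    # polygenic information; they are skipped here (QC would drop them)
    fobs <- colMeans(genotypes$dosage, na.rm = TRUE) / 2
    poly <- which(!is.na(fobs) & fobs > 0 & fobs < 1)
    if (!length(poly))
      stop("no polymorphic SNPs to build a polygenic value from")
    S <- standardize_genotypes(
      genotype_matrix(genotypes$dosage[, poly, drop = FALSE],
                      genotypes$map[poly, , drop = FALSE]))$S
    beta <- stats::rnorm(ncol(S))
    u <- drop(S %*% beta)
    su <- stats::sd(u)
    u <- if (su > 0) u * sqrt(sigma_g2) / su else u
  }
  ind <- matrix(0L, n, length(major_ids),
                dimnames = list(rownames(genotypes$dosage), major_ids))
  major_dev <- numeric(n)
  if (length(major_ids)) {
    ind <- suppressWarnings(
      code_recessive(genotypes, major_ids,
                     recessive_allele = stats::setNames(
                       genotypes$map$allele_counted[match(major_ids, genotypes$map$snp_id)],
                       major_ids)))
    major_dev <- drop(ind %*% config$major_effect_sizes)
  }
  nb <- sample(config$breedings_range[1]:config$breedings_range[2], n,
               replace = TRUE)
  rel <- nb / (nb + config$reliability_shape)
  e <- stats::rnorm(n, 0, sqrt(sigma_e2 / rel))
  y <- u + major_dev + e
  y <- y - mean(y)
  phen <- data.frame(id = rownames(genotypes$dosage), scr = y,
                     n_breedings = nb, reliability = rel,
                     stringsAsFactors = FALSE)
  structure(list(
    genotypes = genotypes, phenotypes = phen,
    true_polygenic_values = stats::setNames(u, phen$id),
    true_major_indicator = ind,
    true_variance_components = c(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
    major_locus_ids = major_ids
  ), class = "sim_population")
}

#' @rdname simulate_phenotypes
#' @param config A [sim_config()].
#' @export
simulate_population <- function(config) {
  simulate_phenotypes(simulate_genotypes(config), config)
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Simulated population:", nrow(x$genotypes$dosage), "bulls,",
      ncol(x$genotypes$dosage), "SNPs\n")
  vc <- x$true_variance_components
  cat(sprintf("  sigma_g2 = %.3f, sigma_e2 = %.3f (h2 = %.2f)\n",
              vc[1], vc[2], vc[1] / sum(vc)))
  if (length(x$major_locus_ids))
    cat("  major recessive loci:", paste(x$major_locus_ids, collapse = ", "),
        "(", sum(x$true_major_indicator), "recessive homozygote calls )\n")
  cat(sprintf("  SCR range: %.1f to %.1f; breedings %d to %d\n",
              min(x$phenotypes$scr), max(x$phenotypes$scr),
              min(x$phenotypes$n_breedings), max(x$phenotypes$n_breedings)))
  invisible(x)
}

#' Write a simulated population to disk
#'
#' Writes the genotypes (PLINK raw text or bed/bim/fam), a tab-separated
#' phenotype table (`id`, `scr`, `n_breedings`, `reliability`) and a
#' tab-separated truth table (true polygenic values, major-locus indicators
#' and generating variance components in a comment header) for use as test
#' oracles.
#'
#' @param pop A `"sim_population"` from [simulate_population()].
#' @param prefix Output path prefix.
#' @param format `"raw"` (text) or `"bed"` (PLINK binary).
#' @return `prefix`, invisibly.
#' @export
write_population <- function(pop, prefix, format = c("raw", "bed")) {
  format <- match.arg(format)
  stopifnot(inherits(pop, "sim_population"))
  if (format == "raw") write_plink_raw(pop$genotypes, paste0(prefix, ".raw"))
  else write_plink_bed(pop$genotypes, prefix)
  utils::write.table(pop$phenotypes, paste0(prefix, ".pheno.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(id = pop$phenotypes$id,
                      true_polygenic = pop$true_polygenic_values)
  if (length(pop$major_locus_ids))
    truth <- cbind(truth, as.data.frame(pop$true_major_indicator))
  con <- file(paste0(prefix, ".truth.tsv"), "w")
  on.exit(close(con))
  vc <- pop$true_variance_components
  writeLines(sprintf("# sigma_g2=%.10g sigma_e2=%.10g major_locus_ids=%s",
                     vc[1], vc[2],
                     paste(pop$major_locus_ids, collapse = ",")), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a tab-separated phenotype table
#'
#' Expects columns `id`, `scr`, `n_breedings`, `reliability` as written by
#' [write_population()].
#'
#' @param path File path.
#' @return Data frame, one record per sire.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("id", "scr", "n_breedings", "reliability")
  if (!all(req %in% names(tab)))
    stop("phenotype table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("phenotype table has duplicate ids (one record per sire expected)")
  if (any(tab$reliability <= 0 | tab$reliability > 1))
    stop("reliabilities must lie in (0, 1]")
  tab
}
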