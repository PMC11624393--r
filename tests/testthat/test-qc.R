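test_that("planted QC violations are removed with matching reason lists", {
  g <- qc_fixture()
  res <- qc_filter(g)
  rep <- res$report
  expect_identical(rep$removed_monomorphic, "s031")
  expect_identical(rep$removed_maf, "s032")
  expect_identical(rep$removed_snp_callrate, "s033")
  expect_identical(rep$removed_individual_callrate, "i050")
  expect_equal(rep$n_snps_out, rep$n_snps_in - 3L)
  expect_equal(rep$n_individuals_out, rep$n_individuals_in - 1L)
  expect_false(any(c("s031", "s032", "s033") %in% snp_ids(res$genotypes)))
  expect_false("i050" %in% individual_ids(res$genotypes))
})

test_that("qc_filter is idempotent", {
  res1 <- qc_filter(qc_fixture())
  res2 <- qc_filter(res1$genotypes)
  expect_identical(res2$genotypes$dosage, res1$genotypes$dosage)
  expect_length(res2$report$removed_monomorphic, 0)
  expect_length(res2$report$removed_maf, 0)
  expect_length(res2$report$removed_snp_callrate, 0)
  expect_length(res2$report$removed_individual_callrate, 0)
})

test_that("a clean matrix passes through unchanged and a gutted one errors", {
  g <- toy_geno(matrix(rep(c(0L, 1L, 2L, 1L), 5), 5, 4))
  res <- qc_filter(g)
  expect_identical(res$genotypes$dosage, g$dosage)
  mono <- toy_geno(matrix(2L, 4, 3))
  expect_error(qc_filter(mono), "empty after QC")
})

test_that("MAF exactly at the boundary is kept", {
  # 50 individuals, one het: f = 0.01 exactly -> kept under strict '<'
  d <- matrix(rep_len(c(0L, 1L, 2L, 1L), 50 * 3), 50, 3)
  d[, 3] <- 0L
  d[1, 3] <- 1L
  g <- toy_geno(d)
  res <- qc_filter(g)
  expect_true("s003" %in% snp_ids(res$genotypes))
})

test_that("QC report writers emit JSON and text", {
  rep <- qc_filter(qc_fixture())$report
  fj <- tempfile(fileext = ".json")
  ft <- tempfile(fileext = ".txt")
  write_qc_report(rep, fj)
  write_qc_report(rep, ft)
  parsed <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(parsed$removed_maf, "s032")
  expect_match(paste(readLines(ft), collapse = " "), "SNPs: 33 -> 30")
})

test_that("standardization matches the hand-computed formula", {
  g <- toy_geno(matrix(c(0L, 1L, 2L, 1L), 4, 1))
  s <- standardize_genotypes(g)
  expect_equal(unname(s$allele_freqs), 0.5)
  expect_equal(unname(s$S[, 1]), c(-1, 0, 1, 0) * sqrt(2),
               tolerance = 1e-12)
})

test_that("missing dosages standardize to exactly zero (mean imputation)", {
  g <- toy_geno(matrix(c(0L, 1L, 2L, NA), 4, 1))
  s <- standardize_genotypes(g)
  expect_identical(s$S[4, 1], 0)
  expect_equal(mean(s$S[, 1]), 0, tolerance = 1e-12)
  expect_identical(s$imputation_policy, "mean")
})

test_that("all-heterozygous SNP standardizes to a zero column but is retained", {
  g <- toy_geno(matrix(1L, 6, 1))
  s <- standardize_genotypes(g)
  expect_equal(unname(s$allele_freqs), 0.5)
  expect_true(all(s$S == 0))
})

test_that("monomorphic columns are refused by name", {
  g <- toy_geno(cbind(matrix(c(0L, 1L, 2L, 1L), 4, 1), matrix(2L, 4, 1)))
  expect_error(standardize_genotypes(g), "s002")
})

test_that("columns of S have mean zero on realistic data with missingness", {
  g <- simulate_genotypes(sim_config(n_individuals = 200, n_snps = 100,
                                     n_major_loci = 0, missing_rate = 0.05,
                                     seed = 13))
  S <- standardize_genotypes(g)$S
  expect_lt(max(abs(colMeans(S))), 1e-8)
})

test_that("linear kernel matches hand-computed single-SNP outer product", {
  g <- toy_geno(matrix(c(0L, 1L, 2L, 1L), 4, 1))
  K <- build_linear_kernel(standardize_genotypes(g))$K
  expect_equal(K[1, 1], 2, tolerance = 1e-12)
  expect_equal(K[1, 3], -2, tolerance = 1e-12)
  expect_equal(K[2, 2], 0, tolerance = 1e-12)
})

test_that("identical genotypes give identical kernel entries", {
  d <- rbind(c(0L, 1L, 2L), c(0L, 1L, 2L), c(2L, 1L, 0L), c(1L, 0L, 1L))
  K <- build_linear_kernel(standardize_genotypes(toy_geno(d)))$K
  expect_equal(K[1, 1], K[1, 2], tolerance = 1e-12)
  expect_equal(K[1, 1], K[2, 2], tolerance = 1e-12)
})

test_that("kernel equals the brute-force double loop on random instances", {
  for (s in 1:5) {
    set.seed(200 + s)
    n <- sample(5:20, 1)
    p <- sample(10:50, 1)
    g <- toy_geno(matrix(rbinom(n * p, 2, runif(p, 0.2, 0.5)[rep(1:p, each = n)]),
                         n, p))
    ok <- colMeans(g$dosage) / 2
    g <- toy_geno(g$dosage[, ok > 0 & ok < 1, drop = FALSE])
    std <- standardize_genotypes(g)
    K <- build_linear_kernel(std)
    expect_equal(K$K, brute_kernel(std$S), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(K$p_used, ncol(std$S))
  }
})

test_that("kernel rows and columns average to zero without missing data", {
  g <- simulate_genotypes(sim_config(n_individuals = 50, n_snps = 300,
                                     n_major_loci = 0, seed = 21))
  K <- build_linear_kernel(standardize_genotypes(g))$K
  expect_lt(max(abs(rowMeans(K))), 1e-8)
  expect_lt(max(abs(colMeans(K))), 1e-8)
  expect_lt(max(abs(K - t(K))), 1e-10)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("kernel writer and reader round-trip", {
  g <- simulate_genotypes(sim_config(n_individuals = 10, n_snps = 30,
                                     n_major_loci = 0, seed = 2))
  K <- kernel_of(g)
  f <- tempfile(fileext = ".tsv")
  write_kernel(K, f)
  K2 <- read_kernel(f)
  expect_equal(K2$K, K$K, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(K2$individual_ids, K$individual_ids)
})

test_that("recessive coding flags only recessive homozygotes", {
  # counted allele A at freq 0.25 (minor): homozygote = dosage 2
  d <- matrix(c(2L, 1L, 0L, 0L, 1L, 2L, 0L, 0L), 4, 2)
  g <- toy_geno(d)
  Z <- code_recessive(g, c("s001", "s002"))
  expect_identical(unname(Z[, "s001"]), c(1L, 0L, 0L, 0L))
  expect_identical(unname(Z[, "s002"]), c(0L, 1L, 0L, 0L))
  expect_identical(unname(attr(Z, "recessive_allele")), c("A", "A"))
})

test_that("recessive coding defaults to the minor allele and can be pinned", {
  # counted allele frequency 0.75 -> minor is the *other* allele; homozygote
  # for the minor allele has dosage 0
  d <- matrix(c(2L, 2L, 1L, 0L), 4, 1)
  g <- toy_geno(d)
  Z <- code_recessive(g, "s001")
  expect_identical(unname(Z[, 1]), c(0L, 0L, 0L, 1L))
  expect_identical(unname(attr(Z, "recessive_allele")), "B")
  # pinning the counted allele flips the indicator
  Zp <- code_recessive(g, "s001", recessive_allele = c(s001 = "A"))
  expect_identical(unname(Zp[, 1]), c(1L, 1L, 0L, 0L))
})

test_that("recessive coding is invariant to swapping allele orientation", {
  set.seed(31)
  d <- matrix(rbinom(60, 2, 0.3), 20, 3)
  g <- toy_geno(d)
  gs <- toy_geno(2L - d, counted = "B", other = "A")  # swapped orientation
  pin <- c(s001 = "A", s002 = "A", s003 = "A")
  expect_identical(
    suppressWarnings(code_recessive(g, names(pin), recessive_allele = pin)),
    suppressWarnings(code_recessive(gs, names(pin), recessive_allele = pin)))
})

test_that("missing calls and empty designs warn as specified", {
  d <- matrix(c(2L, NA, 0L, 1L, 1L, 0L), 3, 2)
  g <- toy_geno(d)
  expect_warning(code_recessive(g, "s001"), "missing genotype")
  expect_warning(code_recessive(g, "s002"), "inestimable")
  expect_error(code_recessive(g, "nope"), "unknown SNP id")
  Z <- suppressWarnings(code_recessive(g, "s001"))
  expect_identical(unname(Z[2, 1]), 0L)
})
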