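test_that("fold assignments are balanced, exhaustive and seed-deterministic", {
  ids <- sprintf("b%02d", 1:10)
  fa <- make_folds(ids, k = 5, repetition_seeds = 1L)[[1]]
  expect_setequal(names(fa$fold), ids)
  expect_true(all(table(fa$fold) == 2))
  fa2 <- make_folds(ids, k = 5, repetition_seeds = 1L)[[1]]
  expect_identical(fa$fold, fa2$fold)

  ids20 <- sprintf("b%02d", 1:23)
  fs <- make_folds(ids20, k = 5, repetition_seeds = c(3L, 4L))
  expect_false(identical(fs[[1]]$fold, fs[[2]]$fold))
  expect_lte(diff(range(table(fs[[1]]$fold))), 1)
  expect_error(make_folds(ids, k = 11, repetition_seeds = 1L), "exceeds")
})

test_that("pearson matches the product-moment formula and guards degeneracy", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(1:4, 1:5), "length")
})

test_that("msep is the mean squared difference", {
  expect_equal(msep(1:4, 1:4), 0)
  expect_equal(msep(c(0, 0), c(1, -1)), 1)
  expect_equal(msep(c(-2, 3), c(0, 0)), 6.5)
  expect_error(msep(1:3, 1:2), "length")
})

test_that("scaling observations and predictions jointly behaves as expected", {
  set.seed(61)
  o <- rnorm(50)
  p <- o + rnorm(50, 0, 0.5)
  expect_equal(pearson(3 * o, 3 * p), pearson(o, p), tolerance = 1e-12)
  expect_equal(msep(3 * o, 3 * p), 9 * msep(o, p), tolerance = 1e-12)
})

cv_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_population(sim_config(
        n_individuals = 120, n_snps = 300, heritability = 0.5,
        major_recessive_allele_freqs = c(0.35, 0.35),
        major_effect_sizes = c(-10, -10), seed = 62))
    cache
  }
})

test_that("out-of-fold predictions cover every individual once with paired folds", {
  pop <- cv_data()
  cv <- cross_validate(pop$genotypes, pop$phenotypes,
                       major_snp_ids = pop$major_locus_ids,
                       k = 4, reps = 2, control = fast_ctl(), seed = 10)
  expect_equal(nrow(cv$per_repetition), 2 * 2)
  expect_true(all(c("polygenic", "polygenic_majors") %in%
                  cv$per_repetition$model))
  for (fa in cv$folds) {
    expect_setequal(names(fa$fold), pop$phenotypes$id)
    expect_lte(diff(range(table(fa$fold))), 1)
  }
  expect_true(all(cv$per_repetition$msep >= 0))
})

test_that("cross-validation is bit-reproducible under the same seed", {
  pop <- cv_data()
  cv1 <- cross_validate(pop$genotypes, pop$phenotypes, variants = "polygenic",
                        k = 4, reps = 2, control = fast_ctl(), seed = 11)
  cv2 <- cross_validate(pop$genotypes, pop$phenotypes, variants = "polygenic",
                        k = 4, reps = 2, control = fast_ctl(), seed = 11)
  expect_identical(cv1$per_repetition, cv2$per_repetition)
})

test_that("permuted phenotypes carry no predictive signal", {
  # each permutation carries chance association of order 1/sqrt(n); average
  # over independent permutations so the null check is stable
  pop <- cv_data()
  cors <- vapply(1:4, function(s) {
    phen <- pop$phenotypes
    set.seed(63 + s)
    phen$scr <- sample(phen$scr)
    cv <- cross_validate(pop$genotypes, phen, variants = "polygenic",
                         k = 4, reps = 1, control = fast_ctl(),
                         seed = 12 + s)
    cv$per_repetition$correlation
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("correlation and MSEP rank repetitions consistently", {
  pop <- cv_data()
  cv <- cross_validate(pop$genotypes, pop$phenotypes,
                       major_snp_ids = pop$major_locus_ids,
                       k = 4, reps = 10, control = fast_ctl(), seed = 13)
  d <- cv$per_repetition
  # pooled over both variants: 20 repetition-level points
  expect_lt(stats::cor(d$correlation, d$msep, method = "spearman"), 0)
})

test_that("an inestimable major-marker column inside a fold is dropped, not fatal", {
  pop <- simulate_population(sim_config(
    n_individuals = 60, n_snps = 150, n_major_loci = 1,
    major_recessive_allele_freqs = 0.16, major_effect_sizes = -8, seed = 64))
  # with few recessive homozygotes some training folds will lack them
  expect_no_error(suppressMessages(
    cross_validate(pop$genotypes, pop$phenotypes,
                   major_snp_ids = pop$major_locus_ids,
                   variants = "polygenic_majors", k = 5, reps = 1,
                   control = fast_ctl(), seed = 14)))
})

test_that("misconfigured cross-validation calls fail loudly", {
  pop <- cv_data()
  expect_error(cross_validate(pop$genotypes, pop$phenotypes,
                              variants = "polygenic_majors", k = 4, reps = 1),
               "major_snp_ids")
  expect_error(cross_validate(pop$genotypes, pop$phenotypes[-1, ],
                              variants = "polygenic", k = 4, reps = 1),
               "missing")
})
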