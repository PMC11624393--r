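sim_small <- function(n = 40, p = 200, seed = 1, ...) {
  pop <- simulate_population(sim_config(n_individuals = n, n_snps = p,
                                        n_major_loci = 0, seed = seed, ...))
  list(pop = pop, K = kernel_of(pop$genotypes),
       y = pop$phenotypes$scr, w = pop$phenotypes$reliability)
}

test_that("with variance components fixed at truth the chain reproduces the BLUP", {
  d <- sim_small(n = 40, p = 250, seed = 51)
  vc <- d$pop$true_variance_components
  fit <- rkhs_fit(d$y, d$K, weights = d$w,
                  control = rkhs_control(n_iter = 20000, burn_in = 2000,
                                         thin = 2, seed = 7,
                                         fix_sigma_g2 = vc[["sigma_g2"]],
                                         fix_sigma_e2 = vc[["sigma_e2"]]))
  bl <- blup_closed_form(d$y, d$K, weights = d$w,
                         sigma_g2 = vc[["sigma_g2"]],
                         sigma_e2 = vc[["sigma_e2"]])
  expect_gt(stats::cor(fit$g_mean, bl$g_hat), 0.999)
  se_b <- mcse(fit$b_draws[, 1])
  expect_lt(abs(fit$b_mean[[1]] - bl$b_hat[[1]]), 3 * se_b)
})

test_that("zero genetic variance collapses the sampler to weighted least squares", {
  d <- sim_small(n = 30, p = 100, seed = 52)
  fit <- rkhs_fit(d$y, d$K, weights = d$w,
                  control = rkhs_control(n_iter = 5000, burn_in = 1000,
                                         seed = 2, fix_sigma_g2 = 0,
                                         fix_sigma_e2 = 10))
  expect_true(all(fit$g_mean == 0))
  wls <- stats::lm.wfit(fit$X, d$y, d$w)
  se_b <- mcse(fit$b_draws[, 1])
  expect_lt(abs(fit$b_mean[[1]] - wls$coefficients[[1]]), 3 * se_b)
})

test_that("lambda is the posterior mean of the per-draw variance ratio", {
  d <- sim_small(n = 25, p = 80, seed = 53)
  fit <- rkhs_fit(d$y, d$K, weights = d$w, control = fast_ctl())
  expect_equal(fit$lambda_mean,
               mean(fit$draws$sigma_e2 / fit$draws$sigma_g2),
               tolerance = 1e-12)
  expect_gt(fit$sigma_g2_mean, 0)
  expect_gt(fit$sigma_e2_mean, 0)
})

test_that("chains are deterministic given the seed", {
  d <- sim_small(n = 20, p = 60, seed = 54)
  f1 <- rkhs_fit(d$y, d$K, weights = d$w, control = fast_ctl())
  f2 <- rkhs_fit(d$y, d$K, weights = d$w, control = fast_ctl())
  expect_identical(f1$g_mean, f2$g_mean)
  expect_identical(f1$draws, f2$draws)
})

test_that("masked individuals are predicted through the kernel", {
  d <- sim_small(n = 30, p = 150, seed = 55, heritability = 0.6)
  train <- rep(TRUE, 30)
  train[c(3, 17)] <- FALSE
  fit <- rkhs_fit(d$y, d$K, weights = d$w, train = train,
                  control = fast_ctl())
  pr <- predict(fit)
  expect_length(pr, 30)
  expect_identical(unname(attr(pr, "test")), !train)
  expect_false(anyNA(pr))
  r <- residuals(fit)
  expect_true(all(is.na(r[!train])))
  expect_false(anyNA(r[train]))
})

test_that("genotypically identical individuals get identical predictions", {
  # duplicate a genotype row; the kernel rows coincide, so posterior genetic
  # values and predictions coincide too, even when one copy is masked
  pop <- simulate_population(sim_config(n_individuals = 20, n_snps = 100,
                                        n_major_loci = 0, heritability = 0.6,
                                        seed = 56))
  d <- pop$genotypes$dosage
  d[20, ] <- d[1, ]
  K <- build_linear_kernel(standardize_genotypes(toy_geno(d)))
  y <- pop$phenotypes$scr
  train <- rep(TRUE, 20)
  train[20] <- FALSE
  fit <- rkhs_fit(y, K, weights = pop$phenotypes$reliability, train = train,
                  control = fast_ctl())
  pr <- predict(fit)
  expect_equal(unname(pr[20]), unname(pr[1]), tolerance = 1e-8)
})

test_that("permuting individuals permutes the posterior consistently", {
  d <- sim_small(n = 30, p = 120, seed = 57, heritability = 0.6)
  perm <- sample(30)
  ctl <- rkhs_control(n_iter = 12000, burn_in = 2000, thin = 2, seed = 5)
  f0 <- rkhs_fit(d$y, d$K, weights = d$w, control = ctl)
  fp <- rkhs_fit(d$y[perm], d$K$K[perm, perm], weights = d$w[perm],
                 control = ctl)
  # chains see a re-ordered eigensystem, so agreement is statistical
  expect_gt(stats::cor(fp$g_mean, f0$g_mean[perm]), 0.99)
})

test_that("misaligned or degenerate inputs are rejected", {
  d <- sim_small(n = 15, p = 40, seed = 58)
  expect_error(rkhs_fit(d$y[-1], d$K), "individuals")
  expect_error(rkhs_fit(d$y, d$K, weights = rep(1, 3)), "weights")
  expect_error(rkhs_fit(d$y, d$K, train = rep(FALSE, 15)), "training records")
  notpsd <- diag(15) - 0.5
  expect_error(rkhs_fit(d$y, notpsd), "positive semidefinite")
  X <- cbind(1, matrix(1, 15, 1))
  expect_error(rkhs_fit(d$y, d$K, X = X), "collinear")
})

test_that("the centered kernel's null eigenvalue is truncated", {
  d <- sim_small(n = 25, p = 100, seed = 59)
  fit <- rkhs_fit(d$y, d$K, weights = d$w, control = fast_ctl())
  expect_gte(fit$eigen$n_dropped, 1L)
  expect_equal(length(fit$eigen$d) + fit$eigen$n_dropped, 25L)
})
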