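#' MCMC settings for the kernel regression sampler
#'
#' @param n_iter Total Gibbs iterations. Default 30000.
#' @param burn_in Iterations discarded before summarizing. Default 5000.
#' @param thin Keep every `thin`-th post-burn-in draw. Default 5.
#' @param seed Integer seed; the chain is deterministic given it.
#' @param prior_df_g,prior_df_e Degrees of freedom of the scaled-inverse-
#'   chi-square priors on the genetic and residual variances. Default 5.
#' @param prior_scale_g,prior_scale_e Prior scale parameters, or `"auto"`
#'   (default) to set each scale so the prior mode equals half the training
#'   phenotypic variance.
#' @param fix_sigma_g2,fix_sigma_e2 Optional numeric values at which to hold
#'   a variance component fixed (its sampling step is disabled); `NULL`
#'   (default) samples it.
#' @param store_g Keep the per-draw genetic values (memory `n` per kept
#'   draw)? Default `FALSE`; posterior mean/sd are always returned.
#' @return A list of class `"rkhs_control"`.
#' @export
rkhs_control <- function(n_iter = 30000, burn_in = 5000, thin = 5, seed = 1L,
                         prior_df_g = 5, prior_df_e = 5,
                         prior_scale_g = "auto", prior_scale_e = "auto",
                         fix_sigma_g2 = NULL, fix_sigma_e2 = NULL,
                         store_g = FALSE) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df_g = prior_df_g, prior_df_e = prior_df_e,
                 prior_scale_g = prior_scale_g, prior_scale_e = prior_scale_e,
                 fix_sigma_g2 = fix_sigma_g2, fix_sigma_e2 = fix_sigma_e2,
                 store_g = isTRUE(store_g)),
            class = "rkhs_control")
}

kernel_matrix <- function(kernel) {
  if (inherits(kernel, "linear_kernel")) kernel$K
  else if (is.matrix(kernel)) kernel
  else stop("'kernel' must be a linear_kernel or a symmetric matrix")
}

# Eigendecomposition of K with small/negative eigenvalues dropped.
# The centered linear kernel always has (at least) one zero eigenvalue, so
# sampling is done on the retained eigenspace rather than through K^{-1}.
kernel_eigen <- function(K, tol = 1e-8) {
  if (max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K))))
    stop("kernel matrix is not symmetric")
  ev <- eigen(K, symmetric = TRUE)
  dmax <- max(ev$values)
  if (dmax <= 0) stop("degenerate kernel: no positive eigenvalues")
  if (min(ev$values) < -1e-6 * dmax)
    stop(sprintf("kernel is not positive semidefinite (min eigenvalue %.3g)",
                 min(ev$values)))
  keep <- ev$values > tol * dmax
  if (!any(keep)) stop("degenerate kernel: no retained eigenvalues")
  list(U = ev$vectors[, keep, drop = FALSE], d = ev$values[keep],
       n_dropped = sum(!keep))
}

build_design <- function(X, n) {
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("design matrix X has ", nrow(X), " rows; expected ", n)
    if (is.null(colnames(X)))
      colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (!all(X[, 1] == 1))
      X <- cbind("(Intercept)" = 1, X)
  }
  X
}

check_design_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit the Bayesian reliability-weighted kernel regression by Gibbs sampling
#'
#' Fits the kernel-based genomic prediction model
#' \deqn{y = Xb + g + e, \quad g \sim N(0, K\sigma_g^2), \quad
#'       e \sim N(0, R^{-1}\sigma_e^2),}
#' where `K` is a genomic kernel (for the linear kernel this is GBLUP) and
#' `R = diag(r_i)` holds the record reliabilities, so a record with
#' reliability `r_i` has residual variance `sigma_e2 / r_i`. Equivalently,
#' `g = K alpha` with RKHS coefficients `alpha ~ N(0, K^{-1} sigma_g2)`
#' penalized by `lambda alpha' K alpha`, `lambda = sigma_e2 / sigma_g2`.
#'
#' Sampling uses the spectral reparameterization `g = U z` from the
#' eigendecomposition `K = U diag(d) U'` (eigenvalues below `1e-8 * max(d)`
#' dropped), which avoids inverting the — always singular, once centered —
#' kernel. Records with `train = FALSE` contribute no likelihood; their
#' genetic values are still sampled through the kernel, which is how
#' yet-to-be-observed individuals are predicted. Variance components get
#' scaled-inverse-chi-square priors; fixed effects a flat prior.
#'
#' @param y Numeric phenotype vector (one record per individual, percent
#'   deviations for SCR). May contain `NA` for individuals to predict; those
#'   are treated as `train = FALSE`.
#' @param kernel A `"linear_kernel"` from [build_linear_kernel()], or a bare
#'   symmetric PSD matrix, indexed like `y`.
#' @param X Optional fixed-effect design matrix (an intercept column is
#'   prepended if absent), e.g. recessive-homozygote indicators from
#'   [code_recessive()]. Default: intercept only.
#' @param weights Record reliabilities in (0, 1]; default 1 for all.
#' @param train Logical vector marking records that enter the likelihood;
#'   default: all records with non-missing `y`.
#' @param control An [rkhs_control()].
#' @param eigen_K Optional precomputed result of the kernel
#'   eigendecomposition (as returned in `$eigen` of a previous fit on the
#'   same kernel); lets repeated fits — e.g. cross-validation folds — reuse
#'   one decomposition.
#' @return An object of class `"rkhs_fit"`; see [summary.rkhs_fit()],
#'   [coef.rkhs_fit()], [predict.rkhs_fit()], [residuals.rkhs_fit()],
#'   [plot.rkhs_fit()].
#' @export
#' @examples
#' pop <- simulate_population(sim_config(n_individuals = 150, n_snps = 600,
#'                                       n_major_loci = 0, seed = 3))
#' K <- build_linear_kernel(standardize_genotypes(pop$genotypes))
#' fit <- rkhs_fit(pop$phenotypes$scr, K, weights = pop$phenotypes$reliability,
#'                 control = rkhs_control(n_iter = 2000, burn_in = 500))
#' summary(fit)
rkhs_fit <- function(y, kernel, X = NULL, weights = NULL, train = NULL,
                     control = rkhs_control(), eigen_K = NULL) {
  K <- kernel_matrix(kernel)
  n <- length(y)
  if (nrow(K) != n)
    stop("kernel has ", nrow(K), " individuals but y has ", n)
  ids <- if (inherits(kernel, "linear_kernel")) kernel$individual_ids
         else rownames(K)
  if (!is.null(names(y)) && !is.null(ids) && !identical(names(y), ids))
    stop("names(y) do not match the kernel's individual ids")
  if (is.null(train)) train <- !is.na(y) else train <- as.logical(train)
  if (length(train) != n) stop("'train' must have one entry per individual")
  train <- train & !is.na(y)
  X <- build_design(X, n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("'weights' must have one entry per individual")
  if (any(weights[train] <= 0)) stop("reliability weights must be positive")
  if (sum(train) < ncol(X) + 2)
    stop("need at least q + 2 training records (q = ", ncol(X), ")")
  check_design_rank(X[train, , drop = FALSE])

  eig <- if (is.null(eigen_K)) kernel_eigen(K) else eigen_K
  vy <- stats::var(y[train])
  auto_scale <- function(s, df) {
    if (identical(s, "auto")) 0.5 * vy * (df + 2) / df else as.numeric(s)
  }
  Sg <- auto_scale(control$prior_scale_g, control$prior_df_g)
  Se <- auto_scale(control$prior_scale_e, control$prior_df_e)
  fix_g <- !is.null(control$fix_sigma_g2)
  fix_e <- !is.null(control$fix_sigma_e2)
  init_g <- if (fix_g) control$fix_sigma_g2 else 0.5 * vy
  init_e <- if (fix_e) control$fix_sigma_e2 else 0.5 * vy
  if (fix_e && init_e <= 0) stop("fixed residual variance must be positive")

  set.seed(control$seed)
  raw <- gibbs_rkhs_cpp(eig$U[train, , drop = FALSE], eig$U, eig$d,
                        X[train, , drop = FALSE], y[train], weights[train],
                        control$n_iter, control$burn_in, control$thin,
                        control$prior_df_g, control$prior_df_e, Sg, Se,
                        init_g, init_e, fix_g, fix_e, control$store_g)

  b_draws <- raw$b_draws
  colnames(b_draws) <- colnames(X)
  lambda_draws <- raw$sigma_e2_draws / raw$sigma_g2_draws
  g_mean <- drop(raw$g_mean)
  g_sd <- drop(raw$g_sd)
  names(g_mean) <- names(g_sd) <- ids
  out <- list(
    b_mean = colMeans(b_draws), b_sd = apply(b_draws, 2, stats::sd),
    b_draws = b_draws,
    g_mean = g_mean, g_sd = g_sd,
    sigma_g2_mean = mean(raw$sigma_g2_draws),
    sigma_g2_sd = stats::sd(raw$sigma_g2_draws),
    sigma_e2_mean = mean(raw$sigma_e2_draws),
    sigma_e2_sd = stats::sd(raw$sigma_e2_draws),
    lambda_mean = mean(lambda_draws),
    draws = data.frame(sigma_g2 = raw$sigma_g2_draws,
                       sigma_e2 = raw$sigma_e2_draws,
                       lambda = lambda_draws),
    g_draws = raw$g_draws,
    n_kept = raw$n_kept,
    eigen = eig, y = y, X = X, weights = weights, train = train,
    individual_ids = ids, control = control, call = match.call()
  )
  class(out) <- "rkhs_fit"
  out
}

#' @export
print.rkhs_fit <- function(x, ...) {
  cat("Reliability-weighted kernel regression (Gibbs)\n")
  cat(sprintf("  %d individuals (%d in likelihood), %d fixed effect(s)\n",
              length(x$y), sum(x$train), ncol(x$X)))
  cat(sprintf("  sigma_g2 = %.3f, sigma_e2 = %.3f, lambda = %.3f  (%d draws kept)\n",
              x$sigma_g2_mean, x$sigma_e2_mean, x$lambda_mean, x$n_kept))
  invisible(x)
}

#' Posterior summary of a kernel regression fit
#'
#' @param object An `"rkhs_fit"`.
#' @param ... Unused.
#' @return A list of class `"summary.rkhs_fit"` with the fixed-effect table,
#'   variance components, the shrinkage ratio lambda and the genomic
#'   variance ratio (an h2-style quantity on the training records).
#' @export
summary.rkhs_fit <- function(object, ...) {
  fx <- data.frame(estimate = object$b_mean, sd = object$b_sd)
  vr <- object$sigma_g2_mean / (object$sigma_g2_mean + object$sigma_e2_mean)
  structure(list(fixed = fx,
                 sigma_g2 = c(mean = object$sigma_g2_mean, sd = object$sigma_g2_sd),
                 sigma_e2 = c(mean = object$sigma_e2_mean, sd = object$sigma_e2_sd),
                 lambda = object$lambda_mean, variance_ratio = vr,
                 n = length(object$y), n_train = sum(object$train),
                 n_kept = object$n_kept,
                 n_dropped_eigenvalues = object$eigen$n_dropped),
            class = "summary.rkhs_fit")
}

#' @export
print.summary.rkhs_fit <- function(x, ...) {
  cat("Fixed effects (posterior mean and sd):\n")
  print(round(x$fixed, 4))
  cat(sprintf("\nVariance components: sigma_g2 = %.3f (sd %.3f), sigma_e2 = %.3f (sd %.3f)\n",
              x$sigma_g2["mean"], x$sigma_g2["sd"],
              x$sigma_e2["mean"], x$sigma_e2["sd"]))
  cat(sprintf("lambda (sigma_e2/sigma_g2) = %.3f; variance ratio = %.3f\n",
              x$lambda, x$variance_ratio))
  cat(sprintf("%d of %d records in likelihood; %d draws kept; %d eigenvalue(s) dropped\n",
              x$n_train, x$n, x$n_kept, x$n_dropped_eigenvalues))
  invisible(x)
}

#' @export
coef.rkhs_fit <- function(object, ...) object$b_mean

#' @export
fitted.rkhs_fit <- function(object, ...) {
  drop(object$X %*% object$b_mean) + object$g_mean
}

#' Predicted phenotypes from a kernel regression fit
#'
#' Returns `X b + g` (posterior means) for every individual in the kernel,
#' including those excluded from the likelihood (`train = FALSE`), whose
#' genetic values are borrowed through the kernel — the prediction used for
#' yet-to-be-observed records. The logical attribute `"test"` flags them.
#'
#' @param object An `"rkhs_fit"`.
#' @param ... Unused.
#' @return Named numeric vector with attribute `"test"`.
#' @export
predict.rkhs_fit <- function(object, ...) {
  pred <- fitted(object)
  attr(pred, "test") <- !object$train
  pred
}

#' Training-record residuals of a kernel regression fit
#'
#' @param object An `"rkhs_fit"`.
#' @param ... Unused.
#' @return `y - X b - g` for training records, `NA` for masked ones.
#' @export
residuals.rkhs_fit <- function(object, ...) {
  r <- object$y - fitted(object)
  r[!object$train] <- NA_real_
  r
}

#' Diagnostic plots for a kernel regression fit
#'
#' Draws trace plots of the variance components and, when training records
#' exist, observed versus fitted phenotypes.
#'
#' @param x An `"rkhs_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rkhs_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$draws$sigma_g2, type = "l", xlab = "kept draw",
                 ylab = expression(sigma[g]^2), main = "genetic variance", ...)
  graphics::plot(x$draws$sigma_e2, type = "l", xlab = "kept draw",
                 ylab = expression(sigma[e]^2), main = "residual variance", ...)
  f <- fitted(x)[x$train]
  graphics::plot(f, x$y[x$train], xlab = "fitted", ylab = "observed",
                 main = "training records", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
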