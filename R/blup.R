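#' Closed-form weighted BLUP with known variance components
#'
#' Solves the mixed model `y = Xb + g + e`, `g ~ N(0, K sigma_g2)`,
#' `var(e_i) = sigma_e2 / r_i`, on the training records with the variance
#' components held at known values. Fixed effects are generalized least
#' squares under `V = K_tt sigma_g2 + diag(sigma_e2 / r)`; genetic values for
#' all individuals — including masked ones, via the kernel cross-block — are
#' the usual BLUP `sigma_g2 K[, t] V^{-1} (y - X b)`. This is the
#' deterministic counterpart of [rkhs_fit()] and its testing oracle.
#'
#' @inheritParams rkhs_fit
#' @param sigma_g2,sigma_e2 Known positive variance components.
#' @return List with `b_hat` (named), `g_hat` (length n, all individuals)
#'   and `fitted` (`X b_hat + g_hat`).
#' @export
blup_closed_form <- function(y, kernel, X = NULL, weights = NULL,
                             train = NULL, sigma_g2, sigma_e2) {
  stopifnot(sigma_g2 >= 0, sigma_e2 > 0)
  K <- kernel_matrix(kernel)
  n <- length(y)
  if (nrow(K) != n) stop("kernel/phenotype dimension mismatch")
  if (is.null(train)) train <- !is.na(y) else train <- as.logical(train)
  train <- train & !is.na(y)
  X <- build_design(X, n)
  if (is.null(weights)) weights <- rep(1, n)
  Xt <- X[train, , drop = FALSE]
  check_design_rank(Xt)
  yt <- y[train]
  V <- sigma_g2 * K[train, train, drop = FALSE] +
    diag(sigma_e2 / weights[train], nrow = sum(train))
  Vi <- solve(V)
  XtVi <- crossprod(Xt, Vi)
  b_hat <- drop(solve(XtVi %*% Xt, XtVi %*% yt))
  names(b_hat) <- colnames(X)
  resid <- yt - drop(Xt %*% b_hat)
  g_hat <- drop(sigma_g2 * K[, train, drop = FALSE] %*% (Vi %*% resid))
  ids <- if (inherits(kernel, "linear_kernel")) kernel$individual_ids
         else rownames(K)
  names(g_hat) <- ids
  list(b_hat = b_hat, g_hat = g_hat,
       fitted = drop(X %*% b_hat) + g_hat)
}
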