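# Shared fixture builders; everything is generated in code at test time.

# A genotype_matrix from a bare dosage matrix with default metadata.
toy_geno <- function(dosage, chromosome = "1", counted = "A", other = "B") {
  n <- nrow(dosage)
  p <- ncol(dosage)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("i%03d", seq_len(n))
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("s%03d", seq_len(p))
  map <- data.frame(snp_id = colnames(dosage),
                    chromosome = rep_len(chromosome, p),
                    position = seq_len(p) * 100L,
                    allele_counted = rep_len(counted, p),
                    allele_other = rep_len(other, p),
                    stringsAsFactors = FALSE)
  genotype_matrix(dosage, map)
}

# Deterministic QC fixture with planted violations:
#  - one monomorphic SNP, one SNP with MAF < 0.01, one SNP with call rate
#    0.9833 (< 0.99), one individual with call rate 0.879 (< 0.95),
#  - all remaining SNPs near MAF 0.5 with complete calls.
qc_fixture <- function() {
  n <- 60L
  p <- 33L
  d <- matrix(rep_len(c(0L, 1L, 2L, 1L), n * p), n, p)  # maf ~ 0.5 everywhere
  colnames(d) <- sprintf("s%03d", seq_len(p))
  rownames(d) <- sprintf("i%03d", seq_len(n))
  d[, "s031"] <- 0L                         # monomorphic
  d[, "s032"] <- 0L; d["i002", "s032"] <- 1L   # MAF 1/120 < 0.01
  d["i003", "s033"] <- NA_integer_          # SNP call rate 59/60 < 0.99
  d["i050", 1:4] <- NA_integer_             # individual call rate 29/33 < 0.95
  toy_geno(d)
}

# Brute-force linear kernel: the literal double-loop sum over SNPs.
brute_kernel <- function(S) {
  n <- nrow(S)
  p <- ncol(S)
  K <- matrix(0, n, n)
  for (i in seq_len(n))
    for (k in seq_len(n))
      K[i, k] <- sum(S[i, ] * S[k, ]) / p
  K
}

# Brute-force weighted BLUP by literally assembling and solving the joint
# penalized normal equations on the retained eigenspace of K
# (g = U sqrt(d) a, ridge on a). Independent of blup_closed_form's V-inverse
# route.
brute_blup <- function(y, K, X, w, train, sigma_g2, sigma_e2) {
  ev <- eigen(K, symmetric = TRUE)
  keep <- ev$values > 1e-8 * max(ev$values)
  M <- ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev$values[keep]),
                                                 sum(keep))
  Xt <- X[train, , drop = FALSE]
  Mt <- M[train, , drop = FALSE]
  W <- diag(w[train], sum(train))
  q <- ncol(Xt)
  m <- ncol(Mt)
  A <- rbind(
    cbind(crossprod(Xt, W %*% Xt) / sigma_e2, crossprod(Xt, W %*% Mt) / sigma_e2),
    cbind(crossprod(Mt, W %*% Xt) / sigma_e2,
          crossprod(Mt, W %*% Mt) / sigma_e2 + diag(m) / sigma_g2))
  rhs <- c(crossprod(Xt, W %*% y[train]) / sigma_e2,
           crossprod(Mt, W %*% y[train]) / sigma_e2)
  sol <- solve(A, rhs)
  list(b_hat = sol[seq_len(q)], g_hat = drop(M %*% sol[-seq_len(q)]))
}

# Batch-means Monte Carlo standard error of a chain of draws.
mcse <- function(draws, n_batches = 25) {
  nb <- max(2, min(n_batches, length(draws) %/% 10))
  bm <- tapply(draws, cut(seq_along(draws), nb), mean)
  stats::sd(bm) / sqrt(nb)
}

fast_ctl <- function(...) rkhs_control(n_iter = 2000, burn_in = 500,
                                       thin = 2, seed = 99, ...)

# QC then kernel, for tiny simulated instances that may carry monomorphic SNPs.
kernel_of <- function(g) build_linear_kernel(
  standardize_genotypes(qc_filter(g)$genotypes))
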