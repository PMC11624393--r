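#' Single-marker genome scan for recessive effects
#'
#' For each SNP, fits the weighted least-squares regression
#' `y = mu + delta * I(two copies of the recessive allele) + e` with record
#' reliabilities as weights, and reports the recessive-contrast estimate
#' `delta`, its standard error, and a two-sided p-value from the t
#' distribution. This is a deliberately simplified per-marker scan: `delta`
#' is the weighted mean phenotype of recessive homozygotes minus that of all
#' other individuals, with no polygenic-background adjustment. SNPs with
#' fewer recessive homozygotes than `min_homozygotes` (among non-missing
#' calls) are skipped with a reason. A Bonferroni threshold over the tested
#' SNPs is attached.
#'
#' @param g A QC-passed [genotype_matrix()].
#' @param y Numeric phenotype vector aligned with the rows of `g`.
#' @param weights Record reliabilities aligned with `y`; default 1.
#' @param min_homozygotes Minimum recessive-homozygote count for a SNP to be
#'   tested. Default 5.
#' @param recessive_allele Optional named character vector pinning the
#'   recessive allele of specific SNPs; default is the cohort minor allele
#'   (see [code_recessive()]).
#' @param alpha Nominal family-wise error rate for the Bonferroni threshold.
#'   Default 0.05.
#' @return A data frame of class `"scan_result"`, one row per SNP:
#'   `snp_id`, `chromosome`, `position`, `n_recessive_homozygotes`,
#'   `effect_estimate`, `standard_error`, `p_value`, `tested`, `reason`.
#'   Attributes: `"bonferroni"` (threshold `alpha / n_tested`), `"n_tested"`,
#'   `"alpha"`.
#' @export
#' @examples
#' pop <- simulate_population(sim_config(n_individuals = 300, n_snps = 200,
#'                                       n_major_loci = 1,
#'                                       major_recessive_allele_freqs = 0.3,
#'                                       major_effect_sizes = -8, seed = 9))
#' sc <- scan_recessive(pop$genotypes, pop$phenotypes$scr,
#'                      pop$phenotypes$reliability)
#' head(sc[order(sc$p_value), ])
scan_recessive <- function(g, y, weights = NULL, min_homozygotes = 5,
                           recessive_allele = NULL, alpha = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosage)
  if (length(y) != n)
    stop("phenotype vector has ", length(y), " entries; genotypes have ", n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("weights have ", length(weights), " entries; genotypes have ", n)
  p <- ncol(g$dosage)
  d <- g$dosage

  # recessive allele per SNP: pinned by label where given, else cohort minor
  f <- colMeans(d, na.rm = TRUE) / 2           # counted-allele frequency
  rec_is_counted <- is.na(f) | f <= 0.5
  if (!is.null(recessive_allele)) {
    idx <- match(names(recessive_allele), snp_ids(g))
    if (anyNA(idx))
      stop("unknown SNP id(s) in recessive_allele: ",
           paste(names(recessive_allele)[is.na(idx)], collapse = ", "))
    ac <- g$map$allele_counted[idx]
    ao <- g$map$allele_other[idx]
    bad <- !(recessive_allele == ac | recessive_allele == ao)
    if (any(bad))
      stop("recessive allele label matches neither allele for: ",
           paste(names(recessive_allele)[bad], collapse = ", "))
    rec_is_counted[idx] <- recessive_allele == ac
  }
  hom_dosage <- ifelse(rec_is_counted, 2L, 0L)

  obs <- !is.na(d)
  H <- matrix(0, n, p)
  H[obs] <- as.numeric(d[obs] == rep(hom_dosage, each = n)[obs])

  W <- matrix(weights, n, p) * obs             # per-SNP weights, 0 if missing
  wy <- weights * y
  wy2 <- weights * y^2
  sw1 <- colSums(W * H)
  sw0 <- colSums(W) - sw1
  n1 <- colSums(H * obs)
  n_obs <- colSums(obs)
  m1 <- colSums(wy * obs * H) / sw1
  m0 <- (colSums(wy * obs) - colSums(wy * obs * H)) / sw0
  delta <- m1 - m0
  ssw <- colSums(wy2 * obs) - sw1 * m1^2 - sw0 * m0^2
  df <- n_obs - 2
  s2 <- pmax(ssw, 0) / df
  se <- sqrt(s2 * (1 / sw1 + 1 / sw0))
  tval <- delta / se
  pval <- 2 * stats::pt(-abs(tval), df)

  tested <- n1 >= min_homozygotes & (n_obs - n1) >= min_homozygotes & df >= 1
  reason <- rep(NA_character_, p)
  reason[n1 == 0] <- "no recessive homozygotes"
  reason[n1 > 0 & n1 < min_homozygotes] <-
    sprintf("fewer than %d recessive homozygotes", min_homozygotes)
  reason[tested == FALSE & is.na(reason)] <-
    sprintf("fewer than %d non-homozygous records", min_homozygotes)
  delta[!tested] <- NA_real_
  se[!tested] <- NA_real_
  pval[!tested] <- NA_real_

  res <- data.frame(
    snp_id = snp_ids(g), chromosome = g$map$chromosome,
    position = g$map$position,
    n_recessive_homozygotes = as.integer(n1),
    effect_estimate = delta, standard_error = se, p_value = pval,
    tested = tested, reason = reason, stringsAsFactors = FALSE)
  class(res) <- c("scan_result", "data.frame")
  attr(res, "n_tested") <- sum(tested)
  attr(res, "alpha") <- alpha
  attr(res, "bonferroni") <- if (sum(tested) > 0) alpha / sum(tested) else NA_real_
  res
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Recessive-effect genome scan:", nrow(x), "SNPs,",
      attr(x, "n_tested"), "tested\n")
  cat(sprintf("  Bonferroni threshold (alpha = %.3g): %.3g\n",
              attr(x, "alpha"), attr(x, "bonferroni")))
  top <- x[x$tested, ]
  top <- utils::head(top[order(top$p_value), ], 5L)
  class(top) <- "data.frame"
  if (nrow(top)) {
    cat("  top signals:\n")
    print(top[, c("snp_id", "chromosome", "position",
                  "n_recessive_homozygotes", "effect_estimate", "p_value")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Manhattan-plot table for a genome scan
#'
#' Lays out the tested SNPs along a cumulative genome coordinate
#' (chromosomes in input order, positions stacked end to end) with
#' `-log10(p)` for plotting.
#'
#' @param scan A `"scan_result"` from [scan_recessive()].
#' @return Data frame: `snp_id`, `chromosome`, `position`,
#'   `cumulative_position`, `neg_log10_p`.
#' @export
manhattan_table <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  chr <- unique(scan$chromosome)
  offs <- c(0, cumsum(vapply(chr, function(cc)
    max(scan$position[scan$chromosome == cc]), numeric(1))))
  names(offs) <- c(chr, "end")
  out <- scan[scan$tested,
              c("snp_id", "chromosome", "position", "p_value")]
  out$cumulative_position <- out$position + offs[out$chromosome]
  out$neg_log10_p <- -log10(out$p_value)
  out$p_value <- NULL
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Manhattan plot of a recessive genome scan
#'
#' @param x A `"scan_result"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scan_result <- function(x, ...) {
  tab <- manhattan_table(x)
  chr_idx <- match(tab$chromosome, unique(tab$chromosome))
  graphics::plot(tab$cumulative_position, tab$neg_log10_p,
                 col = c("grey30", "steelblue")[1 + chr_idx %% 2],
                 pch = 16, cex = 0.6, xlab = "cumulative position (bp)",
                 ylab = expression(-log[10](p)), ...)
  bf <- attr(x, "bonferroni")
  if (is.finite(bf)) graphics::abline(h = -log10(bf), lty = 2, col = "red")
  invisible(x)
}
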