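#' Quality control of a SNP genotype matrix
#'
#' Applies the standard pre-analysis filters in a fixed order: individuals
#' with genotype call rate below `ind_callrate_min` are removed first, then —
#' with allele frequencies recomputed on the retained individuals — SNPs that
#' are monomorphic, have minor allele frequency strictly below `maf_min`, or
#' have call rate below `snp_callrate_min`. Each SNP is attributed to the
#' first rule it violates, so the removal lists are disjoint.
#'
#' @param g A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency; SNPs with MAF `< maf_min`
#'   are removed (MAF exactly equal is kept). Default 0.01.
#' @param snp_callrate_min Minimum per-SNP call rate. Default 0.99.
#' @param ind_callrate_min Minimum per-individual call rate. Default 0.95.
#' @return A list with elements `genotypes` (filtered [genotype_matrix()])
#'   and `report` (class `"qc_report"`).
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 50, n_snps = 100,
#'                                    n_major_loci = 0, seed = 7))
#' qc <- qc_filter(g)
#' qc$report
qc_filter <- function(g, maf_min = 0.01, snp_callrate_min = 0.99,
                      ind_callrate_min = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$dosage) == 0 || ncol(g$dosage) == 0) stop("empty genotype matrix")
  obs <- !is.na(g$dosage)
  ind_cr <- rowMeans(obs)
  drop_ind <- individual_ids(g)[ind_cr < ind_callrate_min]
  keep_ind <- !(individual_ids(g) %in% drop_ind)
  if (!any(keep_ind)) stop("empty after QC: all individuals removed by call-rate filter")
  d <- g$dosage[keep_ind, , drop = FALSE]
  obs <- obs[keep_ind, , drop = FALSE]
  ncall <- colSums(obs)
  f <- ifelse(ncall > 0, colSums(d, na.rm = TRUE) / (2 * ncall), NA_real_)
  mono <- ncall == 0 | f == 0 | f == 1
  maf <- pmin(f, 1 - f)
  low_maf <- !mono & maf < maf_min
  low_cr <- !mono & !low_maf & (ncall / nrow(d)) < snp_callrate_min
  sid <- snp_ids(g)
  keep_snp <- !(mono | low_maf | low_cr)
  if (!any(keep_snp)) stop("empty after QC: all SNPs removed")
  out <- genotype_matrix(d[, keep_snp, drop = FALSE],
                         g$map[keep_snp, , drop = FALSE])
  if (!is.null(attr(g, "major_locus_ids")))
    attr(out, "major_locus_ids") <-
      intersect(attr(g, "major_locus_ids"), snp_ids(out))
  report <- structure(list(
    n_individuals_in = nrow(g$dosage), n_individuals_out = nrow(out$dosage),
    n_snps_in = ncol(g$dosage), n_snps_out = ncol(out$dosage),
    removed_monomorphic = sid[mono],
    removed_maf = sid[low_maf],
    removed_snp_callrate = sid[low_cr],
    removed_individual_callrate = drop_ind,
    thresholds = c(maf_min = maf_min, snp_callrate_min = snp_callrate_min,
                   ind_callrate_min = ind_callrate_min)
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  individuals: %d -> %d (%d removed, call rate < %.2f)\n",
              x$n_individuals_in, x$n_individuals_out,
              length(x$removed_individual_callrate),
              x$thresholds["ind_callrate_min"]))
  cat(sprintf("  SNPs: %d -> %d\n", x$n_snps_in, x$n_snps_out))
  cat(sprintf("    monomorphic:          %d\n", length(x$removed_monomorphic)))
  cat(sprintf("    MAF < %.3g:           %d\n", x$thresholds["maf_min"],
              length(x$removed_maf)))
  cat(sprintf("    call rate < %.2f:     %d\n",
              x$thresholds["snp_callrate_min"], length(x$removed_snp_callrate)))
  invisible(x)
}

#' Write a QC report to disk
#'
#' @param report A `"qc_report"` from [qc_filter()].
#' @param path Output file; written as JSON if it ends in `.json`, otherwise
#'   as the human-readable text of the print method.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  } else {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path)
  }
  invisible(path)
}

#' Center and standardize a genotype matrix
#'
#' Computes `s_ij = (g_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))` with `p_j` the
#' observed counted-allele frequency among non-missing calls. Missing dosages
#' are mean-imputed before standardization, i.e. their standardized value is
#' exactly 0. Each column of the result has mean 0.
#'
#' @param g A QC-passed [genotype_matrix()] (no monomorphic SNPs).
#' @return A list of class `"std_geno"`: `S` (n x p numeric),
#'   `allele_freqs` (named per-SNP counted-allele frequency),
#'   `imputation_policy` (`"mean"`).
#' @export
standardize_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  ncall <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * ncall)
  bad <- ncall == 0 | f == 0 | f == 1
  if (any(bad))
    stop("monomorphic SNP(s) cannot be standardized: ",
         paste(utils::head(snp_ids(g)[bad], 5L), collapse = ", "),
         if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L) else "",
         "; run qc_filter() first")
  S <- sweep(d, 2L, 2 * f, `-`)
  S[is.na(S)] <- 0
  S <- sweep(S, 2L, sqrt(2 * f * (1 - f)), `/`)
  dimnames(S) <- dimnames(d)
  structure(list(S = S, allele_freqs = stats::setNames(f, snp_ids(g)),
                 imputation_policy = "mean"),
            class = "std_geno")
}

#' Build the linear genomic kernel (additive relationship matrix)
#'
#' `K = S S' / p`, with `S` the centered, standardized genotype matrix and
#' `p` the number of SNPs averaged — the classical SNP-derived additive
#' genomic relationship matrix. Symmetric and positive semidefinite by
#' construction (up to round-off).
#'
#' @param s A `"std_geno"` from [standardize_genotypes()].
#' @return A list of class `"linear_kernel"`: `K` (n x n), `individual_ids`,
#'   `p_used`.
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 20, n_snps = 200,
#'                                    n_major_loci = 0, seed = 1))
#' K <- build_linear_kernel(standardize_genotypes(g))
#' mean(diag(K$K))  # near 1 under Hardy-Weinberg equilibrium
build_linear_kernel <- function(s) {
  stopifnot(inherits(s, "std_geno"))
  p <- ncol(s$S)
  if (p < 1) stop("no SNPs to build a kernel from")
  K <- tcrossprod(s$S) / p
  K <- (K + t(K)) / 2
  structure(list(K = K, individual_ids = rownames(s$S), p_used = p),
            class = "linear_kernel")
}

#' @export
print.linear_kernel <- function(x, ...) {
  cat("Linear genomic kernel:", nrow(x$K), "individuals, built from",
      x$p_used, "SNPs\n")
  cat(sprintf("  mean diagonal %.3f, off-diagonal range [%.3f, %.3f]\n",
              mean(diag(x$K)), min(x$K[upper.tri(x$K)]),
              max(x$K[upper.tri(x$K)])))
  invisible(x)
}

#' Write / read a kernel as a square tab-separated matrix with id header
#'
#' @param k A `"linear_kernel"`.
#' @param path File path.
#' @return `path` (writer) or a `"linear_kernel"` (reader).
#' @export
write_kernel <- function(k, path) {
  stopifnot(inherits(k, "linear_kernel"))
  tab <- as.data.frame(k$K)
  names(tab) <- k$individual_ids
  utils::write.table(cbind(id = k$individual_ids, tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(tab$id)
  K <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(K) <- list(ids, ids)
  if (nrow(K) != ncol(K)) stop("kernel file is not square: ", path)
  structure(list(K = K, individual_ids = ids, p_used = NA_integer_),
            class = "linear_kernel")
}

#' Recessive-homozygote coding of designated major markers
#'
#' Codes each designated SNP as a 0/1 indicator equal to 1 only for
#' individuals carrying two copies of that SNP's recessive allele — the
#' coding used to fit known large-effect recessive loci as fixed covariates
#' alongside a polygenic kernel. By default the recessive allele is taken to
#' be the minor allele in the analyzed cohort; it can be pinned per SNP by
#' label via `recessive_allele`. Missing genotypes at a designated SNP are
#' coded 0 with a warning.
#'
#' @param g A [genotype_matrix()].
#' @param major_snp_ids Character vector of SNP ids to code.
#' @param recessive_allele Optional named character vector (names = SNP ids)
#'   giving the recessive allele label where known; unnamed SNPs fall back to
#'   the cohort minor allele.
#' @return An `n x length(major_snp_ids)` 0/1 integer matrix with the
#'   recessive-allele label of each column in `attr(, "recessive_allele")`.
#' @export
code_recessive <- function(g, major_snp_ids, recessive_allele = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  major_snp_ids <- as.character(major_snp_ids)
  miss <- setdiff(major_snp_ids, snp_ids(g))
  if (length(miss))
    stop("unknown SNP id(s): ", paste(miss, collapse = ", "))
  n <- nrow(g$dosage)
  out <- matrix(0L, n, length(major_snp_ids),
                dimnames = list(individual_ids(g), major_snp_ids))
  rec_lab <- character(length(major_snp_ids))
  for (j in seq_along(major_snp_ids)) {
    id <- major_snp_ids[j]
    col <- g$dosage[, id]
    i <- match(id, g$map$snp_id)
    a_counted <- g$map$allele_counted[i]
    a_other <- g$map$allele_other[i]
    rec <- recessive_allele[[id]]
    if (is.null(rec) || is.na(rec)) {
      f <- mean(col, na.rm = TRUE) / 2      # counted-allele frequency
      rec <- if (is.nan(f) || f <= 0.5) a_counted else a_other
    } else if (!rec %in% c(a_counted, a_other)) {
      stop(sprintf("recessive allele '%s' for %s matches neither allele (%s/%s)",
                   rec, id, a_counted, a_other))
    }
    rec_lab[j] <- rec
    hom_dosage <- if (rec == a_counted) 2L else 0L
    v <- as.integer(!is.na(col) & col == hom_dosage)
    if (anyNA(col))
      warning(sprintf("%d missing genotype(s) at major SNP %s coded as 0",
                      sum(is.na(col)), id))
    if (sum(v) == 0L)
      warning(sprintf("major SNP %s has no recessive homozygotes; its fixed effect is inestimable",
                      id))
    out[, j] <- v
  }
  attr(out, "recessive_allele") <- stats::setNames(rec_lab, major_snp_ids)
  out
}
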