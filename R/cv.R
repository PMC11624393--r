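#' Balanced random fold assignments for repeated k-fold cross-validation
#'
#' @param ids Character vector of individual ids.
#' @param k Number of folds. Default 5.
#' @param repetition_seeds Integer vector, one seed per repetition; each
#'   yields a uniformly random balanced partition (fold sizes differ by at
#'   most one), deterministic given the seed.
#' @return List of `"fold_assignment"` objects: `repetition`, `fold` (named
#'   integer vector id -> fold), `k`, `seed`.
#' @export
make_folds <- function(ids, k = 5, repetition_seeds) {
  ids <- as.character(ids)
  n <- length(ids)
  if (k > n) stop("k = ", k, " exceeds the number of individuals (", n, ")")
  if (k < 2) stop("k must be at least 2")
  lapply(seq_along(repetition_seeds), function(r) {
    set.seed(repetition_seeds[r])
    fold <- integer(n)
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
    structure(list(repetition = r,
                   fold = stats::setNames(fold, ids),
                   k = as.integer(k),
                   seed = as.integer(repetition_seeds[r])),
              class = "fold_assignment")
  })
}

#' Pearson product-moment correlation between observed and predicted values
#'
#' @param obs,pred Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return The correlation coefficient.
#' @export
pearson <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred differ in length")
  if (length(obs) < 3) stop("need at least 3 pairs for a correlation")
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    stop("correlation undefined: constant vector")
  stats::cor(obs, pred)
}

#' Mean squared error of prediction
#'
#' @param obs,pred Numeric vectors of equal length.
#' @return Mean of squared differences.
#' @export
msep <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred differ in length")
  if (length(obs) < 1) stop("empty vectors")
  mean((obs - pred)^2)
}

#' Repeated cross-validation of kernel prediction model variants
#'
#' Scores the predictive ability of the whole-genome kernel model
#' (`"polygenic"`) and, when major-marker ids are supplied, the variant that
#' additionally fits recessive-homozygote indicators for those markers as
#' fixed effects (`"polygenic_majors"`). Per repetition, individuals are
#' partitioned into `k` balanced folds; each fold's phenotypes are masked in
#' turn, the model is refitted, masked records are predicted through the
#' kernel, and one predictive correlation and one mean squared error of
#' prediction (MSEP) are computed per repetition over the pooled out-of-fold
#' predictions. Fold assignments are shared across variants within a
#' repetition, giving a paired comparison. The kernel is eigendecomposed
#' once and reused across all fits.
#'
#' If a training fold has no recessive homozygote for a major marker, that
#' indicator column is dropped for that fold (its coefficient is
#' inestimable) with a message.
#'
#' @param genotypes A QC-passed [genotype_matrix()].
#' @param phenotypes Data frame with columns `id`, `scr`, `reliability`
#'   covering every genotyped individual.
#' @param major_snp_ids Character vector of major-marker SNP ids, or `NULL`.
#' @param variants Subset of `c("polygenic", "polygenic_majors")`.
#' @param k Folds per repetition. Default 5.
#' @param reps Repetitions. Default 10.
#' @param control An [rkhs_control()]; shorter chains than the fitting
#'   default are customary here.
#' @param seed Integer master seed for the fold assignments.
#' @param exclude_majors_from_kernel Drop the major markers from the SNP set
#'   before building the kernel? Default `FALSE` (they stay in the polygenic
#'   background as well).
#' @param weighted_metrics Weight correlation and MSEP by record reliability?
#'   Default `FALSE`.
#' @param recessive_allele Passed to [code_recessive()].
#' @return A list of class `"cv_result"`: `per_repetition` (data frame:
#'   `model`, `repetition`, `correlation`, `msep`), `summary` (mean/sd per
#'   model), `folds`, and the call's configuration.
#' @export
cross_validate <- function(genotypes, phenotypes, major_snp_ids = NULL,
                           variants = c("polygenic", "polygenic_majors"),
                           k = 5, reps = 10,
                           control = rkhs_control(n_iter = 3000,
                                                  burn_in = 500, thin = 2),
                           seed = 1L, exclude_majors_from_kernel = FALSE,
                           weighted_metrics = FALSE,
                           recessive_allele = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  variants <- match.arg(variants, several.ok = TRUE)
  if ("polygenic_majors" %in% variants && is.null(major_snp_ids))
    stop("variant 'polygenic_majors' requires major_snp_ids")
  ids <- individual_ids(genotypes)
  mi <- match(ids, phenotypes$id)
  if (anyNA(mi))
    stop("phenotypes missing for ", sum(is.na(mi)), " genotyped individual(s)")
  phen <- phenotypes[mi, , drop = FALSE]
  y <- phen$scr
  w <- phen$reliability
  n <- length(ids)

  gk <- genotypes
  if (exclude_majors_from_kernel && length(major_snp_ids)) {
    keep <- !(snp_ids(genotypes) %in% major_snp_ids)
    gk <- genotype_matrix(genotypes$dosage[, keep, drop = FALSE],
                          genotypes$map[keep, , drop = FALSE])
  }
  kern <- build_linear_kernel(standardize_genotypes(gk))
  eig <- kernel_eigen(kern$K)
  Z <- if (length(major_snp_ids))
    suppressWarnings(code_recessive(genotypes, major_snp_ids,
                                    recessive_allele = recessive_allele))
  else NULL

  rep_seeds <- as.integer(seed) + seq_len(reps) - 1L
  folds <- make_folds(ids, k = k, repetition_seeds = rep_seeds)

  rows <- list()
  for (r in seq_len(reps)) {
    fold <- folds[[r]]$fold
    pred <- matrix(NA_real_, n, length(variants),
                   dimnames = list(ids, variants))
    for (f in seq_len(k)) {
      test <- fold == f
      if (sum(test) < 2) stop("fold with fewer than 2 test records")
      train <- !test
      for (v in variants) {
        X <- NULL
        if (v == "polygenic_majors") {
          est <- colSums(Z[train, , drop = FALSE]) > 0
          if (!all(est))
            message("repetition ", r, " fold ", f,
                    ": dropping inestimable major-marker column(s) ",
                    paste(colnames(Z)[!est], collapse = ", "))
          if (any(est)) X <- Z[, est, drop = FALSE]
        }
        fit <- rkhs_fit(y, kern, X = X, weights = w, train = train,
                        control = control, eigen_K = eig)
        pr <- predict(fit)
        pred[test, v] <- pr[test]
      }
    }
    for (v in variants) {
      co <- tryCatch(
        if (weighted_metrics) stats::cov.wt(cbind(y, pred[, v]), wt = w,
                                            cor = TRUE)$cor[1, 2]
        else pearson(y, pred[, v]),
        error = function(e) {
          message("repetition ", r, ", model ", v,
                  ": correlation undefined (", conditionMessage(e), ")")
          NA_real_
        })
      ms <- if (weighted_metrics) sum(w * (y - pred[, v])^2) / sum(w)
            else msep(y, pred[, v])
      rows[[length(rows) + 1L]] <-
        data.frame(model = v, repetition = r, correlation = co, msep = ms)
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_rep, per_rep$model), function(d)
    data.frame(model = d$model[1],
               mean_correlation = mean(d$correlation, na.rm = TRUE),
               sd_correlation = stats::sd(d$correlation),
               mean_msep = mean(d$msep), sd_msep = stats::sd(d$msep))))
  rownames(agg) <- NULL
  structure(list(per_repetition = per_rep, summary = agg, folds = folds,
                 k = k, reps = reps, seed = seed, variants = variants,
                 weighted_metrics = weighted_metrics,
                 major_snp_ids = major_snp_ids, control = control),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repetitions\n", x$k, x$reps))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s correlation %.3f (sd %.3f)   MSEP %.2f (sd %.2f)\n",
                s$model[i], s$mean_correlation[i], s$sd_correlation[i],
                s$mean_msep[i], s$sd_msep[i]))
  if (all(c("polygenic", "polygenic_majors") %in% s$model)) {
    r0 <- s$mean_correlation[s$model == "polygenic"]
    r1 <- s$mean_correlation[s$model == "polygenic_majors"]
    cat(sprintf("  relative gain in predictive correlation: %.0f%%\n",
                100 * (r1 - r0) / r0))
  }
  invisible(x)
}
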