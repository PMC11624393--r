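#' Run one stage of the genomic-prediction pipeline
#'
#' Programmatic entry point behind the command-line wrapper shipped at
#' `system.file("cli", "sirefert.R", package = "sirefert")`. Dispatches one
#' of the pipeline stages — `simulate`, `qc`, `kernel`, `fit`, `cv`, `scan`
#' — from a flat configuration list, writes the stage's artifacts under an
#' output prefix, and drops a JSON run manifest (configuration snapshot,
#' seeds, input-file digests, package version, timestamps, record counts)
#' next to them. Inputs are never modified.
#'
#' Configuration keys per stage (all optional unless noted):
#' \describe{
#'   \item{simulate}{the arguments of [sim_config()]; plus `format`
#'     (`"raw"`/`"bed"`).}
#'   \item{qc}{`genotypes` (path, required), `format`, `maf_min`,
#'     `snp_callrate_min`, `ind_callrate_min`.}
#'   \item{kernel}{`genotypes` (required), `format`, `major_snps`
#'     (comma-separated ids), `exclude_majors_from_kernel`.}
#'   \item{fit}{`kernel` (path from the kernel stage, required), `pheno`
#'     (required), `major_snps` + `genotypes` for recessive covariates,
#'     `n_iter`, `burn_in`, `thin`, `seed`.}
#'   \item{cv}{`genotypes`, `pheno` (required), `major_snps`, `models`,
#'     `k`, `reps`, `n_iter`, `burn_in`, `thin`, `seed`,
#'     `exclude_majors_from_kernel`, `weighted_metrics`.}
#'   \item{scan}{`genotypes`, `pheno` (required), `min_homozygotes`,
#'     `alpha`.}
#' }
#'
#' @param subcommand One of `"simulate"`, `"qc"`, `"kernel"`, `"fit"`,
#'   `"cv"`, `"scan"`.
#' @param config Named list of configuration values, or the path of a JSON
#'   file holding one.
#' @param out Output path prefix (required).
#' @param overrides Named list merged over `config` (command-line flags win).
#' @return Invisibly, the list of artifact paths written (including the
#'   manifest).
#' @export
run_pipeline <- function(subcommand = c("simulate", "qc", "kernel", "fit",
                                        "cv", "scan"),
                         config = list(), out, overrides = list()) {
  subcommand <- match.arg(subcommand)
  if (missing(out) || !nzchar(out)) stop("an output prefix 'out' is required")
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("'config' must be a list or a JSON file path")
  config[names(overrides)] <- overrides
  t0 <- Sys.time()
  log_msg <- function(...) message("[sirefert ", subcommand, "] ", ...)
  log_msg("start")

  grab <- function(key, default = NULL, required = FALSE) {
    if (!is.null(config[[key]])) return(config[[key]])
    if (required) stop("config key '", key, "' is required for '",
                       subcommand, "'")
    default
  }
  read_geno <- function() {
    path <- grab("genotypes", required = TRUE)
    fmt <- grab("format", if (grepl("\\.raw$", path)) "plink-raw" else "plink-bed")
    read_genotypes(path, fmt)
  }
  inputs <- character(0)
  artifacts <- character(0)
  record <- function(path) artifacts <<- c(artifacts, path)

  known <- list(
    simulate = c(names(formals(sim_config)), "format"),
    qc = c("genotypes", "format", "maf_min", "snp_callrate_min",
           "ind_callrate_min"),
    kernel = c("genotypes", "format", "major_snps",
               "exclude_majors_from_kernel"),
    fit = c("kernel", "pheno", "genotypes", "format", "major_snps",
            "n_iter", "burn_in", "thin", "seed"),
    cv = c("genotypes", "format", "pheno", "major_snps", "models", "k",
           "reps", "n_iter", "burn_in", "thin", "seed",
           "exclude_majors_from_kernel", "weighted_metrics"),
    scan = c("genotypes", "format", "pheno", "min_homozygotes", "alpha"))
  unknown <- setdiff(names(config), known[[subcommand]])
  if (length(unknown))
    stop("unknown config key(s) for '", subcommand, "': ",
         paste(unknown, collapse = ", "))

  if (subcommand == "simulate") {
    cfg_args <- config[intersect(names(config), names(formals(sim_config)))]
    cfg <- do.call(sim_config, cfg_args)
    pop <- simulate_population(cfg)
    write_population(pop, out, format = grab("format", "raw"))
    record(paste0(out, if (identical(grab("format", "raw"), "raw"))
      ".raw" else ".bed"))
    record(paste0(out, ".pheno.tsv"))
    record(paste0(out, ".truth.tsv"))
    log_msg(nrow(pop$genotypes$dosage), " individuals, ",
            ncol(pop$genotypes$dosage), " SNPs written")
  } else if (subcommand == "qc") {
    inputs <- grab("genotypes", required = TRUE)
    g <- read_geno()
    res <- qc_filter(g, maf_min = grab("maf_min", 0.01),
                     snp_callrate_min = grab("snp_callrate_min", 0.99),
                     ind_callrate_min = grab("ind_callrate_min", 0.95))
    write_plink_raw(res$genotypes, paste0(out, ".qc.raw"))
    write_qc_report(res$report, paste0(out, ".qc_report.json"))
    write_qc_report(res$report, paste0(out, ".qc_report.txt"))
    record(paste0(out, c(".qc.raw", ".qc_report.json", ".qc_report.txt")))
    log_msg(res$report$n_snps_out, " of ", res$report$n_snps_in,
            " SNPs retained")
  } else if (subcommand == "kernel") {
    inputs <- grab("genotypes", required = TRUE)
    g <- read_geno()
    majors <- grab("major_snps")
    if (!is.null(majors))
      majors <- strsplit(as.character(majors), ",")[[1]]
    if (isTRUE(grab("exclude_majors_from_kernel", FALSE)) && length(majors)) {
      keep <- !(snp_ids(g) %in% majors)
      g <- genotype_matrix(g$dosage[, keep, drop = FALSE],
                           g$map[keep, , drop = FALSE])
    }
    kern <- build_linear_kernel(standardize_genotypes(g))
    write_kernel(kern, paste0(out, ".kernel.tsv"))
    record(paste0(out, ".kernel.tsv"))
    log_msg("kernel over ", nrow(kern$K), " individuals from ",
            kern$p_used, " SNPs")
  } else if (subcommand == "fit") {
    kpath <- grab("kernel", required = TRUE)
    ppath <- grab("pheno", required = TRUE)
    inputs <- c(kpath, ppath)
    kern <- read_kernel(kpath)
    phen <- read_phenotypes(ppath)
    mi <- match(kern$individual_ids, phen$id)
    if (anyNA(mi)) stop("phenotypes missing for ", sum(is.na(mi)),
                        " kernel individual(s) in ", ppath)
    phen <- phen[mi, ]
    X <- NULL
    majors <- grab("major_snps")
    if (!is.null(majors)) {
      g <- read_geno()
      inputs <- c(inputs, grab("genotypes"))
      X <- code_recessive(g, strsplit(as.character(majors), ",")[[1]])
    }
    ctl <- rkhs_control(n_iter = grab("n_iter", 30000),
                        burn_in = grab("burn_in", 5000),
                        thin = grab("thin", 5), seed = grab("seed", 1L))
    fit <- rkhs_fit(phen$scr, kern, X = X, weights = phen$reliability,
                    control = ctl)
    utils::write.table(
      data.frame(id = kern$individual_ids, g_mean = fit$g_mean,
                 g_sd = fit$g_sd, predicted = predict(fit)),
      paste0(out, ".genetic_values.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(effect = names(fit$b_mean), mean = fit$b_mean,
                 sd = fit$b_sd),
      paste0(out, ".fixed_effects.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(fit$draws, paste0(out, ".variance_draws.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record(paste0(out, c(".genetic_values.tsv", ".fixed_effects.tsv",
                         ".variance_draws.tsv")))
    log_msg(sprintf("sigma_g2 %.3f sigma_e2 %.3f lambda %.3f",
                    fit$sigma_g2_mean, fit$sigma_e2_mean, fit$lambda_mean))
  } else if (subcommand == "cv") {
    ppath <- grab("pheno", required = TRUE)
    inputs <- c(grab("genotypes", required = TRUE), ppath)
    g <- read_geno()
    phen <- read_phenotypes(ppath)
    majors <- grab("major_snps")
    if (!is.null(majors))
      majors <- strsplit(as.character(majors), ",")[[1]]
    models <- grab("models", if (is.null(majors)) "polygenic"
                   else c("polygenic", "polygenic_majors"))
    if (length(models) == 1L && grepl(",", models))
      models <- strsplit(models, ",")[[1]]
    ctl <- rkhs_control(n_iter = grab("n_iter", 3000),
                        burn_in = grab("burn_in", 500),
                        thin = grab("thin", 2), seed = grab("seed", 1L))
    cv <- cross_validate(
      g, phen, major_snp_ids = majors, variants = models,
      k = grab("k", 5), reps = grab("reps", 10), control = ctl,
      seed = grab("seed", 1L),
      exclude_majors_from_kernel = isTRUE(grab("exclude_majors_from_kernel",
                                               FALSE)),
      weighted_metrics = isTRUE(grab("weighted_metrics", FALSE)))
    utils::write.table(cv$per_repetition, paste0(out, ".cv_repetitions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cv$summary, paste0(out, ".cv_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    fold_tab <- do.call(rbind, lapply(cv$folds, function(fa)
      data.frame(repetition = fa$repetition, id = names(fa$fold),
                 fold = unname(fa$fold))))
    utils::write.table(fold_tab, paste0(out, ".cv_folds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record(paste0(out, c(".cv_repetitions.tsv", ".cv_summary.json",
                         ".cv_folds.tsv")))
    log_msg("done: ", nrow(cv$per_repetition), " repetition x model rows")
  } else if (subcommand == "scan") {
    ppath <- grab("pheno", required = TRUE)
    inputs <- c(grab("genotypes", required = TRUE), ppath)
    g <- read_geno()
    phen <- read_phenotypes(ppath)
    mi <- match(individual_ids(g), phen$id)
    if (anyNA(mi)) stop("phenotypes missing for ", sum(is.na(mi)),
                        " genotyped individual(s) in ", ppath)
    phen <- phen[mi, ]
    sc <- scan_recessive(g, phen$scr, phen$reliability,
                         min_homozygotes = grab("min_homozygotes", 5),
                         alpha = grab("alpha", 0.05))
    utils::write.table(as.data.frame(sc), paste0(out, ".scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(manhattan_table(sc), paste0(out, ".manhattan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record(paste0(out, c(".scan.tsv", ".manhattan.tsv")))
    log_msg(attr(sc, "n_tested"), " of ", nrow(sc), " SNPs tested")
  }

  manifest <- list(
    subcommand = subcommand,
    config = config,
    seed = config$seed,
    inputs = lapply(stats::setNames(inputs, inputs), function(f)
      unname(tools::md5sum(f))),
    artifacts = artifacts,
    package_version = as.character(utils::packageVersion("sirefert")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- paste0(out, ".manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  record(mpath)
  log_msg("end")
  invisible(artifacts)
}
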