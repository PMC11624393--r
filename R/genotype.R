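#' Construct a genotype matrix object
#'
#' Container for an individuals-by-SNP allele-dosage matrix plus per-SNP map
#' information (chromosome, position, allele labels). Dosages count copies of
#' the *counted* allele, take values 0/1/2, and use `NA` for missing calls.
#'
#' @param dosage Integer or numeric matrix, individuals in rows and SNPs in
#'   columns. Values must be 0, 1, 2 or `NA`. Row names are individual ids and
#'   column names SNP ids; both must be present and unique.
#' @param map Data frame with one row per SNP and columns `snp_id`,
#'   `chromosome`, `position`, `allele_counted`, `allele_other`. `snp_id` must
#'   match `colnames(dosage)` in order.
#'
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `dosage` and `map`.
#' @export
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 1L), 2, 2,
#'             dimnames = list(c("b1", "b2"), c("s1", "s2")))
#' m <- data.frame(snp_id = c("s1", "s2"), chromosome = "1",
#'                 position = c(100L, 200L),
#'                 allele_counted = "A", allele_other = "B")
#' genotype_matrix(d, m)
genotype_matrix <- function(dosage, map) {
  if (!is.matrix(dosage)) stop("'dosage' must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("'dosage' must carry individual ids as row names and SNP ids as column names")
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate individual ids in genotype matrix")
  if (anyDuplicated(colnames(dosage)))
    stop("duplicate SNP ids in genotype matrix")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosage entries must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  req <- c("snp_id", "chromosome", "position", "allele_counted", "allele_other")
  if (!is.data.frame(map) || !all(req %in% names(map)))
    stop("'map' must be a data frame with columns: ", paste(req, collapse = ", "))
  map <- map[, req]
  if (nrow(map) != ncol(dosage) || !identical(as.character(map$snp_id), colnames(dosage)))
    stop("map rows must match dosage columns (same SNP ids, same order)")
  if (any(map$position < 0)) stop("SNP positions must be non-negative")
  map$chromosome <- as.character(map$chromosome)
  map$position <- as.integer(map$position)
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosage))
  cat("Genotype matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs\n")
  cat("  chromosomes:", length(unique(x$map$chromosome)),
      " missing calls:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / length(x$dosage)))
  invisible(x)
}

#' Individual and SNP identifiers of a genotype matrix
#'
#' @param g A [genotype_matrix()] object.
#' @return Character vector of ids.
#' @export
individual_ids <- function(g) rownames(g$dosage)

#' @rdname individual_ids
#' @export
snp_ids <- function(g) colnames(g$dosage)

# ---------------------------------------------------------------------------
# PLINK additive-dosage text ("raw", as written by plink --recode A)
# ---------------------------------------------------------------------------

#' Read genotypes from file
#'
#' Reads a genotype matrix either from a PLINK binary fileset (`.bed` +
#' `.bim` + `.fam`, SNP-major v1 format) or from PLINK additive-dosage text
#' (the `--recode A` "raw" layout: header `FID IID PAT MAT SEX PHENOTYPE`
#' followed by one `<snp>_<allele>` column per SNP, entries 0/1/2/NA).
#'
#' @param path For `"plink-bed"`, the fileset prefix or the `.bed` path (the
#'   `.bim`/`.fam` companions must sit alongside); for `"plink-raw"`, the text
#'   file.
#' @param format `"plink-bed"` or `"plink-raw"`.
#' @return A [genotype_matrix()]. For the raw format chromosome/position are
#'   not stored in the file and default to `"0"`/`0`.
#' @export
read_genotypes <- function(path, format = c("plink-bed", "plink-raw")) {
  format <- match.arg(format)
  switch(format,
         "plink-bed" = read_plink_bed(path),
         "plink-raw" = read_plink_raw(path))
}

read_plink_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 7L || !identical(header[1:6], fixed))
    stop("not a PLINK raw file (expected header starting 'FID IID PAT MAT SEX PHENOTYPE'): ",
         path)
  snp_cols <- header[-(1:6)]
  # column labels are <snp_id>_<counted allele>
  us <- regexpr("_[^_]*$", snp_cols)
  ids <- substr(snp_cols, 1L, us - 1L)
  counted <- substring(snp_cols, us + 1L)
  if (any(us < 1L) || any(!nzchar(ids)))
    stop("malformed SNP column label(s) in raw header: ",
         paste(utils::head(snp_cols[us < 1L | !nzchar(ids)], 3L), collapse = ", "))
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           colClasses = c(rep("character", 2L), rep("NULL", 4L),
                                          rep("character", length(snp_cols))),
                           na.strings = "NA")
  geno <- as.matrix(tab[, -(1:2), drop = FALSE])
  bad <- !is.na(geno) & !(geno %in% c("0", "1", "2"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid dosage token '%s' at data row %d, SNP column '%s' in %s",
                 geno[bad][1L], idx[1L], snp_cols[idx[2L]], path))
  }
  dosage <- matrix(as.integer(geno), nrow = nrow(geno),
                   dimnames = list(tab[[2L]], ids))
  map <- data.frame(snp_id = ids, chromosome = "0", position = 0L,
                    allele_counted = counted, allele_other = ".",
                    stringsAsFactors = FALSE)
  genotype_matrix(dosage, map)
}

#' Write genotypes as PLINK additive-dosage text
#'
#' @param g A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(g, path) {
  hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
           paste0(snp_ids(g), "_", g$map$allele_counted))
  body <- cbind(individual_ids(g), individual_ids(g), "0", "0", "0", "-9",
                ifelse(is.na(g$dosage), "NA", g$dosage))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = " "), con)
  utils::write.table(body, con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

# ---------------------------------------------------------------------------
# PLINK binary bed/bim/fam (v1, SNP-major, magic 0x6c 0x1b 0x01)
# ---------------------------------------------------------------------------

plink_prefix <- function(path) sub("\\.bed$", "", path)

read_plink_bed <- function(path) {
  prefix <- plink_prefix(path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)
  bim_tab <- utils::read.table(bim, header = FALSE, colClasses = "character")
  if (ncol(bim_tab) != 6L) stop("malformed .bim (expected 6 columns): ", bim)
  fam_tab <- utils::read.table(fam, header = FALSE, colClasses = "character")
  if (ncol(fam_tab) != 6L) stop("malformed .fam (expected 6 columns): ", fam)
  n <- nrow(fam_tab)
  p <- nrow(bim_tab)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("bad magic bytes at offset 0 of ", bed, " (not a PLINK v1 bed file)")
  if (raw[3L] != as.raw(0x01))
    stop("unsupported bed mode byte at offset 2 of ", bed,
         " (only SNP-major 0x01 supported)")
  bps <- ceiling(n / 4)               # bytes per SNP block
  if (length(raw) - 3L != bps * p)
    stop(sprintf("bed payload of %s is %d bytes; expected %d for %d individuals x %d SNPs",
                 bed, length(raw) - 3L, bps * p, n, p))
  codes <- matrix(0L, nrow = 4L * bps, ncol = p)
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bps)
  # unpack 2-bit genotype codes, least-significant pair first
  for (s in 0:3) {
    codes[seq.int(s + 1L, by = 4L, length.out = bps), ] <-
      body %% 4L
    body <- body %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of allele 1 (counted); 01 -> missing; 10 -> het; 11 -> 0
  dosage <- matrix(c(2L, NA_integer_, 1L, 0L)[codes + 1L], nrow = n,
                   dimnames = list(fam_tab[[2L]], bim_tab[[2L]]))
  map <- data.frame(snp_id = bim_tab[[2L]], chromosome = bim_tab[[1L]],
                    position = as.integer(bim_tab[[4L]]),
                    allele_counted = bim_tab[[5L]], allele_other = bim_tab[[6L]],
                    stringsAsFactors = FALSE)
  genotype_matrix(dosage, map)
}

#' Write genotypes as a PLINK bed/bim/fam fileset
#'
#' Writes the v1 SNP-major binary layout (magic bytes `0x6c 0x1b 0x01`). The
#' counted allele is written as allele 1 of the `.bim`.
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return `prefix`, invisibly.
#' @export
write_plink_bed <- function(g, prefix) {
  n <- nrow(g$dosage)
  p <- ncol(g$dosage)
  bim <- data.frame(g$map$chromosome, g$map$snp_id, 0L, g$map$position,
                    g$map$allele_counted, g$map$allele_other)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(individual_ids(g), individual_ids(g), 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  code_of <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  bps <- ceiling(n / 4)
  codes <- matrix(0L, nrow = 4L * bps, ncol = p)
  codes[seq_len(n), ] <- code_of(g$dosage)
  bytes <- codes[seq.int(1L, by = 4L, length.out = bps), , drop = FALSE] +
    4L * codes[seq.int(2L, by = 4L, length.out = bps), , drop = FALSE] +
    16L * codes[seq.int(3L, by = 4L, length.out = bps), , drop = FALSE] +
    64L * codes[seq.int(4L, by = 4L, length.out = bps), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
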