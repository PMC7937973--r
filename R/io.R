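#' Read and write landmark configurations as long-format TSV
#'
#' The on-disk format is one row per (individual, landmark):
#' `id, landmark_index, x, y, z`.
#'
#' @param configs n x p x 3 array of configurations.
#' @param ids Individual identifiers (default `ind0001`...).
#' @param path Output file.
#' @return `write_landmarks_tsv()` returns `path` invisibly;
#'   `read_landmarks_tsv()` returns a list with `configs` (n x p x 3) and
#'   `ids`.
#' @export
write_landmarks_tsv <- function(configs, path, ids = NULL) {
  n <- dim(configs)[1]; p <- dim(configs)[2]
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(n))
  long <- tibble(
    id = rep(ids, each = p),
    landmark_index = rep(seq_len(p), times = n),
    x = as.vector(t(configs[, , 1])),
    y = as.vector(t(configs[, , 2])),
    z = as.vector(t(configs[, , 3])))
  readr::write_tsv(long, path)
  invisible(path)
}

#' @rdname write_landmarks_tsv
#' @export
read_landmarks_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- unique(long$id)
  p <- max(long$landmark_index)
  configs <- array(NA_real_, dim = c(length(ids), p, 3))
  for (i in seq_along(ids)) {
    sub <- long[long$id == ids[i], ]
    sub <- sub[order(sub$landmark_index), ]
    configs[i, , ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  list(configs = configs, ids = ids)
}

#' Read and write GWAS summary statistics TSV
#'
#' Standard column dialect: SNP, CHR, BP, A1, A2, BETA, SE, P.
#'
#' @param sumstats Tibble in the dialect above.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write); reading rejects
#'   files missing any required column.
#' @export
write_sumstats_tsv <- function(sumstats, path) {
  readr::write_tsv(sumstats, path)
  invisible(path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  ss <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(CHR = readr::col_character()))
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P")
  missing <- setdiff(need, names(ss))
  if (length(missing))
    abort(paste("summary statistics missing columns:", paste(missing, collapse = ", ")))
  ss[, need]
}

#' Write simulated genotypes as a minimal VCF
#'
#' Emits VCFv4.2 with GT fields; the REF allele is the major allele (the
#' one the package's dosages count), ALT the minor. Hemizygous male X
#' genotypes are written as a single allele.
#'
#' @param genotypes An `endo_geno` object.
#' @param path Output `.vcf` path (plain text).
#' @param ids Sample identifiers.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, ids = NULL) {
  stopifnot(inherits(genotypes, "endo_geno"))
  n <- nrow(genotypes$dosages)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(n))
  m <- genotypes$snp_meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (j in seq_len(nrow(m))) {
    d <- genotypes$dosages[, j]           # major-allele count
    alt_count <- 2L - d                   # ALT = minor allele
    gt <- ifelse(alt_count == 2L, "1/1", ifelse(alt_count == 1L, "0/1", "0/0"))
    if (m$chrom[j] == "X") {
      male <- genotypes$sex == 1L
      gt[male] <- ifelse(alt_count[male] >= 1L, "1", "0")
    }
    writeLines(paste(c(m$chrom[j], m$pos[j], m$snp[j], m$a_major[j],
                       m$a_minor[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a segment hierarchy as TSV
#'
#' One row per segment: `segment_id, level, parent, size, landmarks`
#' (semicolon-separated indices).
#'
#' @param hierarchy An [spectral_hierarchy()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hierarchy_tsv <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "endo_hierarchy"))
  out <- dplyr::mutate(hierarchy$segments,
                       landmarks = vapply(.data$landmarks, paste, "", collapse = ";"))
  readr::write_tsv(out, path)
  invisible(path)
}
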