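# Genotype/phenotype ingestion, MAF filtering, standardization, tabular outputs.

#' Construct a genotype matrix object
#'
#' Bundles an N x k allele-dosage matrix with its SNP map and the allele-1
#' frequencies computed from the data. Dosages are counts of allele 1
#' (0/1/2 for called genotypes; mean-imputed values may be fractional).
#'
#' @param counts N x k numeric matrix of allele-1 dosages in \[0, 2\].
#' @param map data.frame with columns `chrom`, `pos` (1-based bp), `id`;
#'   one row per SNP, sorted by (chrom, pos). Reordered if not sorted.
#' @param ids optional character vector of individual ids (row names).
#' @return An object of class `genotype_matrix`: list with elements
#'   `counts`, `map`, `freq`, `ids`.
#' @export
genotype_matrix <- function(counts, map, ids = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("genotype dosages must be finite and non-missing after ingestion")
  }
  if (any(counts < 0 | counts > 2)) {
    stop("genotype dosages must lie in [0, 2]")
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "id") %in% names(map))) {
    stop("map must have columns chrom, pos, id")
  }
  if (nrow(map) != ncol(counts)) {
    stop("map rows (", nrow(map), ") != genotype columns (", ncol(counts), ")")
  }
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    counts <- counts[, ord, drop = FALSE]
  }
  rownames(map) <- NULL
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(counts)))
  g <- list(counts = counts, map = map, freq = colMeans(counts) / 2, ids = ids)
  class(g) <- "genotype_matrix"
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$map$chrom))
  ))
  invisible(x)
}

#' Read genotypes from VCF or plain matrix format
#'
#' VCF input keeps biallelic SNP records only (multi-allelic or non-SNP
#' records are skipped with a message); allele 1 is the ALT allele.
#' Missing genotypes (`./.`) are imputed to the column mean dosage `2p`
#' computed from the non-missing calls, and the per-file missingness rate
#' is reported. The matrix format is a whitespace-delimited N x k table of
#' {0,1,2} plus a 3-column map file (chrom, pos, id).
#'
#' @param path genotype file.
#' @param format `"vcf"`, `"matrix"`, or `"auto"` (by file extension).
#' @param map_path SNP map file, required for `format = "matrix"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "matrix"
  }
  if (format == "vcf") .read_genotypes_vcf(path) else {
    .read_genotypes_matrix(path, map_path)
  }
}

.read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  nalt <- S4Vectors::elementNROWS(rr$ALT)
  altc <- rep(NA_character_, length(nalt))
  altc[nalt == 1L] <- as.character(unlist(rr$ALT[nalt == 1L]))
  keep <- nalt == 1L & nchar(ref) == 1L & !is.na(altc) & nchar(altc) == 1L
  n_skip <- sum(!keep)
  if (n_skip > 0L) {
    message("read_genotypes: skipped ", n_skip, " non-biallelic/non-SNP record(s)")
  }
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  # alt-allele dosage from GT strings; tolerate phased separators
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
           "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2)
  dos <- matrix(unname(lut[gt]), nrow = nrow(gt), ncol = ncol(gt))
  miss <- is.na(dos)
  if (any(miss)) {
    message(sprintf("read_genotypes: %.3f%% missing genotypes mean-imputed",
                    100 * mean(miss)))
    rowmean <- rowMeans(dos, na.rm = TRUE)
    if (anyNA(rowmean)) stop("SNP(s) with all genotypes missing")
    dos[miss] <- rowmean[row(dos)[miss]]
  }
  map <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    id = rownames(vcf)[keep],
    stringsAsFactors = FALSE
  )
  genotype_matrix(t(dos), map, ids = colnames(gt))
}

.read_genotypes_matrix <- function(path, map_path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(map_path) || !file.exists(map_path)) {
    stop("matrix format requires an existing map_path")
  }
  counts <- as.matrix(data.table::fread(path, header = FALSE))
  if (anyNA(counts)) stop("non-rectangular or non-numeric genotype matrix: ", path)
  map <- data.table::fread(map_path, header = FALSE,
                           col.names = c("chrom", "pos", "id"),
                           colClasses = list(character = c(1L, 3L)))
  genotype_matrix(counts, as.data.frame(map))
}

#' Write genotypes in the plain matrix format
#'
#' @param g a [genotype_matrix()].
#' @param path output path for the N x k dosage table.
#' @param map_path output path for the 3-column map.
#' @export
write_genotype_matrix <- function(g, path, map_path) {
  stopifnot(inherits(g, "genotype_matrix"))
  data.table::fwrite(data.table::as.data.table(g$counts), path,
                     sep = " ", col.names = FALSE)
  data.table::fwrite(g$map[, c("chrom", "pos", "id")], map_path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write genotypes as an uncompressed VCF 4.2 file
#'
#' Dosages must be integral (0/1/2): allele 1 is written as ALT with
#' placeholder REF/ALT bases A/T.
#'
#' @param g a [genotype_matrix()].
#' @param path output `.vcf` path.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  cnt <- round(g$counts)
  if (max(abs(cnt - g$counts)) > 1e-9) {
    stop("write_vcf requires integral dosages (no imputed values)")
  }
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=svdbayesc",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$ids), collapse = "\t")
  ), con)
  body <- matrix(gt_code[cnt + 1L], nrow = nrow(cnt))
  lines <- paste(g$map$chrom, g$map$pos, g$map$id, "A", "T", ".", ".", ".",
                 "GT", apply(body, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a two-column phenotype table (id, value)
#'
#' @param path TSV with individual id and phenotypic value, no header or a
#'   header starting with a non-numeric second field.
#' @param ids optional genotype ids; phenotypes are reordered to match and
#'   completeness is enforced.
#' @return list with `ids` and numeric `y`.
#' @export
read_phenotypes <- function(path, ids = NULL) {
  ph <- as.data.frame(data.table::fread(path, header = FALSE,
                                        col.names = c("id", "value"),
                                        colClasses = list(character = 1L)))
  if (is.character(ph$value)) { # header line present
    ph <- ph[-1L, , drop = FALSE]
    ph$value <- as.numeric(ph$value)
  }
  if (anyNA(ph$value) || any(!is.finite(ph$value))) {
    stop("phenotypes must be finite")
  }
  if (!is.null(ids)) {
    idx <- match(ids, ph$id)
    if (anyNA(idx)) stop("phenotypes missing for ", sum(is.na(idx)), " id(s)")
    ph <- ph[idx, , drop = FALSE]
  }
  list(ids = ph$id, y = ph$value)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains exactly the columns with `min(p, 1 - p) > threshold`, matching
#' the convention of keeping SNPs with MAF strictly higher than the cutoff.
#'
#' @param g a [genotype_matrix()].
#' @param threshold MAF cutoff in `[0, 0.5)`; default 0.01.
#' @return filtered [genotype_matrix()].
#' @export
filter_maf <- function(g, threshold = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (threshold < 0 || threshold >= 0.5) stop("threshold must be in [0, 0.5)")
  maf <- pmin(g$freq, 1 - g$freq)
  keep <- maf > threshold
  if (!any(keep)) stop("no SNPs pass MAF threshold ", threshold)
  genotype_matrix(g$counts[, keep, drop = FALSE],
                  g$map[keep, , drop = FALSE], ids = g$ids)
}

#' Standardize genotypes
#'
#' Column j is coded so that dosages 0, 1 and 2 map to
#' `-2p/sqrt(2p(1-p))`, `(1-2p)/sqrt(2p(1-p))` and `(2-2p)/sqrt(2p(1-p))`,
#' where `p` is the frequency of allele 1. When `freq` is taken from the
#' data itself each column has mean zero; supplying reference-population
#' frequencies (for descendant genotypes) keeps effect estimates on the
#' training scale.
#'
#' @param g a [genotype_matrix()].
#' @param freq per-SNP allele-1 frequencies; defaults to `g$freq`
#'   (frequencies computed from the data). All must lie strictly in (0, 1).
#' @return An object of class `std_geno`: list with `X` (N x k numeric),
#'   `map`, `freq`, `ids`.
#' @export
standardize <- function(g, freq = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- if (is.null(freq)) g$freq else freq
  if (length(p) != ncol(g$counts)) stop("freq length mismatch")
  if (any(p <= 0 | p >= 1)) {
    stop("cannot standardize monomorphic SNPs (p in {0,1}); filter first")
  }
  scale <- sqrt(2 * p * (1 - p))
  X <- sweep(g$counts, 2L, 2 * p, "-")
  X <- sweep(X, 2L, scale, "/")
  out <- list(X = X, map = g$map, freq = p, ids = g$ids)
  class(out) <- "std_geno"
  out
}

#' @export
print.std_geno <- function(x, ...) {
  cat(sprintf("std_geno: %d x %d standardized genotype matrix\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Write the per-SNP report
#'
#' TSV with header `snp_id chrom pos freq b_hat pev llr pp d_weight`;
#' numeric columns round-trip at better than 12 significant digits.
#'
#' @param map SNP map (`chrom`, `pos`, `id`).
#' @param freq,b_hat,pev,llr,pp,d_weight per-SNP columns; the last four
#'   may be omitted (written as NA) for a plain SNP-BLUP report.
#' @param path output path.
#' @export
write_snp_report <- function(map, freq, b_hat, pev,
                             llr = NULL, pp = NULL, d_weight = NULL, path) {
  k <- nrow(map)
  fill <- function(x) if (is.null(x)) rep(NA_real_, k) else x
  cols <- list(freq = freq, b_hat = b_hat, pev = fill(pev),
               llr = fill(llr), pp = fill(pp), d_weight = fill(d_weight))
  if (any(vapply(cols, length, 1L) != k)) {
    stop("column lengths do not match the SNP map")
  }
  dt <- data.table::data.table(
    snp_id = map$id, chrom = map$chrom, pos = map$pos,
    freq = cols$freq, b_hat = cols$b_hat, pev = cols$pev,
    llr = cols$llr, pp = cols$pp, d_weight = cols$d_weight
  )
  data.table::fwrite(dt, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read back a per-SNP report written by [write_snp_report()]
#' @param path report path.
#' @return data.frame of the report columns.
#' @export
read_snp_report <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write genomic estimated breeding values
#'
#' TSV with header `id generation gebv`.
#'
#' @param ids individual ids.
#' @param generation integer generation labels (same length or scalar).
#' @param gebv estimated breeding values.
#' @param path output path.
#' @export
write_gebv <- function(ids, generation, gebv, path) {
  if (length(generation) == 1L) generation <- rep(generation, length(ids))
  if (length(ids) != length(gebv) || length(ids) != length(generation)) {
    stop("ids, generation and gebv lengths differ")
  }
  data.table::fwrite(
    data.table::data.table(id = ids, generation = generation, gebv = gebv),
    path, sep = "\t"
  )
  invisible(path)
}
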