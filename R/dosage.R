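#' Biallelic SNP dosage matrices
#'
#' A `dosage_matrix` is a genotypes-by-markers numeric matrix with values
#' in {0, 1, 2} or `NA` (missing). After mean imputation fractional
#' dosages are allowed and the object carries `imputed = TRUE`. Optional
#' per-marker metadata (chromosome, position) supports base-pair LD
#' pruning windows.
#'
#' @param values numeric matrix, genotypes in rows, markers in columns,
#'   with dimnames.
#' @param marker_meta optional data.frame with columns `marker`, `chrom`,
#'   `pos` covering (at least) all markers in `values`.
#' @param imputed logical; when `FALSE` (default) values are checked to be
#'   0/1/2/NA.
#' @return a `dosage_matrix`.
#' @export
dosage_matrix <- function(values, marker_meta = NULL, imputed = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("dosage_matrix requires genotype rownames and marker colnames")
  }
  if (anyDuplicated(colnames(values))) stop("duplicated marker ids")
  if (anyDuplicated(rownames(values))) stop("duplicated genotype ids")
  storage.mode(values) <- "double"
  if (!imputed) {
    v <- values[!is.na(values)]
    if (length(v) > 0 && !all(v %in% c(0, 1, 2))) {
      stop("raw dosages must be 0, 1, 2 or NA; use imputed = TRUE for fractional values")
    }
  }
  if (!is.null(marker_meta)) {
    need <- c("marker", "chrom", "pos")
    if (!all(need %in% names(marker_meta))) {
      stop("marker_meta needs columns marker, chrom, pos")
    }
    miss <- setdiff(colnames(values), marker_meta$marker)
    if (length(miss) > 0) {
      stop("marker_meta is missing markers: ", paste(utils::head(miss, 5), collapse = ", "))
    }
    marker_meta <- marker_meta[match(colnames(values), marker_meta$marker), , drop = FALSE]
    rownames(marker_meta) <- NULL
  }
  structure(values, class = c("dosage_matrix", "matrix", "array"),
            marker_meta = marker_meta, imputed = imputed)
}

#' @rdname dosage_matrix
#' @param x a `dosage_matrix`.
#' @export
marker_meta <- function(x) attr(x, "marker_meta")

#' @rdname dosage_matrix
#' @export
is_imputed <- function(x) isTRUE(attr(x, "imputed"))

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix: %d genotypes x %d markers, %.1f%% missing%s>\n",
              nrow(x), ncol(x), 100 * mean(is.na(x)),
              if (is_imputed(x)) ", imputed" else ""))
  invisible(x)
}

#' Subset a dosage matrix by genotype and/or marker ids
#'
#' Keeps marker metadata and the imputation flag consistent.
#'
#' @param d a [dosage_matrix].
#' @param genotypes,markers identifiers to keep, in the requested order.
#' @export
subset_dosage <- function(d, genotypes = rownames(d), markers = colnames(d)) {
  meta <- marker_meta(d)
  if (!is.null(meta)) meta <- meta[meta$marker %in% markers, , drop = FALSE]
  dosage_matrix(unclass(d)[genotypes, markers, drop = FALSE],
                marker_meta = meta, imputed = is_imputed(d))
}

#' Read / write dosage TSV
#'
#' Genotypes as rows, markers as columns; header row carries marker ids,
#' first column (`id`) the genotype id; missing calls are `NA`.
#'
#' @param path file path.
#' @param marker_meta optional marker metadata (see [dosage_matrix()]).
#' @export
read_dosage_tsv <- function(path, marker_meta = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  frac <- any(!is.na(m) & m != round(m))
  dosage_matrix(m, marker_meta = marker_meta, imputed = frac)
}

#' @rdname read_dosage_tsv
#' @param d a `dosage_matrix`.
#' @export
write_dosage_tsv <- function(d, path) {
  df <- data.frame(id = rownames(d), unclass(d), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read dosages from a VCF file
#'
#' Biallelic sites only; the dosage is the alternate-allele count taken
#' from the GT field (0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> missing).
#' Multi-allelic sites are rejected and counted in a message. Requires the
#' VariantAnnotation package.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a `dosage_matrix` (genotypes = samples) with marker metadata
#'   from CHROM/POS.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_dosage_vcf requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- lengths(VariantAnnotation::alt(vcf))
  multi <- nalt != 1L
  if (any(multi)) {
    message(sum(multi), " multi-allelic site(s) rejected")
    vcf <- vcf[!multi, ]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  conv <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0")] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% c("1/1")] <- 2
    out
  }
  m <- apply(gt, 2, conv)
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(gt))
  dimnames(m) <- dimnames(gt)
  rr <- SummarizedExperiment::rowRanges(vcf)
  meta <- data.frame(marker = rownames(gt),
                     chrom = as.character(GenomeInfoDb::seqnames(rr)),
                     pos = BiocGenerics::start(rr),
                     stringsAsFactors = FALSE)
  dosage_matrix(t(m), marker_meta = meta)
}
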