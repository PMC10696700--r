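#' Labeled relationship / distance matrices
#'
#' A `relmat` is a square numeric matrix with genotype identifiers as
#' dimnames and a `kind` attribute recording what the values mean:
#' \describe{
#'   \item{A}{pedigree-based (expected IBD) additive relationships}
#'   \item{A22}{the genotyped-by-genotyped block of A}
#'   \item{G}{VanRaden genomic relationships (realized IBS)}
#'   \item{Ga}{G rescaled to the pedigree base}
#'   \item{H}{hybrid pedigree-genomic relationships}
#'   \item{Hcor}{H converted to a correlation matrix}
#'   \item{D}{scaled distances derived from Hcor}
#'   \item{Astar}{directional individual-to-ancestor relationships}
#'   \item{IBD}{realized IBD from gene-dropping simulation}
#' }
#'
#' All kinds except `Astar` are symmetric. `Astar` keeps, per row, only the
#' relationships of an individual with its own ancestors and is therefore
#' directional.
#'
#' @param values square numeric matrix.
#' @param kind one of `"A"`, `"A22"`, `"G"`, `"Ga"`, `"H"`, `"Hcor"`,
#'   `"D"`, `"Astar"`, `"IBD"`.
#' @param ids character identifiers; defaults to `rownames(values)`.
#' @return a `relmat` object.
#' @export
relmat <- function(values, kind, ids = rownames(values)) {
  kind <- match.arg(kind, c("A", "A22", "G", "Ga", "H", "Hcor", "D", "Astar", "IBD"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("relmat values must be square, got ", nrow(values), "x", ncol(values))
  }
  if (is.null(ids)) {
    if (nrow(values) > 0) stop("relmat requires ids (or rownames on values)")
    ids <- character(0)
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicated ids in relmat: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(ids) != nrow(values)) stop("ids length does not match matrix dimension")
  dimnames(values) <- list(ids, ids)
  if (kind != "Astar" && nrow(values) > 1) {
    asym <- max(abs(values - t(values)))
    if (asym > 1e-6) stop("relmat of kind ", kind, " must be symmetric (max asymmetry ", format(asym), ")")
    values <- (values + t(values)) / 2
  }
  structure(values, class = c("relmat", "matrix", "array"), kind = kind)
}

#' @rdname relmat
#' @param x a `relmat`.
#' @export
relmat_kind <- function(x) attr(x, "kind")

#' @rdname relmat
#' @export
relmat_ids <- function(x) rownames(x)

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("<relmat kind=%s, %d genotypes>\n", relmat_kind(x), nrow(x)))
  m <- unclass(x)
  attr(m, "kind") <- NULL
  if (nrow(m) > 8) {
    print(m[1:8, 1:8, drop = FALSE], ...)
    cat("... (", nrow(x), "rows total )\n")
  } else {
    print(m, ...)
  }
  invisible(x)
}

#' Subset a relationship matrix to a set of ids
#'
#' Keeps the `kind` tag; rows and columns are returned in the order of
#' `ids`.
#'
#' @param x a `relmat`.
#' @param ids identifiers, all present in `x`.
#' @export
relmat_subset <- function(x, ids) {
  ids <- as.character(ids)
  miss <- setdiff(ids, relmat_ids(x))
  if (length(miss) > 0) {
    stop("ids absent from relationship matrix: ", paste(miss, collapse = ", "))
  }
  relmat(unclass(x)[ids, ids, drop = FALSE], kind = relmat_kind(x))
}

#' Write / read a relationship matrix as TSV
#'
#' The format is a full square matrix with ids as the first row and first
#' column. The `kind` tag is stored in a `#kind=` comment line above the
#' header so that files round-trip exactly.
#'
#' @param x a `relmat`.
#' @param path output file path.
#' @export
write_relmat <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind=", relmat_kind(x)), con)
  ids <- relmat_ids(x)
  writeLines(paste(c("id", ids), collapse = "\t"), con)
  m <- unclass(x)
  for (i in seq_along(ids)) {
    writeLines(paste(c(ids[i], format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- "A"
  skip <- 0L
  if (startsWith(first, "#kind=")) {
    kind <- sub("^#kind=", "", first)
    skip <- 1L
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                           check.names = FALSE, colClasses = NA,
                           comment.char = "", stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  relmat(m, kind = kind, ids = ids)
}
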