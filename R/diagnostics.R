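#' Overall correlation between two relationship matrices
#'
#' Pearson correlation over the strict upper triangle (diagonal and
#' symmetric duplicates excluded); self-relationships vary little and
#' would inflate the correlation if included.
#'
#' @param A22,Ga [relmat] objects with identical ids in identical order.
#' @param include_diagonal include the diagonal in the correlation
#'   (non-default convention, exposed for comparability).
#' @return Pearson correlation coefficient.
#' @export
matrix_correlation <- function(A22, Ga, include_diagonal = FALSE) {
  if (!identical(relmat_ids(A22), relmat_ids(Ga))) {
    stop("matrices must share identical ids in identical order")
  }
  a <- unclass(A22); g <- unclass(Ga)
  sel <- upper.tri(a, diag = include_diagonal)
  x <- a[sel]; y <- g[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant relationship values; correlation undefined")
  }
  stats::cor(x, y)
}

#' Per-genotype correlation between pedigree and genomic relationships
#'
#' For each genotype, the Pearson correlation between its column of A22
#' and its column of Ga, excluding the self entry. Genotypes whose
#' column is constant in either matrix get `NA` with a warning. With very
#' few genotypes the correlations rest on few points; they are still
#' returned (the caller sees the support as `length(ids) - 1`).
#'
#' @inheritParams matrix_correlation
#' @return named numeric vector of correlations (may contain `NA`).
#' @export
per_genotype_correlation <- function(A22, Ga) {
  if (!identical(relmat_ids(A22), relmat_ids(Ga))) {
    stop("matrices must share identical ids in identical order")
  }
  ids <- relmat_ids(A22)
  if (length(ids) < 3) stop("need >= 3 genotypes for per-genotype correlations")
  a <- unclass(A22); g <- unclass(Ga)
  out <- vapply(seq_along(ids), function(i) {
    x <- a[-i, i]; y <- g[-i, i]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  names(out) <- ids
  if (anyNA(out)) {
    warning("constant column(s); correlation undefined for: ",
            paste(ids[is.na(out)], collapse = ", "))
  }
  out
}

#' Flag pedigree-vs-genomic outlier pairs
#'
#' Unordered pairs whose pedigree and genomic relationships disagree
#' strongly: pedigree > `high` with genomic < `low`, or pedigree < `low`
#' with genomic > `high`. Such pairs typically indicate sample swaps or
#' missing/incorrect pedigree records.
#'
#' @inheritParams matrix_correlation
#' @param high,low thresholds, defaults 0.8 and 0.2.
#' @return data.frame with columns `id1`, `id2`, `pedigree`, `genomic`.
#' @export
flag_pair_outliers <- function(A22, Ga, high = 0.8, low = 0.2) {
  if (!identical(relmat_ids(A22), relmat_ids(Ga))) {
    stop("matrices must share identical ids in identical order")
  }
  a <- unclass(A22); g <- unclass(Ga)
  sel <- which(upper.tri(a) & ((a > high & g < low) | (a < low & g > high)),
               arr.ind = TRUE)
  ids <- relmat_ids(A22)
  data.frame(id1 = ids[sel[, 1]], id2 = ids[sel[, 2]],
             pedigree = a[sel], genomic = g[sel],
             stringsAsFactors = FALSE)
}

#' Flag outlier genotypes
#'
#' Genotypes whose pedigree is well recorded (completeness above
#' `completeness_min`) yet whose pedigree and genomic relationship
#' profiles barely correlate (below `corr_max`): prime suspects for
#' sample swaps or wrong pedigree entries.
#'
#' @param per_genotype_corr named correlations from
#'   [per_genotype_correlation()].
#' @param completeness named completeness from
#'   [pedigree_completeness()]; must cover the same ids.
#' @param corr_max flag below this correlation, default 0.2.
#' @param completeness_min flag above this completeness, default 5.
#' @return character ids of flagged genotypes.
#' @export
flag_genotype_outliers <- function(per_genotype_corr, completeness,
                                   corr_max = 0.2, completeness_min = 5) {
  ids <- names(per_genotype_corr)
  if (!all(ids %in% names(completeness))) {
    stop("completeness is missing ids: ",
         paste(setdiff(ids, names(completeness)), collapse = ", "))
  }
  comp <- completeness[ids]
  flagged <- !is.na(per_genotype_corr) & per_genotype_corr < corr_max &
    comp > completeness_min
  sort(ids[flagged])
}

#' Marker-subsampling reliability of the G matrix
#'
#' How many markers are needed for stable genomic relationships? For
#' each subset size, markers are repeatedly drawn uniformly without
#' replacement, the G matrix is recomputed on the subset, and its Pearson
#' correlation (strict upper triangle) with the full-marker G is
#' recorded. The report includes, per size, all replicate correlations,
#' their median and minimum, and the smallest size whose minimum
#' correlation reaches `threshold`.
#'
#' @param d an imputed [dosage_matrix].
#' @param sizes marker subset sizes (default 50 to 3000 in steps of 50,
#'   truncated to the available marker count).
#' @param reps replicates per size, default 200.
#' @param seed integer seed; the analysis is bit-reproducible given the
#'   seed.
#' @param threshold reliability target, default 0.95.
#' @return a `subsample_report`: list with `sizes`, `correlations`
#'   (reps x sizes matrix), `median`, `min`, `threshold`,
#'   `min_size_reliable`.
#' @export
subsample_analysis <- function(d, sizes = seq(50, 3000, by = 50), reps = 200,
                               seed, threshold = 0.95) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(d, "dosage_matrix"))
  if (anyNA(unclass(d))) stop("subsample_analysis requires imputed dosages")
  p <- ncol(d)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes > p)) stop("subset size exceeds marker count (", p, ")")
  Gfull <- unclass(vanraden_g(d))
  ref <- Gfull[upper.tri(Gfull)]
  set.seed(as.integer(seed %% .Machine$integer.max))
  cors <- matrix(NA_real_, nrow = reps, ncol = length(sizes),
                 dimnames = list(NULL, sizes))
  for (j in seq_along(sizes)) {
    for (r in seq_len(reps)) {
      mk <- sample(p, sizes[j])
      Gs <- suppressWarnings(vanraden_g(subset_dosage(d, markers = colnames(d)[mk])))
      gs <- unclass(Gs)[upper.tri(Gfull)]
      cors[r, j] <- stats::cor(ref, gs)
    }
  }
  med <- apply(cors, 2, stats::median)
  mn <- apply(cors, 2, min)
  reliable <- sizes[mn >= threshold]
  structure(list(sizes = sizes, correlations = cors, median = med, min = mn,
                 threshold = threshold,
                 min_size_reliable = if (length(reliable)) min(reliable) else NA_integer_),
            class = "subsample_report")
}

#' @export
print.subsample_report <- function(x, ...) {
  cat(sprintf("<subsample_report: %d sizes x %d reps; smallest size with min r >= %g: %s>\n",
              length(x$sizes), nrow(x$correlations), x$threshold,
              ifelse(is.na(x$min_size_reliable), "none", x$min_size_reliable)))
  invisible(x)
}

#' Principal components of a relationship matrix
#'
#' Classical multidimensional scaling on the relationship kernel: the
#' matrix is double-centered and eigendecomposed; coordinates are
#' eigenvectors scaled by the square root of their eigenvalues, and the
#' explained-variance fraction of an axis is its eigenvalue over the
#' trace of the centered matrix.
#'
#' @param M a symmetric [relmat] (H, G, A, ...).
#' @param axes number of axes to return, default 2.
#' @return list with `coordinates` (genotypes x axes) and
#'   `explained_variance` (fractions, non-increasing).
#' @export
pca_relationship <- function(M, axes = 2) {
  m <- unclass(M)
  if (max(abs(m - t(m))) > 1e-8) stop("relationship matrix must be symmetric")
  n <- nrow(m)
  axes <- min(axes, n)
  J <- diag(n) - matrix(1 / n, n, n)
  C <- J %*% m %*% J
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  coords <- e$vectors[, seq_len(axes), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(axes)]), axes)
  rownames(coords) <- relmat_ids(M)
  colnames(coords) <- paste0("PC", seq_len(axes))
  list(coordinates = coords,
       explained_variance = (e$values / sum(diag(C)))[seq_len(axes)])
}
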