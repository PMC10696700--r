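#' Filter markers on minor allele frequency and missingness
#'
#' A marker is kept iff its missing fraction is at most `miss_max` and its
#' minor allele frequency, computed on non-missing calls, is at least
#' `maf_min`. Defaults follow common SNP-array curation practice for
#' breeding germplasm: MAF >= 0.05 and missing data <= 10%.
#'
#' @param d a [dosage_matrix] (raw calls; filters operate before
#'   imputation).
#' @param maf_min minimum minor allele frequency, in \[0, 0.5\].
#' @param miss_max maximum missing fraction, in \[0, 1\].
#' @return list with `dosage` (filtered [dosage_matrix]) and `report`
#'   (a [curation_report] step table).
#' @export
filter_markers <- function(d, maf_min = 0.05, miss_max = 0.10) {
  stopifnot(inherits(d, "dosage_matrix"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (miss_max < 0 || miss_max > 1) stop("miss_max must be in [0, 1]")
  m <- unclass(d)
  missfrac <- colMeans(is.na(m))
  p <- colMeans(m, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_           # all-missing marker
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & missfrac <= miss_max & maf >= maf_min
  if (!any(keep)) {
    stop("all markers removed by MAF/missingness filtering; review maf_min (",
         maf_min, ") and miss_max (", miss_max, ")")
  }
  out <- subset_dosage(d, markers = colnames(m)[keep])
  rep <- curation_report(
    step = c("input", sprintf("MAF >= %g and missing <= %g%%", maf_min, 100 * miss_max)),
    n_markers = c(ncol(d), ncol(out)),
    n_genotypes = c(nrow(d), nrow(out)))
  list(dosage = out, report = rep)
}

#' Curation step tables
#'
#' Records markers and genotypes retained after each curation step, in
#' the layout of a per-step SNP count table. Marker counts must be
#' non-increasing across filter steps.
#'
#' @param step character step labels.
#' @param n_markers,n_genotypes integer counts per step.
#' @export
curation_report <- function(step, n_markers, n_genotypes) {
  df <- data.frame(step = step, n_markers = as.integer(n_markers),
                   n_genotypes = as.integer(n_genotypes), stringsAsFactors = FALSE)
  structure(df, class = c("curation_report", "data.frame"))
}

#' @rdname curation_report
#' @param ... `curation_report`s to concatenate in pipeline order.
#' @export
bind_reports <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(df) <- NULL
  structure(df, class = c("curation_report", "data.frame"))
}

#' Mean-impute missing dosages
#'
#' Replaces each missing call by the mean dosage of its marker over
#' non-missing calls; imputed values may be fractional. Downstream
#' relationship computations treat these as expected dosages.
#'
#' @param d a [dosage_matrix]; every marker needs at least one
#'   non-missing call.
#' @return an imputed [dosage_matrix] with no missing values.
#' @export
mean_impute <- function(d) {
  stopifnot(inherits(d, "dosage_matrix"))
  m <- unclass(d)
  mu <- colMeans(m, na.rm = TRUE)
  bad <- colnames(m)[is.nan(mu)]
  if (length(bad) > 0) {
    stop("marker(s) with no non-missing calls cannot be imputed: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx) > 0) m[na_idx] <- mu[na_idx[, 2]]
  dosage_matrix(m, marker_meta = marker_meta(d), imputed = TRUE)
}

#' Greedy LD pruning of markers
#'
#' Scans markers left to right; each retained marker eliminates all later
#' markers within the window whose squared Pearson correlation of dosages
#' exceeds `r2_max`. The surviving set is deterministic given the marker
#' order ("first kept wins"). With `window_type = "bp"` the window is in
#' base pairs on the same chromosome (requires marker metadata); with
#' `"markers"` it is a count of subsequent markers.
#'
#' Zero-variance (monomorphic) markers have undefined correlation and are
#' dropped up front with a warning.
#'
#' @param d an imputed [dosage_matrix] (no missing values).
#' @param r2_max maximum squared correlation tolerated between retained
#'   markers, default 0.5.
#' @param window window size, default 50 markers.
#' @param window_type `"markers"` or `"bp"`.
#' @return the pruned [dosage_matrix].
#' @export
ld_prune <- function(d, r2_max = 0.5, window = 50, window_type = c("markers", "bp")) {
  stopifnot(inherits(d, "dosage_matrix"))
  window_type <- match.arg(window_type)
  m <- unclass(d)
  if (anyNA(m)) stop("ld_prune requires imputed dosages (no missing values)")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance marker(s) dropped (correlation undefined)")
    m <- m[, v > 0, drop = FALSE]
  }
  meta <- marker_meta(d)
  if (window_type == "bp") {
    if (is.null(meta)) stop("bp windows require marker metadata (chrom, pos)")
    meta <- meta[match(colnames(m), meta$marker), , drop = FALSE]
    ord <- order(meta$chrom, meta$pos)
    m <- m[, ord, drop = FALSE]
    meta <- meta[ord, , drop = FALSE]
  }
  p <- ncol(m)
  keep <- rep(TRUE, p)
  for (i in seq_len(p)) {
    if (!keep[i]) next
    if (window_type == "markers") {
      j <- seq(i + 1L, min(p, i + window))
    } else {
      j <- which(meta$chrom == meta$chrom[i] &
                 meta$pos > meta$pos[i] & meta$pos - meta$pos[i] <= window)
    }
    j <- j[j > i & j <= p & keep[j]]
    if (length(j) == 0) next
    r <- suppressWarnings(stats::cor(m[, i], m[, j, drop = FALSE]))
    keep[j[!is.na(r) & r^2 > r2_max]] <- FALSE
  }
  subset_dosage(dosage_matrix(m, marker_meta = meta, imputed = is_imputed(d)),
                markers = colnames(m)[keep])
}

#' Merge two genotyping platforms on concordant markers
#'
#' For every marker shared by both platforms, the Pearson correlation of
#' dosages across the genotypes present in both is computed. Markers are
#' retained when the squared correlation (default mode, `"r2"`) or the
#' raw correlation (mode `"r"`) reaches `min_concordance`. The merged
#' matrix covers the union of genotypes on the retained markers, with
#' `d1` taking precedence for genotypes present in both platforms.
#'
#' @param d1,d2 [dosage_matrix] objects (raw calls allowed; correlations
#'   use pairwise-complete observations).
#' @param min_concordance concordance threshold, default 0.7.
#' @param mode `"r2"` (threshold applies to the squared correlation) or
#'   `"r"`.
#' @return list with `dosage` (merged), `concordance` (named numeric per
#'   shared marker) and `report`.
#' @export
merge_platforms <- function(d1, d2, min_concordance = 0.7, mode = c("r2", "r")) {
  stopifnot(inherits(d1, "dosage_matrix"), inherits(d2, "dosage_matrix"))
  mode <- match.arg(mode)
  overlap <- intersect(rownames(d1), rownames(d2))
  if (length(overlap) == 0) stop("no overlapping genotypes between platforms")
  if (length(overlap) < 2) stop("need >= 2 overlapping genotypes to compute concordance")
  shared <- intersect(colnames(d1), colnames(d2))
  if (length(shared) == 0) stop("no shared markers between platforms")
  x1 <- unclass(d1)[overlap, shared, drop = FALSE]
  x2 <- unclass(d2)[overlap, shared, drop = FALSE]
  conc <- vapply(seq_along(shared), function(k) {
    ok <- !is.na(x1[, k]) & !is.na(x2[, k])
    if (sum(ok) < 2) return(NA_real_)
    suppressWarnings(stats::cor(x1[ok, k], x2[ok, k]))
  }, numeric(1))
  names(conc) <- shared
  pass <- if (mode == "r2") !is.na(conc) & conc^2 >= min_concordance
          else !is.na(conc) & conc >= min_concordance
  kept <- shared[pass]
  if (length(kept) == 0) stop("no markers pass the concordance threshold")
  only2 <- setdiff(rownames(d2), rownames(d1))
  merged <- rbind(unclass(d1)[, kept, drop = FALSE],
                  unclass(d2)[only2, kept, drop = FALSE])
  meta <- marker_meta(d1)
  if (is.null(meta)) meta <- marker_meta(d2)
  if (!is.null(meta)) meta <- meta[meta$marker %in% kept, , drop = FALSE]
  out <- dosage_matrix(merged, marker_meta = meta,
                       imputed = is_imputed(d1) || is_imputed(d2))
  rep <- curation_report(
    step = c("platform 1", "platform 2",
             sprintf("merge platforms (%s >= %g)", mode, min_concordance)),
    n_markers = c(ncol(d1), ncol(d2), ncol(out)),
    n_genotypes = c(nrow(d1), nrow(d2), nrow(out)))
  list(dosage = out, concordance = conc, report = rep)
}

#' VanRaden genomic relationship matrix
#'
#' Computes \eqn{G = Z Z' / (2 \sum_i p_i (1 - p_i))} where
#' \eqn{Z = M - 2P}, M is the (imputed) dosage matrix and \eqn{p_i} the
#' observed alternate-allele frequency of marker i in the analyzed set
#' itself. Monomorphic markers contribute nothing to either numerator or
#' denominator and are excluded with a warning.
#'
#' @param d an imputed [dosage_matrix] with at least one polymorphic
#'   marker.
#' @return a [relmat] of kind `"G"` over the genotypes of `d`.
#' @export
vanraden_g <- function(d) {
  stopifnot(inherits(d, "dosage_matrix"))
  m <- unclass(d)
  if (anyNA(m)) stop("vanraden_g requires imputed dosages (no missing values)")
  p <- colMeans(m) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; G denominator is zero")
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic marker(s) excluded from G")
    m <- m[, poly, drop = FALSE]
    p <- p[poly]
  }
  Z <- sweep(m, 2, 2 * p, "-")
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  relmat(G, kind = "G", ids = rownames(m))
}
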