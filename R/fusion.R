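#' Rescale G to the pedigree base (Ga = beta * G + alpha)
#'
#' Pedigree and genomic relationships estimate the same quantities on
#' different bases: G is centered on the current allele frequencies while
#' A22 is expressed relative to the pedigree founders. Before fusing the
#' two, G is rescaled elementwise as `Ga = beta * G + alpha`, where
#' (beta, alpha) solve the 2x2 linear system that matches the mean
#' diagonal and the overall mean of Ga to those of A22:
#' \deqn{\beta\,\overline{diag(G)} + \alpha = \overline{diag(A_{22})},
#'       \qquad \beta\,\bar G + \alpha = \bar A_{22}.}
#'
#' @param G a [relmat] of kind `"G"`.
#' @param A22 pedigree relationships of the same genotypes, same order.
#' @return list with `beta`, `alpha`, and `scaled` (a [relmat] of kind
#'   `"Ga"`). Both mean constraints hold to 1e-10.
#' @export
scale_g <- function(G, A22) {
  if (!identical(relmat_ids(G), relmat_ids(A22))) {
    stop("G and A22 must share identical ids in identical order")
  }
  g <- unclass(G); a <- unclass(A22)
  mdg <- mean(diag(g)); mg <- mean(g)
  mda <- mean(diag(a)); ma <- mean(a)
  if (abs(mdg - mg) < 1e-12) {
    stop("degenerate scaling system: mean(diag(G)) equals mean(G); ",
         "more markers or genotypes are needed")
  }
  beta <- (mda - ma) / (mdg - mg)
  alpha <- mda - beta * mdg
  list(beta = beta, alpha = alpha,
       scaled = relmat(beta * g + alpha, kind = "Ga", ids = relmat_ids(G)))
}

#' Single-step hybrid relationship matrix H
#'
#' Fuses pedigree relationships (A over all individuals) with genomic
#' relationships (Ga over the genotyped subset) by the single-step block
#' formula. With subscript 1 = ungenotyped and 2 = genotyped:
#' \deqn{H = \begin{bmatrix}
#'   A_{11} + A_{12} A_{22}^{-1} (G_a - A_{22}) A_{22}^{-1} A_{21} &
#'   A_{12} A_{22}^{-1} G_a \\
#'   G_a A_{22}^{-1} A_{21} & G_a \end{bmatrix}}
#' The genomic correction is propagated to ungenotyped relatives through
#' the pedigree projection \eqn{A_{12} A_{22}^{-1}}; individuals with no
#' pedigree connection to any genotyped individual are left unchanged.
#' The H22 block equals Ga exactly and H is returned in pedigree order,
#' symmetrized as (H + H')/2 to absorb floating-point asymmetry.
#'
#' If A22 is numerically singular (e.g. duplicated individuals/clones) a
#' ridge `ridge * I` is added to A22 for the inversion only, with a
#' warning; set `ridge = 0` to error instead.
#'
#' @param A pedigree [relmat] (kind `"A"`) over all individuals.
#' @param Ga scaled genomic [relmat] (kind `"Ga"` or `"G"`); its ids are
#'   the genotyped individuals.
#' @param genotyped character ids of the genotyped individuals; defaults
#'   to the ids of `Ga`. All must be present in `A`.
#' @param ridge ridge added to A22 only on singularity; default 1e-6.
#' @return a [relmat] of kind `"H"` over all individuals of `A`, in the
#'   order of `A`.
#' @export
build_h <- function(A, Ga, genotyped = relmat_ids(Ga), ridge = 1e-6) {
  ids <- relmat_ids(A)
  genotyped <- as.character(genotyped)
  miss <- setdiff(genotyped, ids)
  if (length(miss) > 0) {
    stop("genotyped id(s) absent from pedigree: ", paste(miss, collapse = ", "))
  }
  if (!setequal(relmat_ids(Ga), genotyped)) {
    stop("ids of Ga must coincide with the genotyped set")
  }
  i2 <- ids[ids %in% genotyped]          # pedigree order within blocks
  i1 <- setdiff(ids, i2)
  a <- unclass(A)
  g <- unclass(Ga)[i2, i2, drop = FALSE]
  A22 <- a[i2, i2, drop = FALSE]

  inv_mult <- function(B) {              # A22^{-1} %*% B
    tryCatch(solve(A22, B), error = function(e) {
      if (ridge <= 0) stop("A22 is singular (", conditionMessage(e),
                           "); supply a positive ridge to regularize")
      warning("A22 singular; ridge ", ridge, " applied for inversion")
      solve(A22 + diag(ridge, nrow(A22)), B)
    })
  }

  H <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(i1) > 0) {
    A12 <- a[i1, i2, drop = FALSE]
    S <- inv_mult(t(A12))                # A22^{-1} A21, n2 x n1
    H11 <- a[i1, i1, drop = FALSE] + t(S) %*% (g - A22) %*% S
    H12 <- t(S) %*% g
    H[i1, i1] <- H11
    H[i1, i2] <- H12
    H[i2, i1] <- t(H12)
  }
  H[i2, i2] <- g
  H <- (H + t(H)) / 2
  H[i2, i2] <- g                         # H22 equals Ga exactly
  relmat(H, kind = "H", ids = ids)
}

#' Convert a relationship (covariance) matrix to a correlation matrix
#'
#' `Hcor(i, j) = H(i, j) / sqrt(H(i, i) H(j, j))`; the diagonal is set to
#' exactly 1.
#'
#' @param H a [relmat] with strictly positive diagonal.
#' @return a [relmat] of kind `"Hcor"`.
#' @export
cov_to_cor <- function(H) {
  h <- unclass(H)
  d <- diag(h)
  bad <- rownames(h)[d <= 0]
  if (length(bad) > 0) {
    stop("non-positive diagonal for genotype(s): ", paste(bad, collapse = ", "))
  }
  s <- 1 / sqrt(d)
  hc <- h * tcrossprod(s)
  diag(hc) <- 1
  relmat(hc, kind = "Hcor", ids = relmat_ids(H))
}

#' Convert a correlation matrix to a scaled distance matrix
#'
#' Produces the distance matrix D consumed by the core-collection
#' optimizer: diagonal 0, off-diagonal in \[0, 1\], monotonically
#' decreasing in correlation (so nearest-neighbor ranking under D equals
#' ranking under -Hcor).
#'
#' Mode `"normalized"` (default) computes
#' `D = (1 - Hcor) / (1 - min(Hcor))`, which provably satisfies those
#' properties for any correlation matrix. Mode `"as_printed"` evaluates
#' the alternative form `D = ((1 - Hcor) + |min(Hcor)|) / (1 + |min(Hcor)|)`,
#' which satisfies them only when `min(Hcor) = 0` (the two modes then
#' agree); when the minimum correlation is negative this form shifts the
#' diagonal away from zero, so it is kept only for exact reproduction of
#' legacy scripts.
#'
#' @param Hcor a [relmat] of kind `"Hcor"` (diagonal 1).
#' @param mode `"normalized"` or `"as_printed"`.
#' @return a [relmat] of kind `"D"`.
#' @export
cor_to_dist <- function(Hcor, mode = c("normalized", "as_printed")) {
  mode <- match.arg(mode)
  h <- unclass(Hcor)
  if (max(abs(diag(h) - 1)) > 1e-8) stop("cor_to_dist expects a correlation matrix (diagonal 1)")
  mn <- min(h)
  if (mn >= 1) stop("constant correlation matrix: zero range, distances undefined")
  if (mode == "normalized") {
    dmat <- (1 - h) / (1 - mn)
    diag(dmat) <- 0
  } else {
    dmat <- ((1 - h) + abs(mn)) / (1 + abs(mn))
  }
  relmat(dmat, kind = "D", ids = relmat_ids(Hcor))
}
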