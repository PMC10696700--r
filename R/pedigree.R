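#' Build a validated, canonically ordered pedigree
#'
#' Assembles a pedigree from (individual, mother, father) records. Unknown
#' parents may be encoded as `NA`, the empty string, or `"0"`; all three
#' are normalized to `NA` internally. Parents that are named but never
#' listed as individuals are appended as founders with unknown parents
#' (breeding records routinely omit the oldest generations). The result is
#' stored in canonical order: a topological order of the parent-offspring
#' graph in which every parent precedes all of its offspring, ties broken
#' by input order, so matrix layouts are reproducible.
#'
#' @param records a data.frame (or matrix) whose first three columns are
#'   individual, mother, father; or a list of length-3 character vectors.
#' @param groups optional named character vector mapping identifiers to
#'   free-form group labels (e.g. sub-population names).
#' @return an object of class `pedigree`, a data.frame with columns
#'   `id`, `mother`, `father` (NA = unknown) and optionally `group`,
#'   in canonical order.
#' @examples
#' ped <- build_pedigree(data.frame(id = "C", mother = "A", father = "B"))
#' ped$id  # founders A, B precede C
#' @export
build_pedigree <- function(records, groups = NULL) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) as.character(r[1:3])))
  }
  if (is.null(records) || NROW(records) == 0) {
    df <- data.frame(id = character(0), mother = character(0), father = character(0),
                     stringsAsFactors = FALSE)
    return(structure(df, class = c("pedigree", "data.frame")))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (ncol(records) < 3) stop("pedigree records need 3 columns: individual, mother, father")
  id <- norm_id(records[[1]])
  mother <- norm_parent(records[[2]])
  father <- norm_parent(records[[3]])
  if (anyNA(id) || any(id == "")) stop("individual identifiers must be non-empty")

  # collapse exact duplicates, reject conflicting ones
  key <- paste(id, mother, father, sep = "\r")
  keep <- !duplicated(key)
  id <- id[keep]; mother <- mother[keep]; father <- father[keep]
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    stop("conflicting parent records for individual(s): ", paste(dup, collapse = ", "))
  }

  # auto-register parents that are not listed as individuals
  known <- c(mother, father)
  extra <- setdiff(known[!is.na(known)], id)
  if (length(extra) > 0) {
    id <- c(id, extra)
    mother <- c(mother, rep(NA_character_, length(extra)))
    father <- c(father, rep(NA_character_, length(extra)))
  }

  ord <- topo_order(id, mother, father)
  df <- data.frame(id = id[ord], mother = mother[ord], father = father[ord],
                   stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    df$group <- unname(groups[df$id])
  }
  rownames(df) <- NULL
  structure(df, class = c("pedigree", "data.frame"))
}

norm_id <- function(x) trimws(as.character(x))

norm_parent <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "0", "NA", "-")] <- NA_character_
  x
}

# Kahn's algorithm; ties broken by position in the input so the canonical
# order is stable. Errors with the offending ids if a cycle exists.
topo_order <- function(id, mother, father) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  pm <- ifelse(is.na(mother), 0L, idx[mother])
  pf <- ifelse(is.na(father), 0L, idx[father])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(c(pm[i], pf[i]))) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  out <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail) > 0) {
    v <- avail[1]           # smallest input index first
    avail <- avail[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- sort(c(avail, ch))
    }
  }
  if (length(out) < n) {
    cyc <- id[setdiff(seq_len(n), out)]
    stop("pedigree contains a parent-offspring cycle involving: ",
         paste(cyc, collapse = ", "))
  }
  out
}

#' Read a pedigree CSV
#'
#' Expects a header CSV with columns `id,mother,father` and optionally
#' `group`; unknown parents are the empty field or `"0"`.
#'
#' @param path file path.
#' @return a `pedigree`.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "mother", "father")
  if (!all(need %in% names(tab))) {
    stop("pedigree CSV must have columns id,mother,father; got: ",
         paste(names(tab), collapse = ", "))
  }
  groups <- NULL
  if ("group" %in% names(tab)) {
    groups <- stats::setNames(tab$group, tab$id)
  }
  build_pedigree(tab[, need], groups = groups)
}

#' Write a pedigree CSV
#'
#' @param ped a `pedigree`.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$mother[is.na(df$mother)] <- ""
  df$father[is.na(df$father)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parent_indices <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  list(
    mother = ifelse(is.na(ped$mother), 0L, idx[ped$mother]),
    father = ifelse(is.na(ped$father), 0L, idx[ped$father])
  )
}

#' Additive relationship matrix by the tabular method
#'
#' Computes the numerator relationship matrix A over all individuals of a
#' pedigree by the standard tabular recursion: founders have diagonal 1
#' and off-diagonal 0; for individual i with parents s and d (processed in
#' canonical order),
#' \deqn{a_{ij} = 0.5 (a_{js} + a_{jd}) \quad (j < i), \qquad
#'       a_{ii} = 1 + 0.5\, a_{sd},}
#' with unknown parents contributing zero. The entry \eqn{a_{ij}} equals
#' \eqn{0.5[(i_1,j_1)+(i_1,j_2)+(i_2,j_1)+(i_2,j_2)]}, where \eqn{(x,y)}
#' is the probability that alleles x and y are identical by descent, so a
#' parent-offspring pair scores 0.5 and a founder grandparent with its
#' non-inbred grandchild scores 0.25. The diagonal is 1 plus the
#' inbreeding coefficient; inbreeding is handled exactly.
#'
#' @param ped a `pedigree` from [build_pedigree()].
#' @return a [relmat] of kind `"A"` in canonical pedigree order.
#' @export
amatrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  pp <- parent_indices(ped)
  pm <- pp$mother; pf <- pp$father
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    rm_ <- if (pm[i] > 0L) A[seq_len(i - 1L), pm[i]] else numeric(i - 1L)
    rf_ <- if (pf[i] > 0L) A[seq_len(i - 1L), pf[i]] else numeric(i - 1L)
    if (i > 1L) {
      v <- 0.5 * (rm_ + rf_)
      A[seq_len(i - 1L), i] <- v
      A[i, seq_len(i - 1L)] <- v
    }
    f <- if (pm[i] > 0L && pf[i] > 0L) 0.5 * A[pm[i], pf[i]] else 0
    A[i, i] <- 1 + f
  }
  relmat(A, kind = "A", ids = ped$id)
}

ancestor_sets <- function(ped) {
  n <- nrow(ped)
  pp <- parent_indices(ped)
  anc <- vector("list", n)
  for (i in seq_len(n)) {   # canonical order: parents already resolved
    ps <- c(pp$mother[i], pp$father[i])
    ps <- ps[ps > 0L]
    anc[[i]] <- sort(unique(c(ps, unlist(anc[ps]))))
  }
  anc
}

#' Individual-to-ancestor relationship matrix (A*)
#'
#' Derives the directional matrix A* from A by keeping, in each row i,
#' only the relationships of i with its own ancestors (parents,
#' grandparents, and so on to any depth) and zeroing everything else,
#' including the diagonal and all parent-to-offspring directions. Row
#' sums of A* are the pedigree-completeness measure of
#' [pedigree_completeness()].
#'
#' @param ped a `pedigree`.
#' @param A the additive relationship matrix for `ped`; computed when
#'   omitted. Must share ids (and order) with `ped`.
#' @return a [relmat] of kind `"Astar"`.
#' @export
ancestor_matrix <- function(ped, A = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(A)) A <- amatrix(ped)
  if (!identical(relmat_ids(A), ped$id)) {
    stop("ids of A do not match the pedigree (same ids, same order required)")
  }
  n <- nrow(ped)
  anc <- ancestor_sets(ped)
  S <- matrix(0, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) {
    if (length(anc[[i]]) > 0) S[i, anc[[i]]] <- unclass(A)[i, anc[[i]]]
  }
  relmat(S, kind = "Astar", ids = ped$id)
}

#' Pedigree completeness per individual
#'
#' The sum of an individual's additive relationships to all of its
#' recorded ancestors (row sums of the A* matrix). In a non-inbred,
#' fully recorded pedigree each known ancestral generation contributes
#' exactly 1 (two parents at 0.5, four grandparents at 0.25, ...), so the
#' value reads as "number of fully known ancestral generations". Founders
#' score 0.
#'
#' @param ped a `pedigree`.
#' @param A optional precomputed A matrix (same ids/order as `ped`).
#' @return named numeric vector over `ped$id`.
#' @export
pedigree_completeness <- function(ped, A = NULL) {
  S <- ancestor_matrix(ped, A)
  rowSums(unclass(S))
}
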