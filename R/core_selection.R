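#' Select frequently used recent crossing parents
#'
#' Breeding programs carry "advanced selections" that are still under
#' phenotypic selection; their genetic variation is represented in a core
#' collection through their parents rather than themselves. This selects
#' every genotype used as a crossing parent at least `min_uses` times
#' within the `window_years`-year window ending at `reference_year`.
#' Mother and father roles both count, so a self-cross counts twice (the
#' count is per parental slot; switch to per-cross counting by
#' deduplicating records upstream if desired).
#'
#' @param crossings data.frame with columns `mother`, `father`, `year`.
#' @param min_uses minimum number of uses, default 4.
#' @param window_years window length in years, default 3 (so
#'   `reference_year - 2` through `reference_year`).
#' @param reference_year last year of the window (required).
#' @return character vector of parent ids meeting the threshold.
#' @export
select_recent_parents <- function(crossings, min_uses = 4, window_years = 3,
                                  reference_year) {
  if (missing(reference_year)) stop("reference_year is required")
  if (min_uses < 1) stop("min_uses must be >= 1")
  if (NROW(crossings) == 0) {
    warning("empty crossing list; no recent parents selected")
    return(character(0))
  }
  stopifnot(all(c("mother", "father", "year") %in% names(crossings)))
  yr <- as.integer(crossings$year)
  inwin <- yr >= reference_year - window_years + 1 & yr <= reference_year
  slots <- c(as.character(crossings$mother[inwin]), as.character(crossings$father[inwin]))
  slots <- slots[!is.na(slots) & slots != ""]
  cnt <- table(slots)
  sort(names(cnt)[cnt >= min_uses])
}

#' Accession-to-nearest-entry criterion (A-NE)
#'
#' The mean, over every genotype of the whole collection, of its distance
#' to the nearest entry of the core; core entries contribute 0 (their
#' nearest entry is themselves). Minimizing A-NE yields a CC-I core
#' collection in which every accession is represented by a similar entry.
#'
#' @param D a [relmat] of kind `"D"` (diagonal 0).
#' @param core character ids of the core entries (non-empty, subset of
#'   `collection`).
#' @param collection character ids of the whole collection; defaults to
#'   all ids of `D`.
#' @return the A-NE value (non-negative scalar).
#' @export
ane <- function(D, core, collection = relmat_ids(D)) {
  core <- as.character(core); collection <- as.character(collection)
  if (length(core) == 0) stop("core must be non-empty")
  if (!all(collection %in% relmat_ids(D))) {
    stop("collection ids absent from D: ",
         paste(setdiff(collection, relmat_ids(D)), collapse = ", "))
  }
  if (!all(core %in% collection)) {
    stop("core ids outside the collection: ",
         paste(setdiff(core, collection), collapse = ", "))
  }
  sub <- unclass(D)[collection, core, drop = FALSE]
  mean(apply(sub, 1, min))
}

#' Core selection result
#'
#' Holds the mandatory (`fixed`) and optimizer-chosen (`free`) entries of
#' a core collection, the A-NE value of the final set, and, for consensus
#' runs, per-candidate selection frequencies and the number of free slots
#' whose occupant was selected in every iteration.
#'
#' @param fixed,free character id vectors (disjoint).
#' @param criterion A-NE of `c(fixed, free)`.
#' @param frequencies optional named numeric in \[0, 1\] per candidate.
#' @param seeds integer seeds used.
#' @param always_selected optional count of free entries with frequency 1.
#' @export
core_selection <- function(fixed, free, criterion, frequencies = NULL,
                           seeds = NULL, always_selected = NULL) {
  if (length(intersect(fixed, free)) > 0) stop("fixed and free entries overlap")
  structure(list(fixed = as.character(fixed), free = sort(as.character(free)),
                 entries = c(as.character(fixed), sort(as.character(free))),
                 criterion = criterion, frequencies = frequencies,
                 seeds = seeds, always_selected = always_selected),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("<core_selection: %d entries (%d fixed + %d optimized), A-NE = %.6g>\n",
              length(x$entries), length(x$fixed), length(x$free), x$criterion))
  if (!is.null(x$always_selected)) {
    cat(sprintf("  consensus: %d/%d free slots always selected\n",
                x$always_selected, length(x$free)))
  }
  invisible(x)
}

# Greedy forward initialization: starting from the fixed entries, add the
# candidate that most reduces A-NE until the core is full. A strong,
# deterministic starting basin for the swap descent.
greedy_init <- function(Dsub, fixed_idx, cand_idx, k_free) {
  free <- integer(0)
  cur <- if (length(fixed_idx) > 0) {
    apply(Dsub[, fixed_idx, drop = FALSE], 1, min)
  } else rep(Inf, nrow(Dsub))
  for (step in seq_len(k_free)) {
    pool <- setdiff(cand_idx, free)
    vals <- colMeans(pmin(Dsub[, pool, drop = FALSE], cur))
    pick <- pool[which.min(vals)]
    free <- c(free, pick)
    cur <- pmin(cur, Dsub[, pick])
  }
  free
}

# Incremental A-NE bookkeeping: for the current core, each collection
# member's nearest core entry (index into `core`), its distance, and the
# second-nearest distance. Swap evaluation is then O(n) per candidate.
ane_state <- function(Dsub, core_idx) {
  sub <- Dsub[, core_idx, drop = FALSE]
  if (length(core_idx) == 1L) {
    d1 <- sub[, 1]
    list(n1 = rep(core_idx, nrow(Dsub)), d1 = d1, d2 = rep(Inf, nrow(Dsub)))
  } else {
    ord1 <- max.col(-sub, ties.method = "first")
    d1 <- sub[cbind(seq_len(nrow(sub)), ord1)]
    sub2 <- sub
    sub2[cbind(seq_len(nrow(sub)), ord1)] <- Inf
    d2 <- apply(sub2, 1, min)
    list(n1 = core_idx[ord1], d1 = d1, d2 = d2)
  }
}

#' Optimize a core collection by stochastic swap descent (single run)
#'
#' Minimizes A-NE over subsets of the collection of the requested size
#' that contain all `fixed` entries. The search is a seeded
#' best-improvement local search: uniform random initializations of the
#' free slots, plus one final descent from a greedy forward construction;
#' in each descent the single swap (one free entry out, one non-entry in)
#' that most decreases A-NE is applied repeatedly until no swap improves,
#' and the best local optimum over all restarts is returned (value ties
#' keep the earliest optimum, so equivalent optima vary with the seed).
#' Fixed entries are never swapped out. The result is deterministic given
#' `seed`.
#'
#' @param D a [relmat] of kind `"D"`.
#' @param size total core size (`|fixed| <= size <= |collection|`).
#' @param fixed character ids of mandatory entries.
#' @param collection character ids of the whole collection (default: all
#'   of `D`).
#' @param seed integer RNG seed (required for reproducibility).
#' @param restarts number of random restarts, default 5.
#' @param max_sweeps cap on best-improvement steps per restart, default
#'   `100 * size`; must be positive.
#' @return a [core_selection] with the criterion recomputed on the final
#'   set.
#' @export
optimize_core <- function(D, size, fixed = character(0),
                          collection = relmat_ids(D), seed,
                          restarts = 5, max_sweeps = NULL) {
  if (missing(seed)) stop("seed is required")
  fixed <- as.character(fixed); collection <- as.character(collection)
  if (!all(fixed %in% collection)) {
    stop("fixed ids outside the collection: ",
         paste(setdiff(fixed, collection), collapse = ", "))
  }
  if (!all(collection %in% relmat_ids(D))) {
    stop("collection ids absent from D: ",
         paste(setdiff(collection, relmat_ids(D)), collapse = ", "))
  }
  n <- length(collection)
  if (size < length(fixed)) stop("size (", size, ") smaller than number of fixed entries (",
                                 length(fixed), ")")
  if (size > n) stop("size exceeds collection size")
  if (is.null(max_sweeps)) max_sweeps <- 100L * max(size, 1L)
  if (max_sweeps <= 0 || restarts <= 0) stop("search budget must be positive")

  Dsub <- unclass(D)[collection, collection, drop = FALSE]
  fixed_idx <- match(fixed, collection)
  cand_idx <- setdiff(seq_len(n), fixed_idx)
  k_free <- size - length(fixed)

  if (k_free == 0) {
    return(core_selection(fixed, character(0), ane(D, fixed, collection), seeds = seed))
  }
  if (size == n) {
    return(core_selection(fixed, collection[cand_idx], 0, seeds = seed))
  }

  set.seed(as.integer(seed %% .Machine$integer.max))
  best_val <- Inf
  best_free <- NULL
  for (r in seq_len(restarts)) {
    # random restarts first, one greedy-construction descent last; on
    # exact value ties the earlier (seed-dependent) optimum is kept, so
    # interchangeable optima still vary across seeds
    free <- if (r == restarts) greedy_init(Dsub, fixed_idx, cand_idx, k_free)
            else sample(cand_idx, k_free)
    core <- c(fixed_idx, free)
    st <- ane_state(Dsub, core)
    val <- mean(st$d1)
    for (sweep in seq_len(max_sweeps)) {
      out_pool <- free
      in_pool <- setdiff(cand_idx, free)
      sw_best <- val
      sw_out <- sw_in <- NA_integer_
      for (e in out_pool) {
        base <- ifelse(st$n1 == e, st$d2, st$d1)
        vals <- colMeans(pmin(Dsub[, in_pool, drop = FALSE], base))
        m <- which.min(vals)
        if (vals[m] < sw_best - 1e-12) {
          sw_best <- vals[m]; sw_out <- e; sw_in <- in_pool[m]
        }
      }
      if (is.na(sw_out)) break
      free <- c(setdiff(free, sw_out), sw_in)
      core <- c(fixed_idx, free)
      st <- ane_state(Dsub, core)
      val <- mean(st$d1)
    }
    if (val < best_val - 1e-12) {
      best_val <- val
      best_free <- free
    }
  }
  free_ids <- collection[best_free]
  core_selection(fixed, free_ids, ane(D, c(fixed, free_ids), collection), seeds = seed)
}

#' Consensus core collection over repeated stochastic runs
#'
#' Runs [optimize_core()] `n_iter` times with seeds `base_seed`,
#' `base_seed + 1`, ..., records how often each candidate occupies a free
#' slot, and fills the free slots with the most frequently selected
#' candidates. Frequency ties are broken by (1) the breeder preference
#' order when supplied, then (2) lexicographic id, so the result is
#' deterministic. The criterion is recomputed by [ane()] on the final
#' set, and the number of free entries selected in every single run (the
#' "always selected" count) is reported.
#'
#' @param D a [relmat] of kind `"D"`.
#' @param size total core size.
#' @param fixed mandatory entries.
#' @param collection whole-collection ids.
#' @param n_iter number of independent runs, default 3000.
#' @param base_seed first seed.
#' @param preference optional ordered id vector; earlier = preferred on
#'   frequency ties.
#' @param ... passed to [optimize_core()] (`restarts`, `max_sweeps`).
#' @return a [core_selection] with per-candidate `frequencies`.
#' @export
consensus_core <- function(D, size, fixed = character(0),
                           collection = relmat_ids(D), n_iter = 3000,
                           base_seed, preference = NULL, ...) {
  if (missing(base_seed)) stop("base_seed is required")
  if (n_iter < 1) stop("n_iter must be >= 1")
  fixed <- as.character(fixed); collection <- as.character(collection)
  cand <- setdiff(collection, fixed)
  counts <- stats::setNames(numeric(length(cand)), cand)
  seeds <- base_seed + seq_len(n_iter) - 1
  for (s in seeds) {
    run <- optimize_core(D, size, fixed, collection, seed = s, ...)
    counts[run$free] <- counts[run$free] + 1
  }
  freq <- counts / n_iter
  k_free <- size - length(fixed)
  pref_rank <- rep(length(cand) + 1L, length(cand))
  if (!is.null(preference)) {
    r <- match(cand, as.character(preference))
    pref_rank[!is.na(r)] <- r[!is.na(r)]
  }
  ord <- order(-freq, pref_rank, cand)
  free_ids <- cand[ord][seq_len(k_free)]
  core_selection(fixed, free_ids,
                 criterion = ane(D, c(fixed, free_ids), collection),
                 frequencies = freq,
                 seeds = c(base_seed, base_seed + n_iter - 1),
                 always_selected = sum(freq[free_ids] >= 1))
}

#' A-NE versus core size, with random-sampling baseline
#'
#' For each requested size, runs the optimizer and also draws seeded
#' random cores (fixed entries kept, remaining slots uniform without
#' replacement) as a baseline. The optimized series is made non-increasing
#' in size by also considering, at each size, the previous optimum
#' greedily extended with the best additional entries, and keeping
#' whichever set scores lower (optima at nested sizes are nested-monotone,
#' so this never misreports).
#'
#' @param D a [relmat] of kind `"D"`.
#' @param sizes increasing integer sizes, all `>= length(fixed)`.
#' @param fixed mandatory entries.
#' @param collection whole-collection ids.
#' @param seed integer seed.
#' @param n_random random cores per size for the baseline, default 20.
#' @param ... passed to [optimize_core()].
#' @return data.frame with columns `size`, `ane_optimized`, `ane_random`.
#' @export
ane_curve <- function(D, sizes, fixed = character(0),
                      collection = relmat_ids(D), seed, n_random = 20, ...) {
  if (missing(seed)) stop("seed is required")
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < length(fixed))) stop("sizes must all be >= number of fixed entries")
  fixed <- as.character(fixed); collection <- as.character(collection)
  cand <- setdiff(collection, fixed)
  Dsub <- unclass(D)[collection, , drop = FALSE]

  greedy_extend <- function(core, target) {
    while (length(core) < target) {
      pool <- setdiff(collection, core)
      cur <- apply(Dsub[, core, drop = FALSE], 1, min)
      gain <- vapply(pool, function(c2) mean(pmin(cur, Dsub[, c2])), numeric(1))
      core <- c(core, pool[which.min(gain)])
    }
    core
  }

  prev <- NULL
  out <- data.frame(size = sizes, ane_optimized = NA_real_, ane_random = NA_real_)
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    res <- optimize_core(D, s, fixed, collection, seed = seed + i, ...)
    val <- res$criterion
    entries <- res$entries
    if (!is.null(prev)) {
      ext <- greedy_extend(prev, s)
      ext_val <- ane(D, ext, collection)
      if (ext_val < val) { val <- ext_val; entries <- ext }
    }
    prev <- entries
    out$ane_optimized[i] <- val
    set.seed(as.integer((seed + 10000 * i) %% .Machine$integer.max))
    rnd <- replicate(n_random, {
      core <- c(fixed, sample(cand, s - length(fixed)))
      ane(D, core, collection)
    })
    out$ane_random[i] <- mean(rnd)
  }
  out
}
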