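#' Configuration for the breeding-program simulator
#'
#' The simulator emulates the structure of a multi-decade strawberry-type
#' breeding program: a few weakly connected sub-populations (e.g. June
#' bearing / everbearing / Mediterranean), founders unrelated within and
#' between sub-populations, several generations of within-program
#' crossing with occasional between-population crosses, and the data
#' defects that motivate hybrid relationships — only a fraction of
#' individuals genotyped, a fraction of parent links missing from the
#' records, and occasional sample swaps.
#'
#' Defaults describe a desk-scale program: 3 sub-populations of 8
#' founders, 4 generations of 8 crosses each producing 2 offspring,
#' 10% between-population crossing, 1000 unlinked biallelic markers with
#' founder allele frequencies uniform on \[0.05, 0.5\], half of the
#' individuals genotyped, 20% of parent links lost from the records, and
#' no sample swaps unless asked for.
#'
#' @param n_subpops number of sub-populations.
#' @param founders_per_subpop founders per sub-population.
#' @param generations number of crossing generations after the founders.
#' @param crosses_per_gen crosses per sub-population per generation.
#' @param offspring_per_cross offspring per cross.
#' @param migration_rate probability that a cross takes its father from
#'   another sub-population.
#' @param n_markers number of unlinked biallelic markers.
#' @param freq_range founder allele-frequency range (uniform draw).
#' @param genotyped_fraction fraction of individuals with SNP data.
#' @param link_missing_rate fraction of parent links absent from the
#'   observed pedigree.
#' @param n_swaps number of sample swaps to inject.
#' @param seed integer seed (mandatory; every draw is seeded).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subpops = 3, founders_per_subpop = 8, generations = 4,
                       crosses_per_gen = 8, offspring_per_cross = 2,
                       migration_rate = 0.1, n_markers = 1000,
                       freq_range = c(0.05, 0.5), genotyped_fraction = 0.5,
                       link_missing_rate = 0.2, n_swaps = 0, seed) {
  if (missing(seed)) stop("sim_config requires a seed")
  cfg <- list(n_subpops = n_subpops, founders_per_subpop = founders_per_subpop,
              generations = generations, crosses_per_gen = crosses_per_gen,
              offspring_per_cross = offspring_per_cross,
              migration_rate = migration_rate, n_markers = n_markers,
              freq_range = freq_range, genotyped_fraction = genotyped_fraction,
              link_missing_rate = link_missing_rate, n_swaps = n_swaps,
              seed = as.integer(seed))
  fr <- c(cfg$migration_rate, cfg$genotyped_fraction, cfg$link_missing_rate)
  if (any(fr < 0 | fr > 1)) stop("rates and fractions must lie in [0, 1]")
  cnt <- c(cfg$n_subpops, cfg$founders_per_subpop, cfg$generations,
           cfg$crosses_per_gen, cfg$offspring_per_cross, cfg$n_markers, cfg$n_swaps)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (cfg$founders_per_subpop == 0 || cfg$n_subpops == 0) stop("need at least one founder")
  structure(cfg, class = "sim_config")
}

subpop_labels <- function(n) {
  base <- c("JuneBearing", "Everbearing", "Mediterranean")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("SubPop", seq_len(n - 3) + 3))
}

#' Simulate a structured breeding pedigree
#'
#' Produces the true pedigree, an observed pedigree with parent links
#' deleted at the configured rate, and the crossing records (mother,
#' father, year; the last generation is dated to the reference year
#' 2022, earlier generations one year apart).
#'
#' @param cfg a [sim_config()].
#' @return list with `true` and `observed` (both [build_pedigree()]
#'   objects with group labels), `crossings` (data.frame), and `groups`
#'   (named character).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  labs <- subpop_labels(cfg$n_subpops)
  id <- character(0); mo <- character(0); fa <- character(0)
  subpop <- character(0); gen <- integer(0)
  for (s in seq_len(cfg$n_subpops)) {
    fid <- sprintf("%s.F%02d", labs[s], seq_len(cfg$founders_per_subpop))
    id <- c(id, fid); mo <- c(mo, rep(NA_character_, length(fid)))
    fa <- c(fa, rep(NA_character_, length(fid)))
    subpop <- c(subpop, rep(labs[s], length(fid))); gen <- c(gen, rep(0L, length(fid)))
  }
  crossings <- NULL
  for (g in seq_len(cfg$generations)) {
    prev <- id[gen == g - 1L]
    prev_pop <- subpop[gen == g - 1L]
    year <- 2022L - cfg$generations + g
    for (s in seq_len(cfg$n_subpops)) {
      own <- prev[prev_pop == labs[s]]
      other <- prev[prev_pop != labs[s]]
      for (k in seq_len(cfg$crosses_per_gen)) {
        mother <- sample(own, 1)
        father <- if (length(other) > 0 && stats::runif(1) < cfg$migration_rate) {
          sample(other, 1)
        } else sample(own, 1)
        crossings <- rbind(crossings, data.frame(mother = mother, father = father,
                                                 year = year, stringsAsFactors = FALSE))
        kid <- sprintf("%s.G%d.C%02d.%d", labs[s], g, k, seq_len(cfg$offspring_per_cross))
        id <- c(id, kid)
        mo <- c(mo, rep(mother, length(kid)))
        fa <- c(fa, rep(father, length(kid)))
        subpop <- c(subpop, rep(labs[s], length(kid)))
        gen <- c(gen, rep(g, length(kid)))
      }
    }
  }
  groups <- stats::setNames(subpop, id)
  true <- build_pedigree(data.frame(id = id, mother = mo, father = fa,
                                    stringsAsFactors = FALSE), groups = groups)
  drop_mo <- stats::runif(length(id)) < cfg$link_missing_rate
  drop_fa <- stats::runif(length(id)) < cfg$link_missing_rate
  mo_obs <- ifelse(drop_mo, NA_character_, mo)
  fa_obs <- ifelse(drop_fa, NA_character_, fa)
  observed <- build_pedigree(data.frame(id = id, mother = mo_obs, father = fa_obs,
                                        stringsAsFactors = FALSE), groups = groups)
  list(true = true, observed = observed, crossings = crossings, groups = groups)
}

#' Gene-dropping simulation with exact realized IBD
#'
#' Drops uniquely labeled founder alleles through a pedigree: every
#' founder (and every unknown-parent slot) contributes two globally
#' unique allele labels; each non-founder inherits, independently per
#' locus, one uniformly chosen allele from each parent. Allelic states
#' (0/1) are assigned per founder allele and locus from the configured
#' frequency distribution, giving dosages, and the labels give exact
#' realized IBD: per locus,
#' \eqn{0.5[(i_1,j_1)+(i_1,j_2)+(i_2,j_1)+(i_2,j_2)]} with \eqn{(x,y)}
#' the indicator that labels x and y are identical, averaged over loci.
#' The mean realized IBD converges to the tabular-method A matrix, which
#' makes this the package's independent oracle for pedigree
#' relationships.
#'
#' @param ped a `pedigree` (typically the true pedigree of
#'   [simulate_pedigree()]).
#' @param n_markers number of unlinked loci.
#' @param freq_range founder allele-frequency range (uniform draw per
#'   locus).
#' @param seed integer seed.
#' @param compute_ibd set `FALSE` to skip the O(n^2 loci) realized-IBD
#'   summary when only dosages are needed.
#' @return list with `dosage` (a [dosage_matrix]), `ibd` (a [relmat] of
#'   kind `"IBD"`, or `NULL`), `ibd_se` (Monte-Carlo standard errors per
#'   entry), `founder_freq` (per-locus allele frequencies), and `paths`
#'   (the two allele-label matrices, individuals x loci).
#' @export
gene_drop <- function(ped, n_markers, freq_range = c(0.05, 0.5), seed,
                      compute_ibd = TRUE) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(ped, "pedigree"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- nrow(ped)
  L <- as.integer(n_markers)
  pp <- parent_indices(ped)
  M1 <- matrix(0L, n, L); M2 <- matrix(0L, n, L)
  next_allele <- 0L
  fresh <- function() { next_allele <<- next_allele + 1L; next_allele }
  for (i in seq_len(n)) {
    if (pp$mother[i] > 0L) {
      pick <- stats::runif(L) < 0.5
      M1[i, ] <- ifelse(pick, M1[pp$mother[i], ], M2[pp$mother[i], ])
    } else {
      M1[i, ] <- fresh()
    }
    if (pp$father[i] > 0L) {
      pick <- stats::runif(L) < 0.5
      M2[i, ] <- ifelse(pick, M1[pp$father[i], ], M2[pp$father[i], ])
    } else {
      M2[i, ] <- fresh()
    }
  }
  freq <- stats::runif(L, freq_range[1], freq_range[2])
  # allelic state per founder allele per locus
  S <- matrix(stats::rbinom(next_allele * L, 1, rep(freq, each = next_allele)),
              nrow = next_allele, ncol = L)
  li <- rep(seq_len(L), each = n)
  dos <- matrix(S[cbind(as.vector(M1), li)] + S[cbind(as.vector(M2), li)],
                nrow = n, ncol = L,
                dimnames = list(ped$id, sprintf("M%05d", seq_len(L))))
  ibd_rel <- NULL; se <- NULL
  if (compute_ibd) {
    ibd <- matrix(0, n, n); se <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in i:n) {
        v <- 0.5 * ((M1[i, ] == M1[j, ]) + (M1[i, ] == M2[j, ]) +
                    (M2[i, ] == M1[j, ]) + (M2[i, ] == M2[j, ]))
        ibd[i, j] <- ibd[j, i] <- mean(v)
        se[i, j] <- se[j, i] <- stats::sd(v) / sqrt(L)
      }
    }
    dimnames(ibd) <- dimnames(se) <- list(ped$id, ped$id)
    ibd_rel <- relmat(ibd, kind = "IBD", ids = ped$id)
  }
  list(dosage = dosage_matrix(dos), ibd = ibd_rel,
       ibd_se = se, founder_freq = freq, paths = list(M1 = M1, M2 = M2))
}

#' Degrade a dosage matrix: missing calls and sample swaps
#'
#' Sets cells to missing uniformly at `missing_rate` and exchanges
#' `n_swaps` pairs of genotype rows, recording the truth in a swap
#' ledger. Swap pairs default to random disjoint pairs; supply
#' `swap_pairs` (two-column matrix of ids) for a designed scenario, e.g.
#' [default_swap_design()].
#'
#' @param d a [dosage_matrix].
#' @param missing_rate fraction of cells set to missing.
#' @param n_swaps number of row swaps (ignored when `swap_pairs` given).
#' @param seed integer seed.
#' @param swap_pairs optional 2-column character matrix of row pairs to
#'   exchange.
#' @return list with `dosage` and `swaps` (data.frame `id1`, `id2`).
#' @export
degrade <- function(d, missing_rate = 0, n_swaps = 0, seed, swap_pairs = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(d, "dosage_matrix"))
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  set.seed(as.integer(seed %% .Machine$integer.max))
  m <- unclass(d)
  if (is.null(swap_pairs)) {
    if (n_swaps > floor(nrow(m) / 2)) stop("n_swaps exceeds floor(n/2): disjoint pairs impossible")
    if (n_swaps > 0) {
      picks <- sample(rownames(m), 2L * n_swaps)
      swap_pairs <- matrix(picks, ncol = 2, byrow = TRUE)
    } else {
      swap_pairs <- matrix(character(0), ncol = 2)
    }
  } else {
    swap_pairs <- as.matrix(swap_pairs)
    if (anyDuplicated(as.vector(swap_pairs))) stop("swap pairs must be disjoint")
  }
  for (k in seq_len(nrow(swap_pairs))) {
    i <- swap_pairs[k, 1]; j <- swap_pairs[k, 2]
    tmp <- m[i, ]; m[i, ] <- m[j, ]; m[j, ] <- tmp
  }
  if (missing_rate > 0) {
    m[stats::runif(length(m)) < missing_rate] <- NA_real_
  }
  list(dosage = dosage_matrix(m, marker_meta = marker_meta(d), imputed = is_imputed(d)),
       swaps = data.frame(id1 = swap_pairs[, 1], id2 = swap_pairs[, 2],
                          stringsAsFactors = FALSE))
}

#' Default sample-swap scenario for outlier-detection validation
#'
#' Picks swap pairs the way real mix-ups bite hardest and are best
#' detectable: individuals with deep recorded pedigrees (highest
#' completeness first), paired across different sub-population groups so
#' the swapped genomic profile contradicts the pedigree. Deterministic
#' given the pedigree.
#'
#' @param ped a `pedigree` with a `group` column.
#' @param n_swaps number of pairs, default 5.
#' @param candidates ids eligible for swapping (e.g. the genotyped set);
#'   default all.
#' @return 2-column character matrix of swap pairs.
#' @export
default_swap_design <- function(ped, n_swaps = 5, candidates = ped$id) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(ped$group)) stop("pedigree has no group labels")
  comp <- pedigree_completeness(ped)
  cand <- intersect(ped$id, candidates)
  cand <- cand[order(-comp[cand], cand)]
  grp <- stats::setNames(ped$group, ped$id)
  pairs <- matrix(character(0), ncol = 2)
  used <- character(0)
  for (a in cand) {
    if (nrow(pairs) >= n_swaps) break
    if (a %in% used) next
    b <- setdiff(cand[grp[cand] != grp[a]], c(used, a))
    if (length(b) == 0) next
    pairs <- rbind(pairs, c(a, b[1]))
    used <- c(used, a, b[1])
  }
  if (nrow(pairs) < n_swaps) {
    stop("could not form ", n_swaps, " cross-group swap pairs from the candidates")
  }
  pairs
}
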