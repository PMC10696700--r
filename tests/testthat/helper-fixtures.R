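# Shared fixture builders and independent oracles. Everything is built in
# code; no binary fixtures.

# Random symmetric distance matrix with zero diagonal, labeled g1..gn.
random_dmat <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("g", seq_len(n))
  relmat(m, kind = "D")
}

# Brute-force A-NE: explicit double loop, no shared code with ane().
ane_bruteforce <- function(D, core, collection = rownames(D)) {
  m <- unclass(D)
  total <- 0
  for (a in collection) {
    best <- Inf
    for (e in core) if (m[a, e] < best) best <- m[a, e]
    total <- total + best
  }
  total / length(collection)
}

# Exhaustive optimum of A-NE over all subsets of the given size that
# contain `fixed`. Returns the minimal criterion value.
ane_exhaustive_opt <- function(D, size, fixed = character(0),
                               collection = rownames(D)) {
  cand <- setdiff(collection, fixed)
  k <- size - length(fixed)
  m <- unclass(D)[collection, , drop = FALSE]
  best <- Inf
  for (pick in utils::combn(cand, k, simplify = FALSE)) {
    core <- c(fixed, pick)
    val <- mean(do.call(pmin, lapply(core, function(e) m[, e])))
    if (val < best) best <- val
  }
  best
}

# Pearson correlation from first principles (oracle for cor-based ops).
pearson_manual <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# A three-generation pedigree: founders GA,GB,GC,GD; parents P1 = GA x GB,
# P2 = GC x GD; child K = P1 x P2.
three_gen_pedigree <- function() {
  build_pedigree(data.frame(
    id = c("P1", "P2", "K"),
    mother = c("GA", "GC", "P1"),
    father = c("GB", "GD", "P2")))
}

# Tiny raw dosage matrix used across curation tests.
toy_dosages <- function() {
  m <- rbind(
    g1 = c(0, 2, 1, 0),
    g2 = c(1, 2, 1, 0),
    g3 = c(2, 2, 0, NA),
    g4 = c(1, 2, 2, 0))
  colnames(m) <- paste0("m", 1:4)
  dosage_matrix(m)
}

# Small simulated world shared by fusion / diagnostics tests.
small_sim <- function(seed, generations = 4, n_markers = 500,
                      link_missing_rate = 0.2, founders = 6, subpops = 2,
                      crosses = 4, ibd = TRUE) {
  cfg <- sim_config(n_subpops = subpops, founders_per_subpop = founders,
                    generations = generations, crosses_per_gen = crosses,
                    offspring_per_cross = 2, migration_rate = 0.1,
                    n_markers = n_markers, link_missing_rate = link_missing_rate,
                    seed = seed)
  sim <- simulate_pedigree(cfg)
  gd <- gene_drop(sim$true, cfg$n_markers, cfg$freq_range, seed = seed + 1000,
                  compute_ibd = ibd)
  list(cfg = cfg, sim = sim, gd = gd)
}
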