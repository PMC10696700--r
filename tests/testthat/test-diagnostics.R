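test_that("matrix_correlation uses the strict upper triangle", {
  ids <- paste0("g", 1:4)
  set.seed(1)
  a <- crossprod(matrix(rnorm(16), 4)); dimnames(a) <- list(ids, ids)
  A22 <- relmat(a, "A22")
  expect_equal(matrix_correlation(A22, A22), 1)
  neg <- relmat(-a + 2, "Ga")
  expect_equal(matrix_correlation(A22, neg), -1)

  g <- a + matrix(c(0, 1, 2, 0, 1, 0, 0, 3, 2, 0, 0, 1, 0, 3, 1, 0), 4)
  g <- (g + t(g)) / 2; dimnames(g) <- list(ids, ids)
  # oracle on the 6 upper-triangle values
  expect_equal(matrix_correlation(A22, relmat(g, "Ga")),
               pearson_manual(a[upper.tri(a)], g[upper.tri(g)]))

  cst <- matrix(1, 4, 4, dimnames = list(ids, ids))
  expect_error(matrix_correlation(relmat(cst, "A22"), A22), "constant")
})

test_that("per_genotype_correlation excludes the self entry", {
  ws <- small_sim(seed = 60, generations = 3, n_markers = 10, founders = 4,
                  crosses = 3)
  A <- amatrix(ws$sim$true)
  A22 <- relmat(unclass(A), "A22")
  same <- suppressWarnings(per_genotype_correlation(A22, relmat(unclass(A), "Ga")))
  # identical matrices correlate perfectly wherever defined (a founder
  # without offspring has a constant column -> NA)
  expect_true(all(abs(same[!is.na(same)] - 1) < 1e-12))
  expect_gt(mean(!is.na(same)), 0.8)

  # permuting one genotype's column degrades its correlation most
  g <- unclass(A)
  set.seed(2)
  victim <- "JuneBearing.G3.C01.1"
  perm <- sample(setdiff(rownames(g), victim))
  g[victim, perm] <- g[victim, setdiff(rownames(g), victim)]
  g[perm, victim] <- g[victim, perm]
  pg <- per_genotype_correlation(A22, relmat(g, "Ga"))
  expect_lt(pg[victim], sort(pg, decreasing = TRUE)[5])

  expect_error(per_genotype_correlation(relmat(diag(2) |>
    `dimnames<-`(list(c("a", "b"), c("a", "b"))), "A22"),
    relmat(diag(2) |> `dimnames<-`(list(c("a", "b"), c("a", "b"))), "Ga")),
    ">= 3")
})

test_that("outlier pair flagging follows both threshold boxes", {
  ids <- c("w", "x", "y", "z")
  a <- diag(4); g <- diag(4)
  dimnames(a) <- dimnames(g) <- list(ids, ids)
  a["w", "x"] <- a["x", "w"] <- 0.9; g["w", "x"] <- g["x", "w"] <- 0.1  # flagged
  a["w", "y"] <- a["y", "w"] <- 0.1; g["w", "y"] <- g["y", "w"] <- 0.9  # flagged
  a["x", "y"] <- a["y", "x"] <- 0.5; g["x", "y"] <- g["y", "x"] <- 0.5  # not
  a["y", "z"] <- a["z", "y"] <- 0.85; g["y", "z"] <- g["z", "y"] <- 0.3 # not
  fl <- flag_pair_outliers(relmat(a, "A22"), relmat(g, "Ga"))
  expect_equal(nrow(fl), 2)
  expect_setequal(paste(fl$id1, fl$id2), c("w x", "w y"))
})

test_that("outlier genotype flagging needs low corr AND deep pedigree", {
  pg <- c(a = 0.1, b = 0.9, c = 0.1, d = NA)
  comp <- c(a = 6, b = 6, c = 1, d = 10)
  expect_equal(flag_genotype_outliers(pg, comp), "a")
  expect_equal(flag_genotype_outliers(pg, comp, corr_max = 0.95), c("a", "b"))
  expect_error(flag_genotype_outliers(pg, comp[1:2]), "missing ids")
})

test_that("per-genotype accuracy rises with pedigree completeness", {
  ws <- small_sim(seed = 81, generations = 4, n_markers = 1500, founders = 5,
                  subpops = 2, crosses = 5, link_missing_rate = 0.3)
  ped <- ws$sim$observed
  A <- amatrix(ped)
  genotyped <- ped$id      # everyone genotyped: isolates the pedigree effect
  A22 <- relmat(unclass(A), "A22")
  G <- suppressWarnings(vanraden_g(ws$gd$dosage))
  Ga <- scale_g(relmat(unclass(G)[ped$id, ped$id], "G"), A22)$scaled
  pg <- suppressWarnings(per_genotype_correlation(A22, Ga))
  comp <- pedigree_completeness(ped)
  ok <- !is.na(pg)
  expect_gt(stats::cor(comp[ok], pg[ok], method = "spearman"), 0)
})

test_that("injected sample swaps are recovered by the outlier flags", {
  # default swap scenario: deep pedigrees, swaps across sub-populations
  cfg <- sim_config(n_subpops = 3, founders_per_subpop = 6, generations = 6,
                    crosses_per_gen = 6, offspring_per_cross = 2,
                    migration_rate = 0.05, n_markers = 800, seed = 92)
  sim <- simulate_pedigree(cfg)
  gd <- gene_drop(sim$true, cfg$n_markers, cfg$freq_range, seed = 93)
  ped <- sim$true
  comp <- pedigree_completeness(ped)
  set.seed(94)
  genotyped <- union(sample(ped$id, round(0.5 * nrow(ped))),
                     ped$id[comp > 5])            # deep pedigrees genotyped
  pairs <- default_swap_design(ped, n_swaps = 5, candidates = genotyped)
  deg <- degrade(subset_dosage(gd$dosage, genotypes = genotyped),
                 n_swaps = 5, seed = 95, swap_pairs = pairs)
  swapped <- c(pairs)

  A <- amatrix(ped)
  genotyped <- ped$id[ped$id %in% genotyped]
  A22 <- relmat(unclass(A)[genotyped, genotyped], "A22")
  G <- suppressWarnings(vanraden_g(subset_dosage(deg$dosage, genotypes = genotyped)))
  Ga <- scale_g(G, A22)$scaled
  pg <- suppressWarnings(per_genotype_correlation(A22, Ga))
  flags <- union(flag_genotype_outliers(pg, comp),
                 unique(unlist(flag_pair_outliers(A22, Ga)[, c("id1", "id2")])))
  sensitivity <- mean(swapped %in% flags)
  expect_gte(sensitivity, 0.9)
})

test_that("subsample_analysis is reproducible and size-consistent", {
  ws <- small_sim(seed = 44, generations = 3, n_markers = 600, founders = 6,
                  subpops = 2, crosses = 4)
  d <- dosage_matrix(unclass(ws$gd$dosage), imputed = TRUE)
  r1 <- suppressWarnings(subsample_analysis(d, sizes = c(50, 200, 400), reps = 10, seed = 7))
  r2 <- suppressWarnings(subsample_analysis(d, sizes = c(50, 200, 400), reps = 10, seed = 7))
  expect_identical(r1$correlations, r2$correlations)    # bit-reproducible
  expect_true(all(r1$correlations <= 1 + 1e-12))

  # full-marker subset correlates exactly
  rfull <- suppressWarnings(subsample_analysis(d, sizes = ncol(d), reps = 2, seed = 1))
  expect_equal(unname(rfull$correlations[, 1]), c(1, 1))
  expect_equal(rfull$min_size_reliable, ncol(d))

  expect_error(suppressWarnings(subsample_analysis(d, sizes = ncol(d) + 1,
                                                   reps = 2, seed = 1)), "exceeds")
})

test_that("pca_relationship performs classical MDS on the kernel", {
  # duplicated genotypes coincide
  ids <- c("a", "b", "c")
  m <- matrix(c(1, 1, 0.2, 1, 1, 0.2, 0.2, 0.2, 1), 3, dimnames = list(ids, ids))
  p <- pca_relationship(relmat(m, "G"), axes = 2)
  expect_equal(p$coordinates["a", ], p$coordinates["b", ], tolerance = 1e-6)
  expect_true(all(p$explained_variance >= 0 & p$explained_variance <= 1))
  expect_true(all(diff(p$explained_variance) <= 1e-12))

  # 3-point toy with an analytic decomposition: centered matrix has
  # eigenvalues {3d/2, d/2... } for the pattern below -> check against eigen
  d0 <- 0.4
  mm <- matrix(c(1, d0, d0, d0, 1, d0, d0, d0, 1), 3, dimnames = list(ids, ids))
  pp <- pca_relationship(relmat(mm, "G"), axes = 2)
  # centered matrix is (1 - d0) * centering projector: all nonzero
  # eigenvalues equal 1 - d0, explained variance 1/2 each
  expect_equal(pp$explained_variance, c(0.5, 0.5))
  expect_equal(sqrt(rowSums(pp$coordinates^2)),
               rep(sqrt((1 - d0) * 2 / 3), 3), ignore_attr = TRUE)

  asym <- matrix(c(1, 0.5, 0, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(pca_relationship(structure(asym, class = c("relmat", "matrix", "array"),
                                          kind = "G")), "symmetric")
})
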