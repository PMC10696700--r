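#' Pipeline run configuration
#'
#' A single declarative configuration for the full stepwise workflow
#' (curate, relate, fuse, select, diagnose), holding file paths and every
#' threshold with its standard default: MAF minimum 0.05, missingness
#' maximum 0.10, cross-platform concordance 0.7 (on r-squared), LD
#' pruning r-squared 0.5 in 50-marker windows, crossing-parent rule 4
#' uses in a 3-year window, 3000 consensus iterations, marker
#' subsampling 50..3000 by 50 with 200 replicates, and outlier thresholds
#' 0.8 / 0.2 / 5. Unknown keys are rejected so that a typo cannot
#' silently fall back to a default.
#'
#' @param pedigree path to the pedigree CSV (`id,mother,father[,group]`).
#' @param dosages path to the primary dosage TSV or VCF.
#' @param collection path to the whole-collection id list (one id per
#'   line); the whole collection is always explicit, never inferred.
#' @param out_dir output directory for the run.
#' @param size total core-collection size.
#' @param seed integer seed for all stochastic stages.
#' @param dosages2 optional second-platform dosage file to merge.
#' @param crossings optional crossing-record CSV (`mother,father,year`).
#' @param fixed optional id-list file of must-have entries.
#' @param sequenced optional id-list file of already-sequenced entries
#'   (also treated as mandatory).
#' @param preference optional id-list file, breeder tie-break order.
#' @param maf_min,miss_max marker filter thresholds.
#' @param concordance,concordance_mode platform-merge threshold and mode
#'   (`"r2"` or `"r"`).
#' @param ld_r2_max,ld_window LD pruning parameters.
#' @param min_uses,window_years,reference_year crossing-parent rule.
#' @param iterations consensus iterations.
#' @param restarts optimizer restarts per iteration.
#' @param dist_mode distance conversion mode (see [cor_to_dist()]).
#' @param ridge ridge for a singular A22 (see [build_h()]).
#' @param outlier_high,outlier_low,outlier_corr_max,outlier_completeness_min
#'   outlier-flagging thresholds.
#' @return a `run_config` list.
#' @export
run_config <- function(pedigree, dosages, collection, out_dir, size, seed,
                       dosages2 = NULL, crossings = NULL, fixed = NULL,
                       sequenced = NULL, preference = NULL,
                       maf_min = 0.05, miss_max = 0.10,
                       concordance = 0.7, concordance_mode = "r2",
                       ld_r2_max = 0.5, ld_window = 50,
                       min_uses = 4, window_years = 3, reference_year = 2022,
                       iterations = 3000, restarts = 5,
                       dist_mode = "normalized", ridge = 1e-6,
                       outlier_high = 0.8, outlier_low = 0.2,
                       outlier_corr_max = 0.2, outlier_completeness_min = 5) {
  cfg <- as.list(environment())
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1,
            concordance >= 0, concordance <= 1, ld_r2_max >= 0, ld_r2_max <= 1,
            min_uses >= 1, iterations >= 1, size >= 1)
  cfg$dist_mode <- match.arg(dist_mode, c("normalized", "as_printed"))
  cfg$concordance_mode <- match.arg(concordance_mode, c("r2", "r"))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Keys must be a subset of the [run_config()] arguments; unknown keys
#' raise an error.
#'
#' @param path JSON file.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

read_id_list <- function(path) {
  if (is.null(path)) return(character(0))
  x <- trimws(readLines(path))
  x[x != ""]
}

read_dosage_any <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_dosage_vcf(path) else read_dosage_tsv(path)
}

#' Run the full stepwise core-collection pipeline
#'
#' Executes curation (optional platform merge, MAF/missingness filter,
#' mean imputation, LD pruning), pedigree relationships (A, A22,
#' completeness), genomic relationships (G, Ga), hybrid fusion (H, Hcor,
#' D), mandatory-entry assembly (recent crossing parents + must-haves +
#' sequenced), consensus A-NE optimization, and concordance diagnostics.
#' Every intermediate matrix and report is persisted in `out_dir`; the
#' log records package version, configuration and seeds. Re-running with
#' an identical configuration is bit-identical.
#'
#' @param cfg a [run_config()] (or path to its JSON).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ped <- stage("pedigree", read_pedigree(cfg$pedigree))
  d <- stage("dosages", read_dosage_any(cfg$dosages))
  reports <- list()
  if (!is.null(cfg$dosages2)) {
    d2 <- stage("dosages", read_dosage_any(cfg$dosages2))
    mg <- stage("merge", merge_platforms(d, d2, min_concordance = cfg$concordance,
                                         mode = cfg$concordance_mode))
    d <- mg$dosage
    reports <- c(reports, list(mg$report))
  }

  fl <- stage("filter", filter_markers(d, maf_min = cfg$maf_min, miss_max = cfg$miss_max))
  reports <- c(reports, list(fl$report))
  imp <- stage("impute", mean_impute(fl$dosage))
  pruned <- stage("ld_prune", ld_prune(imp, r2_max = cfg$ld_r2_max, window = cfg$ld_window))
  reports <- c(reports, list(curation_report("LD pruning", ncol(pruned), nrow(pruned))))
  report <- do.call(bind_reports, reports)

  unknown_geno <- setdiff(rownames(pruned), ped$id)
  if (length(unknown_geno) > 0) {
    stop("pipeline stage 'relate' failed: genotyped id(s) absent from pedigree: ",
         paste(unknown_geno, collapse = ", "), call. = FALSE)
  }
  A <- stage("amatrix", amatrix(ped))
  genotyped <- ped$id[ped$id %in% rownames(pruned)]   # pedigree order
  A22 <- relmat(unclass(A)[genotyped, genotyped, drop = FALSE], kind = "A22")
  G <- stage("gmatrix", vanraden_g(subset_dosage(pruned, genotypes = genotyped)))
  sg <- stage("scale_g", scale_g(G, A22))
  H <- stage("build_h", build_h(A, sg$scaled, genotyped, ridge = cfg$ridge))
  Hcor <- stage("cov_to_cor", cov_to_cor(H))
  D <- stage("cor_to_dist", cor_to_dist(Hcor, mode = cfg$dist_mode))

  collection <- stage("collection", {
    coll <- read_id_list(cfg$collection)
    bad <- setdiff(coll, relmat_ids(D))
    if (length(bad) > 0) stop("collection id(s) absent from D: ", paste(bad, collapse = ", "))
    coll
  })

  recent <- character(0)
  if (!is.null(cfg$crossings)) {
    cr <- stage("crossings", utils::read.csv(cfg$crossings, stringsAsFactors = FALSE))
    recent <- stage("recent_parents",
                    select_recent_parents(cr, min_uses = cfg$min_uses,
                                          window_years = cfg$window_years,
                                          reference_year = cfg$reference_year))
  }
  fixed <- sort(unique(c(intersect(recent, collection),
                         intersect(read_id_list(cfg$fixed), collection),
                         intersect(read_id_list(cfg$sequenced), collection))))
  preference <- read_id_list(cfg$preference)
  core <- stage("select",
                consensus_core(D, size = cfg$size, fixed = fixed,
                               collection = collection, n_iter = cfg$iterations,
                               base_seed = cfg$seed,
                               preference = if (length(preference)) preference else NULL,
                               restarts = cfg$restarts))

  comp <- pedigree_completeness(ped, A)
  pg <- suppressWarnings(per_genotype_correlation(A22, sg$scaled))
  diag <- list(
    overall_correlation = matrix_correlation(A22, sg$scaled),
    per_genotype_correlation = as.list(pg),
    completeness = as.list(comp),
    pair_outliers = flag_pair_outliers(A22, sg$scaled, high = cfg$outlier_high,
                                       low = cfg$outlier_low),
    genotype_outliers = flag_genotype_outliers(pg, comp, corr_max = cfg$outlier_corr_max,
                                               completeness_min = cfg$outlier_completeness_min),
    scale = list(beta = sg$beta, alpha = sg$alpha))

  out <- function(f) file.path(cfg$out_dir, f)
  write_relmat(A, out("A.tsv"))
  write_relmat(A22, out("A22.tsv"))
  write_relmat(G, out("G.tsv"))
  write_relmat(sg$scaled, out("Ga.tsv"))
  write_relmat(H, out("H.tsv"))
  write_relmat(Hcor, out("Hcor.tsv"))
  write_relmat(D, out("D.tsv"))
  write_dosage_tsv(pruned, out("dosages_curated.tsv"))
  utils::write.table(as.data.frame(report), out("curation_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(diag, out("diagnostics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(list(
    size = cfg$size, fixed = core$fixed, free = core$free, entries = core$entries,
    criterion = core$criterion, frequencies = as.list(core$frequencies),
    always_selected = core$always_selected, seeds = core$seeds),
    out("core.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_cfg <- cfg
  class(log_cfg) <- NULL
  writeLines(c(
    paste0("stepcore version: ", as.character(utils::packageVersion("stepcore"))),
    paste0("seed: ", cfg$seed),
    paste0("config: ", jsonlite::toJSON(log_cfg, auto_unbox = TRUE, null = "null"))),
    out("run_log.txt"))

  invisible(list(pedigree = ped, dosage = pruned, report = report, A = A, A22 = A22,
                 G = G, Ga = sg$scaled, H = H, Hcor = Hcor, D = D,
                 fixed = fixed, core = core, diagnostics = diag))
}
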