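#' Run configuration for the end-to-end analysis
#'
#' Defaults follow standard RAD-seq seascape practice: MAF > 0.05, call
#' rate 0.8 in at least n - 1 populations, 999 permutations, cumulative
#' variance 0.85 for the retained environmental components, FDR 0.05.
#'
#' @param vcf,popmap,sites,env,raster input paths; leave `NULL` to
#'   simulate the inputs from `sim` instead.
#' @param sim a [sim_config] used when input paths are `NULL`.
#' @param maf_min,call_rate_min,min_pops_present locus filter thresholds.
#' @param nperm MMRR permutations.
#' @param cum_var retained-component rule for the environmental PCA.
#' @param fdr outlier false discovery rate.
#' @param run_demography whether to run the JSFS model comparison.
#' @param demog list of demography settings (`projection`, `runs`,
#'   `nreps`, `maxit`, `split_barrier`: barrier whose sides define the
#'   two populations).
#' @param seed master seed.
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, popmap = NULL, sites = NULL, env = NULL,
                       raster = NULL, sim = sim_config(),
                       maf_min = 0.05, call_rate_min = 0.8,
                       min_pops_present = NULL, nperm = 999,
                       cum_var = 0.85, fdr = 0.05,
                       run_demography = FALSE,
                       demog = list(projection = c(10, 10), runs = 5,
                                    nreps = 1500, maxit = 100,
                                    split_barrier = NULL),
                       seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full seascape-genomics analysis
#'
#' Orchestrates: genotype input (or simulation) -> locus filtering ->
#' diversity table -> pairwise FST -> least-cost geographic,
#' environmental-PCA and barrier distance predictors -> candidate model
#' enumeration -> MMRR fits ranked by AICc -> per-locus FST outlier scan
#' -> optional folded-JSFS divergence-model comparison. Every stage logs
#' its record counts; artifacts are returned as a list and, when
#' `out_dir` is set, written as TSV/JSON.
#'
#' @param cfg a [run_config].
#' @param quiet suppress progress messages.
#' @return A list with elements `genotypes`, `diversity`, `fst`,
#'   `geo_dist`, `env_pca`, `env_dist`, `barrier_vars`, `model_table`,
#'   `best_fit`, `outliers`, and (optionally) `demography`, plus a `log`
#'   tibble of stage messages.
#' @export
run_full_analysis <- function(cfg = run_config(), quiet = FALSE) {
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, message = msg)
    if (!quiet) message("[", stage, "] ", msg)
  }
  if (is.null(cfg$vcf)) {
    sea <- simulate_seascape(cfg$sim)
    g <- simulate_genotypes(cfg$sim, sea$sites)
    sites <- sea$sites; env <- sea$env; rast <- sea$raster
    note("input", sprintf("simulated %d individuals x %d loci at %d sites (seed %d)",
                          nrow(g$calls), ncol(g$calls), nrow(sites), cfg$sim$seed))
  } else {
    g <- read_genotypes(cfg$vcf, cfg$popmap)
    sites <- readr::read_csv(cfg$sites, show_col_types = FALSE)
    env <- readr::read_csv(cfg$env, show_col_types = FALSE)
    rast <- read_ascii_raster(cfg$raster)
    note("input", sprintf("read %d individuals x %d loci", nrow(g$calls), ncol(g$calls)))
  }
  n0 <- ncol(g$calls)
  g <- filter_loci(g, cfg$maf_min, cfg$call_rate_min, cfg$min_pops_present)
  note("filter", sprintf("loci in %d, retained %d, removed %d (MAF > %g, call rate >= %g)",
                         n0, ncol(g$calls), n0 - ncol(g$calls), cfg$maf_min, cfg$call_rate_min))

  div <- diversity_stats(g)
  fst <- pairwise_fst(g)
  note("popgen", sprintf("diversity for %d sites; pairwise FST range [%.4f, %.4f]",
                         nrow(div), min(fst), max(fst)))

  geo <- least_cost_distance(rast, sites)
  epca <- env_pca(env)
  edist <- env_distance(epca, cum_var = cfg$cum_var)
  barrier_names <- sub("^side_", "", grep("^side_", names(sites), value = TRUE))
  bvars <- if (length(barrier_names) > 0) barrier_variables(sites, barrier_names) else list()
  note("distances", sprintf("geo span %.0f km; %d env components retained; %d barrier variables",
                            max(geo) / 1000, attr(edist, "n_components"), length(bvars)))

  specs <- build_model_set(TRUE, TRUE, names(bvars))
  Xs <- c(list(geo = geo, env = edist), bvars)
  set.seed(cfg$seed)
  fit_seeds <- sample.int(2^30, length(specs))
  fits <- purrr::map2(specs, fit_seeds, function(sp, sd) {
    mmrr_fit(fst, Xs, sp, nperm = cfg$nperm, seed = sd)
  })
  ranking <- rank_models(fits)
  best <- attr(ranking, "fits")[[1]]
  note("mmrr", sprintf("%d candidate models fitted; best: FST ~ %s (AICc %.2f, weight %.3f)",
                       length(specs), ranking$model[1], ranking$aicc[1], ranking$weight[1]))

  pl <- per_locus_fst(g)
  out <- tryCatch({
    f <- fit_trimmed_chisq(pl)
    outlier_pvalues(f, fdr = cfg$fdr)
  }, error = function(e) {
    note("outliers", paste("scan failed:", conditionMessage(e)))
    NULL
  })
  if (!is.null(out)) {
    note("outliers", sprintf("null df %.2f, FSTbar %.4f; %d outliers at FDR %g",
                             out$df, out$fstbar, out$n_outliers, cfg$fdr))
  }

  demog_res <- NULL
  if (isTRUE(cfg$run_demography)) {
    bsplit <- cfg$demog$split_barrier %||% barrier_names[length(barrier_names)]
    sidev <- sites[[paste0("side_", bsplit)]]
    grouping <- stats::setNames(ifelse(sidev == sidev[1], "pop1", "pop2"), sites$site)
    obs <- folded_jsfs(g, grouping, projection = cfg$demog$projection)
    demog_res <- compare_models(obs, seed = cfg$seed, runs = cfg$demog$runs,
                                nreps = cfg$demog$nreps, maxit = cfg$demog$maxit)
    note("demography", sprintf("7 divergence models compared; best: %s (AIC %.2f)",
                               demog_res$model[1], demog_res$aic[1]))
  }

  res <- list(
    genotypes = g, diversity = div, fst = fst, geo_dist = geo,
    env_pca = epca, env_dist = edist, barrier_vars = bvars,
    model_table = ranking, best_fit = best, outliers = out,
    demography = demog_res, log = dplyr::bind_rows(log),
    config = cfg
  )
  if (!is.null(cfg$out_dir)) write_run_outputs(res, cfg$out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_matrix_tsv <- function(m, path) {
  df <- data.frame(site = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path)
}

write_run_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$diversity, file.path(dir, "diversity.tsv"))
  write_matrix_tsv(res$fst, file.path(dir, "pairwise_fst.tsv"))
  write_matrix_tsv(res$geo_dist, file.path(dir, "geo_dist.tsv"))
  write_matrix_tsv(res$env_dist, file.path(dir, "env_dist.tsv"))
  readr::write_tsv(tibble::as_tibble(res$model_table), file.path(dir, "model_table.tsv"))
  if (!is.null(res$outliers)) {
    readr::write_tsv(res$outliers$loci, file.path(dir, "outliers.tsv"))
  }
  if (!is.null(res$demography)) {
    readr::write_tsv(tibble::as_tibble(res$demography), file.path(dir, "demography.tsv"))
  }
  readr::write_tsv(res$log, file.path(dir, "run_log.tsv"))
  meta <- list(
    seed = res$config$seed, nperm = res$config$nperm,
    maf_min = res$config$maf_min, call_rate_min = res$config$call_rate_min,
    fdr = res$config$fdr,
    model_formulas = res$model_table$model,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}
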