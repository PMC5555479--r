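# Pipeline orchestration: simulate/read -> QC -> crossovers -> heterochiasmy
# -> QTL scan, with a consolidated report bundle and manifest.

#' Pipeline configuration
#'
#' Exactly one of `input_dir` (holding map.csv, geno.csv, pheno.csv in the
#' documented dialects) or `sim` (a [sim_config()]) must be supplied.
#'
#' @param input_dir directory with the three input tables, or `NULL`.
#' @param sim a `sim_config`, or `NULL`.
#' @param out_dir output directory for the report bundle.
#' @param qc named list of [run_qc()] arguments.
#' @param correction a [correction_params()].
#' @param informative_both_only restrict heterochiasmy crossover detection to
#'   marker types informative in both parents.
#' @param scan named list: `traits` (`NULL` = all), `n_perm`, `alpha_genome`,
#'   `alpha_chrom`, `lod_drop`, `sex_screen_p`.
#' @param windows window widths for the sensitivity table.
#' @param seed integer seed governing all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL,
                            out_dir = tempfile("chiasmr_run_"),
                            qc = list(), correction = correction_params(),
                            informative_both_only = TRUE,
                            scan = list(), windows = c(50, 25, 10),
                            seed = 1L) {
  if (is.null(input_dir) == is.null(sim)) {
    stop("exactly one of 'input_dir' and 'sim' must be supplied")
  }
  scan_defaults <- list(traits = NULL, n_perm = 1000, alpha_genome = 0.05,
                        alpha_chrom = 0.01, lod_drop = 1.5, sex_screen_p = 0.20)
  scan <- utils::modifyList(scan_defaults, scan)
  structure(list(input_dir = input_dir, sim = sim, out_dir = out_dir,
                 qc = qc, correction = correction,
                 informative_both_only = informative_both_only,
                 scan = scan, windows = windows, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in fixed order: input (simulate or read) -> QC -> crossover
#' detection and double-crossover correction -> heterochiasmy summaries ->
#' QTL scan per trait.  The bundle written to `out_dir` contains
#' qc_report.json, crossovers.tsv, heterochiasmy.json, scan_<trait>.tsv,
#' qtl_table.tsv and MANIFEST.json (version, parameters, seed, completed
#' stages).  A stage failure aborts with the failing stage named; partial
#' outputs are kept and the manifest marks the run incomplete.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages_done <- character(0)
  manifest <- list(
    package = "chiasmr",
    version = as.character(utils::packageVersion("chiasmr")),
    seed = config$seed,
    parameters = list(qc = config$qc, correction = unclass(config$correction),
                      scan = config$scan, windows = config$windows,
                      informative_both_only = config$informative_both_only),
    complete = FALSE, stages = character(0))
  write_manifest <- function() {
    manifest$stages <<- stages_done
    jsonlite::write_json(manifest, file.path(config$out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages_done <<- c(stages_done, name)
    res
  }

  set.seed(config$seed)
  inp <- run_stage("input", {
    if (!is.null(config$sim)) {
      sim <- simulate_cross(config$sim)
      list(map = sim$map, geno = sim$geno, pheno = sim$pheno, sim = sim)
    } else {
      map <- read_map(file.path(config$input_dir, "map.csv"))
      list(map = map,
           geno = read_genotypes(file.path(config$input_dir, "geno.csv"), map),
           pheno = read_phenotypes(file.path(config$input_dir, "pheno.csv")),
           sim = NULL)
    }
  })

  qc <- run_stage("qc", {
    r <- do.call(run_qc, c(list(geno = inp$geno, map = inp$map,
                                pheno = inp$pheno), config$qc))
    jsonlite::write_json(
      list(markers_removed = r$markers_removed,
           n_markers_retained = r$n_markers_retained,
           offspring_removed = r$offspring_removed,
           phenotype_outliers = r$phenotype_outliers,
           duplicates = r$duplicates,
           xo_outlier = r$xo_outlier[c("removed", "cutoff", "mean", "median")],
           params = r$params),
      file.path(config$out_dir, "qc_report.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA, null = "null")
    r
  })

  xo <- run_stage("crossovers", {
    raw <- detect_all_crossovers(qc$geno, qc$map,
                                 informative_both_only =
                                   config$informative_both_only)
    corr <- apply_correction(raw, qc$map, config$correction)
    write_crossovers(corr, file.path(config$out_dir, "crossovers.tsv"))
    list(raw = raw, corrected = corr)
  })

  het <- run_stage("heterochiasmy", {
    sm <- summarize_crossovers(xo$corrected, qc$map)
    dist <- positional_distribution(xo$corrected, qc$map)
    cen <- infer_centromere_end(xo$corrected, qc$map)
    sens <- window_sensitivity(xo$raw, qc$map, windows = config$windows,
                               chaining = config$correction$chaining,
                               odd_policy = config$correction$odd_policy)
    write_heterochiasmy_json(sm, file.path(config$out_dir, "heterochiasmy.json"),
                             extra = list(external20 = as.list(dist$external20),
                                          centromere_calls = cen,
                                          window_sensitivity = sens))
    utils::write.table(dist$counts,
                       file.path(config$out_dir, "positional_bins.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(summary = sm, distribution = dist, centromere = cen,
         sensitivity = sens)
  })

  scan_res <- run_stage("scan", {
    traits <- config$scan$traits
    if (is.null(traits)) traits <- trait_names(qc$pheno)
    fits <- list(); scans <- list(); rows <- list()
    for (tr in traits) {
      use_sex <- isTRUE(sex_covariate_screen(qc$pheno, tr,
                                             config$scan$sex_screen_p))
      covs <- if (use_sex) "sex" else NULL
      sc <- marker_scan(qc$pheno, qc$geno, qc$map, tr, covariates = covs,
                        shapiro_advisory = FALSE)
      th <- permutation_thresholds(qc$pheno, qc$geno, qc$map, tr,
                                   covariates = covs,
                                   n_perm = config$scan$n_perm,
                                   alpha_genome = config$scan$alpha_genome,
                                   alpha_chrom = config$scan$alpha_chrom,
                                   seed = config$seed + match(tr, traits))
      pk <- scan_peaks(sc, th, drop = config$scan$lod_drop)
      write_scan(sc, file.path(config$out_dir,
                               paste0("scan_", make.names(tr), ".tsv")))
      scans[[tr]] <- list(scan = sc, thresholds = th, peaks = pk)
      if (nrow(pk)) {
        fit <- fit_multi_qtl(qc$pheno, qc$geno, qc$map, tr, pk$marker,
                             sex = use_sex)
        fits[[tr]] <- fit
        pk$trait <- tr
        pk$total_pve <- fit$total_pve
        pk$term_pve <- fit$term_pve[make.names(pk$marker)]
        rows[[tr]] <- pk
      }
    }
    qtl_table <- if (length(rows)) do.call(rbind, rows) else
      data.frame(trait = character(0), lg = character(0), marker = character(0),
                 pos = numeric(0), lod = numeric(0), significance = character(0),
                 ci_lo = numeric(0), ci_hi = numeric(0),
                 total_pve = numeric(0), term_pve = numeric(0))
    write_qtl_table(qtl_table, file.path(config$out_dir, "qtl_table.tsv"))
    list(scans = scans, fits = fits, qtl_table = qtl_table)
  })

  manifest$complete <- TRUE
  write_manifest()
  invisible(list(input = inp, qc = qc, crossovers = xo, heterochiasmy = het,
                 scan = scan_res, out_dir = config$out_dir))
}
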