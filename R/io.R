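# Fixed-dialect readers and writers for the pipeline tables and artifacts.
#
# map.csv:   marker,lg,pos_cM,seg_type,lg_class,tetraploid,sex_linked,centromere_end
# geno.csv:  offspring id column, then one column per marker with phase codes
#            {ac,ad,bc,bd,a-,b-,-c,-d,hk,-}; raw allele pairs also accepted.
# pheno.csv: offspring,sex,<trait columns>; "-" and "" parse as missing.

#' Read a genetic map CSV
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "lg", "pos_cM", "seg_type", "lg_class", "tetraploid",
            "sex_linked", "centromere_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("map file missing column(s): ",
                         paste(miss, collapse = ", "))
  names(df)[names(df) == "pos_cM"] <- "pos"
  genetic_map(df)
}

#' Write a genetic map CSV
#' @param map a `genetic_map`.
#' @param path file path.
#' @export
write_map <- function(map, path) {
  df <- as.data.frame(map)
  names(df)[names(df) == "pos"] <- "pos_cM"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype CSV against a map
#'
#' The first column holds offspring ids; remaining columns are markers, which
#' must all be present in the map.  Codes are validated against each marker's
#' segregation type; the hkxhk heterozygote is stored as ambiguous.
#'
#' @param path file path.
#' @param map the `genetic_map`.
#' @return a [phased_genotypes()] object.
#' @export
read_genotypes <- function(path, map) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  unknown <- setdiff(colnames(mat), map$marker)
  if (length(unknown)) {
    stop("genotype file contains marker(s) not in the map: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  phased_genotypes(mat, map)
}

#' Write a genotype CSV (phase-code dialect)
#' @param geno a `phased_geno`.
#' @param map the matching `genetic_map`.
#' @param path file path.
#' @export
write_genotypes <- function(geno, map, path) {
  out <- geno$raw
  for (st in unique(map$seg_type)) {
    j <- which(map$seg_type == st)
    out[, j] <- .raw_to_phase(st, out[, j, drop = FALSE])
  }
  out[is.na(out)] <- "-"
  df <- data.frame(offspring = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#' @param path file path.
#' @param transform optional named per-trait transform flags.
#' @return a [pheno_table()].
#' @export
read_phenotypes <- function(path, transform = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("-", "", "NA"))
  pheno_table(df, transform = transform)
}

#' Write a phenotype CSV
#' @param pheno a `pheno_table`.
#' @param path file path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE,
                   na = "-")
  invisible(path)
}

#' Write crossover events to TSV
#' @param events an `xo_events` data.frame.
#' @param path file path.
#' @export
write_crossovers <- function(events, path) {
  cols <- c("offspring", "parent", "lg", "left_marker", "left_pos",
            "right_marker", "right_pos", "midpoint", "percent_pos",
            "cluster", "status")
  utils::write.table(as.data.frame(events)[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read crossover events from TSV
#' @param path file path.
#' @return an `xo_events` data.frame.
#' @export
read_crossovers <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(offspring = "character",
                                         lg = "character",
                                         left_marker = "character",
                                         right_marker = "character",
                                         cluster = "integer",
                                         status = "character"))
  class(ev) <- c("xo_events", "data.frame")
  ev
}

#' Write the heterochiasmy summary to JSON
#' @param summary an `xo_summary`.
#' @param path file path.
#' @param extra optional named list merged into the JSON object (e.g. the
#'   positional distribution or centromere calls).
#' @export
write_heterochiasmy_json <- function(summary, path, extra = NULL) {
  obj <- list(totals = summary$totals, per_lg = summary$per_lg,
              per_chrom_means = summary$per_chrom_means,
              removed = summary$removed,
              include_sex_lg = summary$include_sex_lg)
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a LOD scan to TSV
#' @param scan a `qtl_scan`.
#' @param path file path.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a LOD scan from TSV
#' @param path file path.
#' @return a `qtl_scan` data.frame (without threshold attributes).
#' @export
read_scan <- function(path) {
  sc <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(marker = "character",
                                         lg = "character"))
  class(sc) <- c("qtl_scan", "data.frame")
  sc
}

#' Write the QTL result table to TSV
#' @param qtl_table data.frame of significant QTL (trait, lg, pos, CI,
#'   significance, PVE, effects).
#' @param path file path.
#' @export
write_qtl_table <- function(qtl_table, path) {
  utils::write.table(qtl_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write simulated inputs and ground truth to a directory
#'
#' Emits the three standard pipeline inputs (map.csv, geno.csv, pheno.csv)
#' plus truth.json for a simulated cross.
#'
#' @param sim a `sim_cross`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_cross <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cross"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map(sim$map, file.path(dir, "map.csv"))
  write_genotypes(sim$geno, sim$map, file.path(dir, "geno.csv"))
  write_phenotypes(sim$pheno, file.path(dir, "pheno.csv"))
  jsonlite::write_json(
    list(true_crossovers = sim$truth$true_crossovers,
         true_error_sites = sim$truth$true_error_sites,
         true_qtl = sim$truth$true_qtl,
         true_ratio = sim$truth$true_ratio),
    file.path(dir, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields override the [sim_config()] defaults; `lg_spec` and
#' `qtl_effects`, when present, are coerced to data.frames.
#'
#' @param path YAML file path.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("lg_spec", "qtl_effects")) {
    if (!is.null(raw[[nm]])) {
      raw[[nm]] <- as.data.frame(lapply(raw[[nm]], unlist),
                                 stringsAsFactors = FALSE)
    }
  }
  for (nm in c("marker_type_mix", "sex_effect", "interaction_effect",
               "residual_sd", "transform")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}
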