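# Core data containers: genetic map, phased genotypes, phenotype table.

LG_CLASSES <- c("fused_metacentric", "acrocentric")

#' Construct a genetic map
#'
#' One row per marker, ordered by linkage group and position, with per-lg
#' annotations (chromosome class, residual-tetraploidy flag, sex linkage,
#' centromere end) repeated on each marker row.
#'
#' @param markers data.frame with columns `marker`, `lg`, `pos` (cM),
#'   `seg_type`, `lg_class`, `tetraploid`, `sex_linked`, `centromere_end`.
#' @return object of class `genetic_map` (a validated data.frame).
#' @export
genetic_map <- function(markers) {
  need <- c("marker", "lg", "pos", "seg_type", "lg_class", "tetraploid",
            "sex_linked", "centromere_end")
  miss <- setdiff(need, names(markers))
  if (length(miss)) stop("map is missing column(s): ", paste(miss, collapse = ", "))
  markers <- as.data.frame(markers)[, need]
  markers$marker <- as.character(markers$marker)
  markers$lg <- as.character(markers$lg)
  markers$seg_type <- as.character(markers$seg_type)
  markers$lg_class <- as.character(markers$lg_class)
  markers$centromere_end <- as.character(markers$centromere_end)
  markers$tetraploid <- as.logical(markers$tetraploid)
  markers$sex_linked <- as.logical(markers$sex_linked)
  if (anyDuplicated(markers$marker)) stop("duplicate marker ids in map")
  if (!all(markers$seg_type %in% SEG_TYPES)) {
    stop("unknown seg_type: ",
         paste(setdiff(unique(markers$seg_type), SEG_TYPES), collapse = ", "))
  }
  if (!all(markers$lg_class %in% LG_CLASSES)) stop("unknown lg_class")
  if (!all(markers$centromere_end %in% c("start", "end", "unknown"))) {
    stop("centromere_end must be start/end/unknown")
  }
  if (any(markers$pos < 0)) stop("negative cM position")
  for (lg in unique(markers$lg)) {
    p <- markers$pos[markers$lg == lg]
    if (is.unsorted(p)) stop("positions not non-decreasing within ", lg)
  }
  # per-lg annotations must be constant within lg
  for (col in c("lg_class", "tetraploid", "sex_linked", "centromere_end")) {
    n_per <- tapply(markers[[col]], markers$lg, function(x) length(unique(x)))
    if (any(n_per > 1)) stop("per-lg column '", col, "' varies within a linkage group")
  }
  rownames(markers) <- NULL
  class(markers) <- c("genetic_map", "data.frame")
  markers
}

#' Per-linkage-group annotation table of a genetic map
#'
#' @param map a `genetic_map`.
#' @return data.frame with one row per lg: class, tetraploid and sex-linkage
#'   flags, centromere end, marker count and map length (last marker position).
#' @export
lg_info <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  sp <- split(seq_len(nrow(map)), factor(map$lg, levels = unique(map$lg)))
  out <- do.call(rbind, lapply(names(sp), function(lg) {
    i <- sp[[lg]]
    data.frame(lg = lg, lg_class = map$lg_class[i[1]],
               tetraploid = map$tetraploid[i[1]],
               sex_linked = map$sex_linked[i[1]],
               centromere_end = map$centromere_end[i[1]],
               n_markers = length(i), length = max(map$pos[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Construct phased genotypes for a four-way cross
#'
#' Validates an offspring-by-marker matrix of observed genotype codes against
#' the map's segregation types and resolves each call into its dam (a/b) and
#' sire (c/d) haplotype contributions.  Accepts either raw allele-pair codes
#' (`ee`, `ef`, `hk`, `nn`, ...) or phase codes (`ac`, `bd`, `-c`, `a-`, ...);
#' `"-"`, `""` and `NA` are missing.  The hkxhk heterozygote `hk` is stored as
#' observed but is ambiguous (unknown) for both parental contributions.
#'
#' @param raw character matrix, rows = offspring (rownames = ids), columns in
#'   the map's marker order.
#' @param map a `genetic_map` whose markers match `colnames(raw)`.
#' @return object of class `phased_geno`: list with matrices `raw`, `dam`,
#'   `sire` and the `map` marker ids.
#' @export
phased_genotypes <- function(raw, map) {
  stopifnot(inherits(map, "genetic_map"))
  raw <- as.matrix(raw)
  if (is.null(colnames(raw))) colnames(raw) <- map$marker
  if (!identical(colnames(raw), map$marker)) {
    if (!all(colnames(raw) %in% map$marker)) {
      stop("genotype matrix contains marker(s) absent from the map: ",
           paste(utils::head(setdiff(colnames(raw), map$marker), 5), collapse = ", "))
    }
    raw <- raw[, map$marker, drop = FALSE]
  }
  if (is.null(rownames(raw))) rownames(raw) <- paste0("off", seq_len(nrow(raw)))
  dam <- sire <- matrix(NA_character_, nrow(raw), ncol(raw),
                        dimnames = dimnames(raw))
  for (st in unique(map$seg_type)) {
    j <- which(map$seg_type == st)
    codes <- .normalise_code(st, raw[, j, drop = FALSE])
    bad <- !is.na(codes) & !(codes %in% .seg_raw_codes[[st]])
    if (any(bad)) {
      k <- which(bad, arr.ind = TRUE)[1, ]
      stop("illegal code '", codes[bad][1], "' for ", st, " marker ",
           map$marker[j[k[2]]], ", offspring ", rownames(raw)[k[1]])
    }
    raw[, j] <- codes
    res <- resolve_genotype(st, codes)
    dam[, j] <- res$dam
    sire[, j] <- res$sire
  }
  structure(list(raw = raw, dam = dam, sire = sire, markers = map$marker),
            class = "phased_geno")
}

#' Per-offspring missing-call fraction
#' @param geno a `phased_geno`.
#' @return named numeric vector.
#' @export
missing_fraction <- function(geno) {
  stopifnot(inherits(geno, "phased_geno"))
  rowMeans(is.na(geno$raw))
}

#' Construct a phenotype table
#'
#' @param df data.frame with columns `offspring`, `sex` (`"F"`/`"M"`) and one
#'   numeric column per trait.
#' @param transform optional named character vector per trait, values `"none"`
#'   or `"log"`; unnamed traits default to `"none"`.
#' @return object of class `pheno_table`.
#' @export
pheno_table <- function(df, transform = NULL) {
  df <- as.data.frame(df)
  if (!all(c("offspring", "sex") %in% names(df))) {
    stop("phenotype table needs 'offspring' and 'sex' columns")
  }
  df$offspring <- as.character(df$offspring)
  df$sex <- as.character(df$sex)
  if (!all(is.na(df$sex) | df$sex %in% c("F", "M"))) stop("sex must be F or M")
  traits <- setdiff(names(df), c("offspring", "sex"))
  for (tr in traits) df[[tr]] <- as.numeric(df[[tr]])
  tf <- stats::setNames(rep("none", length(traits)), traits)
  if (!is.null(transform)) {
    if (!all(names(transform) %in% traits)) stop("transform names not all traits")
    if (!all(transform %in% c("none", "log"))) stop("transform must be none/log")
    tf[names(transform)] <- transform
  }
  attr(df, "transform") <- tf
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Trait names of a phenotype table
#' @param pheno a `pheno_table`.
#' @return character vector.
#' @export
trait_names <- function(pheno) {
  setdiff(names(pheno), c("offspring", "sex"))
}

# trait values with the per-trait transform applied
.trait_values <- function(pheno, trait) {
  if (!trait %in% trait_names(pheno)) stop("unknown trait: ", trait)
  x <- pheno[[trait]]
  if (identical(attr(pheno, "transform")[[trait]], "log")) x <- log(x)
  x
}
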