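# Marker- and sample-level quality control preceding all analyses.

#' Segregation-distortion chi-square tests per marker
#'
#' Tests each marker's observed genotype-class counts against its Mendelian
#' expectation: 1:1 for one-parent-informative markers (nnxnp, lmxll; df 1),
#' 1:2:1 for hkxhk (df 2), 1:1:1:1 for efxeg (df 3).  Markers with
#' `p <= p_threshold` are flagged removed (no multiple-testing correction,
#' matching the conventional raw-P map-filtering practice).  Markers with
#' fewer than 2 non-missing calls are skipped with a warning and not removed.
#'
#' @param geno a `phased_geno`.
#' @param map the `genetic_map`.
#' @param p_threshold removal threshold on the upper-tail p-value.
#' @return data.frame per tested marker: observed counts (list column
#'   `counts`), `chisq`, `df`, `p`, `removed`.
#' @export
segregation_filter <- function(geno, map, p_threshold = 0.01) {
  stopifnot(inherits(geno, "phased_geno"), inherits(map, "genetic_map"))
  m <- nrow(map)
  chisq <- p <- rep(NA_real_, m)
  df <- rep(NA_integer_, m)
  counts <- vector("list", m)
  skipped <- 0L
  for (j in seq_len(m)) {
    st <- map$seg_type[j]
    lev <- .seg_raw_codes[[st]]
    obs <- table(factor(geno$raw[, j], levels = lev))
    n <- sum(obs)
    counts[[j]] <- as.integer(obs)
    if (n < 2) { skipped <- skipped + 1L; next }
    expd <- .seg_expected[[st]] * n
    chisq[j] <- sum((obs - expd)^2 / expd)
    df[j] <- length(lev) - 1L
    p[j] <- stats::pchisq(chisq[j], df[j], lower.tail = FALSE)
  }
  if (skipped > 0) {
    warning(skipped, " marker(s) with < 2 non-missing calls skipped")
  }
  out <- data.frame(marker = map$marker, lg = map$lg, seg_type = map$seg_type,
                    chisq = chisq, df = df, p = p,
                    removed = !is.na(p) & p <= p_threshold,
                    stringsAsFactors = FALSE)
  out$counts <- counts
  out
}

#' Single-pass k-SD phenotype outlier filter
#'
#' Values more than `k` standard deviations from the mean (both computed once
#' over the non-missing values) are set to missing.  With zero SD nothing is
#' removed.  The single pass is deliberately conservative at small n.
#'
#' @param x numeric vector (may contain NA).
#' @param k SD multiplier (default 3).
#' @param ids optional ids parallel to `x`.
#' @return list: `values` (x with outliers set NA), `removed` (ids or indices).
#' @export
phenotype_outlier_filter <- function(x, k = 3, ids = seq_along(x)) {
  ok <- !is.na(x)
  if (sum(ok) < 3) return(list(values = x, removed = ids[0]))
  mu <- mean(x[ok]); sdev <- stats::sd(x[ok])
  if (!is.finite(sdev) || sdev == 0) return(list(values = x, removed = ids[0]))
  out <- ok & abs(x - mu) > k * sdev
  x[out] <- NA
  list(values = x, removed = ids[which(out)])
}

#' Duplicate-sample check by pairwise genotype identity
#'
#' Computes, for every offspring pair, the proportion of identical calls over
#' markers non-missing in both, and reports pairs at or above the threshold
#' (candidate mislabelled duplicates).
#'
#' @param geno a `phased_geno`.
#' @param threshold identity proportion at or above which a pair is reported.
#' @return data.frame `id1`, `id2`, `n_compared`, `identity` for flagged pairs.
#' @export
duplicate_sample_check <- function(geno, threshold = 0.9) {
  raw <- geno$raw
  n <- nrow(raw)
  # integer recoding makes the ~n^2/2 vector comparisons cheap
  codes <- matrix(match(raw, sort(unique(as.vector(raw)))), n,
                  dimnames = dimnames(raw))
  ok <- !is.na(codes)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      xi <- codes[i, ]; oki <- ok[i, ]
      for (j in seq((i + 1), n)) {
        both <- oki & ok[j, ]
        nc <- sum(both)
        idp <- if (nc > 0) sum(xi[both] == codes[j, both]) / nc else NA_real_
        if (!is.na(idp) && idp >= threshold) {
          out[[length(out) + 1]] <- data.frame(
            id1 = rownames(raw)[i], id2 = rownames(raw)[j],
            n_compared = nc, identity = idp, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(id1 = character(0), id2 = character(0),
               n_compared = integer(0), identity = numeric(0),
               stringsAsFactors = FALSE)
}

#' Flag offspring with outlying raw obligate crossover counts
#'
#' Operationalises the removal of samples whose raw obligate crossover count
#' is grossly inflated (typically by genotyping problems): counts exceeding
#' `median + m * max(MAD, 1)` are flagged (plain median absolute deviation,
#' no consistency constant).  An explicit `exclude_ids` list can be given
#' instead of, or in addition to, the rule.
#'
#' @param counts named per-offspring raw obligate crossover counts, as from
#'   [count_obligate()].
#' @param m MAD multiplier (default 10).
#' @param exclude_ids ids to flag unconditionally.
#' @return list: `removed` ids, `cutoff`, and `mean`/`median` of the retained
#'   counts.
#' @export
crossover_outlier_filter <- function(counts, m = 10, exclude_ids = character(0)) {
  med <- stats::median(counts)
  mad0 <- stats::mad(counts, constant = 1)
  cutoff <- med + m * max(mad0, 1)
  removed <- union(names(counts)[counts > cutoff],
                   intersect(exclude_ids, names(counts)))
  kept <- counts[setdiff(names(counts), removed)]
  list(removed = removed, cutoff = cutoff,
       mean = mean(kept), median = stats::median(kept))
}

#' Run the full QC stage
#'
#' Applies, in order: segregation-distortion marker removal, duplicate-sample
#' detection, raw-crossover-count outlier removal, optional per-offspring
#' missingness filtering, and per-trait phenotype outlier trimming.  Each
#' filter is idempotent and the composition is applied once.
#'
#' @param geno,map,pheno the three validated inputs.
#' @param distortion_p segregation-distortion removal threshold.
#' @param sd_k phenotype outlier SD multiplier.
#' @param dup_threshold duplicate identity threshold.
#' @param xo_outlier_m crossover-count MAD multiplier.
#' @param max_missing optional maximum per-offspring missing-call fraction.
#' @param exclude_ids offspring ids excluded unconditionally.
#' @return object of class `qc_report`: filtered `geno`, `map`, `pheno` plus
#'   removal tables (`markers_removed`, `offspring_removed`,
#'   `phenotype_outliers`, `duplicates`, `segregation`).
#' @export
run_qc <- function(geno, map, pheno, distortion_p = 0.01, sd_k = 3,
                   dup_threshold = 0.9, xo_outlier_m = 10,
                   max_missing = NULL, exclude_ids = character(0)) {
  seg <- segregation_filter(geno, map, p_threshold = distortion_p)
  markers_removed <- seg$marker[seg$removed]
  keep_m <- !(map$marker %in% markers_removed)
  map2 <- map[keep_m, , drop = FALSE]
  class(map2) <- class(map)
  geno2 <- structure(list(raw = geno$raw[, keep_m, drop = FALSE],
                          dam = geno$dam[, keep_m, drop = FALSE],
                          sire = geno$sire[, keep_m, drop = FALSE],
                          markers = map2$marker), class = "phased_geno")

  dups <- duplicate_sample_check(geno2, threshold = dup_threshold)
  dup_ids <- unique(dups$id2)          # keep the first of each pair

  counts <- count_obligate(geno2, map2)
  xo <- crossover_outlier_filter(counts, m = xo_outlier_m)

  miss_ids <- character(0)
  if (!is.null(max_missing)) {
    mf <- missing_fraction(geno2)
    miss_ids <- names(mf)[mf > max_missing]
  }

  offspring_removed <- rbind(
    if (length(dup_ids)) data.frame(offspring = dup_ids, reason = "duplicate"),
    if (length(xo$removed)) data.frame(offspring = xo$removed,
                                       reason = "crossover_outlier"),
    if (length(miss_ids)) data.frame(offspring = miss_ids,
                                     reason = "missingness"),
    if (length(exclude_ids)) data.frame(offspring = exclude_ids,
                                        reason = "excluded"))
  if (is.null(offspring_removed)) {
    offspring_removed <- data.frame(offspring = character(0),
                                    reason = character(0))
  }
  offspring_removed <-
    offspring_removed[!duplicated(offspring_removed$offspring), , drop = FALSE]
  keep_o <- setdiff(rownames(geno2$raw), offspring_removed$offspring)
  geno3 <- structure(list(raw = geno2$raw[keep_o, , drop = FALSE],
                          dam = geno2$dam[keep_o, , drop = FALSE],
                          sire = geno2$sire[keep_o, , drop = FALSE],
                          markers = map2$marker), class = "phased_geno")

  pheno2 <- pheno[pheno$offspring %in% keep_o, , drop = FALSE]
  class(pheno2) <- class(pheno)
  attr(pheno2, "transform") <- attr(pheno, "transform")
  outliers <- list()
  for (tr in trait_names(pheno2)) {
    res <- phenotype_outlier_filter(pheno2[[tr]], k = sd_k,
                                    ids = pheno2$offspring)
    pheno2[[tr]] <- res$values
    outliers[[tr]] <- res$removed
  }

  structure(list(geno = geno3, map = map2, pheno = pheno2,
                 markers_removed = markers_removed,
                 n_markers_retained = nrow(map2),
                 offspring_removed = offspring_removed,
                 phenotype_outliers = outliers,
                 duplicates = dups, segregation = seg,
                 xo_outlier = xo,
                 params = list(distortion_p = distortion_p, sd_k = sd_k,
                               dup_threshold = dup_threshold,
                               xo_outlier_m = xo_outlier_m,
                               max_missing = max_missing)),
            class = "qc_report")
}
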