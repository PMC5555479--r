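# Sex-stratified recombination summaries, positional distributions, and
# centromere-end inference from corrected crossovers.

.ratio_or_na <- function(dam, sire) if (isTRUE(sire > 0)) dam / sire else NA_real_

#' Summarise sex-stratified crossover counts
#'
#' Retained crossover totals per parent, overall and stratified by chromosome
#' class (fused metacentric vs acrocentric) and residual-tetraploidy status,
#' with female:male ratios (reported to one decimal, raw quotient also kept),
#' per-chromosome means, and removed-event totals.  The sex-linked linkage
#' group is excluded from autosomal totals and class strata but reported
#' separately; `include_sex_lg = TRUE` adds it back to its class stratum.
#'
#' @param events corrected `xo_events` (from [apply_correction()]); raw events
#'   are accepted and treated as all retained.
#' @param map the `genetic_map`.
#' @param include_sex_lg include the sex-linked lg in class/tetraploidy strata.
#' @return object of class `xo_summary`.
#' @export
summarize_crossovers <- function(events, map, include_sex_lg = FALSE) {
  stopifnot(inherits(map, "genetic_map"))
  info <- lg_info(map)
  ret <- retained_events(events)
  per_lg <- merge(info[, c("lg", "lg_class", "tetraploid", "sex_linked")],
                  data.frame(
                    lg = info$lg,
                    dam = as.integer(table(factor(ret$lg[ret$parent == "dam"],
                                                  levels = info$lg))),
                    sire = as.integer(table(factor(ret$lg[ret$parent == "sire"],
                                                   levels = info$lg)))),
                  by = "lg", sort = FALSE)

  auto <- if (include_sex_lg) per_lg else per_lg[!per_lg$sex_linked, , drop = FALSE]
  strat <- function(name, sub) {
    data.frame(stratum = name, n_lg = nrow(sub),
               dam = sum(sub$dam), sire = sum(sub$sire),
               ratio = .ratio_or_na(sum(sub$dam), sum(sub$sire)),
               stringsAsFactors = FALSE)
  }
  totals <- rbind(
    strat("autosomes", per_lg[!per_lg$sex_linked, ]),
    strat("overall", per_lg),
    strat("fused_metacentric", auto[auto$lg_class == "fused_metacentric", ]),
    strat("acrocentric", auto[auto$lg_class == "acrocentric", ]),
    strat("tetraploid", auto[auto$tetraploid, ]),
    strat("rediploidized", auto[!auto$tetraploid, ]),
    strat("sex_lg", per_lg[per_lg$sex_linked, ]))
  totals$ratio_1dp <- round(totals$ratio, 1)

  means <- do.call(rbind, lapply(LG_CLASSES, function(cl) {
    sub <- auto[auto$lg_class == cl, , drop = FALSE]
    data.frame(lg_class = cl, n_lg = nrow(sub),
               dam_mean = if (nrow(sub)) mean(sub$dam) else NA_real_,
               sire_mean = if (nrow(sub)) mean(sub$sire) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  removed <- attr(events, "removed")
  if (is.null(removed)) {
    rem <- events$status == "removed"
    removed <- do.call(rbind, lapply(c("dam", "sire"), function(p) {
      data.frame(parent = p,
                 autosomes = sum(rem & events$parent == p &
                                   !(events$lg %in% info$lg[info$sex_linked])),
                 sex_lg = sum(rem & events$parent == p &
                                events$lg %in% info$lg[info$sex_linked]),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(totals = totals, per_lg = per_lg, per_chrom_means = means,
                 removed = removed, include_sex_lg = include_sex_lg),
            class = "xo_summary")
}

#' Positional distribution of crossovers along the percent axis
#'
#' Histograms retained events on the 0-100% axis (percent of linkage-group
#' length) per parent and chromosome class, with cumulative counts and the
#' "external 20%" share per parent (events with percent position in the
#' closed intervals \[0, 20\] or \[80, 100\]).  Linkage groups of zero map
#' length are excluded with a warning.
#'
#' @param events `xo_events` with `percent_pos` populated.
#' @param map the `genetic_map`.
#' @param bin_width bin width in percent (default 5).
#' @return object of class `xo_distribution`: list with `counts` (data.frame
#'   bin x parent x class), `external20` (named per parent) and `bin_width`.
#' @export
positional_distribution <- function(events, map, bin_width = 5) {
  ret <- retained_events(events)
  if (any(is.na(ret$percent_pos))) {
    warning("excluding events on zero-length linkage groups")
    ret <- ret[!is.na(ret$percent_pos), , drop = FALSE]
  }
  info <- lg_info(map)
  cls <- stats::setNames(info$lg_class, info$lg)
  edges <- seq(0, 100, by = bin_width)
  if (utils::tail(edges, 1) < 100) edges <- c(edges, 100)
  grid <- expand.grid(bin_lo = utils::head(edges, -1),
                      parent = c("dam", "sire"),
                      lg_class = LG_CLASSES, stringsAsFactors = FALSE)
  grid$bin_hi <- grid$bin_lo + diff(edges)[match(grid$bin_lo, utils::head(edges, -1))]
  cnt <- integer(nrow(grid))
  if (nrow(ret)) {
    b <- findInterval(ret$percent_pos, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    key_ev <- paste(edges[b], ret$parent, cls[ret$lg])
    tab <- table(key_ev)
    key <- paste(grid$bin_lo, grid$parent, grid$lg_class)
    cnt <- as.integer(ifelse(key %in% names(tab), tab[key], 0L))
  }
  grid$count <- cnt
  grid <- grid[, c("parent", "lg_class", "bin_lo", "bin_hi", "count")]
  grid$cum_count <- stats::ave(grid$count, grid$parent, grid$lg_class,
                               FUN = cumsum)
  ext <- vapply(c("dam", "sire"), function(p) {
    pp <- ret$percent_pos[ret$parent == p]
    if (!length(pp)) return(NA_real_)
    mean(pp <= 20 | pp >= 80)
  }, numeric(1))
  structure(list(counts = grid, external20 = ext, bin_width = bin_width),
            class = "xo_distribution")
}

#' Infer the centromere end of acrocentric linkage groups
#'
#' In species where male crossovers are confined to the chromosome end
#' opposite the centromere, the centromere of an acrocentric chromosome can
#' be placed at the end opposite the terminal 20% that holds the bulk of the
#' male events.
#'
#' By default only isolated crossovers (singleton clusters, status
#' `"retained"`) are used: a collapsed odd-cluster representative sits at the
#' median member's midpoint and so carries positional uncertainty up to the
#' correction window, which would dilute the terminal-20% signal.  Because a
#' crossover's position is interval-censored between its flanking markers, an
#' event is assigned to a terminal 20% when its flanking interval reaches
#' into it (right flank for the distal end, left flank for the proximal end),
#' not by its midpoint.
#'
#' @param events corrected `xo_events`.
#' @param map the `genetic_map`.
#' @param min_events minimum usable male events required per lg.
#' @param threshold minimum fraction of male events in the modal terminal 20%.
#' @param use `"isolated"` (singleton clusters only, default) or
#'   `"retained"` (include collapsed representatives).
#' @return data.frame per acrocentric lg: `lg`, `n_events`, `call`
#'   (`start`/`end`/`undetermined`), `confidence` (fraction of events in the
#'   modal terminal 20%), and the lg's annotated `centromere_end` for
#'   comparison.
#' @export
infer_centromere_end <- function(events, map, min_events = 5, threshold = 0.8,
                                 use = c("isolated", "retained")) {
  use <- match.arg(use)
  info <- lg_info(map)
  acro <- info[info$lg_class == "acrocentric", , drop = FALSE]
  ret <- if (use == "isolated") {
    events[events$status == "retained", , drop = FALSE]
  } else {
    retained_events(events)
  }
  ret <- ret[ret$parent == "sire" & !is.na(ret$percent_pos), , drop = FALSE]
  lg_len <- stats::setNames(info$length, info$lg)
  out <- do.call(rbind, lapply(seq_len(nrow(acro)), function(k) {
    sub <- ret[ret$lg == acro$lg[k], , drop = FALSE]
    len <- lg_len[[acro$lg[k]]]
    n <- nrow(sub)
    # interval-censored terminal assignment; ties broken by midpoint
    in_lo <- 100 * sub$left_pos / len <= 20
    in_hi <- 100 * sub$right_pos / len >= 80
    both <- in_lo & in_hi
    in_lo[both] <- sub$percent_pos[both] <= 50
    in_hi[both] <- !in_lo[both]
    lo <- sum(in_lo); hi <- sum(in_hi)
    conf <- if (n > 0) max(lo, hi) / n else NA_real_
    call <- "undetermined"
    if (n >= min_events && !is.na(conf) && conf >= threshold) {
      # crossovers at the start => centromere at the opposite (end) side
      call <- if (lo >= hi) "end" else "start"
    }
    data.frame(lg = acro$lg[k], n_events = n, call = call,
               confidence = conf, annotated = acro$centromere_end[k],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Window-sensitivity of the heterochiasmy ratio
#'
#' Re-applies the double-crossover correction to the same raw events at
#' several window widths and reports the overall female:male ratio and the
#' external-20% shares per parent for each window.
#'
#' @param raw_events raw `xo_events` from [detect_all_crossovers()].
#' @param map the `genetic_map`.
#' @param windows numeric vector of window widths in cM.
#' @param chaining,odd_policy passed to [correction_params()].
#' @param include_sex_lg passed to [summarize_crossovers()]; the reported
#'   ratio is the autosomal one unless TRUE.
#' @return data.frame with one row per window: totals, ratio, external20.
#' @export
window_sensitivity <- function(raw_events, map, windows = c(50, 25, 10),
                               chaining = "gap",
                               odd_policy = "collapse_to_one",
                               include_sex_lg = FALSE) {
  out <- lapply(windows, function(w) {
    corr <- apply_correction(raw_events, map,
                             correction_params(window = w, chaining = chaining,
                                               odd_policy = odd_policy))
    sm <- summarize_crossovers(corr, map, include_sex_lg = include_sex_lg)
    tot <- sm$totals[sm$totals$stratum ==
                       if (include_sex_lg) "overall" else "autosomes", ]
    dist <- positional_distribution(corr, map)
    data.frame(window = w, dam = tot$dam, sire = tot$sire, ratio = tot$ratio,
               ratio_1dp = round(tot$ratio, 1),
               external20_dam = dist$external20[["dam"]],
               external20_sire = dist$external20[["sire"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
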