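# Crossover detection from phased genotypes and the windowed even-parity
# correction for genotyping-error-induced double crossovers.

#' Correction parameters for the double-crossover filter
#'
#' @param window window W in cM within which successive crossovers are chained
#'   into a cluster (default 50; 25 and 10 are the usual sensitivity variants).
#' @param chaining `"gap"`: an event joins the current cluster while its gap to
#'   the previous event is <= W; `"anchor"`: while it lies within W of the
#'   cluster's first event.
#' @param odd_policy for clusters of odd size k > 1: `"collapse_to_one"` keeps
#'   a single representative at the median member's midpoint (net phase change
#'   is one switch); `"keep_all"` retains all k members.
#' @return list of class `correction_params`.
#' @export
correction_params <- function(window = 50, chaining = c("gap", "anchor"),
                              odd_policy = c("collapse_to_one", "keep_all")) {
  if (window <= 0) stop("window must be > 0")
  structure(list(window = window, chaining = match.arg(chaining),
                 odd_policy = match.arg(odd_policy)),
            class = "correction_params")
}

#' Ordered parental phase sequence for one offspring on one linkage group
#'
#' Restricts to markers informative for the given parent; ambiguous (`hk`)
#' and missing calls yield unknown (`NA`) labels.
#'
#' @param geno a `phased_geno`.
#' @param map a `genetic_map`.
#' @param offspring offspring id.
#' @param lg linkage-group id.
#' @param parent `"dam"` or `"sire"`.
#' @param informative_both_only restrict to marker types informative in both
#'   parents (efxeg, hkxhk), as done for heterochiasmy analyses.
#' @return data.frame `marker`, `pos`, `label` (`a`/`b` or `c`/`d` or `NA`).
#' @export
parental_phase_sequence <- function(geno, map, offspring, lg,
                                    parent = c("dam", "sire"),
                                    informative_both_only = FALSE) {
  parent <- match.arg(parent)
  j <- which(map$lg == lg)
  if (!length(j)) stop("unknown linkage group: ", lg)
  if (informative_both_only) j <- j[map$seg_type[j] %in% c("efxeg", "hkxhk")]
  lab <- geno[[parent]][offspring, map$marker[j]]
  data.frame(marker = map$marker[j], pos = map$pos[j],
             label = unname(lab), stringsAsFactors = FALSE)
}

#' Detect crossovers in one phase sequence
#'
#' One event is scored per change of haplotype label between consecutive
#' known-label markers; unknown labels are skipped, so a label change across a
#' run of unknowns counts as exactly one event placed at the midpoint of the
#' bounding known markers.  The event count is the minimal number of phase
#' switches consistent with the observed labels.
#'
#' @param phase data.frame as from [parental_phase_sequence()], ordered by
#'   position.
#' @return data.frame with one row per event: `left_marker`, `left_pos`,
#'   `right_marker`, `right_pos`, `midpoint`.
#' @export
detect_crossovers <- function(phase) {
  known <- which(!is.na(phase$label))
  if (length(known) < 2) {
    return(data.frame(left_marker = character(0), left_pos = numeric(0),
                      right_marker = character(0), right_pos = numeric(0),
                      midpoint = numeric(0), stringsAsFactors = FALSE))
  }
  lab <- phase$label[known]
  sw <- which(lab[-1] != lab[-length(lab)])
  li <- known[sw]; ri <- known[sw + 1]
  data.frame(left_marker = phase$marker[li], left_pos = phase$pos[li],
             right_marker = phase$marker[ri], right_pos = phase$pos[ri],
             midpoint = (phase$pos[li] + phase$pos[ri]) / 2,
             stringsAsFactors = FALSE)
}

#' Detect all raw crossover events in a cross
#'
#' Runs [detect_crossovers()] for every offspring x parent x linkage group
#' and annotates each event with its percent position on the linkage group
#' (100 * midpoint / map length, map length = last marker position).
#'
#' @inheritParams parental_phase_sequence
#' @param parents parents to scan.
#' @return data.frame of class `xo_events`: `offspring`, `parent`, `lg`,
#'   flank columns, `midpoint`, `percent_pos`, `cluster` (NA until corrected)
#'   and `status` (`"retained"` for raw events).
#' @export
detect_all_crossovers <- function(geno, map, parents = c("dam", "sire"),
                                  informative_both_only = FALSE) {
  stopifnot(inherits(geno, "phased_geno"), inherits(map, "genetic_map"))
  info <- lg_info(map)
  lg_len <- stats::setNames(info$length, info$lg)
  off <- rownames(geno$raw)
  acc_off <- acc_par <- acc_lg <- acc_lm <- acc_rm <- list()
  acc_lp <- acc_rp <- list()
  a <- 0L
  for (lg in info$lg) {
    j <- which(map$lg == lg)
    if (informative_both_only) j <- j[map$seg_type[j] %in% c("efxeg", "hkxhk")]
    if (length(j) < 2) next
    pos <- map$pos[j]; mk <- map$marker[j]
    for (parent in parents) {
      labm <- geno[[parent]][, mk, drop = FALSE]
      for (i in seq_along(off)) {
        row <- labm[i, ]
        known <- which(!is.na(row))
        if (length(known) < 2) next
        lab <- row[known]
        sw <- which(lab[-1] != lab[-length(lab)])
        if (!length(sw)) next
        li <- known[sw]; ri <- known[sw + 1]
        a <- a + 1L
        acc_off[[a]] <- rep.int(i, length(sw))
        acc_par[[a]] <- rep.int(match(parent, c("dam", "sire")), length(sw))
        acc_lg[[a]] <- rep.int(match(lg, info$lg), length(sw))
        acc_lm[[a]] <- j[li]; acc_rm[[a]] <- j[ri]
        acc_lp[[a]] <- pos[li]; acc_rp[[a]] <- pos[ri]
      }
    }
  }
  if (a > 0) {
    lmk <- unlist(acc_lm); rmk <- unlist(acc_rm)
    lp <- unlist(acc_lp); rp <- unlist(acc_rp)
    ev <- data.frame(
      offspring = off[unlist(acc_off)],
      parent = c("dam", "sire")[unlist(acc_par)],
      lg = info$lg[unlist(acc_lg)],
      left_marker = map$marker[lmk], left_pos = lp,
      right_marker = map$marker[rmk], right_pos = rp,
      midpoint = (lp + rp) / 2, stringsAsFactors = FALSE)
  } else {
    ev <- data.frame(offspring = character(0), parent = character(0),
                     lg = character(0), left_marker = character(0),
                     left_pos = numeric(0), right_marker = character(0),
                     right_pos = numeric(0), midpoint = numeric(0),
                     stringsAsFactors = FALSE)
  }
  len <- lg_len[ev$lg]
  ev$percent_pos <- ifelse(len > 0, 100 * ev$midpoint / len, NA_real_)
  ev$cluster <- NA_integer_
  ev$status <- rep("retained", nrow(ev))
  class(ev) <- c("xo_events", "data.frame")
  ev
}

#' Per-offspring obligate crossover counts
#'
#' Total minimal (obligate) crossover count per offspring, summed over both
#' parental haplotypes and all linkage groups, using all markers informative
#' for each parent.
#'
#' @inheritParams parental_phase_sequence
#' @return named integer vector, one entry per offspring.
#' @export
count_obligate <- function(geno, map) {
  ev <- detect_all_crossovers(geno, map, informative_both_only = FALSE)
  off <- rownames(geno$raw)
  cnt <- table(factor(ev$offspring, levels = off))
  stats::setNames(as.integer(cnt), off)
}

#' Cluster and correct putative double crossovers on one chromosome
#'
#' Events (for one offspring, parent and linkage group, sorted by midpoint)
#' are chained into clusters within the window W.  An even-sized cluster
#' implies no net phase change, the signature of a genotyping error, and all
#' its members are removed.  An odd cluster of size k > 1 carries a net
#' single phase change; under `collapse_to_one` it is collapsed to one
#' representative at the median member's midpoint (k - 1 removed), under
#' `keep_all` all members are retained.  Singletons are retained.
#'
#' @param midpoints sorted numeric vector of event midpoints (cM).
#' @param params a [correction_params()].
#' @return list with integer `cluster` ids and character `status` per event
#'   (`retained` / `removed` / `collapsed_representative`).
#' @export
correct_double_crossovers <- function(midpoints, params = correction_params()) {
  k <- length(midpoints)
  if (k == 0) return(list(cluster = integer(0), status = character(0)))
  if (is.unsorted(midpoints)) stop("midpoints must be sorted")
  cl <- integer(k)
  cl[1] <- 1L
  if (k > 1) {
    if (params$chaining == "gap") {
      newc <- c(FALSE, diff(midpoints) > params$window)
      cl <- cumsum(newc) + 1L
    } else {
      anchor <- midpoints[1]; cur <- 1L
      for (i in 2:k) {
        if (midpoints[i] - anchor > params$window) {
          cur <- cur + 1L
          anchor <- midpoints[i]
        }
        cl[i] <- cur
      }
    }
  }
  status <- rep("retained", k)
  for (g in unique(cl)) {
    idx <- which(cl == g)
    sz <- length(idx)
    if (sz == 1) next
    if (sz %% 2 == 0) {
      status[idx] <- "removed"
    } else if (params$odd_policy == "collapse_to_one") {
      status[idx] <- "removed"
      status[idx[(sz + 1) / 2]] <- "collapsed_representative"
    }
  }
  list(cluster = cl, status = status)
}

#' Apply the double-crossover correction to a full event set
#'
#' The correction runs independently per (offspring, parent, linkage group).
#' Removed totals are tallied per parent, with autosomes and the sex-linked
#' linkage group reported separately.
#'
#' @param events raw `xo_events` from [detect_all_crossovers()].
#' @param map the `genetic_map` (identifies the sex-linked lg).
#' @param params a [correction_params()].
#' @return the events with `cluster` and `status` assigned; attribute
#'   `removed` holds a data.frame of removed totals per parent
#'   (autosomes / sex-linked lg).
#' @export
apply_correction <- function(events, map, params = correction_params()) {
  stopifnot(inherits(events, "xo_events"))
  ev <- as.data.frame(events)
  if (nrow(ev)) {
    ord <- order(ev$offspring, ev$parent, ev$lg, ev$midpoint)
    ev <- ev[ord, ]
    grp <- paste(ev$offspring, ev$parent, ev$lg, sep = "\r")
    idx <- split(seq_len(nrow(ev)), grp)
    for (i in idx) {
      res <- correct_double_crossovers(ev$midpoint[i], params)
      ev$cluster[i] <- res$cluster
      ev$status[i] <- res$status
    }
    rownames(ev) <- NULL
  }
  info <- lg_info(map)
  sex_lgs <- info$lg[info$sex_linked]
  removed <- do.call(rbind, lapply(c("dam", "sire"), function(p) {
    rem <- ev$status == "removed" & ev$parent == p
    data.frame(parent = p,
               autosomes = sum(rem & !(ev$lg %in% sex_lgs)),
               sex_lg = sum(rem & ev$lg %in% sex_lgs),
               stringsAsFactors = FALSE)
  }))
  class(ev) <- c("xo_events", "data.frame")
  attr(ev, "removed") <- removed
  attr(ev, "params") <- params
  ev
}

#' Retained events of a (corrected) event set
#' @param events an `xo_events` data.frame.
#' @return the subset with status `retained` or `collapsed_representative`.
#' @export
retained_events <- function(events) {
  out <- events[events$status != "removed", , drop = FALSE]
  class(out) <- c("xo_events", "data.frame")
  out
}
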