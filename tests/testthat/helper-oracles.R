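# Independent oracles and small fixtures shared across test files.

# Brute-force minimal-switch oracle: enumerate all assignments of unknown
# labels to the two phases and take the minimum number of adjacent changes.
min_switch_oracle <- function(labels) {
  known <- labels[!is.na(labels)]
  if (length(known) < 2 && sum(is.na(labels)) == 0) return(0L)
  alpha <- sort(unique(known))
  if (length(alpha) == 0) return(0L)
  if (length(alpha) == 1) alpha <- c(alpha, paste0(alpha, "2"))
  unk <- which(is.na(labels))
  if (length(unk) > 14) stop("oracle limited to 14 unknowns")
  best <- Inf
  n_assign <- 2^length(unk)
  for (a in seq_len(n_assign) - 1L) {
    lab <- labels
    if (length(unk)) {
      bits <- as.integer(intToBits(a))[seq_along(unk)]
      lab[unk] <- alpha[bits + 1L]
    }
    sw <- sum(lab[-1] != lab[-length(lab)])
    best <- min(best, sw)
  }
  as.integer(best)
}

# Observable crossover count oracle for an error-free simulation:
# per (offspring, parent, lg), true crossovers collapse to per-marker-interval
# parity, and crossovers outside the span of the first/last marker are
# invisible.
observable_xo_oracle <- function(map, true_xo) {
  tot <- 0L
  for (lg in unique(map$lg)) {
    pos <- map$pos[map$lg == lg]
    sub <- true_xo[true_xo$lg == lg, , drop = FALSE]
    if (!nrow(sub)) next
    inside <- sub$pos > min(pos) & sub$pos < max(pos)
    sub <- sub[inside, , drop = FALSE]
    if (!nrow(sub)) next
    iv <- findInterval(sub$pos, pos)
    key <- paste(sub$offspring, sub$parent, iv)
    tot <- tot + sum(table(key) %% 2)
  }
  as.integer(tot)
}

# Small karyotype for cheap end-to-end tests: 1 fused metacentric +
# 3 acrocentric (one sex-linked).
small_lg_spec <- function() {
  data.frame(
    lg = c("M1", "A1", "A2", "AX"),
    lg_class = c("fused_metacentric", rep("acrocentric", 3)),
    female_len = c(120, 60, 60, 60),
    male_len = c(120, 60, 60, 60) / 2.7,
    tetraploid = c(TRUE, TRUE, FALSE, FALSE),
    sex_linked = c(FALSE, FALSE, FALSE, TRUE),
    centromere_end = c("unknown", "start", "end", "start"),
    stringsAsFactors = FALSE)
}

small_sim_config <- function(seed = 1, ...) {
  args <- list(n_offspring = 40, lg_spec = small_lg_spec(),
               n_markers_per_lg = 40,
               qtl_effects = data.frame(trait = "growth", lg = "A1",
                                        marker_index = 20, effect = 0.5),
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# one-lg map built directly, for unit tests that need full control
tiny_map <- function(pos = seq(0, 100, by = 10), seg_type = "efxeg",
                     lg = "L1", lg_class = "acrocentric",
                     centromere_end = "start", sex_linked = FALSE) {
  genetic_map(data.frame(
    marker = sprintf("%s_m%02d", lg, seq_along(pos)), lg = lg, pos = pos,
    seg_type = seg_type, lg_class = lg_class, tetraploid = FALSE,
    sex_linked = sex_linked, centromere_end = centromere_end,
    stringsAsFactors = FALSE))
}

# synthetic event table matching the xo_events layout
make_events <- function(offspring, parent, lg, midpoint, lg_len = 100,
                        status = "retained", half_gap = 1) {
  n <- max(lengths(list(offspring, parent, lg, midpoint)))
  if (length(midpoint) == 0) n <- 0
  midpoint <- rep_len(midpoint, n)
  offspring <- rep_len(as.character(offspring), n)
  parent <- rep_len(as.character(parent), n)
  lg <- rep_len(as.character(lg), n)
  status <- rep_len(status, n)
  ev <- data.frame(offspring = offspring, parent = parent, lg = lg,
                   left_marker = rep_len("l", n),
                   left_pos = midpoint - half_gap,
                   right_marker = rep_len("r", n),
                   right_pos = midpoint + half_gap,
                   midpoint = midpoint,
                   percent_pos = 100 * midpoint / lg_len,
                   cluster = rep_len(NA_integer_, n), status = status,
                   stringsAsFactors = FALSE)
  class(ev) <- c("xo_events", "data.frame")
  ev
}
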