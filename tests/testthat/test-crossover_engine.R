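# Crossover detection and the windowed even-parity correction.

phase_df <- function(labels, pos = seq(0, by = 10, length.out = length(labels))) {
  data.frame(marker = paste0("m", seq_along(labels)), pos = pos,
             label = labels, stringsAsFactors = FALSE)
}

test_that("detect_crossovers scores minimal phase switches with unknowns skipped", {
  expect_identical(nrow(detect_crossovers(phase_df(c("a", "a", "a", "a")))), 0L)
  ev <- detect_crossovers(phase_df(c("a", "a", "b", "b")))
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$left_pos, 10)
  expect_equal(ev$right_pos, 20)
  expect_equal(ev$midpoint, 15)
  # unknown bridged: a ? b a -> two events at midpoints 10 and 25
  ev <- detect_crossovers(phase_df(c("a", NA, "b", "a")))
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$midpoint, c(10, 25))
  # all-missing sequence detects nothing
  expect_identical(nrow(detect_crossovers(phase_df(c(NA, NA, NA)))), 0L)
})

test_that("detector equals the brute-force minimal-switch oracle", {
  # exhaustive over all two-label sequences up to length 12
  for (len in 2:12) {
    for (code in seq_len(2^len) - 1L) {
      labels <- c("a", "b")[as.integer(intToBits(code))[1:len] + 1L]
      ev <- detect_crossovers(phase_df(labels))
      expect_identical(nrow(ev), min_switch_oracle(labels))
    }
  }
})

test_that("detector equals the oracle on random sequences with unknowns", {
  set.seed(41)
  for (r in 1:300) {
    len <- sample(2:12, 1)
    labels <- sample(c("a", "b", NA), len, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    ev <- detect_crossovers(phase_df(labels))
    expect_identical(nrow(ev), min_switch_oracle(labels))
  }
})

test_that("parental phase sequences respect informativeness and ambiguity", {
  map <- tiny_map(pos = c(0, 10, 20),
                  seg_type = c("efxeg", "hkxhk", "nnxnp"))
  raw <- matrix(c("eg", "hk", "np"), 1, dimnames = list("o1", map$marker))
  g <- phased_genotypes(raw, map)
  dam <- parental_phase_sequence(g, map, "o1", "L1", "dam")
  expect_identical(dam$label, c("a", NA, NA))
  sire <- parental_phase_sequence(g, map, "o1", "L1", "sire")
  expect_identical(sire$label, c("d", NA, "d"))
  both <- parental_phase_sequence(g, map, "o1", "L1", "sire",
                                  informative_both_only = TRUE)
  expect_identical(both$marker, map$marker[1:2])
})

test_that("correction clusters by gap, removes even, collapses odd", {
  # even cluster within W: no net phase change, both removed
  res <- correct_double_crossovers(c(10, 15), correction_params(window = 50))
  expect_identical(res$status, c("removed", "removed"))
  # far apart: two singletons retained
  res <- correct_double_crossovers(c(10, 90), correction_params(window = 50))
  expect_identical(res$status, c("retained", "retained"))
  expect_identical(res$cluster, c(1L, 2L))
  # odd cluster of 3: one representative at the median member
  res <- correct_double_crossovers(c(10, 20, 30), correction_params(window = 50))
  expect_identical(res$status,
                   c("removed", "collapsed_representative", "removed"))
  # keep_all policy retains odd clusters entirely
  res <- correct_double_crossovers(
    c(10, 20, 30), correction_params(window = 50, odd_policy = "keep_all"))
  expect_identical(res$status, rep("retained", 3))
  # anchor chaining measures from the first event of the cluster
  res <- correct_double_crossovers(
    c(0, 40, 80), correction_params(window = 50, chaining = "anchor"))
  expect_identical(res$cluster, c(1L, 1L, 2L))
  res <- correct_double_crossovers(
    c(0, 40, 80), correction_params(window = 50, chaining = "gap"))
  expect_identical(res$cluster, c(1L, 1L, 1L))
})

test_that("W -> 0+ makes the correction the identity", {
  set.seed(42)
  mids <- sort(stats::runif(20, 0, 100))
  res <- correct_double_crossovers(mids, correction_params(window = 1e-9))
  expect_identical(res$status, rep("retained", 20))
})

test_that("parity is conserved per chromosome under collapse_to_one", {
  set.seed(43)
  for (chaining in c("gap", "anchor")) {
    for (r in 1:200) {
      k <- sample(0:12, 1)
      mids <- sort(stats::runif(k, 0, 200))
      res <- correct_double_crossovers(
        mids, correction_params(window = sample(c(10, 25, 50), 1),
                                chaining = chaining))
      retained <- sum(res$status != "removed")
      expect_identical(retained %% 2, k %% 2)
      expect_lte(retained, k)
      if (k > 0 && !any(table(res$cluster) >= 2)) {
        expect_identical(retained, k)  # equality iff no cluster of size >= 2
      }
    }
  }
})

test_that("apply_correction is independent of event insertion order", {
  sim <- simulate_cross(small_sim_config(seed = 44, error_rate = 0.01))
  raw <- detect_all_crossovers(sim$geno, sim$map, informative_both_only = TRUE)
  corr1 <- apply_correction(raw, sim$map)
  shuffled <- raw[sample(nrow(raw)), ]
  class(shuffled) <- class(raw)
  corr2 <- apply_correction(shuffled, sim$map)
  key <- function(e) do.call(order, as.data.frame(e)[c("offspring", "parent",
                                                       "lg", "midpoint")])
  expect_equal(as.data.frame(corr1)[key(corr1), ],
               as.data.frame(corr2)[key(corr2), ], ignore_attr = TRUE)
  # removed totals tally per parent, autosomes and sex lg separately
  rem <- attr(corr1, "removed")
  expect_identical(rem$parent, c("dam", "sire"))
  expect_identical(sum(rem$autosomes) + sum(rem$sex_lg),
                   sum(corr1$status == "removed"))
})

test_that("error-free detection matches the simulator parity oracle", {
  sim <- simulate_cross(small_sim_config(seed = 45, error_rate = 0,
                                         missing_rate = 0,
                                         tetraploid_drop_frac = 0,
                                         marker_type_mix = c(nnxnp = 0,
                                                             efxeg = 1,
                                                             hkxhk = 0)))
  raw <- detect_all_crossovers(sim$geno, sim$map)
  expect_identical(nrow(raw),
                   observable_xo_oracle(sim$map, sim$truth$true_crossovers))
  # count_obligate sums both parents over all lgs
  counts <- count_obligate(sim$geno, sim$map)
  expect_identical(sum(counts), nrow(raw))
  expect_identical(names(counts), rownames(sim$geno$raw))
})

test_that("count_obligate handles degenerate rows", {
  map <- tiny_map(pos = c(0, 10, 20, 30), seg_type = "efxeg")
  raw <- rbind(o1 = c("ee", "ee", "fg", "fg"),   # one switch per parent
               o2 = rep(NA_character_, 4))
  colnames(raw) <- map$marker
  g <- phased_genotypes(raw, map)
  counts <- count_obligate(g, map)
  expect_identical(unname(counts), c(2L, 0L))
})
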