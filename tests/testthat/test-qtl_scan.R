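# Marker-regression LOD scan, permutation thresholds, intervals, PVE fits.

scan_fixture <- function(seed = 61, n = 40, ...) {
  sim <- simulate_cross(small_sim_config(seed = seed, n_offspring = n, ...))
  sim
}

test_that("sex screen flags marginal sex effects and guards degenerate input", {
  ph <- pheno_table(data.frame(offspring = sprintf("o%02d", 1:40),
                               sex = rep(c("F", "M"), each = 20),
                               t1 = rep(c(1, 2, 3, 4), 10),     # identical by sex
                               # 2-unit shift with within-group spread
                               t2 = c(rep(0, 20), rep(2, 20)) + (1:40) / 100,
                               t3 = 1))
  expect_false(as.logical(sex_covariate_screen(ph, "t1")))
  expect_equal(attr(sex_covariate_screen(ph, "t1"), "p"), 1)
  expect_true(as.logical(sex_covariate_screen(ph, "t2")))
  expect_false(as.logical(sex_covariate_screen(ph, "t3")))  # zero variance
  ph1 <- pheno_table(data.frame(offspring = c("a", "b", "c", "d"), sex = "F",
                                t = c(1, 2, 3, 4)))
  expect_warning(flag <- sex_covariate_screen(ph1, "t"), "one sex")
  expect_false(as.logical(flag))
})

test_that("scan LOD equals the direct least-squares oracle", {
  set.seed(62)
  sim <- scan_fixture(n = 30)
  sub <- sim$map[sample(nrow(sim$map), 40), , drop = FALSE]
  sc_plain <- marker_scan(sim$pheno, sim$geno, sim$map, "growth",
                          shapiro_advisory = FALSE)
  sc_sex <- marker_scan(sim$pheno, sim$geno, sim$map, "growth",
                        covariates = "sex", shapiro_advisory = FALSE)
  y_all <- sim$pheno$growth
  sexM <- as.numeric(sim$pheno$sex == "M")
  for (mk in sub$marker) {
    g <- sim$geno$raw[sim$pheno$offspring, mk]
    ok <- !is.na(g) & !is.na(y_all)
    if (length(unique(g[ok])) < 2) {
      expect_equal(sc_plain$lod[sc_plain$marker == mk], 0)
      next
    }
    y <- y_all[ok]; gf <- factor(g[ok]); sx <- sexM[ok]
    rss <- function(fit) sum(stats::residuals(fit)^2)
    lod0 <- (sum(ok) / 2) *
      log10(rss(stats::lm(y ~ 1)) / rss(stats::lm(y ~ gf)))
    expect_equal(sc_plain$lod[sc_plain$marker == mk], lod0, tolerance = 1e-8)
    lod1 <- (sum(ok) / 2) *
      log10(rss(stats::lm(y ~ sx)) / rss(stats::lm(y ~ sx + gf)))
    expect_equal(sc_sex$lod[sc_sex$marker == mk], lod1, tolerance = 1e-8)
  }
})

test_that("LOD is affine-invariant and capped at perfect fit", {
  sim <- scan_fixture(seed = 63, n = 30)
  sc1 <- marker_scan(sim$pheno, sim$geno, sim$map, "growth",
                     shapiro_advisory = FALSE)
  ph2 <- sim$pheno
  ph2$growth <- 3.7 * ph2$growth - 11
  sc2 <- marker_scan(ph2, sim$geno, sim$map, "growth",
                     shapiro_advisory = FALSE)
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-9)
  # trait equal to a numeric coding of a marker's classes -> capped sentinel
  mk <- sim$map$marker[which(sim$map$seg_type == "efxeg")[1]]
  ph3 <- sim$pheno
  ph3$growth <- as.numeric(factor(sim$geno$raw[ph3$offspring, mk]))
  ph3$growth[is.na(ph3$growth)] <- 1
  sc3 <- marker_scan(ph3, sim$geno, sim$map, "growth",
                     shapiro_advisory = FALSE)
  expect_equal(sc3$lod[sc3$marker == mk], 50)
})

test_that("permutation thresholds are deterministic, ordered and exact at alpha 1", {
  sim <- scan_fixture(seed = 64)
  th0 <- permutation_thresholds(sim$pheno, sim$geno, sim$map, "growth",
                                n_perm = 100, alpha_genome = 1,
                                alpha_chrom = 1, seed = 5)
  expect_equal(th0$genome, 0, tolerance = 1e-9)
  th1 <- permutation_thresholds(sim$pheno, sim$geno, sim$map, "growth",
                                n_perm = 120, seed = 6)
  th2 <- permutation_thresholds(sim$pheno, sim$geno, sim$map, "growth",
                                n_perm = 120, seed = 6)
  expect_identical(th1, th2)
  # genome-wide threshold dominates every per-lg threshold at equal alpha
  th3 <- permutation_thresholds(sim$pheno, sim$geno, sim$map, "growth",
                                n_perm = 150, alpha_genome = 0.05,
                                alpha_chrom = 0.05, seed = 7)
  expect_true(all(th3$genome >= th3$chrom - 1e-9))
})

test_that("max-statistic thresholds grow with the number of markers scanned", {
  sim <- scan_fixture(seed = 65)
  # scanning a subset of markers cannot raise the genome-wide threshold
  sub_idx <- which(sim$map$lg == "A1")
  map_sub <- sim$map[sub_idx, , drop = FALSE]
  class(map_sub) <- class(sim$map)
  geno_sub <- structure(list(raw = sim$geno$raw[, sub_idx, drop = FALSE],
                             dam = sim$geno$dam[, sub_idx, drop = FALSE],
                             sire = sim$geno$sire[, sub_idx, drop = FALSE],
                             markers = map_sub$marker), class = "phased_geno")
  th_full <- permutation_thresholds(sim$pheno, sim$geno, sim$map, "growth",
                                    n_perm = 200, seed = 8)
  th_sub <- permutation_thresholds(sim$pheno, geno_sub, map_sub, "growth",
                                   n_perm = 200, seed = 8)
  expect_gte(th_full$genome, th_sub$genome)
})

test_that("support intervals cover peaks, plateaus and edges", {
  sc <- data.frame(marker = paste0("m", 1:9), lg = "L1",
                   pos = seq(0, 80, by = 10),
                   lod = c(0, 0, 0, 0, 6, 0, 0, 0, 0))
  class(sc) <- c("qtl_scan", "data.frame")
  ci <- support_interval(sc, "L1")
  expect_equal(c(ci$lo, ci$hi), c(30, 50))   # flanking markers only
  sc$lod <- c(0, 5, 5.5, 5.8, 6, 5.8, 5.5, 5, 0)
  ci <- support_interval(sc, "L1")
  expect_equal(c(ci$lo, ci$hi), c(0, 80))    # plateau covered, edge-truncated
  sc$lod <- c(6, 5, 0, 0, 0, 0, 0, 0, 0)
  ci <- support_interval(sc, "L1")
  expect_equal(ci$lo, 0)                     # truncated at the lg edge
  expect_equal(ci$hi, 20)
})

test_that("planted QTL are localised with covering support intervals", {
  n_rep <- 30
  near <- covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    # homogeneous fully-informative markers at ~5 cM spacing: localisation to
    # the marker grid is then a property of the scan, not of informativeness
    # differences between marker types or of sub-spacing linkage plateaus
    sim <- scan_fixture(seed = 660 + r, n = 170, n_markers_per_lg = 13,
                        marker_type_mix = c(nnxnp = 0, efxeg = 1, hkxhk = 0),
                        qtl_effects = data.frame(trait = "growth", lg = "A1",
                                                 marker_index = 7,
                                                 effect = 1))
    sc <- marker_scan(sim$pheno, sim$geno, sim$map, "growth",
                      covariates = "sex", shapiro_advisory = FALSE)
    true_mk <- sim$map$marker[sim$map$lg == "A1"][7]
    true_pos <- sim$map$pos[sim$map$marker == true_mk]
    sA <- sc[sc$lg == "A1", ]
    near[r] <- abs(sA$pos[which.max(sA$lod)] - true_pos) <= 5.01
    ci <- support_interval(sc, "A1")
    covered[r] <- ci$lo <= true_pos && ci$hi >= true_pos
  }
  # peak at or adjacent to the planted marker, interval covering it, in >=90%
  expect_gte(mean(near), 0.9)
  expect_gte(mean(covered), 0.9)
  # and the peak clears the genome-wide threshold in the last replicate
  th <- permutation_thresholds(sim$pheno, sim$geno, sim$map, "growth",
                               covariates = "sex", n_perm = 200, seed = 9)
  expect_true("A1" %in% scan_peaks(sc, th)$lg)
})

test_that("multi-QTL fits partition variance sensibly", {
  set.seed(67)
  sim <- scan_fixture(seed = 67, n = 120)
  mks <- c(sim$map$marker[sim$map$lg == "A1"][20],
           sim$map$marker[sim$map$lg == "A2"][20])
  fit <- fit_multi_qtl(sim$pheno, sim$geno, sim$map, "growth", mks, sex = TRUE)
  expect_true(fit$total_pve >= 0 && fit$total_pve <= 100)
  expect_true(all(fit$term_pve >= -1e-8))
  expect_true(all(fit$term_pve <= fit$total_pve + 1e-8))
  # single perfect term explains everything
  ph <- sim$pheno
  ph$growth <- as.numeric(factor(sim$geno$raw[ph$offspring, mks[1]]))
  ph$growth[is.na(ph$growth)] <- 1
  # keep rows with observed genotype so the coding is exact
  ok <- !is.na(sim$geno$raw[ph$offspring, mks[1]])
  ph2 <- pheno_table(as.data.frame(ph)[ok, ])
  fit2 <- fit_multi_qtl(ph2, sim$geno, sim$map, "growth", mks[1], sex = FALSE)
  expect_equal(fit2$total_pve, 100, tolerance = 1e-6)
  # exactly collinear marker columns trigger a drop with a warning
  map3 <- tiny_map(pos = c(0, 1, 2), seg_type = "efxeg")
  set.seed(671)
  col <- sample(c("ee", "ef", "eg", "fg"), 60, replace = TRUE)
  raw3 <- cbind(col, col, sample(c("ee", "ef", "eg", "fg"), 60, replace = TRUE))
  dimnames(raw3) <- list(sprintf("s%02d", 1:60), map3$marker)
  g3 <- phased_genotypes(raw3, map3)
  ph3 <- pheno_table(data.frame(offspring = rownames(raw3), sex = "F",
                                y = stats::rnorm(60)))
  expect_warning(
    fit3 <- fit_multi_qtl(ph3, g3, map3, "y", map3$marker[1:2], sex = FALSE),
    "collinear")
  expect_length(fit3$term_pve, 1)
})

test_that("null extra terms have near-zero drop-one PVE on orthogonal designs", {
  set.seed(68)
  sim <- scan_fixture(seed = 68, n = 170,
                      marker_type_mix = c(nnxnp = 0, efxeg = 1, hkxhk = 0),
                      qtl_effects = data.frame(trait = "growth", lg = "A1",
                                               marker_index = 10,
                                               effect = 1),
                      sex_effect = c(growth = 0))
  mks <- c(sim$map$marker[sim$map$lg == "A1"][10],
           sim$map$marker[sim$map$lg == "A2"][30])
  fit <- fit_multi_qtl(sim$pheno, sim$geno, sim$map, "growth", mks)
  expect_lt(fit$term_pve[[make.names(mks[2])]], 5)
  expect_gt(fit$term_pve[[make.names(mks[1])]], 10)
  # markers on different lgs segregate near-independently: PVEs near-additive
  expect_lt(abs(sum(fit$term_pve) - fit$total_pve), 5)
})

test_that("interaction test is gatekept and detects sex-specific effects", {
  set.seed(69)
  n <- 170
  sim <- scan_fixture(seed = 69, n = n, sex_effect = c(growth = 0))
  mk <- sim$map$marker[sim$map$lg == "A2"][20]
  g <- sim$geno$raw[sim$pheno$offspring, mk]
  sexM <- sim$pheno$sex == "M"
  # opposite-sign effect by sex at 1 SD
  ph <- sim$pheno
  score <- as.numeric(factor(g)); score[is.na(score)] <- mean(score, na.rm = TRUE)
  ph$growth <- stats::rnorm(n) + ifelse(sexM, 1, -1) * score
  res <- interaction_test(ph, sim$geno, sim$map, "growth", mk)
  expect_true(res$tested)
  expect_lt(res$p_interaction, 0.05)
  # no genotype effect at all: gatekeeping stops the test
  ph$growth <- stats::rnorm(n, sd = 1e-3) + 5
  res2 <- interaction_test(ph, sim$geno, sim$map, "growth", mk)
  expect_false(res2$tested)
  expect_true(is.na(res2$p_interaction))
})

test_that("sex-linkage scan finds the sex lg with a distal decline", {
  sim <- scan_fixture(seed = 70, n = 170)
  sc <- sex_linkage_scan(sim$pheno, sim$geno, sim$map)
  peaks <- summary(sc)
  expect_identical(peaks$lg[which.max(peaks$lod)], "AX")
  sx <- sc[sc$lg == "AX", ]
  len <- max(sx$pos)
  distal <- sx$lod[sx$pos >= 0.9 * len]
  expect_lt(min(distal), 0.8 * max(sx$lod))
  # single-sex input errors out
  ph <- sim$pheno; ph$sex <- "F"
  ph <- pheno_table(as.data.frame(ph))
  expect_error(sex_linkage_scan(ph, sim$geno, sim$map), "both sexes")
})

test_that("planted 10 percent PVE is recovered within 5 points in the median", {
  # residual sd 1, sex effect 0.5; effect 0.486 per substitution gives
  # var(Q)=0.5*a^2 and PVE = 0.118/1.18 ~ 10%
  a <- sqrt(2 * 0.1 / 0.9 * (1 + 0.0625))
  pves <- vapply(1:60, function(r) {
    sim <- simulate_cross(small_sim_config(
      seed = 700 + r, n_offspring = 170, n_markers_per_lg = 15,
      marker_type_mix = c(nnxnp = 0, efxeg = 1, hkxhk = 0),
      qtl_effects = data.frame(trait = "growth", lg = "A1",
                               marker_index = 8, effect = a)))
    mk <- sim$map$marker[sim$map$lg == "A1"][8]
    fit <- fit_multi_qtl(sim$pheno, sim$geno, sim$map, "growth", mk,
                         sex = TRUE)
    fit$term_pve[[make.names(mk)]]
  }, numeric(1))
  expect_lt(abs(stats::median(pves) - 10), 5)
})
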