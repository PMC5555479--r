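# Synthetic four-way cross simulator with known ground truth.

#' Default linkage-group specification
#'
#' 42 linkage groups emulating a salmonid karyotype: 8 fused metacentric and
#' 34 acrocentric chromosomes, 16 of them flagged as residually tetraploid,
#' with one acrocentric sex-linked chromosome.  Female map lengths are 2.7x
#' the male lengths, matching the overall female:male crossover ratio the
#' simulator is meant to embody.  Acrocentric centromere ends alternate
#' between the two map orientations so both branches of centromere-end
#' inference are exercised.
#'
#' @param female_len_metacentric,female_len_acrocentric female map length (cM).
#' @param fm_ratio female:male map length ratio.
#' @return data.frame with columns `lg`, `lg_class`, `female_len`, `male_len`,
#'   `tetraploid`, `sex_linked`, `centromere_end`.
#' @export
default_lg_spec <- function(female_len_metacentric = 120,
                            female_len_acrocentric = 60,
                            fm_ratio = 2.7) {
  lg <- sprintf("LG%02d", 1:42)
  cls <- c(rep("fused_metacentric", 8), rep("acrocentric", 34))
  flen <- ifelse(cls == "fused_metacentric",
                 female_len_metacentric, female_len_acrocentric)
  cend <- ifelse(cls == "fused_metacentric", "unknown",
                 ifelse(seq_along(lg) %% 2 == 0, "end", "start"))
  sexl <- lg == "LG42"
  cend[sexl] <- "start"   # sex locus at the centromeric end, PAR distal
  data.frame(lg = lg, lg_class = cls, female_len = flen,
             male_len = flen / fm_ratio,
             tetraploid = seq_along(lg) %in% c(1:4, 9:20),
             sex_linked = sexl, centromere_end = cend,
             stringsAsFactors = FALSE)
}

#' Simulation configuration for a synthetic four-way cross
#'
#' The defaults emulate the mapping-family geometry the package targets:
#' ~170 offspring of two outbred parents, 42 linkage groups (8 fused
#' metacentric, 34 acrocentric, 16 residually tetraploid, one sex-linked
#' acrocentric), ~3,780 markers in three segregation types, maternal
#' crossovers biased toward chromosome centers and paternal crossovers
#' confined mostly to the distal 20% of each chromosome, with genotyping
#' error and missingness and one planted additive QTL.
#'
#' Crossover counts follow a stationary gamma-renewal process (mean count =
#' map length / 100) whose shape `interference_nu` controls crossover
#' interference; `interference_nu = 1` gives the no-interference Poisson
#' model with i.i.d. positions from the named density.
#'
#' @param n_offspring number of offspring (>= 2).
#' @param lg_spec linkage-group table, see [default_lg_spec()].
#' @param n_markers_per_lg markers per linkage group, evenly spaced in cM.
#' @param marker_type_mix named proportions over `nnxnp`, `efxeg`, `hkxhk`
#'   (must sum to 1).
#' @param female_density `"uniform"` or `"center_biased"` (symmetric beta).
#' @param male_density `"uniform"` or `"telomere_biased"`.
#' @param telomere_mass fraction of the telomere-biased density falling in the
#'   distal 20% of the axis (split between both ends for fused metacentrics).
#' @param interference_nu integer gamma-renewal shape (1 = Poisson).
#' @param error_rate per-call genotyping error probability (uniform
#'   substitution to another legal code).
#' @param missing_rate per-call missing probability.
#' @param tetraploid_drop_frac terminal fraction of residually tetraploid lgs
#'   in which male-informative marker signal is dropped (0 disables masking).
#' @param pseudoautosomal_frac terminal fraction of the sex-linked lg in which
#'   male recombination is allowed (the pseudoautosomal region).
#' @param qtl_effects data.frame (`trait`, `lg`, `marker_index`, `effect`):
#'   additive effect per haplotype substitution at the marker.
#' @param sex_effect,interaction_effect,residual_sd named per-trait numerics.
#' @param transform named per-trait `"none"`/`"log"` flags.
#' @param seed integer seed; all simulator randomness flows from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_offspring = 170,
                       lg_spec = default_lg_spec(),
                       n_markers_per_lg = 90,
                       marker_type_mix = c(nnxnp = 1/3, efxeg = 1/3, hkxhk = 1/3),
                       female_density = "center_biased",
                       male_density = "telomere_biased",
                       telomere_mass = 0.95,
                       interference_nu = 8,
                       error_rate = 0.005,
                       missing_rate = 0.005,
                       tetraploid_drop_frac = 0.3,
                       pseudoautosomal_frac = 0.2,
                       qtl_effects = data.frame(trait = "growth", lg = "LG05",
                                                marker_index = 45, effect = 0.5),
                       sex_effect = c(growth = 0.5),
                       interaction_effect = c(growth = 0),
                       residual_sd = c(growth = 1),
                       transform = c(growth = "none"),
                       seed = 42L) {
  cfg <- list(n_offspring = as.integer(n_offspring), lg_spec = lg_spec,
              n_markers_per_lg = as.integer(n_markers_per_lg),
              marker_type_mix = marker_type_mix,
              female_density = female_density, male_density = male_density,
              telomere_mass = telomere_mass,
              interference_nu = as.integer(interference_nu),
              error_rate = error_rate, missing_rate = missing_rate,
              tetraploid_drop_frac = tetraploid_drop_frac,
              pseudoautosomal_frac = pseudoautosomal_frac,
              qtl_effects = qtl_effects, sex_effect = sex_effect,
              interaction_effect = interaction_effect,
              residual_sd = residual_sd, transform = transform,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#' @param cfg list as built by [sim_config()].
#' @return the config, invisibly classed `sim_config`; errors on violation.
#' @export
validate_sim_config <- function(cfg) {
  ls <- cfg$lg_spec
  need <- c("lg", "lg_class", "female_len", "male_len", "tetraploid",
            "sex_linked", "centromere_end")
  if (!all(need %in% names(ls))) stop("lg_spec missing columns")
  if (cfg$n_offspring < 2) stop("n_offspring must be >= 2")
  if (any(ls$female_len <= 0) || any(ls$male_len <= 0)) stop("lengths must be > 0")
  rates <- c(cfg$error_rate, cfg$missing_rate, cfg$tetraploid_drop_frac,
             cfg$pseudoautosomal_frac, cfg$telomere_mass)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (sum(ls$sex_linked) != 1) stop("exactly one lg must be sex_linked")
  if (abs(sum(cfg$marker_type_mix) - 1) > 1e-8) stop("marker_type_mix must sum to 1")
  if (!all(names(cfg$marker_type_mix) %in% c("nnxnp", "efxeg", "hkxhk"))) {
    stop("marker_type_mix names must be nnxnp/efxeg/hkxhk")
  }
  if (cfg$interference_nu < 1) stop("interference_nu must be >= 1")
  if (!all(ls$lg_class %in% LG_CLASSES)) stop("unknown lg_class in lg_spec")
  if (nrow(cfg$qtl_effects) > 0 &&
      !all(cfg$qtl_effects$lg %in% ls$lg)) stop("qtl_effects reference unknown lg")
  traits <- unique(c(cfg$qtl_effects$trait, names(cfg$sex_effect),
                     names(cfg$residual_sd)))
  if (length(traits) == 0) stop("at least one trait must be defined")
  for (nm in c("sex_effect", "interaction_effect", "residual_sd")) {
    v <- cfg[[nm]]
    cfg[[nm]] <- stats::setNames(
      ifelse(traits %in% names(v), v[traits], if (nm == "residual_sd") 1 else 0),
      traits)
  }
  class(cfg) <- "sim_config"
  cfg
}

# quantile function of a piecewise-uniform density on (0,1):
# breaks = interior cut points, mass = per-piece masses summing to 1
.qpiecewise <- function(breaks, mass) {
  edges <- c(0, breaks, 1)
  cum <- c(0, cumsum(mass))
  function(u) {
    piece <- findInterval(u, cum, rightmost.closed = TRUE,
                          all.inside = TRUE)
    lo <- edges[piece]; hi <- edges[piece + 1]
    frac <- (u - cum[piece]) / (cum[piece + 1] - cum[piece])
    lo + frac * (hi - lo)
  }
}

# positional density quantile function on the (0,1) axis
.density_qfun <- function(id, lg_class = "acrocentric",
                          centromere_end = "start", telomere_mass = 0.95,
                          par_frac = NULL) {
  switch(id,
    uniform = identity,
    center_biased = function(u) stats::qbeta(u, 2, 2),
    telomere_biased = {
      m <- telomere_mass
      if (lg_class == "fused_metacentric") {
        .qpiecewise(c(0.2, 0.8), c(m / 2, 1 - m, m / 2))
      } else if (centromere_end == "end") {
        .qpiecewise(0.2, c(m, 1 - m))
      } else {
        .qpiecewise(0.8, c(1 - m, m))
      }
    },
    par_only = {
      # male recombination confined to the pseudoautosomal terminal segment
      if (centromere_end == "end") .qpiecewise(par_frac, c(1, 0))
      else .qpiecewise(1 - par_frac, c(0, 1))
    },
    stop("unknown density id: ", id)
  )
}

#' Simulate crossover positions for one gamete
#'
#' Crossover locations follow a stationary gamma-renewal process with unit
#' mean spacing on the density-transformed genetic axis, so the expected
#' crossover count is `genetic_len / 100` and the marginal position density
#' is the named density; `nu = 1` reduces to a Poisson count with i.i.d.
#' positions.
#'
#' @param genetic_len genetic length in cM (> 0); sets the expected count.
#' @param density `"uniform"`, `"center_biased"` or `"telomere_biased"`.
#' @param nu gamma-renewal shape (integer >= 1); interference strength.
#' @param lg_class,centromere_end orient the telomere-biased density.
#' @param telomere_mass see [sim_config()].
#' @param axis_len physical axis length (cM) onto which positions are mapped;
#'   defaults to `genetic_len`.
#' @return sorted numeric vector of crossover positions, strictly inside
#'   `(0, axis_len)`.
#' @examples
#' set.seed(1)
#' simulate_gamete(100, "uniform", nu = 1)
#' @export
simulate_gamete <- function(genetic_len, density = "uniform", nu = 8,
                            lg_class = "acrocentric", centromere_end = "start",
                            telomere_mass = 0.95, axis_len = genetic_len) {
  if (genetic_len <= 0) stop("genetic_len must be > 0")
  qfun <- .density_qfun(density, lg_class, centromere_end, telomere_mass)
  axis_len * qfun(.renewal_points(genetic_len / 100, as.integer(nu)))
}

# stationary gamma(nu, nu) renewal points on (0, total), returned as
# fractions of total; first spacing drawn from the Erlang equilibrium
# distribution (an equal mixture of Gamma(j, nu), j = 1..nu)
.renewal_points <- function(total, nu) {
  if (nu == 1) {
    n <- stats::rpois(1, total)
    return(sort(stats::runif(n)))
  }
  pts <- numeric(0)
  x <- stats::rgamma(1, shape = sample.int(nu, 1), rate = nu)
  while (x < total) {
    pts <- c(pts, x)
    x <- x + stats::rgamma(1, shape = nu, rate = nu)
  }
  pts / total
}

#' Simulate a complete four-way cross with ground truth
#'
#' Builds the genetic map, transmits parental haplotypes through simulated
#' meioses (sex-specific crossover counts and positional densities), derives
#' observed genotype codes per marker type, injects genotyping errors and
#' missing calls, assigns offspring sex from the sire haplotype at the sex
#' locus, simulates phenotypes from the planted QTL, and records everything
#' in a ground-truth object.
#'
#' Residually tetraploid linkage groups lose their male-informative marker
#' signal in a terminal fraction of the map (`tetraploid_drop_frac`):
#' sire-only (nnxnp) markers there are dropped from the map and
#' both-informative markers are re-typed to dam-only (lmxll), emulating
#' marker loss during map filtering in residually tetraploid regions.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_cross`: list with `map` ([genetic_map()]),
#'   `geno` ([phased_genotypes()]), `geno_clean` (same, before error and
#'   missingness corruption), `pheno` ([pheno_table()]), `truth` (list:
#'   `true_crossovers`, `true_error_sites`, `true_qtl`, `true_ratio`) and
#'   `config`.
#' @export
simulate_cross <- function(config) {
  config <- validate_sim_config(unclass(config))
  set.seed(config$seed)
  ls <- config$lg_spec
  n <- config$n_offspring
  off <- sprintf("off%03d", seq_len(n))
  m_per <- config$n_markers_per_lg

  map_rows <- vector("list", nrow(ls))
  dam_lab <- sire_lab <- vector("list", nrow(ls))
  xo_list <- vector("list", 2L * nrow(ls))
  sex <- NULL

  for (k in seq_len(nrow(ls))) {
    L <- ls$female_len[k]
    pos <- seq(0, L, length.out = m_per)
    st <- sample(names(config$marker_type_mix), m_per, replace = TRUE,
                 prob = config$marker_type_mix)

    # residual-tetraploidy masking: define the masked terminal region(s)
    masked <- rep(FALSE, m_per)
    if (ls$tetraploid[k] && config$tetraploid_drop_frac > 0) {
      fr <- config$tetraploid_drop_frac
      if (ls$lg_class[k] == "fused_metacentric") {
        masked <- pos < fr / 2 * L | pos > (1 - fr / 2) * L
      } else if (ls$centromere_end[k] == "end") {
        masked <- pos < fr * L
      } else {
        masked <- pos > (1 - fr) * L
      }
    }
    drop <- masked & st == "nnxnp"           # sire-only markers removed
    st[masked & st %in% c("efxeg", "hkxhk")] <- "lmxll"
    keep <- !drop
    pos <- pos[keep]; st <- st[keep]

    map_rows[[k]] <- data.frame(
      marker = sprintf("%s_m%03d", ls$lg[k], which(keep)),
      lg = ls$lg[k], pos = pos, seg_type = st,
      lg_class = ls$lg_class[k], tetraploid = ls$tetraploid[k],
      sex_linked = ls$sex_linked[k], centromere_end = ls$centromere_end[k],
      stringsAsFactors = FALSE)

    # parental transmission: one gamete per parent per offspring
    qf_f <- .density_qfun(config$female_density, ls$lg_class[k],
                          ls$centromere_end[k], config$telomere_mass)
    male_density <- if (ls$sex_linked[k]) "par_only" else config$male_density
    qf_m <- .density_qfun(male_density, ls$lg_class[k], ls$centromere_end[k],
                          config$telomere_mass,
                          par_frac = config$pseudoautosomal_frac)

    lab_f <- matrix(NA_character_, n, length(pos))
    lab_m <- matrix(NA_character_, n, length(pos))
    xo_f <- xo_m <- vector("list", n)
    for (i in seq_len(n)) {
      xo <- L * qf_f(.renewal_points(ls$female_len[k] / 100,
                                     config$interference_nu))
      start <- sample(c("a", "b"), 1)
      lab_f[i, ] <- c("a", "b")[1 + (match(start, c("a", "b")) - 1 +
                                     findInterval(pos, xo)) %% 2]
      xo_f[[i]] <- xo
      xo <- L * qf_m(.renewal_points(ls$male_len[k] / 100,
                                     config$interference_nu))
      start <- sample(c("c", "d"), 1)
      lab_m[i, ] <- c("c", "d")[1 + (match(start, c("c", "d")) - 1 +
                                     findInterval(pos, xo)) %% 2]
      xo_m[[i]] <- xo
    }
    dam_lab[[k]] <- lab_f; sire_lab[[k]] <- lab_m
    nf <- sum(lengths(xo_f)); nm <- sum(lengths(xo_m))
    xo_list[[2 * k - 1]] <- data.frame(
      offspring = rep(off, lengths(xo_f)), parent = rep("dam", nf),
      lg = rep(ls$lg[k], nf), pos = as.numeric(unlist(xo_f)),
      stringsAsFactors = FALSE)
    xo_list[[2 * k]] <- data.frame(
      offspring = rep(off, lengths(xo_m)), parent = rep("sire", nm),
      lg = rep(ls$lg[k], nm), pos = as.numeric(unlist(xo_m)),
      stringsAsFactors = FALSE)

    if (ls$sex_linked[k]) {
      # sire haplotype transmitted at the sex locus (position 0): c => male
      sex_end <- if (ls$centromere_end[k] == "end") max(pos) else 0
      at <- vapply(seq_len(n), function(i) {
        j <- which.min(abs(pos - sex_end))
        lab_m[i, j]
      }, character(1))
      sex <- ifelse(at == "c", "M", "F")
    }
  }

  map <- genetic_map(do.call(rbind, map_rows))
  dam_all <- do.call(cbind, dam_lab)
  sire_all <- do.call(cbind, sire_lab)
  dimnames(dam_all) <- dimnames(sire_all) <- list(off, map$marker)

  # observed codes from true haplotypes, per (possibly re-typed) marker type
  raw <- matrix(NA_character_, n, nrow(map), dimnames = list(off, map$marker))
  for (st in unique(map$seg_type)) {
    j <- which(map$seg_type == st)
    raw[, j] <- .raw_from_hap(st, dam_all[, j, drop = FALSE],
                              sire_all[, j, drop = FALSE])
  }
  geno_clean <- phased_genotypes(raw, map)

  # genotyping errors: uniform substitution to another legal code
  err <- matrix(stats::runif(length(raw)) < config$error_rate, n, nrow(map))
  err_idx <- which(err, arr.ind = TRUE)
  if (nrow(err_idx)) {
    for (r in seq_len(nrow(err_idx))) {
      i <- err_idx[r, 1]; j <- err_idx[r, 2]
      legal <- .seg_raw_codes[[map$seg_type[j]]]
      raw[i, j] <- sample(setdiff(legal, raw[i, j]), 1)
    }
  }
  true_error_sites <- data.frame(
    offspring = off[err_idx[, 1]],
    marker = map$marker[err_idx[, 2]], stringsAsFactors = FALSE)

  raw[matrix(stats::runif(length(raw)) < config$missing_rate,
             n, nrow(map))] <- NA_character_
  geno <- phased_genotypes(raw, map)

  # phenotypes from true haplotypes at the planted QTL
  traits <- names(config$residual_sd)
  ph <- data.frame(offspring = off, sex = sex, stringsAsFactors = FALSE)
  sexM <- as.numeric(sex == "M")
  for (tr in traits) {
    score <- numeric(n)
    qe <- config$qtl_effects[config$qtl_effects$trait == tr, , drop = FALSE]
    if (nrow(qe)) {
      for (r in seq_len(nrow(qe))) {
        jlg <- which(map$lg == qe$lg[r])
        j <- jlg[min(qe$marker_index[r], length(jlg))]
        score <- score + qe$effect[r] *
          ((dam_all[, j] == "b") + (sire_all[, j] == "d"))
      }
    }
    y <- score + config$sex_effect[[tr]] * sexM +
      config$interaction_effect[[tr]] * sexM * score +
      stats::rnorm(n, 0, config$residual_sd[[tr]])
    if (identical(config$transform[[tr]], "log")) y <- exp(y)
    ph[[tr]] <- y
  }
  tf <- stats::setNames(rep("none", length(traits)), traits)
  tf[names(config$transform)] <- config$transform
  pheno <- pheno_table(ph, transform = tf[traits])

  true_xo <- do.call(rbind, xo_list)
  n_dam <- sum(true_xo$parent == "dam")
  n_sire <- sum(true_xo$parent == "sire")
  truth <- list(true_crossovers = true_xo,
                true_error_sites = true_error_sites,
                true_qtl = config$qtl_effects,
                true_ratio = if (n_sire > 0) n_dam / n_sire else NA_real_)

  structure(list(map = map, geno = geno, geno_clean = geno_clean,
                 pheno = pheno, truth = truth, config = config),
            class = "sim_cross")
}
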