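# Single-locus QTL scan with permutation thresholds, support intervals,
# multi-QTL PVE fits, and sex covariate / interaction handling.
#
# The scan statistic is marker regression: at each marker the genotype
# classes are the legal observed codes for its segregation type (two for
# one-parent-informative markers, three for hkxhk, four for efxeg) and
# LOD = (n/2) * log10(RSS_reduced / RSS_full), reduced = covariates only.

.LOD_CAP <- 50

# Per-marker QR designs over the trait-complete offspring subset.
# Returns a list per marker: idx (rows into the subset), Qf, Qr, n, k.
.scan_designs <- function(geno, map, covar, rows) {
  gsub_ <- geno$raw[rows, , drop = FALSE]
  lapply(seq_len(nrow(map)), function(j) {
    g <- gsub_[, j]
    idx <- which(!is.na(g))
    if (length(idx) < 3) return(NULL)
    f <- factor(g[idx])
    if (nlevels(f) < 2) {
      return(list(idx = idx, uninformative = TRUE, n = length(idx)))
    }
    Xr <- cbind(1, covar[idx, , drop = FALSE])
    Xf <- cbind(Xr, stats::model.matrix(~ f)[, -1, drop = FALSE])
    qrf <- qr(Xf); qrr <- qr(Xr)
    list(idx = idx,
         Qf = qr.Q(qrf)[, seq_len(qrf$rank), drop = FALSE],
         Qr = qr.Q(qrr)[, seq_len(qrr$rank), drop = FALSE],
         n = length(idx), uninformative = FALSE)
  })
}

# LOD for all markers x all columns of Y (offspring-subset rows).
.scan_lod_matrix <- function(designs, Y) {
  P <- ncol(Y)
  lod <- matrix(0, length(designs), P)
  for (j in seq_along(designs)) {
    d <- designs[[j]]
    if (is.null(d) || isTRUE(d$uninformative)) next
    Yi <- Y[d$idx, , drop = FALSE]
    tot <- colSums(Yi^2)
    rssr <- tot - colSums((crossprod(d$Qr, Yi))^2)
    rssf <- tot - colSums((crossprod(d$Qf, Yi))^2)
    rssf <- pmax(rssf, 0)
    # centered TSS guards the perfect-fit cap
    mu <- colMeans(Yi)
    tss <- pmax(tot - d$n * mu^2, .Machine$double.eps)
    l <- ifelse(rssf < 1e-12 * tss, .LOD_CAP,
                (d$n / 2) * log10(pmax(rssr, .Machine$double.eps) / rssf))
    lod[j, ] <- pmin(pmax(l, 0), .LOD_CAP)
  }
  lod
}

# offspring with complete trait (+ covariate) data; returns ids, y, covar
.scan_frame <- function(pheno, geno, trait, covariates) {
  y <- .trait_values(pheno, trait)
  ids <- pheno$offspring
  covar <- NULL
  ok <- !is.na(y) & ids %in% rownames(geno$raw)
  if ("sex" %in% covariates) {
    ok <- ok & !is.na(pheno$sex)
    covar <- cbind(sex = as.numeric(pheno$sex == "M"))
  }
  list(ids = ids[ok], y = y[ok],
       covar = if (is.null(covar)) matrix(numeric(0), sum(ok), 0)
               else covar[ok, , drop = FALSE],
       sex = if ("sex" %in% covariates) pheno$sex[ok] else NULL)
}

#' Marginal sex-effect screen for a trait
#'
#' Two-group linear-model F-test (equivalent to the two-sample t-test) of sex
#' on the trait; when `p <= p_threshold` sex should enter the scan model as a
#' covariate.  Returns `FALSE` with a warning when a sex is absent or has
#' fewer than 3 observations, and `FALSE` for a constant trait.
#'
#' @param pheno a `pheno_table`.
#' @param trait trait name.
#' @param p_threshold marginal inclusion threshold (default 0.20).
#' @return logical flag with attributes `p` and `n`.
#' @export
sex_covariate_screen <- function(pheno, trait, p_threshold = 0.20) {
  y <- .trait_values(pheno, trait)
  ok <- !is.na(y) & !is.na(pheno$sex)
  y <- y[ok]; sex <- pheno$sex[ok]
  tab <- table(factor(sex, levels = c("F", "M")))
  if (any(tab < 3)) {
    warning("fewer than 3 observations in one sex; sex covariate flag FALSE")
    return(structure(FALSE, p = NA_real_, n = sum(ok)))
  }
  if (stats::sd(y) == 0) return(structure(FALSE, p = NA_real_, n = sum(ok)))
  fit <- stats::lm(y ~ sex)
  p <- stats::anova(fit)[["Pr(>F)"]][1]
  structure(p <= p_threshold, p = p, n = sum(ok))
}

#' Single-locus LOD scan over all markers
#'
#' Marker regression of the (transformed) trait on each marker's
#' genotype-class factor, with optional covariates; missing genotypes are
#' dropped marker-wise.  Markers with a single observed class score LOD 0 and
#' are flagged uninformative; a perfect fit is reported at the capped
#' sentinel LOD of 50.
#'
#' @param pheno a `pheno_table`.
#' @param geno a `phased_geno`.
#' @param map the `genetic_map`.
#' @param trait trait name.
#' @param covariates character vector; currently `"sex"` is supported.
#' @param shapiro_advisory print a normality advisory for the residual trait
#'   when the Shapiro-Wilk p-value is < 0.01.
#' @return object of class `qtl_scan`: data.frame `marker`, `lg`, `pos`,
#'   `lod`, `n`, `uninformative`, with the trait and covariates as attributes.
#' @export
marker_scan <- function(pheno, geno, map, trait, covariates = NULL,
                        shapiro_advisory = TRUE) {
  fr <- .scan_frame(pheno, geno, trait, covariates)
  if (length(fr$y) < 4) stop("too few complete observations for trait ", trait)
  if (shapiro_advisory && length(fr$y) >= 3 && length(fr$y) <= 5000 &&
      stats::sd(fr$y) > 0) {
    sw <- stats::shapiro.test(fr$y)
    if (sw$p.value < 0.01) {
      message("advisory: trait '", trait, "' deviates from normality ",
              "(Shapiro-Wilk p = ", signif(sw$p.value, 2),
              "); consider a log transform")
    }
  }
  rows <- match(fr$ids, rownames(geno$raw))
  designs <- .scan_designs(geno, map, fr$covar, rows)
  lod <- .scan_lod_matrix(designs, matrix(fr$y, ncol = 1))[, 1]
  out <- data.frame(marker = map$marker, lg = map$lg, pos = map$pos,
                    lod = lod,
                    n = vapply(designs, function(d) if (is.null(d)) 0L else
                      as.integer(d$n), integer(1)),
                    uninformative = vapply(designs, function(d)
                      is.null(d) || isTRUE(d$uninformative), logical(1)),
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  attr(out, "covariates") <- covariates
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Permutation-based genome- and chromosome-wide LOD thresholds
#'
#' Permutes the trait across offspring (within sex strata when sex is a
#' covariate, preserving the covariate's marginal distribution under the
#' null) and takes the (1 - alpha) quantile of the per-permutation maximum
#' LOD: over all markers for the genome-wide threshold, per linkage group for
#' the chromosome-wide thresholds.
#'
#' @inheritParams marker_scan
#' @param n_perm number of permutations (>= 100).
#' @param alpha_genome genome-wide significance level (default 0.05).
#' @param alpha_chrom chromosome-wide significance level (default 0.01).
#' @param seed integer seed for the permutations.
#' @return list of class `perm_thresholds`: `genome`, `chrom` (named per lg),
#'   `n_perm`, alphas and seed.
#' @export
permutation_thresholds <- function(pheno, geno, map, trait, covariates = NULL,
                                   n_perm = 1000, alpha_genome = 0.05,
                                   alpha_chrom = 0.01, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  fr <- .scan_frame(pheno, geno, trait, covariates)
  n <- length(fr$y)
  Y <- matrix(0, n, n_perm)
  if (!is.null(fr$sex)) {
    for (p in seq_len(n_perm)) {
      yp <- fr$y
      for (s in unique(fr$sex)) {
        i <- which(fr$sex == s)
        yp[i] <- fr$y[sample(i)]
      }
      Y[, p] <- yp
    }
  } else {
    for (p in seq_len(n_perm)) Y[, p] <- fr$y[sample.int(n)]
  }
  rows <- match(fr$ids, rownames(geno$raw))
  designs <- .scan_designs(geno, map, fr$covar, rows)
  lod <- .scan_lod_matrix(designs, Y)
  # alpha >= 1 accepts everything: LOD is bounded below by 0
  qtail <- function(x, alpha) {
    if (alpha >= 1) 0 else unname(stats::quantile(x, 1 - alpha))
  }
  genome <- qtail(apply(lod, 2, max), alpha_genome)
  lgs <- unique(map$lg)
  chrom <- vapply(lgs, function(lg) {
    qtail(apply(lod[map$lg == lg, , drop = FALSE], 2, max), alpha_chrom)
  }, numeric(1))
  structure(list(genome = genome, chrom = stats::setNames(chrom, lgs),
                 n_perm = n_perm, alpha_genome = alpha_genome,
                 alpha_chrom = alpha_chrom, seed = seed),
            class = "perm_thresholds")
}

#' 1.5-LOD support interval around a linkage group's peak
#'
#' The widest contiguous marker span around the peak with LOD >= peak - drop,
#' expanded one marker beyond on each side where available (truncated at the
#' linkage-group edges).
#'
#' @param scan a `qtl_scan`.
#' @param lg linkage group id.
#' @param drop LOD drop defining the interval (default 1.5).
#' @return list: `lo`, `hi` (cM), `peak_marker`, `peak_pos`, `peak_lod`,
#'   `markers` (ids spanned).
#' @export
support_interval <- function(scan, lg, drop = 1.5) {
  s <- scan[scan$lg == lg, , drop = FALSE]
  if (!nrow(s)) stop("unknown linkage group: ", lg)
  pk <- which.max(s$lod)
  ok <- s$lod >= s$lod[pk] - drop
  lo <- pk; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < nrow(s) && ok[hi + 1]) hi <- hi + 1
  lo <- max(1, lo - 1); hi <- min(nrow(s), hi + 1)   # one marker beyond
  list(lo = s$pos[lo], hi = s$pos[hi],
       peak_marker = s$marker[pk], peak_pos = s$pos[pk],
       peak_lod = s$lod[pk], markers = s$marker[lo:hi])
}

#' Scan peaks exceeding permutation thresholds
#'
#' @param scan a `qtl_scan`.
#' @param thresholds a `perm_thresholds`.
#' @param drop LOD drop for the support intervals.
#' @return data.frame of significant peaks: lg, peak marker/pos/LOD,
#'   significance (`genome` / `chrom`), interval bounds.
#' @export
scan_peaks <- function(scan, thresholds, drop = 1.5) {
  out <- list()
  for (lg in unique(scan$lg)) {
    s <- scan[scan$lg == lg, ]
    pk <- which.max(s$lod)
    sig <- if (s$lod[pk] > thresholds$genome) "genome"
           else if (s$lod[pk] > thresholds$chrom[[lg]]) "chrom"
           else NA_character_
    if (is.na(sig)) next
    ci <- support_interval(scan, lg, drop = drop)
    out[[length(out) + 1]] <- data.frame(
      lg = lg, marker = ci$peak_marker, pos = ci$peak_pos,
      lod = ci$peak_lod, significance = sig, ci_lo = ci$lo, ci_hi = ci$hi,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(lg = character(0), marker = character(0), pos = numeric(0),
               lod = numeric(0), significance = character(0),
               ci_lo = numeric(0), ci_hi = numeric(0), stringsAsFactors = FALSE)
}

#' Joint multi-QTL fit with percent variance explained
#'
#' Linear model of the trait on the genotype-class factors of the selected
#' peak markers (plus sex when flagged): total PVE = 100 (1 - RSS/TSS) and
#' per-term drop-one PVE = 100 (RSS_without - RSS_full)/TSS.  Collinear terms
#' are dropped with a warning.  Genotype-class phenotype means are reported
#' per marker, split by sex when sex is in the model.
#'
#' @param pheno,geno,map,trait as in [marker_scan()].
#' @param markers character vector of marker ids (scan peaks).
#' @param sex include sex as a covariate.
#' @return object of class `qtl_fit`: `total_pve`, `term_pve`, `class_means`,
#'   `n`, `fit` (the `lm`).
#' @export
fit_multi_qtl <- function(pheno, geno, map, trait, markers, sex = FALSE) {
  stopifnot(all(markers %in% map$marker))
  fr <- .scan_frame(pheno, geno, trait, if (sex) "sex" else NULL)
  rows <- match(fr$ids, rownames(geno$raw))
  dat <- data.frame(y = fr$y)
  if (sex) dat$sex <- factor(ifelse(fr$covar[, "sex"] == 1, "M", "F"))
  for (mk in markers) dat[[make.names(mk)]] <- factor(geno$raw[rows, mk])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  terms0 <- setdiff(names(dat), "y")
  # drop collinear terms (aliased coefficients)
  repeat {
    fml <- stats::reformulate(terms0, response = "y")
    fit <- stats::lm(fml, data = dat)
    alias_tab <- stats::alias(fit)$Complete
    if (is.null(alias_tab) || !length(terms0)) break
    aliased <- rownames(alias_tab)
    bad <- terms0[vapply(terms0, function(t) any(startsWith(aliased, t)),
                         logical(1))]
    if (!length(bad)) break
    warning("dropping collinear term(s): ", paste(bad, collapse = ", "))
    terms0 <- setdiff(terms0, bad)
    if (!length(terms0)) { fit <- stats::lm(y ~ 1, data = dat); break }
  }
  rss_full <- sum(stats::residuals(fit)^2)
  tss <- sum((dat$y - mean(dat$y))^2)
  total_pve <- 100 * (1 - rss_full / tss)
  term_pve <- vapply(terms0, function(t) {
    rest <- setdiff(terms0, t)
    f0 <- if (length(rest)) stats::reformulate(rest, response = "y") else y ~ 1
    100 * (sum(stats::residuals(stats::lm(f0, data = dat))^2) - rss_full) / tss
  }, numeric(1))
  class_means <- lapply(stats::setNames(markers, markers), function(mk) {
    v <- make.names(mk)
    if (!v %in% names(dat)) return(NULL)
    if (sex) {
      ag <- stats::aggregate(dat$y, list(class = dat[[v]], sex = dat$sex), mean)
      names(ag)[3] <- "mean"
    } else {
      ag <- stats::aggregate(dat$y, list(class = dat[[v]]), mean)
      names(ag)[2] <- "mean"
    }
    ag$effect <- ag$mean - ag$mean[1]
    ag
  })
  structure(list(trait = trait, markers = markers, sex = sex,
                 total_pve = total_pve, term_pve = term_pve,
                 class_means = class_means, n = nrow(dat), fit = fit),
            class = "qtl_fit")
}

#' Sex-by-genotype interaction test at a marker
#'
#' Gatekept F-test: the full model (genotype, sex and their interaction) must
#' itself be significant against the null before the interaction is tested by
#' comparing the full model with the additive one.
#'
#' @param pheno,geno,map,trait as in [marker_scan()].
#' @param marker marker id.
#' @param gate_alpha significance required of the full model (default 0.05).
#' @return list: `p_interaction` (NA when gated out or skipped), `p_full`,
#'   `tested`, `note`.
#' @export
interaction_test <- function(pheno, geno, map, trait, marker,
                             gate_alpha = 0.05) {
  fr <- .scan_frame(pheno, geno, trait, "sex")
  rows <- match(fr$ids, rownames(geno$raw))
  g <- factor(geno$raw[rows, marker])
  sexf <- factor(ifelse(fr$covar[, "sex"] == 1, "M", "F"))
  ok <- !is.na(g)
  y <- fr$y[ok]; g <- droplevels(g[ok]); sexf <- droplevels(sexf[ok])
  if (nlevels(g) < 2 || nlevels(sexf) < 2) {
    warning("degenerate design; interaction test skipped")
    return(list(p_interaction = NA_real_, p_full = NA_real_, tested = FALSE,
                note = "degenerate design"))
  }
  if (any(table(sexf, g) == 0)) {
    warning("empty sex x genotype cell; interaction test skipped")
    return(list(p_interaction = NA_real_, p_full = NA_real_, tested = FALSE,
                note = "empty cell"))
  }
  full <- stats::lm(y ~ sexf * g)
  null <- stats::lm(y ~ 1)
  p_full <- stats::anova(null, full)[["Pr(>F)"]][2]
  if (is.na(p_full) || p_full > gate_alpha) {
    return(list(p_interaction = NA_real_, p_full = p_full, tested = FALSE,
                note = "full model not significant"))
  }
  additive <- stats::lm(y ~ sexf + g)
  p_int <- stats::anova(additive, full)[["Pr(>F)"]][2]
  list(p_interaction = p_int, p_full = p_full, tested = TRUE, note = "ok")
}

#' Binary sex-trait scan to locate the sex-linked linkage group
#'
#' Codes offspring sex as a 0/1 trait and runs the single-locus scan; the
#' sex-linked lg is the one whose markers exceed the genome-wide threshold,
#' with the expected signature of elevated LOD across most of the lg and a
#' decline at the distal pseudoautosomal end.
#'
#' @param pheno a `pheno_table` with both sexes present.
#' @param geno,map as in [marker_scan()].
#' @return a `qtl_scan` of the binary sex trait.
#' @export
sex_linkage_scan <- function(pheno, geno, map) {
  if (length(unique(stats::na.omit(pheno$sex))) < 2) {
    stop("both sexes must be present for the sex-linkage scan")
  }
  ph <- as.data.frame(pheno)
  ph$.sex01 <- as.numeric(ph$sex == "M")
  ph2 <- pheno_table(ph[, c("offspring", "sex", ".sex01")])
  sc <- marker_scan(ph2, geno, map, ".sex01", covariates = NULL,
                    shapiro_advisory = FALSE)
  attr(sc, "trait") <- "sex (binary)"
  sc
}
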