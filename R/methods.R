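# print / summary / plot methods for the package's result classes.

#' @export
print.sim_cross <- function(x, ...) {
  info <- lg_info(x$map)
  cat("Simulated four-way cross:", nrow(x$geno$raw), "offspring,",
      nrow(x$map), "markers on", nrow(info), "linkage groups\n")
  cat("  classes:", sum(info$lg_class == "fused_metacentric"),
      "fused metacentric /", sum(info$lg_class == "acrocentric"),
      "acrocentric;", sum(info$tetraploid), "residually tetraploid;",
      "sex-linked:", info$lg[info$sex_linked], "\n")
  cat("  true crossovers:", nrow(x$truth$true_crossovers),
      sprintf("(female:male ratio %.2f)", x$truth$true_ratio), "\n")
  cat("  error sites:", nrow(x$truth$true_error_sites),
      " traits:", paste(trait_names(x$pheno), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.phased_geno <- function(x, ...) {
  cat("Phased four-way-cross genotypes:", nrow(x$raw), "offspring x",
      ncol(x$raw), "markers\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$raw))))
  invisible(x)
}

#' @export
print.xo_summary <- function(x, ...) {
  cat("Crossover summary (retained events)\n")
  tt <- x$totals
  tt$ratio <- round(tt$ratio, 3)
  print(tt, row.names = FALSE)
  cat("\nPer-chromosome means (autosomes):\n")
  print(x$per_chrom_means, row.names = FALSE)
  cat("\nRemoved by double-crossover correction:\n")
  print(x$removed, row.names = FALSE)
  invisible(x)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  markers removed (segregation distortion):",
      length(x$markers_removed), "->", x$n_markers_retained, "retained\n")
  cat("  offspring removed:", nrow(x$offspring_removed), "\n")
  if (nrow(x$offspring_removed)) {
    print(x$offspring_removed, row.names = FALSE)
  }
  n_out <- sum(lengths(x$phenotype_outliers))
  cat("  phenotype outlier values removed:", n_out, "\n")
  invisible(x)
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf("Permutation thresholds (%d permutations)\n", x$n_perm))
  cat(sprintf("  genome-wide (alpha = %.2f): LOD %.2f\n",
              x$alpha_genome, x$genome))
  cat(sprintf("  chromosome-wide (alpha = %.2f): LOD %.2f - %.2f across %d lgs\n",
              x$alpha_chrom, min(x$chrom), max(x$chrom), length(x$chrom)))
  invisible(x)
}

#' @export
print.qtl_fit <- function(x, ...) {
  cat("Multi-QTL fit for trait '", x$trait, "' (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  total PVE: %.1f%%\n", x$total_pve))
  for (nm in names(x$term_pve)) {
    cat(sprintf("  %s: %.1f%%\n", nm, x$term_pve[[nm]]))
  }
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, thresholds = NULL, drop = 1.5, ...) {
  if (!is.null(thresholds)) return(scan_peaks(object, thresholds, drop = drop))
  out <- do.call(rbind, lapply(unique(object$lg), function(lg) {
    s <- object[object$lg == lg, ]
    pk <- which.max(s$lod)
    data.frame(lg = lg, marker = s$marker[pk], pos = s$pos[pk],
               lod = s$lod[pk], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plot a LOD scan along the genome
#'
#' LOD profile with linkage groups laid end to end, alternating shading, and
#' optional permutation threshold lines.
#'
#' @param x a `qtl_scan`.
#' @param thresholds optional `perm_thresholds` (genome-wide line drawn).
#' @param ... passed to [graphics::plot()].
#' @export
plot.qtl_scan <- function(x, thresholds = NULL, ...) {
  lgs <- unique(x$lg)
  off <- 0; xs <- numeric(nrow(x)); bounds <- numeric(0)
  for (lg in lgs) {
    i <- x$lg == lg
    xs[i] <- x$pos[i] + off
    off <- max(xs[i]) + 5
    bounds <- c(bounds, off - 2.5)
  }
  graphics::plot(xs, x$lod, type = "n", xlab = "cumulative position (cM)",
                 ylab = "LOD", ...)
  for (k in seq_along(lgs)) {
    i <- x$lg == lgs[k]
    graphics::lines(xs[i], x$lod[i],
                    col = if (k %% 2) "grey25" else "steelblue")
  }
  graphics::abline(v = utils::head(bounds, -1), col = "grey85", lty = 3)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$genome, col = "firebrick", lty = 2)
  }
  invisible(x)
}

#' Plot the positional crossover distribution
#'
#' Per-parent histograms of crossover positions on the percent-of-chromosome
#' axis, one panel per chromosome class.
#'
#' @param x an `xo_distribution`.
#' @param ... unused.
#' @export
plot.xo_distribution <- function(x, ...) {
  cnt <- x$counts
  old <- graphics::par(mfrow = c(1, length(unique(cnt$lg_class))))
  on.exit(graphics::par(old))
  for (cl in unique(cnt$lg_class)) {
    sub <- cnt[cnt$lg_class == cl, ]
    dam <- sub$count[sub$parent == "dam"]
    sire <- sub$count[sub$parent == "sire"]
    mids <- (sub$bin_lo[sub$parent == "dam"] +
               sub$bin_hi[sub$parent == "dam"]) / 2
    graphics::matplot(mids, cbind(dam, sire), type = "s", lty = 1,
                      col = c("firebrick", "steelblue"),
                      xlab = "% of chromosome length", ylab = "crossovers",
                      main = cl)
    graphics::legend("top", c("dam", "sire"), lty = 1,
                     col = c("firebrick", "steelblue"), bty = "n")
  }
  invisible(x)
}
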