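#' Plot Q_ST values against the per-SNP F_ST distribution
#'
#' Histogram of per-SNP Hudson F_ST for one contrast with the mean (solid)
#' and mean + 2 SD (dashed) reference lines, and the scanned traits' Q_ST
#' values marked along the axis.
#'
#' @param snps per-SNP table from [hudson_fst_per_snp()].
#' @param scan rows of a [qst_fst_scan()] result for the same contrast.
#' @param main plot title.
#' @export
plot_qst_fst <- function(snps, scan, main = unique(scan$contrast)[1]) {
  fs <- fst_summary(snps)
  x <- snps$fst[!is.na(snps$fst)]
  graphics::hist(x, breaks = 50, main = main, xlab = "per-SNP Hudson F_ST",
                 col = "grey85", border = "grey60",
                 xlim = range(c(x, scan$qst), na.rm = TRUE))
  graphics::abline(v = fs$mean_fst, col = "red", lwd = 2)
  graphics::abline(v = fs$threshold, col = "red", lty = 2, lwd = 2)
  ok <- !is.na(scan$qst)
  graphics::points(scan$qst[ok], rep(0, sum(ok)), pch = 17, cex = 1.3,
                   col = ifelse(isTRUE(scan$significant[ok]), "blue", "black"))
  graphics::text(scan$qst[ok], 0, labels = scan$trait[ok], pos = 3, cex = 0.7)
  invisible(fs)
}

#' Plot population reaction norms for one trait
#'
#' Population x garden cell means joined across gardens, with +/- 1 SD
#' error bars; crossing lines between populations indicate G x E
#' interaction, and crossing of fitness norms indicates local adaptation.
#'
#' @param rn result of [reaction_norms()].
#' @param trait trait to plot.
#' @export
plot_reaction_norms <- function(rn, trait) {
  cc <- rn$cells[rn$cells$trait == trait, ]
  if (!nrow(cc)) stop(sprintf("trait %s not in reaction-norm table", trait))
  gardens <- GARDENS[GARDENS %in% unique(cc$site_id)]
  pops <- unique(cc$population)
  cols <- grDevices::hcl.colors(length(pops), "Dark 3")
  xs <- seq_along(gardens)
  ylim <- range(cc$mean - cc$sd, cc$mean + cc$sd, na.rm = TRUE)
  graphics::plot(NA, xlim = c(0.7, length(gardens) + 0.3), ylim = ylim,
                 xaxt = "n", xlab = "", ylab = trait,
                 main = sprintf("Reaction norms: %s", trait))
  graphics::axis(1, at = xs, labels = gardens)
  for (k in seq_along(pops)) {
    ci <- cc[cc$population == pops[k], ]
    ci <- ci[match(gardens, ci$site_id), ]
    graphics::lines(xs, ci$mean, col = cols[k], lwd = 2, type = "b", pch = 16)
    graphics::arrows(xs, ci$mean - ci$sd, xs, ci$mean + ci$sd, length = 0.03,
                     angle = 90, code = 3, col = cols[k])
  }
  graphics::legend("topleft", legend = pops, col = cols, lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(cc)
}

#' Residual plot for the quadratic environmental-distance fit
#'
#' Stage-1 fitness residuals against environmental distance with the
#' stage-2 quadratic fit and a 95% confidence band.
#'
#' @param result an `envdist_result` from [quadratic_residual_test()].
#' @param distance the distances used in the test (complete cases only).
#' @param xlab x-axis label (variable name and units).
#' @export
plot_envdist_residuals <- function(result, distance, xlab = "environmental distance") {
  e <- result$residuals
  distance <- distance[complete.cases(distance)][seq_along(e)]
  graphics::plot(distance, e, pch = 16, col = "grey40",
                 xlab = xlab, ylab = "fitness residual e")
  xg <- seq(min(distance), max(distance), length.out = 200)
  pr <- stats::predict(result$fit,
                       newdata = data.frame(distance = xg, d2 = xg^2),
                       interval = "confidence")
  graphics::polygon(c(xg, rev(xg)), c(pr[, "lwr"], rev(pr[, "upr"])),
                    col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  graphics::lines(xg, pr[, "fit"], col = "steelblue", lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(result)
}
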