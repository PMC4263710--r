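#' Plot pair-correlation distributions
#'
#' Overlaid frequency polygons of the correlation histograms of several
#' pair classes (e.g. random null, PC-PC all/hi, PC-NC all/hi), the
#' standard visual comparison for cis-coupling analyses.
#'
#' @param ... named numeric vectors of pair correlations (NAs dropped)
#' @param bin_width histogram bin width (default 0.1)
#' @return invisibly, the list of [r_distribution()] results
#' @export
plot_r_distributions <- function(..., bin_width = 0.1) {
  groups <- list(...)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("plot_r_distributions: supply named vectors")
  }
  dists <- lapply(groups, r_distribution, bin_width = bin_width)
  dens <- lapply(dists, function(d) d$counts / d$n)
  cols <- seq_along(dists)
  plot(NA, xlim = c(-1, 1), ylim = c(0, max(unlist(dens))),
       xlab = "Pearson r", ylab = "fraction of pairs",
       main = "Ontogenic correlation of gene pairs")
  for (i in cols) {
    graphics::lines(dists[[i]]$mids, dens[[i]], col = i, lwd = 2)
  }
  graphics::legend("topleft", legend = names(groups), col = cols, lwd = 2,
                   bty = "n")
  invisible(dists)
}

#' Heat-map of inter-age similarity
#'
#' @param r an ages x ages correlation matrix from [age_similarity()]
#' @param main plot title
#' @return invisibly, `r`
#' @export
plot_age_similarity <- function(r, main = "Inter-age similarity (Pearson r)") {
  n <- ncol(r)
  graphics::image(seq_len(n), seq_len(n), t(r[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "age (days)", ylab = "age (days)",
                  main = main, zlim = c(min(r), 1))
  graphics::axis(1, at = seq_len(n), labels = colnames(r), las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(r)), las = 2)
  invisible(r)
}
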