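# User-level genome scan: one high/low pool pair in, a classed scan
# object out.  Wraps the allele-frequency preprocessing (extreme-marker
# filtering, loess-type smoothing, delta-AF) and the binned LOD model.

#' Genome scan contrasting a high and a low sorted pool
#'
#' The central model fit of the package.  Marker frequencies are
#' computed for both pools, markers with an extreme frequency
#' (outside `af_bounds`) in either pool are removed from the pair,
#' both tracks are smoothed by depth-weighted local-linear regression,
#' counts are summed into fixed-width bins and the hidden-frequency
#' contrast LOD is computed per bin ([lod_track()]).  The reported
#' per-bin delta-AF is the smoothed high-minus-low frequency difference
#' interpolated at the bin midpoint.
#'
#' @param high,low `pooled_counts` of the matched high and low pools.
#' @param params a [lod_params()].
#' @param af_bounds retained raw-frequency range (markers strictly
#'   outside it in either pool are dropped from both).
#' @param smooth_bandwidth physical half-width (bp) of the delta-AF
#'   smoother.
#' @param min_median_depth pools whose median marker depth falls below
#'   this are rejected (delta-AF is noise-dominated below ~2-fold
#'   coverage).
#' @return an object of class `qtl_scan` with components `track` (the
#'   [lod_track()] data frame), `delta_markers` (per-marker smoothed
#'   delta-AF), `params`, `n_markers`, `n_filtered` and `metadata`.
#' @seealso [call_peaks()], [plot.qtl_scan()]
#' @export
qtl_scan <- function(high, low, params = lod_params(),
                     af_bounds = c(0.1, 0.9), smooth_bandwidth = 20000,
                     min_median_depth = 2) {
  af_h <- compute_af(high)
  af_l <- compute_af(low)
  for (tr in list(af_h, af_l)) {
    md <- stats::median(tr$depth)
    if (md < min_median_depth) {
      stop_input("pool median depth ", md, " is below the required ",
                 min_median_depth)
    }
  }
  kh <- chrom_key(af_h$chrom, af_h$pos)
  kl <- chrom_key(af_l$chrom, af_l$pos)
  if (length(kh) != length(kl) || any(kh != kl)) {
    stop_input("high and low pools cover different markers")
  }
  ok_h <- is.na(af_h$af) | (af_h$af >= af_bounds[1] & af_h$af <= af_bounds[2])
  ok_l <- is.na(af_l$af) | (af_l$af >= af_bounds[1] & af_l$af <= af_bounds[2])
  keep <- ok_h & ok_l
  n_filtered <- sum(!keep)
  af_h <- af_h[keep, , drop = FALSE]
  af_l <- af_l[keep, , drop = FALSE]
  class(af_h) <- class(af_l) <- c("af_track", "data.frame")
  sm_h <- smooth_af(af_h, smooth_bandwidth)
  sm_l <- smooth_af(af_l, smooth_bandwidth)
  dm <- delta_af(sm_h, sm_l)
  bh <- bin_counts(high[keep, , drop = FALSE], params)
  bl <- bin_counts(low[keep, , drop = FALSE], params)
  delta_bins <- rep(NA_real_, nrow(bh))
  for (chr in unique(bh$chrom)) {
    i <- which(bh$chrom == chr)
    j <- which(dm$chrom == chr & !is.na(dm$delta_af))
    if (length(j) >= 2) {
      mid <- (bh$bin_start[i] + bh$bin_end[i]) / 2
      delta_bins[i] <- stats::approx(dm$pos[j], dm$delta_af[j], xout = mid,
                                     rule = 2)$y
    } else if (length(j) == 1) {
      delta_bins[i] <- dm$delta_af[j]
    }
  }
  track <- lod_track(bh, bl, params, delta = delta_bins)
  md_h <- pool_metadata(high)
  structure(list(track = track,
                 delta_markers = dm,
                 params = params,
                 af_bounds = af_bounds,
                 smooth_bandwidth = smooth_bandwidth,
                 n_markers = sum(keep),
                 n_filtered = n_filtered,
                 metadata = list(gene = md_h$gene, channel = md_h$channel,
                                 replicate = md_h$replicate,
                                 batch = md_h$batch),
                 call = match.call()),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  md <- x$metadata
  cat("QTL genome scan",
      if (!is.na(md$gene %||% NA)) paste0("(", md$gene,
        if (!is.na(md$channel %||% NA)) paste0(", ", md$channel),
        if (!is.na(md$replicate %||% NA)) paste0(", rep ", md$replicate),
        ")"), "\n")
  cat("  markers used:", x$n_markers,
      "(", x$n_filtered, "removed by the allele-frequency filter )\n")
  cat("  bins:", nrow(x$track), " max LOD:",
      round(max(x$track$lod), 2), "\n")
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, threshold = 3, ...) {
  pk <- call_peaks(object, threshold = threshold)
  out <- list(scan = object, threshold = threshold, peaks = pk)
  class(out) <- "summary.qtl_scan"
  out
}

#' @export
print.summary.qtl_scan <- function(x, ...) {
  print(x$scan)
  cat("  peaks at LOD >=", x$threshold, ":", nrow(x$peaks), "\n")
  if (nrow(x$peaks)) {
    print(x$peaks[, c("chrom", "pos", "lod", "delta_af", "ci_lo", "ci_hi")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Plot a QTL genome scan
#'
#' Two stacked panels: per-bin LOD and smoothed per-marker delta-AF,
#' with chromosomes laid side by side.
#'
#' @param x a `qtl_scan` object.
#' @param threshold significance threshold drawn as a dashed line.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.qtl_scan <- function(x, threshold = 4.5, ...) {
  tr <- x$track
  chroms <- unique(tr$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(tr$bin_end[tr$chrom == ch]), numeric(1))))
  names(offs) <- c(chroms, "end")
  gx <- tr$bin_start + offs[match(tr$chrom, chroms)]
  old <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(gx, tr$lod, type = "l", xlab = "", ylab = "LOD", ...)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  graphics::abline(v = offs[-1], col = "grey80")
  dm <- x$delta_markers
  gx2 <- dm$pos + offs[match(dm$chrom, chroms)]
  graphics::plot(gx2, dm$delta_af, type = "l",
                 xlab = "genome position (bp)",
                 ylab = expression(Delta * "AF"), ...)
  graphics::abline(h = 0, col = "grey40")
  graphics::abline(v = offs[-1], col = "grey80")
  invisible(x)
}
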