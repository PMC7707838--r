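# Allele-frequency tracks: per-marker BY allele frequencies, extreme
# frequency filtering, local-regression smoothing and the high-minus-low
# delta-AF contrast.

#' Compute the BY (reference) allele-frequency track of a pool
#'
#' @param counts a `pooled_counts` data frame.
#' @return object of class `af_track`: data frame with columns `chrom`,
#'   `pos`, `af` (BY allele frequency, `NA` where depth is zero) and
#'   `depth`.
#' @export
compute_af <- function(counts) {
  check_columns(counts, c("chrom", "pos", "ref_count", "alt_count"),
                "counts")
  depth <- counts$ref_count + counts$alt_count
  af <- ifelse(depth > 0, counts$ref_count / depth, NA_real_)
  out <- data.frame(chrom = counts$chrom, pos = counts$pos,
                    af = af, depth = depth)
  attr(out, "metadata") <- attr(counts, "metadata")
  class(out) <- c("af_track", "data.frame")
  out
}

#' Remove markers with extreme allele frequencies
#'
#' Markers with frequency strictly above `high` or strictly below `low`
#' are removed (boundary values are retained); such frequencies in a
#' segregating pool indicate unreliable markers rather than selection.
#' Missing frequencies (zero depth) are never treated as extreme.
#'
#' @param track an `af_track`.
#' @param low,high retained frequency bounds (defaults 0.1 and 0.9).
#' @return the filtered `af_track`; the number of removed markers is
#'   stored in `attr(, "n_removed")`.
#' @export
filter_extreme <- function(track, low = 0.1, high = 0.9) {
  check_columns(track, c("chrom", "pos", "af"), "track")
  if (low >= high) stop_input("low must be < high")
  extreme <- !is.na(track$af) & (track$af > high | track$af < low)
  out <- track[!extreme, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metadata") <- attr(track, "metadata")
  attr(out, "n_removed") <- sum(extreme)
  class(out) <- class(track)
  out
}

# Depth-weighted local-linear regression with tri-cube weights and a
# fixed physical bandwidth; returns fitted values at the input positions.
local_linear_smooth <- function(pos, y, w, bandwidth) {
  n <- length(pos)
  fit <- rep(NA_real_, n)
  ok <- which(!is.na(y) & w > 0)
  if (length(ok) < 2) return(y)
  pos_ok <- pos[ok]
  y_ok <- y[ok]
  w_ok <- w[ok]
  lo <- findInterval(pos - bandwidth, pos_ok, left.open = TRUE) + 1L
  hi <- findInterval(pos + bandwidth, pos_ok)
  for (i in seq_len(n)) {
    if (lo[i] > hi[i]) next
    j <- lo[i]:hi[i]
    dx <- pos_ok[j] - pos[i]
    tw <- (1 - pmin(1, abs(dx) / bandwidth)^3)^3 * w_ok[j]
    sw <- sum(tw)
    if (sw <= 0) next
    if (length(j) == 1L) {
      fit[i] <- y_ok[j]
      next
    }
    xbar <- sum(tw * dx) / sw
    sxx <- sum(tw * (dx - xbar)^2)
    ybar <- sum(tw * y_ok[j]) / sw
    if (sxx <= .Machine$double.eps * bandwidth^2) {
      fit[i] <- ybar
    } else {
      beta <- sum(tw * (dx - xbar) * (y_ok[j] - ybar)) / sxx
      fit[i] <- ybar - beta * xbar
    }
  }
  fit
}

#' Smooth an allele-frequency track
#'
#' Depth-weighted local-linear (loess-type) regression of frequency on
#' position, computed per chromosome with tri-cube weights inside a
#' fixed physical bandwidth.  A physical bandwidth (default 20 kb, well
#' below typical QTL confidence-interval widths) is robust to uneven
#' marker density.  Smoothed values are clipped to `[0, 1]`; markers
#' with zero depth stay `NA`.
#'
#' @param track an `af_track`.
#' @param bandwidth_bp half-width of the smoothing window in bp.
#' @return the smoothed `af_track` (raw frequencies kept in `af_raw`).
#' @export
smooth_af <- function(track, bandwidth_bp = 20000) {
  check_columns(track, c("chrom", "pos", "af", "depth"), "track")
  stopifnot(bandwidth_bp > 0)
  out <- track
  out$af_raw <- track$af
  for (chr in unique(track$chrom)) {
    i <- which(track$chrom == chr)
    informative <- sum(!is.na(track$af[i]))
    if (informative < 5) {
      warning("chromosome ", chr, " has fewer than 5 informative markers; ",
              "passed through unsmoothed")
      next
    }
    sm <- local_linear_smooth(track$pos[i], track$af[i],
                              pmax(track$depth[i], 0), bandwidth_bp)
    keep_na <- is.na(track$af[i])
    sm[keep_na] <- NA_real_
    out$af[i] <- pmin(1, pmax(0, sm))
  }
  attr(out, "metadata") <- attr(track, "metadata")
  class(out) <- class(track)
  out
}

#' Delta-AF contrast between a high and a low pool
#'
#' The allele frequency of the low-fluorescence pool subtracted from its
#' matched high-fluorescence pool, per marker.  Positive delta-AF means
#' the BY allele is enriched in the high pool, i.e. the BY allele
#' increases expression.
#'
#' @param high,low `af_track` objects on identical marker sets.
#' @return object of class `delta_track`: data frame with `chrom`,
#'   `pos`, `delta_af`, `depth_high`, `depth_low`.
#' @export
delta_af <- function(high, low) {
  check_columns(high, c("chrom", "pos", "af", "depth"), "high")
  check_columns(low, c("chrom", "pos", "af", "depth"), "low")
  kh <- chrom_key(high$chrom, high$pos)
  kl <- chrom_key(low$chrom, low$pos)
  if (length(kh) != length(kl) || any(kh != kl)) {
    bad <- union(setdiff(kh, kl), setdiff(kl, kh))
    stop_input("marker sets differ between pools: ",
               paste(utils::head(bad, 10), collapse = ", "),
               if (length(bad) > 10) " ...")
  }
  out <- data.frame(chrom = high$chrom, pos = high$pos,
                    delta_af = high$af - low$af,
                    depth_high = high$depth, depth_low = low$depth)
  attr(out, "provenance") <- list(high = attr(high, "metadata"),
                                  low = attr(low, "metadata"))
  class(out) <- c("delta_track", "data.frame")
  out
}
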