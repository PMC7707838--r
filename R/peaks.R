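# Peak calling: discrete QTLs with 2-LOD support intervals from a LOD
# track.

#' Call QTL peaks from a LOD track
#'
#' One peak is reported per maximal contiguous run of bins with LOD at
#' or above the threshold (multiple local maxima inside one run are not
#' split; replicate merging absorbs residual ambiguity).  Contiguity is
#' assessed over informative bins: bins with zero depth in both pools
#' carry no evidence (their LOD is 0 by construction) and do not break
#' a run.  The peak is the run's LOD maximum (ties resolved to the
#' smallest coordinate) and its support interval extends from the peak
#' in both directions to the outer edge of the first bin whose LOD
#' drops `drop` units below the peak value, clamped to the chromosome
#' ends.
#'
#' @param x a `qtl_scan` object or a `lod_track` data frame.
#' @param threshold LOD calling threshold (the study used 3.0 as a
#'   permissive and 4.5 as a stringent threshold).
#' @param drop LOD drop defining the support interval (default 2).
#' @param ... unused.
#' @return data frame of class `qtl_peaks` with columns `chrom`, `pos`
#'   (peak bin midpoint), `lod`, `delta_af`, `ci_lo`, `ci_hi`, `gene`,
#'   `channel`, `replicate`.
#' @export
call_peaks <- function(x, threshold = 3, drop = 2, ...) {
  UseMethod("call_peaks")
}

#' @export
call_peaks.qtl_scan <- function(x, threshold = 3, drop = 2, ...) {
  pk <- call_peaks(x$track, threshold = threshold, drop = drop)
  md <- x$metadata
  pk$gene <- rep(md$gene %||% NA_character_, nrow(pk))
  pk$channel <- rep(md$channel %||% NA_character_, nrow(pk))
  pk$replicate <- rep(md$replicate %||% NA, nrow(pk))
  pk
}

#' @export
call_peaks.data.frame <- function(x, threshold = 3, drop = 2, ...) {
  check_columns(x, c("chrom", "bin_start", "bin_end", "lod"), "track")
  empty <- data.frame(chrom = character(), pos = numeric(), lod = numeric(),
                      delta_af = numeric(), ci_lo = numeric(),
                      ci_hi = numeric())
  if (!nrow(x)) {
    class(empty) <- c("qtl_peaks", "data.frame")
    return(empty)
  }
  has_delta <- "delta_af" %in% names(x)
  if (all(c("depth_high", "depth_low") %in% names(x))) {
    informative <- x$depth_high + x$depth_low > 0
    if (any(informative)) x <- x[informative, , drop = FALSE]
  }
  rows <- list()
  for (chr in unique(x$chrom)) {
    tr <- x[x$chrom == chr, , drop = FALSE]
    above <- tr$lod >= threshold
    if (!any(above)) next
    run_id <- cumsum(c(above[1], diff(above) == 1)) * above
    for (rid in setdiff(unique(run_id), 0)) {
      run <- which(run_id == rid)
      peak_i <- run[which.max(tr$lod[run])]
      peak_lod <- tr$lod[peak_i]
      cut <- peak_lod - drop
      below_left <- which(tr$lod[seq_len(peak_i)] <= cut)
      ci_lo <- if (length(below_left)) {
        tr$bin_start[max(below_left)]
      } else {
        tr$bin_start[1]
      }
      right <- seq.int(peak_i, nrow(tr))
      below_right <- right[tr$lod[right] <= cut]
      ci_hi <- if (length(below_right)) {
        tr$bin_end[min(below_right)]
      } else {
        tr$bin_end[nrow(tr)]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr,
        pos = (tr$bin_start[peak_i] + tr$bin_end[peak_i]) / 2,
        lod = peak_lod,
        delta_af = if (has_delta) tr$delta_af[peak_i] else NA_real_,
        ci_lo = ci_lo, ci_hi = ci_hi)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  class(out) <- c("qtl_peaks", "data.frame")
  out
}
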