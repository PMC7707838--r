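# Replicate integration: merging peaks across biological replicates,
# the stringent significance filter, the reproducibility statistic and
# the inter-replicate empirical false discovery rate.

# LOD / delta-AF of a track at an arbitrary position (value of the bin
# containing the position; nearest bin if outside the tiled range).
track_value_at <- function(track, chrom, pos) {
  if (inherits(track, "qtl_scan")) track <- track$track
  i <- which(track$chrom == chrom)
  if (!length(i)) {
    stop_input("position ", chrom, ":", pos, " outside the track")
  }
  j <- i[pos >= track$bin_start[i] & pos <= track$bin_end[i]]
  if (!length(j)) {
    j <- i[which.min(abs((track$bin_start[i] + track$bin_end[i]) / 2 - pos))]
  }
  list(lod = track$lod[j[1]], delta_af = track$delta_af[j[1]])
}

cluster_positions <- function(pos, window, linkage) {
  if (length(pos) == 1) return(1L)
  if (linkage == "single") {
    ord <- order(pos)
    grp <- integer(length(pos))
    g <- 1L
    grp[ord[1]] <- g
    for (k in seq.int(2, length(ord))) {
      if (pos[ord[k]] - pos[ord[k - 1]] > window) g <- g + 1L
      grp[ord[k]] <- g
    }
    grp
  } else {
    stats::cutree(stats::hclust(stats::dist(pos), method = "complete"),
                  h = window)
  }
}

#' Merge QTL peaks across biological replicates
#'
#' Peaks called at the permissive threshold in each replicate are
#' grouped when their positions on the same chromosome lie within
#' `window` bp of each other (single-linkage closure by default; a
#' strict-clique mode is available for sensitivity analysis).  For each
#' group, the LOD and delta-AF at every member peak position are read
#' from every replicate's track -- without applying a LOD filter per
#' replicate -- and averaged; peak positions and support intervals are
#' averaged over the member peaks.
#'
#' @param peaks a data frame of peaks carrying a `replicate` column, or
#'   a list of per-replicate `qtl_peaks` data frames.
#' @param tracks named list of per-replicate `lod_track` data frames (or
#'   `qtl_scan` objects), names matching the replicate ids; when `NULL`
#'   the merged values are the averages of the member peaks only.
#' @param window maximum peak-to-peak distance within a merged QTL
#'   (default 75,000 bp).
#' @param linkage `"single"` (chain closure, default) or `"clique"`.
#' @return data frame of class `merged_qtl` with columns `gene`,
#'   `channel`, `chrom`, `pos`, `lod`, `delta_af`, `ci_lo`, `ci_hi`,
#'   `n_replicates_detected`, `n_replicates_total`, `n_members`.
#' @export
merge_replicates <- function(peaks, tracks = NULL, window = 75000,
                             linkage = c("single", "clique")) {
  linkage <- match.arg(linkage)
  if (window <= 0) stop_input("window must be > 0")
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- do.call(rbind, peaks)
  }
  check_columns(peaks, c("chrom", "pos", "lod", "replicate"), "peaks")
  if (!"delta_af" %in% names(peaks)) peaks$delta_af <- NA_real_
  if (!"gene" %in% names(peaks)) peaks$gene <- NA_character_
  if (!"channel" %in% names(peaks)) peaks$channel <- NA_character_
  n_total <- if (!is.null(tracks)) {
    length(tracks)
  } else {
    length(unique(peaks$replicate))
  }
  empty <- data.frame(gene = character(), channel = character(),
                      chrom = character(), pos = numeric(), lod = numeric(),
                      delta_af = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), n_replicates_detected = integer(),
                      n_replicates_total = integer(), n_members = integer())
  if (!nrow(peaks)) {
    class(empty) <- c("merged_qtl", "data.frame")
    return(empty)
  }
  rows <- list()
  for (chr in unique(peaks$chrom)) {
    sub <- peaks[peaks$chrom == chr, , drop = FALSE]
    grp <- cluster_positions(sub$pos, window, linkage)
    for (g in unique(grp)) {
      mem <- sub[grp == g, , drop = FALSE]
      if (is.null(tracks)) {
        lod_m <- mean(mem$lod)
        daf_m <- mean(mem$delta_af)
      } else {
        vals <- lapply(mem$pos, function(p) {
          per_rep <- lapply(tracks, track_value_at, chrom = chr, pos = p)
          c(lod = mean(vapply(per_rep, `[[`, numeric(1), "lod")),
            daf = mean(vapply(per_rep, `[[`, numeric(1), "delta_af")))
        })
        lod_m <- mean(vapply(vals, `[`, numeric(1), 1))
        daf_m <- mean(vapply(vals, `[`, numeric(1), 2))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = mem$gene[1], channel = mem$channel[1], chrom = chr,
        pos = mean(mem$pos), lod = lod_m, delta_af = daf_m,
        ci_lo = if ("ci_lo" %in% names(mem)) mean(mem$ci_lo) else NA_real_,
        ci_hi = if ("ci_hi" %in% names(mem)) mean(mem$ci_hi) else NA_real_,
        n_replicates_detected = length(unique(mem$replicate)),
        n_replicates_total = n_total,
        n_members = nrow(mem))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("merged_qtl", "data.frame")
  out
}

#' Retain merged QTLs passing the stringent significance threshold
#'
#' @param merged a `merged_qtl` data frame.
#' @param threshold stringent LOD threshold, inclusive (default 4.5).
#' @return the filtered `merged_qtl`.
#' @export
filter_significant <- function(merged, threshold = 4.5) {
  check_columns(merged, "lod", "merged")
  out <- merged[merged$lod >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(merged)
  out
}

#' Average replicate sharing of merged QTLs
#'
#' The reproducibility statistic
#' `mean[(NshareQTL_ij - 1) / (Nrep_j - 1)]` over significant merged
#' QTLs: a QTL found in every replicate of its gene contributes 1, one
#' found in a single replicate contributes 0 (no overlap among
#' replicates).  Only genes with at least two replicates contribute.
#'
#' @param merged a `merged_qtl` data frame (typically after
#'   [filter_significant()]).
#' @return the statistic in `[0, 1]`, or `NA` (with a warning) when no
#'   QTL is eligible.
#' @export
fraction_overlap <- function(merged) {
  check_columns(merged, c("n_replicates_detected", "n_replicates_total"),
                "merged")
  eligible <- merged$n_replicates_total >= 2
  if (!any(eligible)) {
    warning("no merged QTL from a gene with >= 2 replicates; ",
            "fraction_overlap undefined")
    return(NA_real_)
  }
  with(merged[eligible, ],
       mean((n_replicates_detected - 1) / (n_replicates_total - 1)))
}

#' Empirical FDR curve from inter-replicate null comparisons
#'
#' Pools sorted into the same gate in different replicates of the same
#' gene carry no true signal, so any 'QTL' found when contrasting them
#' is a false positive.  The false discovery rate at threshold `thr` is
#' \deqn{FDR_{thr} = (N_{repQTL,thr} / N_{rep}) / (N_{fluoQTL,thr} / N_{fluo})}
#' the null peak rate per comparison divided by the signal peak rate per
#' high-vs-low comparison.  Raw ratios are reported as computed (values
#' above 1 are possible at sparse thresholds); a monotone non-increasing
#' version (`fdr_monotone`, running minimum over increasing thresholds)
#' is also provided.
#'
#' @param signal_lods numeric vector of peak LOD scores from all
#'   high-vs-low comparisons.
#' @param null_lods numeric vector of peak LOD scores from all
#'   same-gate inter-replicate comparisons (restricted to pairs
#'   sequenced in the same batch).
#' @param n_fluo number of high-vs-low comparisons (the study had 48).
#' @param n_rep number of inter-replicate comparisons (the study had 80).
#' @param thresholds LOD threshold grid.
#' @return object of class `fdr_curve`: data frame with `threshold`,
#'   `n_rep_qtl`, `n_fluo_qtl`, `fdr`, `fdr_monotone`; `fdr` is 0 when
#'   no null peak passes and `NA` (flagged) where no signal peak passes.
#' @export
fdr_curve <- function(signal_lods, null_lods, n_fluo = 48, n_rep = 80,
                      thresholds = seq(2, 10, by = 0.1)) {
  if (n_fluo <= 0 || n_rep <= 0) stop_input("comparison counts must be > 0")
  n_rep_qtl <- vapply(thresholds, function(t) sum(null_lods >= t), 0L)
  n_fluo_qtl <- vapply(thresholds, function(t) sum(signal_lods >= t), 0L)
  fdr <- ifelse(n_rep_qtl == 0, 0,
                ifelse(n_fluo_qtl == 0, NA_real_,
                       (n_rep_qtl / n_rep) / (n_fluo_qtl / n_fluo)))
  if (anyNA(fdr)) {
    warning("FDR undefined at ", sum(is.na(fdr)),
            " threshold(s) with no signal QTLs")
  }
  mono <- fdr
  best <- Inf
  for (i in seq_along(mono)) {
    if (!is.na(mono[i])) best <- min(best, mono[i])
    mono[i] <- if (is.finite(best)) best else NA_real_
  }
  out <- data.frame(threshold = thresholds, n_rep_qtl = n_rep_qtl,
                    n_fluo_qtl = n_fluo_qtl, fdr = fdr,
                    fdr_monotone = mono)
  attr(out, "n_rep") <- n_rep
  attr(out, "n_fluo") <- n_fluo
  class(out) <- c("fdr_curve", "data.frame")
  out
}

#' FDR at a given threshold
#' @param curve an `fdr_curve`.
#' @param threshold LOD threshold (must be on the curve's grid or
#'   between grid points; the nearest grid value is used).
#' @return the (raw) FDR estimate at that threshold.
#' @export
fdr_at <- function(curve, threshold) {
  check_columns(curve, c("threshold", "fdr"), "curve")
  curve$fdr[which.min(abs(curve$threshold - threshold))]
}
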