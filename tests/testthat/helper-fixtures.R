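# Small fixture builders shared across the suite.

tiny_config <- function(n_segregants = 500, seed = 1, n_markers = 40,
                        len = 2e5) {
  cross_config(chrom_lengths = c(chrA = len, chrB = len),
               n_markers = n_markers, n_segregants = n_segregants,
               seed = seed)
}

# Counts object from bare vectors on one chromosome.
counts_1chr <- function(pos, ref, alt, chrom = "chrI", ...) {
  pooled_counts(chrom = rep(chrom, length(pos)), pos = pos,
                ref_count = ref, alt_count = alt, ...)
}

# A LOD track data frame from a vector of per-bin LODs (100-bp bins).
toy_track <- function(lod, chrom = "chrI", delta = NULL, depth = 10) {
  n <- length(lod)
  data.frame(chrom = rep(chrom, n),
             bin_start = (seq_len(n) - 1L) * 100L + 1L,
             bin_end = seq_len(n) * 100L,
             lod = lod,
             delta_af = delta %||% rep(0.1, n),
             depth_high = rep(depth, n), depth_low = rep(depth, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A merged-QTL row for concordance tests.
merged_row <- function(gene, chrom, pos, lod, delta, ci = 25000,
                       det = 2, tot = 2) {
  data.frame(gene = gene, channel = NA_character_, chrom = chrom,
             pos = pos, lod = lod, delta_af = delta,
             ci_lo = pos - ci, ci_hi = pos + ci,
             n_replicates_detected = det, n_replicates_total = tot,
             n_members = det)
}

as_merged <- function(...) {
  out <- rbind(...)
  class(out) <- c("merged_qtl", "data.frame")
  out
}
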