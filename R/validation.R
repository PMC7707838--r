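# Simulation studies that validate the mapping pipeline against its own
# generative model: planted-QTL recovery across seeds and null
# calibration of the LOD threshold.  Used by the test suite and by the
# acceptance script; exported because they are the package's built-in
# operating-characteristic checks.

#' Planted-QTL recovery study
#'
#' Simulates complete experiments (independent segregant populations,
#' tail sorting, pooled sequencing) across seeds, maps each with the
#' full pipeline and scores, per planted locus and channel: detection
#' (a significant merged QTL within `tolerance_bp` of the true position
#' whose delta-AF matches the planted sign) and class recovery
#' (the four-way classification assigns the planted class within the
#' same tolerance).  Peak LODs of the high/low contrasts and of the
#' same-gate inter-replicate null comparisons are collected for
#' false-discovery analysis.
#'
#' @param n_seeds number of independent simulated experiments.
#' @param seed master seed; experiment `i` uses the `i`-th derived seed.
#' @param config a [cross_config()] (desk-scale default).
#' @param model trait model; `NULL` for [default_trait_model()].
#' @param n_replicates biological replicates per experiment.
#' @param tolerance_bp detection tolerance around the true position.
#' @param stringent stringent LOD threshold.
#' @param false_positive_bp significant QTLs farther than this from any
#'   planted locus of their channel count as realized false positives
#'   (wider than `tolerance_bp` because the linked flank of a true QTL
#'   can carry the argmax tens of kb away).
#' @return list with `detection` (per seed x locus x channel),
#'   `classes` (per seed x locus), `signal_lods`, `null_lods`,
#'   `n_signal_comparisons`, `n_null_comparisons`,
#'   `n_false_positives`, `n_significant`, and `truth`.
#' @export
planted_recovery_study <- function(n_seeds = 10, seed = 1,
                                   config = default_cross_config(),
                                   model = NULL, n_replicates = 2,
                                   tolerance_bp = 50000,
                                   stringent = 4.5,
                                   false_positive_bp = 100000) {
  seeds <- derive_seeds(seed, n_seeds)
  detection <- list()
  classes <- list()
  signal_lods <- numeric(0)
  null_lods <- numeric(0)
  n_fp <- 0L
  n_sig <- 0L
  truth <- NULL
  for (s in seq_len(n_seeds)) {
    sim <- simulate_experiment(config = config, model = model,
                               n_replicates = n_replicates,
                               seed = seeds[s])
    truth <- sim$truth
    mp <- run_map(sim$counts, stringent = stringent, fdr = TRUE)
    signal_lods <- c(signal_lods, mp$peaks$lod)
    null_lods <- c(null_lods, mp$null_peaks)
    for (ch in c("mRNA", "protein")) {
      sig <- mp$significant[[1]][[ch]]
      n_sig <- n_sig + nrow(sig)
      eff <- if (ch == "mRNA") truth$effect_mrna else truth$effect_protein
      daf <- if (ch == "mRNA") {
        truth$expected_daf_mrna
      } else {
        truth$expected_daf_protein
      }
      for (i in seq_len(nrow(truth))) {
        near <- sig$chrom == truth$chrom[i] &
          abs(sig$pos - truth$pos[i]) <= tolerance_bp
        detection[[length(detection) + 1L]] <- data.frame(
          seed_index = s, chrom = truth$chrom[i], pos = truth$pos[i],
          channel = ch, class = truth$class[i],
          expected_daf = daf[i],
          detected = any(near),
          sign_ok = any(near & sign(sig$delta_af) == sign(daf[i])))
      }
      # realized false positives: significant QTLs far from every
      # planted locus affecting this channel
      active <- truth[eff != 0, , drop = FALSE]
      if (nrow(sig)) {
        far <- vapply(seq_len(nrow(sig)), function(k) {
          same <- active$chrom == sig$chrom[k]
          !any(same & abs(active$pos - sig$pos[k]) <= false_positive_bp)
        }, logical(1))
        n_fp <- n_fp + sum(far)
      }
    }
    cls <- run_classify(mp, exclusion = NULL)
    loci_pos <- ifelse(is.na(cls$loci$pos_mrna), cls$loci$pos_protein,
                       cls$loci$pos_mrna)
    for (i in seq_len(nrow(truth))) {
      near <- !is.na(cls$loci$class) &
        cls$loci$chrom == truth$chrom[i] &
        abs(loci_pos - truth$pos[i]) <= tolerance_bp
      classes[[length(classes) + 1L]] <- data.frame(
        seed_index = s, chrom = truth$chrom[i], pos = truth$pos[i],
        planted = truth$class[i],
        recovered = any(near & cls$loci$class == truth$class[i]))
    }
  }
  list(detection = do.call(rbind, detection),
       classes = do.call(rbind, classes),
       signal_lods = signal_lods, null_lods = null_lods,
       n_signal_comparisons = n_seeds * n_replicates * 2L,
       n_null_comparisons = n_seeds *
         2L * 2L * choose(n_replicates, 2),
       n_false_positives = n_fp, n_significant = n_sig,
       truth = truth)
}

#' Null calibration of the genome-scan threshold
#'
#' Simulates pairs of unselected pools ([simulate_null_pools()]) across
#' seeds, scans each pair and counts peaks at the stringent threshold.
#' Under a well-calibrated model the expected number of significant
#' peaks per null genome scan is far below one.
#'
#' @param n_seeds number of null scans.
#' @param seed master seed.
#' @param config a [cross_config()].
#' @param pool_size cells per pool (default 10,000, the FACS pool size).
#' @param depth a [depth_model()].
#' @param threshold stringent LOD threshold.
#' @return list with `peaks_per_scan` (integer vector), `max_lod`
#'   (per-scan maximum LOD) and `peak_lods` (all super-threshold peak
#'   LODs).
#' @export
null_calibration_study <- function(n_seeds = 50, seed = 1,
                                   config = default_cross_config(),
                                   pool_size = 10000,
                                   depth = depth_model(),
                                   threshold = 4.5) {
  seeds <- derive_seeds(seed, n_seeds)
  n_peaks <- integer(n_seeds)
  max_lod <- numeric(n_seeds)
  peak_lods <- numeric(0)
  for (s in seq_len(n_seeds)) {
    pools <- simulate_null_pools(config, pool_size = pool_size,
                                 depth = depth, seed = seeds[s])
    sc <- qtl_scan(pools$high, pools$low)
    pk <- call_peaks(sc, threshold = threshold)
    n_peaks[s] <- nrow(pk)
    max_lod[s] <- max(sc$track$lod)
    peak_lods <- c(peak_lods, pk$lod)
  }
  list(peaks_per_scan = n_peaks, max_lod = max_lod,
       peak_lods = peak_lods)
}
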