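# Concordance analysis: pairing mRNA-QTLs with protein-QTLs of the same
# gene, region exclusion, manual curation, four-way locus
# classification and cross-channel effect comparisons.

#' Genomic region (1-based, inclusive)
#' @param chrom chromosome name.
#' @param start,end bounds in bp, `start <= end`.
#' @return object of class `region`.
#' @export
region <- function(chrom, start, end) {
  if (start > end) stop_input("region start must be <= end")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "region")
}

#' Default exclusion region on chromosome XIV
#'
#' The 350-550 kb region of chromosome XIV harbours the highly
#' pleiotropic MKT1 locus and affected the mCherry reporter in every
#' mapped gene (and in a constitutive-mCherry control), so it may act on
#' the reporter itself; QTLs peaking inside it are discarded from the
#' concordance analysis.
#'
#' @return a [region()] spanning chrXIV:350,000-550,000.
#' @export
default_exclusion_region <- function() region("chrXIV", 350000, 550000)

#' Remove merged QTLs peaking inside a region
#'
#' @param merged a `merged_qtl` data frame.
#' @param exclusion a [region()]; bounds inclusive.
#' @return the filtered `merged_qtl`; removals are reported via
#'   `message()` and counted in `attr(, "n_removed")`.
#' @export
exclude_region <- function(merged, exclusion = default_exclusion_region()) {
  check_columns(merged, c("chrom", "pos"), "merged")
  stopifnot(inherits(exclusion, "region"))
  inside <- merged$chrom == exclusion$chrom &
    merged$pos >= exclusion$start & merged$pos <= exclusion$end
  if (any(inside)) {
    message("excluding ", sum(inside), " QTL(s) inside ", exclusion$chrom,
            ":", exclusion$start, "-", exclusion$end)
  }
  out <- merged[!inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(inside)
  class(out) <- class(merged)
  out
}

#' Packaged manual curation overrides
#'
#' Six cases in which the automatic confidence-interval overlap analysis
#' was manually corrected in the study: QTL pairs on chrXV (ARO8),
#' chrVIII (MTD1), chrXIII (CYC1) and chrXIII (RPS10A); mRNA-specific
#' calls on chrV (GPD1) and chrXIV (MTD1).
#'
#' @return data frame with columns `gene`, `chrom`, `status`
#'   (`"pair"`, `"mRNA-specific"` or `"protein-specific"`).
#' @export
curation_overrides <- function() {
  data.frame(
    gene = c("ARO8", "MTD1", "CYC1", "RPS10A", "GPD1", "MTD1"),
    chrom = c("chrXV", "chrVIII", "chrXIII", "chrXIII", "chrV", "chrXIV"),
    status = c("pair", "pair", "pair", "pair",
               "mRNA-specific", "mRNA-specific"))
}

ci_overlaps <- function(lo1, hi1, lo2, hi2) lo1 <= hi2 & lo2 <= hi1

#' Pair mRNA-QTLs with protein-QTLs of the same gene
#'
#' Merged QTLs of the two channels (called at the permissive threshold)
#' are paired per gene when their confidence intervals overlap.  When a
#' QTL's interval overlaps several partners, the highest-LOD partner is
#' chosen (configurable to the closest peak) and the others stay
#' single.  Curation overrides are applied last: `"pair"` forces the
#' gene's two QTLs on the named chromosome into a pair,
#' `"mRNA-specific"` / `"protein-specific"` breaks any automatic pair
#' on that chromosome into singletons.  Unpaired QTLs become
#' single-member loci.
#'
#' @param mrna,protein `merged_qtl` data frames for the two channels
#'   (may cover several genes; pairing is within gene).
#' @param overrides optional data frame as returned by
#'   [curation_overrides()].
#' @param tie_break `"lod"` (default) or `"distance"`.
#' @return data frame of class `qtl_pairs`, one row per locus, with the
#'   two members' positions, LODs, delta-AFs and intervals (`NA` for
#'   absent members) and a `basis` column (`ci_overlap`, `curation`,
#'   `single`).
#' @export
pair_qtls <- function(mrna, protein, overrides = NULL,
                      tie_break = c("lod", "distance")) {
  tie_break <- match.arg(tie_break)
  need <- c("gene", "chrom", "pos", "lod", "delta_af", "ci_lo", "ci_hi")
  check_columns(mrna, need, "mrna")
  check_columns(protein, need, "protein")
  mrna$.id <- seq_len(nrow(mrna))
  protein$.id <- seq_len(nrow(protein))
  pair_m <- rep(NA_integer_, nrow(mrna))
  basis_m <- rep(NA_character_, nrow(mrna))
  # candidate pairs: same gene + chromosome, overlapping CIs
  cand <- NULL
  for (i in seq_len(nrow(mrna))) {
    j <- which(protein$gene == mrna$gene[i] &
                 protein$chrom == mrna$chrom[i] &
                 ci_overlaps(mrna$ci_lo[i], mrna$ci_hi[i],
                             protein$ci_lo, protein$ci_hi))
    if (length(j)) {
      cand <- rbind(cand, data.frame(
        m = i, p = j,
        score = if (tie_break == "lod") {
          mrna$lod[i] + protein$lod[j]
        } else {
          -abs(mrna$pos[i] - protein$pos[j])
        }))
    }
  }
  if (!is.null(cand)) {
    cand <- cand[order(-cand$score, cand$m, cand$p), , drop = FALSE]
    taken_p <- logical(nrow(protein))
    for (k in seq_len(nrow(cand))) {
      i <- cand$m[k]; j <- cand$p[k]
      if (is.na(pair_m[i]) && !taken_p[j]) {
        pair_m[i] <- j
        basis_m[i] <- "ci_overlap"
        taken_p[j] <- TRUE
      }
    }
  }
  # curation overrides
  if (!is.null(overrides) && nrow(overrides)) {
    check_columns(overrides, c("gene", "chrom", "status"), "overrides")
    for (k in seq_len(nrow(overrides))) {
      ov <- overrides[k, ]
      mi <- which(mrna$gene == ov$gene & mrna$chrom == ov$chrom)
      pj <- which(protein$gene == ov$gene & protein$chrom == ov$chrom)
      if (!length(mi) && !length(pj)) {
        stop_input("curation override references no locus: ", ov$gene,
                   " on ", ov$chrom)
      }
      if (ov$status == "pair") {
        if (length(mi) && length(pj)) {
          mi <- mi[which.max(mrna$lod[mi])]
          pj <- pj[which.max(protein$lod[pj])]
          conflict <- which(!is.na(pair_m) & pair_m == pj)
          pair_m[setdiff(conflict, mi)] <- NA
          pair_m[mi] <- pj
          basis_m[mi] <- "curation"
        }
      } else {
        # force specificity: break any automatic pair on this locus
        pair_m[mi] <- NA
        basis_m[mi] <- "curation"
      }
    }
  }
  paired_p <- stats::na.omit(pair_m)
  rows <- list()
  add_row <- function(m_row, p_row, basis) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = if (!is.null(m_row)) m_row$gene else p_row$gene,
      chrom = if (!is.null(m_row)) m_row$chrom else p_row$chrom,
      pos_mrna = if (!is.null(m_row)) m_row$pos else NA_real_,
      lod_mrna = if (!is.null(m_row)) m_row$lod else NA_real_,
      delta_af_mrna = if (!is.null(m_row)) m_row$delta_af else NA_real_,
      ci_lo_mrna = if (!is.null(m_row)) m_row$ci_lo else NA_real_,
      ci_hi_mrna = if (!is.null(m_row)) m_row$ci_hi else NA_real_,
      pos_protein = if (!is.null(p_row)) p_row$pos else NA_real_,
      lod_protein = if (!is.null(p_row)) p_row$lod else NA_real_,
      delta_af_protein = if (!is.null(p_row)) p_row$delta_af else NA_real_,
      ci_lo_protein = if (!is.null(p_row)) p_row$ci_lo else NA_real_,
      ci_hi_protein = if (!is.null(p_row)) p_row$ci_hi else NA_real_,
      basis = basis)
  }
  for (i in seq_len(nrow(mrna))) {
    if (!is.na(pair_m[i])) {
      add_row(mrna[i, ], protein[pair_m[i], ], basis_m[i])
    } else {
      add_row(mrna[i, ], NULL,
              if (identical(basis_m[i], "curation")) "curation" else "single")
    }
  }
  for (j in setdiff(seq_len(nrow(protein)), paired_p)) {
    add_row(NULL, protein[j, ], "single")
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(gene = character(), chrom = character(),
               pos_mrna = numeric(), lod_mrna = numeric(),
               delta_af_mrna = numeric(), ci_lo_mrna = numeric(),
               ci_hi_mrna = numeric(), pos_protein = numeric(),
               lod_protein = numeric(), delta_af_protein = numeric(),
               ci_lo_protein = numeric(), ci_hi_protein = numeric(),
               basis = character())
  }
  rownames(out) <- NULL
  class(out) <- c("qtl_pairs", "data.frame")
  out
}

#' Classify loci into the four QTL classes
#'
#' Loci where neither member reaches the stringent threshold are
#' dropped; applying the stringent threshold only after the permissive
#' pairing keeps pairs in which one member narrowly misses genome-wide
#' significance.  Remaining loci are classified: both members with the
#' same delta-AF sign are `concordant`, with opposite signs
#' `discordant`; single-member loci are `mRNA-specific` or
#' `protein-specific`.
#'
#' @param pairs a `qtl_pairs` data frame from [pair_qtls()].
#' @param stringent stringent LOD threshold (default 4.5), inclusive.
#' @return data frame of class `classified_loci`: the retained rows of
#'   `pairs` plus a `class` column.  A both-member locus whose delta-AF
#'   is exactly zero in either channel gets class `NA` and a warning
#'   (flagged for review, never silently assigned).
#' @export
classify_loci <- function(pairs, stringent = 4.5) {
  check_columns(pairs, c("lod_mrna", "lod_protein", "delta_af_mrna",
                         "delta_af_protein"), "pairs")
  best <- pmax(ifelse(is.na(pairs$lod_mrna), -Inf, pairs$lod_mrna),
               ifelse(is.na(pairs$lod_protein), -Inf, pairs$lod_protein))
  out <- pairs[best >= stringent, , drop = FALSE]
  has_m <- !is.na(out$pos_mrna)
  has_p <- !is.na(out$pos_protein)
  cls <- rep(NA_character_, nrow(out))
  both <- has_m & has_p
  zero <- both & (out$delta_af_mrna == 0 | out$delta_af_protein == 0)
  if (any(zero)) {
    warning(sum(zero), " locus/loci with a zero delta-AF left unclassified")
  }
  same <- both & !zero &
    sign(out$delta_af_mrna) == sign(out$delta_af_protein)
  cls[same] <- "concordant"
  cls[both & !zero & !same] <- "discordant"
  cls[has_m & !has_p] <- "mRNA-specific"
  cls[!has_m & has_p] <- "protein-specific"
  out$class <- cls
  rownames(out) <- NULL
  class(out) <- c("classified_loci", "data.frame")
  out
}

#' Extract the other channel's effect at each locus peak
#'
#' For single-member loci, the delta-AF of the missing channel is read
#' from that channel's replicate tracks at the significant member's
#' peak position -- irrespective of significance in the other data --
#' and averaged across replicates.  Both-member loci keep each member's
#' own value at its own peak.
#'
#' @param loci a `classified_loci` data frame.
#' @param mrna_tracks,protein_tracks lists of per-replicate `lod_track`
#'   data frames (or `qtl_scan` objects) for the two channels; for
#'   multi-gene inputs, named lists of such lists keyed by gene.
#' @return `loci` with `delta_af_mrna` / `delta_af_protein` filled and a
#'   logical `extracted_mrna` / `extracted_protein` marking extracted
#'   (as opposed to member-own) values.
#' @export
effect_at_peak <- function(loci, mrna_tracks, protein_tracks) {
  check_columns(loci, c("gene", "chrom", "pos_mrna", "pos_protein"),
                "loci")
  by_gene <- function(tracks, gene) {
    if (length(tracks) && is.list(tracks) &&
        !is.null(names(tracks)) && gene %in% names(tracks) &&
        !is.data.frame(tracks[[gene]]) &&
        !inherits(tracks[[gene]], "qtl_scan")) {
      return(tracks[[gene]])
    }
    if (!is.null(names(tracks)) && gene %in% names(tracks)) {
      return(tracks[gene])
    }
    tracks
  }
  loci$extracted_mrna <- FALSE
  loci$extracted_protein <- FALSE
  for (i in seq_len(nrow(loci))) {
    if (is.na(loci$pos_mrna[i])) {
      trs <- by_gene(mrna_tracks, loci$gene[i])
      vals <- vapply(trs, function(tr)
        track_value_at(tr, loci$chrom[i], loci$pos_protein[i])$delta_af,
        numeric(1))
      loci$delta_af_mrna[i] <- mean(vals)
      loci$extracted_mrna[i] <- TRUE
    }
    if (is.na(loci$pos_protein[i])) {
      trs <- by_gene(protein_tracks, loci$gene[i])
      vals <- vapply(trs, function(tr)
        track_value_at(tr, loci$chrom[i], loci$pos_mrna[i])$delta_af,
        numeric(1))
      loci$delta_af_protein[i] <- mean(vals)
      loci$extracted_protein[i] <- TRUE
    }
  }
  loci
}

#' Direction agreement between mRNA and protein effects
#'
#' Proportion of loci whose mRNA and protein delta-AF (own or extracted)
#' share the same sign, with an exact binomial test against the 50%
#' expected by chance.  The denominator (loci with two non-zero,
#' non-missing effects) is reported explicitly.
#'
#' @param loci a `classified_loci` data frame with both delta-AF columns
#'   populated (see [effect_at_peak()]).
#' @param alternative passed to [stats::binom.test()] (default
#'   two-sided).
#' @return list with `proportion`, `p_value`, `n_same`, `n` (the
#'   denominator); all `NA` (with a warning) when no locus is eligible.
#' @export
direction_agreement <- function(loci, alternative = "two.sided") {
  check_columns(loci, c("delta_af_mrna", "delta_af_protein"), "loci")
  ok <- !is.na(loci$delta_af_mrna) & !is.na(loci$delta_af_protein) &
    loci$delta_af_mrna != 0 & loci$delta_af_protein != 0
  n <- sum(ok)
  if (n == 0) {
    warning("no locus with both effects available")
    return(list(proportion = NA_real_, p_value = NA_real_,
                n_same = NA_integer_, n = 0L))
  }
  same <- sign(loci$delta_af_mrna[ok]) == sign(loci$delta_af_protein[ok])
  test <- stats::binom.test(sum(same), n, p = 0.5,
                            alternative = alternative)
  list(proportion = sum(same) / n, p_value = test$p.value,
       n_same = sum(same), n = n)
}

#' Effect-size correlations overall and per class
#'
#' Pearson correlation of (delta-AF mRNA, delta-AF protein) over all
#' classified loci and within each class (where at least three loci
#' carry both effects).
#'
#' @param loci a `classified_loci` data frame with both effects
#'   populated.
#' @return data frame with columns `group`, `n`, `r`, `p_value`.
#' @export
effect_correlations <- function(loci) {
  check_columns(loci, c("class", "delta_af_mrna", "delta_af_protein"),
                "loci")
  groups <- c(list(all = seq_len(nrow(loci))),
              split(seq_len(nrow(loci)), loci$class))
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    x <- loci$delta_af_mrna[i]
    y <- loci$delta_af_protein[i]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      return(data.frame(group = g, n = sum(ok), r = NA_real_,
                        p_value = NA_real_))
    }
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(group = g, n = sum(ok), r = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, rows)
}
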