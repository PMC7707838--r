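# End-to-end orchestration: simulate a dataset to disk, map QTLs for
# every gene/channel from a manifest of pools, and classify loci across
# the two channels -- each step a plain function wrapped by the thin
# command-line script shipped in inst/cli.

#' Simulate a dataset and write it to disk
#'
#' Runs [simulate_experiment()] and writes, under `out_dir`: per-pool
#' allele counts as both TSV and VCF, the planted-truth table, the run
#' manifest, the generating configuration (YAML) and a machine-readable
#' provenance record.  Outputs are byte-identical across runs with the
#' same seed.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [cross_config()].
#' @param model a [trait_model()] or `NULL` for [default_trait_model()].
#' @param sort,depth sorting and sequencing models.
#' @param n_replicates biological replicates per gene.
#' @param gene gene label.
#' @param seed master seed.
#' @return the manifest data frame (with file paths), invisibly.
#' @export
run_simulate <- function(out_dir, config = default_cross_config(),
                         model = NULL, sort = sort_config(),
                         depth = depth_model(), n_replicates = 2,
                         gene = "GENE1", seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config = config, model = model, sort = sort,
                             depth = depth, n_replicates = n_replicates,
                             gene = gene, seed = seed)
  files <- character(length(sim$counts))
  for (i in seq_along(sim$counts)) {
    md <- pool_metadata(sim$counts[[i]])
    stem <- paste(md$gene,
                  if (is.na(md$channel)) "none" else md$channel,
                  md$gate, paste0("rep", md$replicate), sep = "_")
    files[i] <- file.path(out_dir, paste0(stem, ".tsv"))
    write_counts(sim$counts[[i]], files[i], "tsv")
    write_counts(sim$counts[[i]], file.path(out_dir, paste0(stem, ".vcf")),
                 "vcf", sample = stem)
  }
  manifest <- cbind(file = files, sim$manifest)
  # manifest on disk holds paths relative to its own directory so the
  # dataset is relocatable (and byte-identical across runs)
  write_manifest(cbind(file = basename(files), sim$manifest),
                 file.path(out_dir, "manifest.tsv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    chrom_lengths = as.list(config$chrom_lengths),
    n_markers = sum(lengths(config$marker_positions)),
    n_segregants = config$n_segregants,
    bp_per_cM = config$bp_per_cM,
    tail_fraction = sort$tail_fraction,
    pool_size = sort$pool_size,
    fsc_gate = sort$fsc_gate,
    mean_depth = depth$mean_depth,
    error_rate = depth$error_rate,
    kappa = sim$model$kappa, sigma_r = sim$model$sigma_r,
    sigma_g = sim$model$sigma_g, gamma = sim$model$gamma,
    n_replicates = n_replicates, gene = gene, seed = seed),
    file.path(out_dir, "config.yaml"))
  yaml::write_yaml(list(
    package = "xqtl",
    version = as.character(utils::packageVersion("xqtl")),
    command = "simulate",
    seed = seed,
    outputs = basename(files)),
    file.path(out_dir, "provenance.yaml"))
  invisible(manifest)
}

# Normalize run_map input to a list of pooled_counts with metadata.
collect_pools <- function(x, markers = NULL) {
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, TRUE, "pooled_counts"))) {
    return(x)
  }
  check_columns(x, c("file", "gene", "channel", "gate", "replicate",
                     "batch"), "manifest")
  missing <- x$file[!file.exists(x$file)]
  if (length(missing)) {
    stop_input("missing pool file(s): ", paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(x)), function(i) {
    read_counts(x$file[i], markers = markers, gene = x$gene[i],
                channel = x$channel[i], gate = x$gate[i],
                replicate = x$replicate[i], batch = x$batch[i])
  })
}

#' Map QTLs for every gene and channel of a pool collection
#'
#' For each gene, channel and replicate the matched high/low pools are
#' contrasted with [qtl_scan()]; peaks are called at the permissive
#' threshold, merged across replicates within the 75 kb window, and
#' filtered at the stringent threshold.  Optionally, same-gate pools of
#' different replicates (within a sequencing batch) are contrasted to
#' build the inter-replicate null and the empirical FDR curve.
#'
#' @param pools a manifest data frame (with a `file` column, read via
#'   [read_counts()]) or a list of in-memory `pooled_counts` (e.g.
#'   `simulate_experiment()$counts`).
#' @param markers optional `marker_list` for reading files.
#' @param params a [lod_params()].
#' @param permissive,stringent detection thresholds (defaults 3.0, 4.5).
#' @param merge_window replicate merge window in bp (default 75,000).
#' @param af_bounds,smooth_bandwidth passed to [qtl_scan()].
#' @param fdr if `TRUE` (default) compute the inter-replicate null and
#'   the [fdr_curve()].
#' @param verbose narrate each stage's input/output counts.
#' @return an object of class `xqtl_map`: list with `scans` (nested
#'   gene / channel / replicate), `peaks` (permissive, all scans),
#'   `merged`, `significant`, `fdr` (or `NULL`), `null_peaks`, and the
#'   thresholds used.
#' @export
run_map <- function(pools, markers = NULL, params = lod_params(),
                    permissive = 3, stringent = 4.5,
                    merge_window = 75000, af_bounds = c(0.1, 0.9),
                    smooth_bandwidth = 20000, fdr = TRUE,
                    verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  counts <- collect_pools(pools, markers)
  meta <- do.call(rbind, lapply(counts, function(pc) {
    md <- pool_metadata(pc)
    data.frame(gene = md$gene, channel = md$channel, gate = md$gate,
               replicate = md$replicate, batch = md$batch)
  }))
  scans <- list()
  peak_list <- list()
  genes <- unique(stats::na.omit(meta$gene))
  for (gene in genes) {
    for (channel in unique(stats::na.omit(meta$channel[meta$gene == gene]))) {
      reps <- sort(unique(meta$replicate[meta$gene == gene &
                                           meta$channel == channel]))
      for (rep_i in reps) {
        hi <- which(meta$gene == gene & meta$channel == channel &
                      meta$replicate == rep_i & meta$gate == "high")
        lo <- which(meta$gene == gene & meta$channel == channel &
                      meta$replicate == rep_i & meta$gate == "low")
        if (length(hi) != 1 || length(lo) != 1) {
          stop_input("gene ", gene, " channel ", channel, " replicate ",
                     rep_i, " lacks a matched high/low pool pair")
        }
        sc <- qtl_scan(counts[[hi]], counts[[lo]], params = params,
                       af_bounds = af_bounds,
                       smooth_bandwidth = smooth_bandwidth)
        scans[[gene]][[channel]][[as.character(rep_i)]] <- sc
        pk <- call_peaks(sc, threshold = permissive)
        say(gene, "/", channel, "/rep", rep_i, ": ", sc$n_markers,
            " markers (", sc$n_filtered, " filtered), ", nrow(pk),
            " peak(s) at LOD>=", permissive)
        peak_list[[length(peak_list) + 1L]] <- pk
      }
    }
  }
  peaks <- do.call(rbind, peak_list)
  merged <- list()
  significant <- list()
  for (gene in names(scans)) {
    for (channel in names(scans[[gene]])) {
      sub <- peaks[!is.na(peaks$gene) & peaks$gene == gene &
                     peaks$channel == channel, , drop = FALSE]
      mg <- merge_replicates(sub, tracks = scans[[gene]][[channel]],
                             window = merge_window)
      mg$gene <- if (nrow(mg)) gene else character(0)
      mg$channel <- if (nrow(mg)) channel else character(0)
      merged[[gene]][[channel]] <- mg
      significant[[gene]][[channel]] <- filter_significant(mg, stringent)
      say(gene, "/", channel, ": ", nrow(mg), " merged QTL(s), ",
          nrow(significant[[gene]][[channel]]), " at LOD>=", stringent)
    }
  }
  fdr_out <- NULL
  null_peaks <- NULL
  if (fdr) {
    null_lods <- numeric(0)
    n_rep_comp <- 0L
    for (gene in genes) {
      for (channel in unique(stats::na.omit(
        meta$channel[meta$gene == gene]))) {
        for (gate in c("high", "low")) {
          idx <- which(meta$gene == gene & meta$channel == channel &
                         meta$gate == gate)
          if (length(idx) < 2) next
          for (a in seq_len(length(idx) - 1)) {
            for (b in seq.int(a + 1, length(idx))) {
              if (!identical(meta$batch[idx[a]], meta$batch[idx[b]])) next
              n_rep_comp <- n_rep_comp + 1L
              sc <- qtl_scan(counts[[idx[a]]], counts[[idx[b]]],
                             params = params, af_bounds = af_bounds,
                             smooth_bandwidth = smooth_bandwidth)
              null_lods <- c(null_lods,
                             call_peaks(sc, threshold = permissive)$lod)
            }
          }
        }
      }
    }
    n_fluo_comp <- length(peak_list)
    if (n_rep_comp > 0 && n_fluo_comp > 0) {
      fdr_out <- fdr_curve(signal_lods = peaks$lod, null_lods = null_lods,
                           n_fluo = n_fluo_comp, n_rep = n_rep_comp)
      say("FDR: ", n_rep_comp, " null comparison(s), ",
          length(null_lods), " null peak(s)")
    }
    null_peaks <- null_lods
  }
  structure(list(scans = scans, peaks = peaks, merged = merged,
                 significant = significant, fdr = fdr_out,
                 null_peaks = null_peaks, permissive = permissive,
                 stringent = stringent, merge_window = merge_window,
                 params = params),
            class = "xqtl_map")
}

#' @export
print.xqtl_map <- function(x, ...) {
  n_sig <- sum(vapply(unlist(x$significant, recursive = FALSE), nrow, 1L))
  cat("xqtl mapping result:", length(x$scans), "gene(s);",
      nrow(x$peaks), "replicate-level peak(s) at LOD >=", x$permissive,
      ";", n_sig, "significant merged QTL(s) at LOD >=", x$stringent, "\n")
  if (!is.null(x$fdr)) {
    cat("  estimated FDR at", x$stringent, ":",
        round(fdr_at(x$fdr, x$stringent), 3), "\n")
  }
  invisible(x)
}

flatten_merged <- function(mapres, channel, which = c("merged",
                                                      "significant")) {
  which <- match.arg(which)
  lst <- lapply(names(mapres[[which]]), function(g)
    mapres[[which]][[g]][[channel]])
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) {
    out <- merge_replicates(data.frame(chrom = character(),
                                       pos = numeric(), lod = numeric(),
                                       replicate = integer()))
    return(out)
  }
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  class(out) <- c("merged_qtl", "data.frame")
  out
}

#' Classify loci across the mRNA and protein channels
#'
#' Applies the exclusion region to the permissive merged QTL lists of
#' both channels, pairs them by confidence-interval overlap (with
#' optional curation overrides), classifies the loci at the stringent
#' threshold, extracts the other channel's effect at each specific
#' locus, and assembles the summary statistics: class counts, per-gene
#' medians of significant QTLs, the replicate-sharing statistic and the
#' direction agreement (with explicit denominator).
#'
#' @param mapres an `xqtl_map` from [run_map()].
#' @param overrides optional curation override table
#'   ([curation_overrides()] ships the study's six cases); `NULL` for
#'   simulated data.
#' @param exclusion a [region()] or `NULL` to disable; defaults to the
#'   chrXIV reporter-artifact region.
#' @param mrna_channel,protein_channel channel labels used in the pool
#'   metadata (defaults `"mRNA"` and `"protein"`; the study's raw
#'   labels were mCherry and GFP).
#' @return an object of class `xqtl_classification`: list with `loci`
#'   (a `classified_loci` data frame) and `summary`.
#' @export
run_classify <- function(mapres, overrides = NULL,
                         exclusion = default_exclusion_region(),
                         mrna_channel = "mRNA",
                         protein_channel = "protein") {
  stopifnot(inherits(mapres, "xqtl_map"))
  mrna <- flatten_merged(mapres, mrna_channel)
  protein <- flatten_merged(mapres, protein_channel)
  if (!is.null(exclusion)) {
    mrna <- exclude_region(mrna, exclusion)
    protein <- exclude_region(protein, exclusion)
  }
  pairs <- pair_qtls(mrna, protein, overrides = overrides)
  loci <- classify_loci(pairs, stringent = mapres$stringent)
  tracks_of <- function(channel) {
    lapply(mapres$scans, function(g) lapply(g[[channel]], `[[`, "track"))
  }
  if (nrow(loci)) {
    loci <- effect_at_peak(loci, tracks_of(mrna_channel),
                           tracks_of(protein_channel))
  }
  sig_m <- flatten_merged(mapres, mrna_channel, "significant")
  sig_p <- flatten_merged(mapres, protein_channel, "significant")
  if (!is.null(exclusion)) {
    sig_m <- exclude_region(sig_m, exclusion)
    sig_p <- exclude_region(sig_p, exclusion)
  }
  class_levels <- c("concordant", "discordant", "mRNA-specific",
                    "protein-specific")
  counts <- table(factor(loci$class, levels = class_levels))
  per_gene_median <- function(sig) {
    if (!nrow(sig)) return(NA_real_)
    stats::median(as.numeric(table(sig$gene)))
  }
  agreement <- if (nrow(loci)) {
    direction_agreement(loci)
  } else {
    list(proportion = NA_real_, p_value = NA_real_, n_same = NA_integer_,
         n = 0L)
  }
  fo <- function(sig) {
    if (!nrow(sig) || !any(sig$n_replicates_total >= 2)) return(NA_real_)
    fraction_overlap(sig)
  }
  summary <- list(
    n_loci = nrow(loci),
    class_counts = counts,
    n_mrna_qtl = nrow(sig_m),
    n_protein_qtl = nrow(sig_p),
    median_mrna_qtl_per_gene = per_gene_median(sig_m),
    median_protein_qtl_per_gene = per_gene_median(sig_p),
    fraction_overlap_mrna = fo(sig_m),
    fraction_overlap_protein = fo(sig_p),
    direction_agreement = agreement)
  structure(list(loci = loci, summary = summary),
            class = "xqtl_classification")
}

#' @export
print.xqtl_classification <- function(x, ...) {
  s <- x$summary
  cat("Classified loci:", s$n_loci, "\n")
  print(s$class_counts)
  cat("significant QTLs: mRNA", s$n_mrna_qtl, "(median/gene",
      s$median_mrna_qtl_per_gene, "), protein", s$n_protein_qtl,
      "(median/gene", s$median_protein_qtl_per_gene, ")\n")
  cat("fraction_overlap: mRNA", round(s$fraction_overlap_mrna, 3),
      ", protein", round(s$fraction_overlap_protein, 3), "\n")
  da <- s$direction_agreement
  if (!is.na(da$proportion)) {
    cat("direction agreement:", round(100 * da$proportion), "% (",
        da$n_same, "of", da$n, "loci, binomial p =",
        signif(da$p_value, 3), ")\n")
  }
  invisible(x)
}

#' Recompute the published QTL totals from a per-replicate QTL table
#'
#' Runs the replicate-integration and classification pipeline on an
#' already-called per-replicate QTL table (such as the study's
#' supplementary per-replicate QTL list): 75 kb single-linkage
#' replicate merging, the stringent LOD filter, the chrXIV exclusion,
#' confidence-interval pairing with the packaged curation overrides and
#' the four-way classification.  Because only peak-level data are
#' available, merged values are averages over member peaks (no track
#' rescan).
#'
#' @param qtl_table data frame or TSV path with columns `gene`,
#'   `channel`, `replicate`, `chrom`, `pos`, `lod`, `delta_af`,
#'   `ci_lo`, `ci_hi`; `channel` must use `mRNA` / `protein` labels.
#' @param n_replicates data frame with columns `gene`, `n` giving the
#'   number of replicates performed per gene (defaults to the number of
#'   distinct replicate ids per gene in the table).
#' @param overrides curation overrides (default [curation_overrides()]).
#' @param exclusion exclusion [region()] (default chrXIV:350-550 kb).
#' @param merge_window,stringent pipeline constants.
#' @return list with `significant` per channel, `loci`, and `totals`
#'   (QTL counts, class counts, per-gene medians, fraction_overlap and
#'   the fraction of QTLs detected in all replicates).
#' @export
reproduce_published <- function(qtl_table,
                                n_replicates = NULL,
                                overrides = curation_overrides(),
                                exclusion = default_exclusion_region(),
                                merge_window = 75000, stringent = 4.5) {
  if (is.character(qtl_table)) {
    qtl_table <- utils::read.table(qtl_table, header = TRUE, sep = "\t")
  }
  check_columns(qtl_table, c("gene", "channel", "replicate", "chrom",
                             "pos", "lod", "delta_af", "ci_lo", "ci_hi"),
                "qtl_table")
  merged <- list(mRNA = NULL, protein = NULL)
  for (channel in names(merged)) {
    per_gene <- list()
    for (gene in unique(qtl_table$gene)) {
      sub <- qtl_table[qtl_table$gene == gene &
                         qtl_table$channel == channel, , drop = FALSE]
      if (!nrow(sub)) next
      mg <- merge_replicates(sub, tracks = NULL, window = merge_window)
      n_tot <- if (!is.null(n_replicates)) {
        n_replicates$n[match(gene, n_replicates$gene)]
      } else {
        length(unique(sub$replicate))
      }
      mg$n_replicates_total <- n_tot
      per_gene[[gene]] <- mg
    }
    out <- do.call(rbind, per_gene)
    rownames(out) <- NULL
    class(out) <- c("merged_qtl", "data.frame")
    merged[[channel]] <- out
  }
  sig <- lapply(merged, filter_significant, threshold = stringent)
  sig_excl <- lapply(sig, exclude_region, exclusion = exclusion)
  merged_excl <- lapply(merged, exclude_region, exclusion = exclusion)
  pairs <- pair_qtls(merged_excl$mRNA, merged_excl$protein,
                     overrides = overrides)
  loci <- classify_loci(pairs, stringent = stringent)
  class_levels <- c("concordant", "discordant", "mRNA-specific",
                    "protein-specific")
  all_sig <- rbind(sig_excl$mRNA, sig_excl$protein)
  totals <- list(
    n_protein_qtl = nrow(sig_excl$protein),
    n_mrna_qtl = nrow(sig_excl$mRNA),
    n_loci = nrow(loci),
    class_counts = table(factor(loci$class, levels = class_levels)),
    median_protein_qtl_per_gene = stats::median(
      as.numeric(table(sig_excl$protein$gene))),
    median_mrna_qtl_per_gene = stats::median(
      as.numeric(table(sig_excl$mRNA$gene))),
    fraction_overlap_protein = fraction_overlap(sig$protein),
    fraction_overlap_mrna = fraction_overlap(sig$mRNA),
    fraction_all_replicates = mean(
      all_sig$n_replicates_detected == all_sig$n_replicates_total))
  list(significant = sig_excl, loci = loci, totals = totals)
}
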