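# Readers and writers: marker lists, per-pool allele counts (TSV and
# VCF with allelic depths), BED regions, run manifests -- plus the
# novel-variant screen over population variant matrices.
#
# Coordinates are 1-based inclusive throughout (VCF convention); BED
# input/output is converted on the fly.  The reference allele is the BY
# allele everywhere.

#' Construct / validate a marker list
#'
#' @param chrom,pos marker coordinates (1-based); must be unique and
#'   sorted within chromosome.
#' @param ref,alt reference (BY) and alternate (RM) alleles.
#' @return data frame of class `marker_list`.
#' @export
marker_list <- function(chrom, pos, ref = "A", alt = "C") {
  out <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    ref = as.character(ref), alt = as.character(alt))
  if (anyDuplicated(chrom_key(out$chrom, out$pos))) {
    stop_input("duplicate (chrom, pos) in marker list")
  }
  for (chr in unique(out$chrom)) {
    if (is.unsorted(out$pos[out$chrom == chr])) {
      stop_input("marker list not sorted on ", chr)
    }
  }
  class(out) <- c("marker_list", "data.frame")
  out
}

#' Read / write a marker list (TSV: chrom, pos, ref, alt)
#' @param path file path.
#' @return a `marker_list`.
#' @export
read_marker_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric",
                                         "character", "character"))
  check_columns(df, c("chrom", "pos", "ref", "alt"), "marker list")
  marker_list(df$chrom, df$pos, df$ref, df$alt)
}

#' @rdname read_marker_list
#' @param markers a `marker_list`.
#' @export
write_marker_list <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-pool allele counts, aligned to a marker list
#'
#' Supports the flat TSV dialect (`chrom`, `pos`, `ref_count`,
#' `alt_count`) and VCF with a per-sample AD (allelic depth) field.
#' Counts are returned in marker-list order; markers absent from the
#' file get zero depth, file positions absent from the list are dropped
#' with a warning, and allele mismatches against the list are dropped
#' with a warning.  Pools whose median marker depth is below
#' `min_median_depth` are rejected.
#'
#' @param path file path.
#' @param markers a `marker_list` to align against (optional; without it
#'   the file's own positions define the order).
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param min_median_depth reject pools below this median depth
#'   (default 2; set to 0 to disable).
#' @param ... metadata passed to [pooled_counts()].
#' @return a `pooled_counts` data frame; the number of dropped records
#'   is in `attr(, "n_dropped")`.
#' @export
read_counts <- function(path, markers = NULL,
                        format = c("auto", "tsv", "vcf"),
                        min_median_depth = 2, ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "tsv"
    }
  }
  raw <- if (format == "tsv") read_counts_tsv(path) else read_counts_vcf(path)
  n_dropped <- 0L
  if (!is.null(markers)) {
    key_m <- chrom_key(markers$chrom, markers$pos)
    key_f <- chrom_key(raw$chrom, raw$pos)
    extra <- !(key_f %in% key_m)
    if (any(extra)) {
      warning(sum(extra), " record(s) not in the marker list; dropped")
      n_dropped <- n_dropped + sum(extra)
      raw <- raw[!extra, , drop = FALSE]
      key_f <- key_f[!extra]
    }
    if (all(c("ref", "alt") %in% names(raw))) {
      mi <- match(key_f, key_m)
      mismatch <- raw$ref != markers$ref[mi] | raw$alt != markers$alt[mi]
      if (any(mismatch)) {
        warning(sum(mismatch), " record(s) with alleles differing from ",
                "the marker list; dropped")
        n_dropped <- n_dropped + sum(mismatch)
        raw <- raw[!mismatch, , drop = FALSE]
        key_f <- key_f[!mismatch]
      }
    }
    ref_count <- alt_count <- integer(nrow(markers))
    mi <- match(key_f, key_m)
    ref_count[mi] <- raw$ref_count
    alt_count[mi] <- raw$alt_count
    out <- pooled_counts(markers$chrom, markers$pos, ref_count, alt_count,
                         ...)
  } else {
    out <- pooled_counts(raw$chrom, raw$pos, raw$ref_count, raw$alt_count,
                         ...)
  }
  md <- stats::median(out$ref_count + out$alt_count)
  if (md < min_median_depth) {
    stop_input("pool median depth ", md, " below required ",
               min_median_depth, " (", path, ")")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

read_counts_tsv <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t"),
    error = function(e) stop_input("cannot parse ", path, ": ",
                                   conditionMessage(e)))
  check_columns(df, c("chrom", "pos", "ref_count", "alt_count"), path)
  bad <- which(!is.finite(df$pos) | !is.finite(df$ref_count) |
                 !is.finite(df$alt_count) | df$ref_count < 0 |
                 df$alt_count < 0)
  if (length(bad)) {
    stop_input("malformed record in ", path, " at line ",
               bad[1] + 1L)  # +1 for the header line
  }
  df
}

read_counts_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || !ncol(ad)) {
    stop_input("VCF ", path, " has no sample AD field")
  }
  parts <- strsplit(ad[, 1], ",", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) {
    stop_input("malformed AD record in ", path, " at variant ", bad[1])
  }
  data.frame(chrom = as.character(fix[, "CHROM"]),
             pos = as.numeric(fix[, "POS"]),
             ref = as.character(fix[, "REF"]),
             alt = as.character(fix[, "ALT"]),
             ref_count = as.integer(vapply(parts, `[`, "", 1)),
             alt_count = as.integer(vapply(parts, `[`, "", 2)))
}

#' Write per-pool allele counts
#'
#' TSV (`chrom`, `pos`, `ref_count`, `alt_count`) or a minimal
#' single-sample VCFv4.2 with AD and DP per marker.
#'
#' @param counts a `pooled_counts` data frame.
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param markers optional `marker_list` supplying REF/ALT alleles for
#'   the VCF output.
#' @param sample sample name used in the VCF column header.
#' @return the path, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "vcf"),
                         markers = NULL, sample = "pool") {
  format <- match.arg(format)
  check_columns(counts, c("chrom", "pos", "ref_count", "alt_count"),
                "counts")
  if (format == "tsv") {
    utils::write.table(
      counts[, c("chrom", "pos", "ref_count", "alt_count")], path,
      sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  ref <- alt <- NULL
  if (!is.null(markers)) {
    mi <- match(chrom_key(counts$chrom, counts$pos),
                chrom_key(markers$chrom, markers$pos))
    ref <- markers$ref[mi]
    alt <- markers$alt[mi]
  }
  ref <- ref %||% rep("A", nrow(counts))
  alt <- alt %||% rep("C", nrow(counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=xqtl",
    paste0("##contig=<ID=", unique(counts$chrom), ">"),
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
           "Description=\"Read depth\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")), con)
  dp <- counts$ref_count + counts$alt_count
  writeLines(paste(counts$chrom, format(counts$pos, scientific = FALSE,
                                        trim = TRUE),
                   ".", ref, alt, ".", "PASS", ".", "AD:DP",
                   paste0(counts$ref_count, ",", counts$alt_count, ":", dp),
                   sep = "\t"), con)
  invisible(path)
}

#' Read / write genomic regions as BED
#'
#' BED is 0-based half-open; regions are converted to 1-based inclusive
#' on read and back on write.
#'
#' @param path file path.
#' @return data frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @export
read_region_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t")
  if (ncol(df) < 3) stop_input("BED file needs >= 3 columns")
  data.frame(chrom = as.character(df[[1]]), start = df[[2]] + 1,
             end = df[[3]])
}

#' @rdname read_region_bed
#' @param regions data frame with `chrom`, `start`, `end` (1-based
#'   inclusive) or a single [region()].
#' @export
write_region_bed <- function(regions, path) {
  if (inherits(regions, "region")) {
    regions <- data.frame(chrom = regions$chrom, start = regions$start,
                          end = regions$end)
  }
  check_columns(regions, c("chrom", "start", "end"), "regions")
  utils::write.table(
    data.frame(regions$chrom, regions$start - 1, regions$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a run manifest
#'
#' One row per pool: `file`, `gene`, `channel`, `gate`, `replicate`,
#' `batch`.
#'
#' @param path file path.
#' @return manifest data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  check_columns(df, c("file", "gene", "channel", "gate", "replicate",
                      "batch"), "manifest")
  df
}

#' @rdname read_manifest
#' @param manifest manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a LOD track as TSV or BedGraph
#'
#' @param track a `lod_track` data frame.
#' @param path output path.
#' @param format `"tsv"` (all columns) or `"bedgraph"` (LOD only,
#'   0-based half-open intervals).
#' @return the path, invisibly.
#' @export
write_lod_track <- function(track, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  check_columns(track, c("chrom", "bin_start", "bin_end", "lod"), "track")
  if (format == "tsv") {
    utils::write.table(track, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(
      data.frame(track$chrom, track$bin_start - 1, track$bin_end,
                 track$lod),
      path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(path)
}

#' Write called peaks as TSV or BED intervals
#'
#' The TSV layout mirrors the study's per-replicate QTL table (gene,
#' channel, replicate, chromosome, position, LOD, delta-AF, interval
#' bounds); BED output uses the support interval as the feature and the
#' LOD as the score.
#'
#' @param peaks a `qtl_peaks` data frame.
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @return the path, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    check_columns(peaks, c("chrom", "ci_lo", "ci_hi", "lod"), "peaks")
    name <- if (all(c("gene", "channel") %in% names(peaks))) {
      paste(peaks$gene, peaks$channel, sep = "_")
    } else {
      rep(".", nrow(peaks))
    }
    utils::write.table(
      data.frame(peaks$chrom, peaks$ci_lo - 1, peaks$ci_hi, name,
                 round(peaks$lod, 3)),
      path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(path)
}

#' Population variant matrix
#'
#' Candidate variant sites by populations, carrying per-population
#' allele frequency and coverage plus a per-site quality score, as
#' produced by joint variant calling across sequenced pools.
#'
#' @param sites data frame with `chrom`, `pos`, `ref`, `alt`, `quality`.
#' @param af numeric matrix (sites x populations) of alternate-allele
#'   frequencies in `[0, 1]` (`NA` where the variant was not called).
#' @param coverage integer matrix (sites x populations) of read depths.
#' @return object of class `population_variant_matrix`.
#' @export
population_variant_matrix <- function(sites, af, coverage) {
  check_columns(sites, c("chrom", "pos", "ref", "alt", "quality"), "sites")
  af <- as.matrix(af)
  coverage <- as.matrix(coverage)
  if (nrow(af) != nrow(sites) || !all(dim(af) == dim(coverage))) {
    stop_input("af / coverage dimensions do not match the sites")
  }
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    stop_input("allele frequencies must be in [0, 1]")
  }
  structure(list(sites = sites, af = af, coverage = coverage),
            class = "population_variant_matrix")
}

#' Screen for novel variants shared across populations
#'
#' Reproduces the filter cascade used to find new mutations segregating
#' in the mapping populations: previously known variants are excluded,
#' sites below the quality cutoff are removed, and variants seen in at
#' most `max_error_populations` populations are discarded as likely
#' sequencing errors.  Each surviving candidate is annotated with the
#' number of populations carrying it and, per design group, the
#' fraction of that group's populations carrying it (a variant private
#' to the strain background of one group stands out with fraction near
#' one there and zero elsewhere).
#'
#' @param matrix a [population_variant_matrix()].
#' @param known a `marker_list` of known variants to exclude.
#' @param min_quality minimum site quality (default 30).
#' @param max_error_populations presence in at most this many
#'   populations is treated as sequencing error (default 2).
#' @param design_groups optional factor/character vector assigning each
#'   population to a design group.
#' @param min_af,min_coverage presence thresholds per population.
#' @return data frame of candidate variants: `chrom`, `pos`, `ref`,
#'   `alt`, `quality`, `n_populations`, and one `frac_<group>` column
#'   per design group.
#' @export
novel_variant_screen <- function(matrix, known, min_quality = 30,
                                 max_error_populations = 2,
                                 design_groups = NULL, min_af = 0.05,
                                 min_coverage = 1) {
  stopifnot(inherits(matrix, "population_variant_matrix"))
  sites <- matrix$sites
  empty <- cbind(sites[0, ], n_populations = integer(0))
  if (!nrow(sites)) return(empty)
  present <- !is.na(matrix$af) & matrix$af >= min_af &
    matrix$coverage >= min_coverage
  n_pop <- rowSums(present)
  keep <- !(chrom_key(sites$chrom, sites$pos) %in%
              chrom_key(known$chrom, known$pos)) &
    sites$quality >= min_quality &
    n_pop > max_error_populations
  out <- cbind(sites[keep, , drop = FALSE],
               n_populations = n_pop[keep])
  if (!is.null(design_groups)) {
    if (length(design_groups) != ncol(matrix$af)) {
      stop_input("design_groups must have one entry per population")
    }
    for (g in unique(design_groups)) {
      cols <- which(design_groups == g)
      out[[paste0("frac_", g)]] <-
        rowSums(present[keep, cols, drop = FALSE]) / length(cols)
    }
  }
  rownames(out) <- NULL
  out
}
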