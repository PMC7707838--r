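# Synthetic yeast cross: recombinant haploid segregants, correlated
# dual-reporter single-cell phenotypes, FACS tail selection and pooled
# sequencing.  Every downstream mapping stage can be exercised against
# the planted ground truth this module records.

#' Configuration of a simulated two-parent haploid cross
#'
#' Describes the genome (chromosome lengths and marker positions), the
#' number of segregants and the physical-to-genetic map scaling.  Allele
#' 0 is the BY (reference) allele, allele 1 the RM (alternate) allele,
#' matching the convention that allele frequencies are always reported
#' for the BY allele.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param marker_positions optional named list of 1-based marker
#'   positions per chromosome; when `NULL`, `n_markers` markers are laid
#'   out evenly, split across chromosomes in proportion to length.
#' @param n_markers total number of markers when `marker_positions` is
#'   `NULL`.
#' @param n_segregants number of haploid segregants to simulate.
#' @param bp_per_cM physical distance corresponding to one centimorgan;
#'   2,200 bp/cM is the scaling of the BY x RM cross.
#' @param seed integer seed making the simulated cross reproducible.
#' @return an object of class `cross_config`.
#' @seealso [simulate_segregants()], [default_cross_config()]
#' @export
cross_config <- function(chrom_lengths, marker_positions = NULL,
                         n_markers = 2000, n_segregants = 50000,
                         bp_per_cM = 2200, seed = 1) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    stop_input("chrom_lengths must be a named vector")
  }
  if (bp_per_cM <= 0) stop_input("bp_per_cM must be > 0")
  if (n_segregants < 1) stop_input("n_segregants must be >= 1")
  if (is.null(marker_positions)) {
    total <- sum(chrom_lengths)
    marker_positions <- lapply(seq_along(chrom_lengths), function(i) {
      m <- max(1L, round(n_markers * chrom_lengths[i] / total))
      step <- chrom_lengths[i] / m
      round(step * (seq_len(m) - 0.5))
    })
    names(marker_positions) <- names(chrom_lengths)
  }
  if (!all(names(marker_positions) %in% names(chrom_lengths))) {
    stop_input("marker_positions has chromosomes absent from chrom_lengths")
  }
  for (chr in names(marker_positions)) {
    p <- marker_positions[[chr]]
    if (length(p) && any(diff(p) <= 0)) {
      stop_input("marker positions must be strictly increasing on ", chr)
    }
    if (length(p) && (any(p < 1) || any(p > chrom_lengths[chr]))) {
      stop_input("marker positions outside [1, length] on ", chr)
    }
  }
  structure(list(chrom_lengths = chrom_lengths,
                 marker_positions = marker_positions,
                 n_segregants = as.integer(n_segregants),
                 bp_per_cM = bp_per_cM,
                 seed = as.integer(seed)),
            class = "cross_config")
}

#' Desk-scale default cross configuration
#'
#' Two 1-Mb chromosomes carrying 1,000 evenly spaced markers each and
#' 50,000 segregants: large enough that tail-sorted pools behave like
#' the real experiment, small enough that a full simulated mapping run
#' takes seconds.
#'
#' @param n_segregants number of segregants (default 50,000).
#' @param seed integer seed.
#' @return a [cross_config()] object.
#' @export
default_cross_config <- function(n_segregants = 50000, seed = 1) {
  cross_config(chrom_lengths = c(chrI = 1e6, chrII = 1e6),
               n_markers = 2000, n_segregants = n_segregants, seed = seed)
}

#' @export
print.cross_config <- function(x, ...) {
  cat("Cross configuration:", length(x$chrom_lengths), "chromosomes,",
      sum(lengths(x$marker_positions)), "markers,",
      x$n_segregants, "segregants,", x$bp_per_cM, "bp/cM\n")
  invisible(x)
}

#' Simulate genotypes of recombinant haploid segregants
#'
#' Each segregant is an independent meiotic product on a linear genetic
#' map without crossover interference: the first marker of every
#' chromosome is Bernoulli(0.5) and the allele switches between
#' adjacent markers `d` bp apart with recombination fraction
#' `r = min(0.5, d / (bp_per_cM * 100))`.
#'
#' @param config a [cross_config()] object.
#' @return an object of class `genotype_matrix`: a list with `geno`, an
#'   integer matrix (segregants x markers, entries 0 = BY / 1 = RM) and
#'   `markers`, a data frame with columns `chrom` and `pos`.
#' @export
simulate_segregants <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  keep <- vapply(config$marker_positions, length, 1L) > 0
  if (any(!keep)) {
    warning("skipping chromosome(s) with zero markers: ",
            paste(names(config$marker_positions)[!keep], collapse = ", "))
  }
  mp <- config$marker_positions[keep]
  n <- config$n_segregants
  m <- sum(lengths(mp))
  geno <- matrix(0L, nrow = n, ncol = m)
  markers <- data.frame(chrom = rep(names(mp), lengths(mp)),
                        pos = unlist(mp, use.names = FALSE))
  with_seed(config$seed, {
    col <- 0L
    for (chr in names(mp)) {
      pos <- mp[[chr]]
      cur <- as.integer(stats::runif(n) < 0.5)
      geno[, col + 1L] <- cur
      if (length(pos) > 1) {
        r <- pmin(0.5, diff(pos) / (config$bp_per_cM * 100))
        for (j in seq_along(r)) {
          if (r[j] > 0) {
            cur <- (cur + (stats::runif(n) < r[j])) %% 2L
          }
          geno[, col + 1L + j] <- cur
        }
      }
      col <- col + length(pos)
    }
  })
  structure(list(geno = geno, markers = markers,
                 bp_per_cM = config$bp_per_cM),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$geno), "segregants x",
      ncol(x$geno), "markers;",
      "mean RM allele frequency",
      round(mean(x$geno), 3), "\n")
  invisible(x)
}

#' Trait model with planted QTL effects on mRNA and protein
#'
#' Defines the generative model of the dual-reporter phenotypes.  Each
#' cell `i` has a latent transcription value `t_i` and a protein-specific
#' value `s_i`, both additive over markers: genotype 0 (BY) contributes
#' `+a_j/2` (resp. `+b_j/2`) and genotype 1 (RM) `-a_j/2`, so a positive
#' effect means the BY allele increases the trait.  The observed
#' log-scale reporter signals are
#' \deqn{R_i = t_i + \gamma \log FSC_i + \epsilon_R}
#' \deqn{G_i = \kappa t_i + s_i + \gamma \log FSC_i + \epsilon_G}
#' Four planted QTL classes are expressible: concordant (`a != 0, b = 0`),
#' protein-specific (`a = 0, b != 0`), mRNA-specific / perfectly buffered
#' (`b = -kappa * a`) and discordant / over-compensated
#' (`b < -kappa * a`, net protein effect opposite in sign to the mRNA
#' effect).
#'
#' @param markers data frame with columns `chrom`, `pos` (the marker map
#'   the effects live on).
#' @param effects data frame with columns `chrom`, `pos`, `a`
#'   (transcription effect) and `b` (protein-specific effect); positions
#'   must be existing markers.
#' @param kappa transmission coefficient from mRNA to protein signal.
#' @param sigma_r,sigma_g independent Gaussian noise SD of the mRNA and
#'   protein reporters (trait units, must be >= 0).
#' @param gamma coupling of both reporters to log cell size.
#' @param size_meanlog,size_sdlog log-normal cell size (FSC) parameters.
#' @return an object of class `trait_model`.
#' @export
trait_model <- function(markers, effects, kappa = 1,
                        sigma_r = 0.6, sigma_g = 0.6, gamma = 1,
                        size_meanlog = log(5e4), size_sdlog = 0.25) {
  check_columns(markers, c("chrom", "pos"), "markers")
  check_columns(effects, c("chrom", "pos", "a", "b"), "effects")
  if (sigma_r < 0 || sigma_g < 0) stop_input("noise SDs must be >= 0")
  idx <- match(chrom_key(effects$chrom, effects$pos),
               chrom_key(markers$chrom, markers$pos))
  if (anyNA(idx)) {
    stop_input("effect position(s) not on the marker map: ",
               paste(chrom_key(effects$chrom, effects$pos)[is.na(idx)],
                     collapse = ", "))
  }
  a <- b <- numeric(nrow(markers))
  a[idx] <- effects$a
  b[idx] <- effects$b
  structure(list(markers = markers, a = a, b = b, effect_idx = idx,
                 kappa = kappa, sigma_r = sigma_r, sigma_g = sigma_g,
                 gamma = gamma, size_meanlog = size_meanlog,
                 size_sdlog = size_sdlog),
            class = "trait_model")
}

#' Default trait model: one planted QTL of each class
#'
#' Plants four well-separated loci, one per QTL class, with effect
#' magnitude 0.3 trait units (discordant protein-specific component
#' -0.6, i.e. over-compensation).  With the default noise (sigma 0.6)
#' and a 3% sorting tail this corresponds to expected |delta-AF| around
#' 0.45 per affected channel -- a strong but realistic X-QTL.
#'
#' @param markers marker map data frame (`chrom`, `pos`).
#' @param effect_size planted effect magnitude (trait units).
#' @param ... passed to [trait_model()].
#' @return a `trait_model` with attribute-free planted classes readable
#'   via [planted_qtls()].
#' @export
default_trait_model <- function(markers, effect_size = 0.3, ...) {
  chroms <- unique(markers$chrom)
  if (length(chroms) < 2) stop_input("default model expects >= 2 chromosomes")
  near <- function(chr, p) {
    sub <- markers[markers$chrom == chr, ]
    sub$pos[which.min(abs(sub$pos - p))]
  }
  e <- effect_size
  effects <- data.frame(
    chrom = c(chroms[1], chroms[1], chroms[2], chroms[2]),
    pos = c(near(chroms[1], 1.5e5), near(chroms[1], 8.5e5),
            near(chroms[2], 1.5e5), near(chroms[2], 8.5e5)),
    a = c(e, 0, e, e),
    b = c(0, e, -e, -2 * e),
    class = c("concordant", "protein-specific", "mRNA-specific",
              "discordant"))
  trait_model(markers, effects, ...)
}

#' Table of planted QTLs with expected pool allele-frequency contrasts
#'
#' Net per-locus effects on each channel are `a` (mRNA) and
#' `kappa * a + b` (protein).  The expected delta-AF of each locus under
#' tail sorting is computed with [expected_delta_af()] using the
#' within-genotype SD of the channel (all other planted loci, cell-size
#' coupling within the FSC gate, and reporter noise).
#'
#' @param model a [trait_model()].
#' @param sort a [sort_config()] providing the tail fraction and FSC gate.
#' @return data frame with one row per planted locus: `chrom`, `pos`,
#'   `class`, `effect_mrna`, `effect_protein`, `expected_daf_mrna`,
#'   `expected_daf_protein`.
#' @export
planted_qtls <- function(model, sort = sort_config()) {
  stopifnot(inherits(model, "trait_model"))
  idx <- model$effect_idx
  if (!length(idx)) {
    return(data.frame(chrom = character(), pos = numeric(),
                      class = character(), effect_mrna = numeric(),
                      effect_protein = numeric(),
                      expected_daf_mrna = numeric(),
                      expected_daf_protein = numeric()))
  }
  eff_m <- model$a[idx]
  eff_p <- model$kappa * model$a[idx] + model$b[idx]
  cls <- ifelse(eff_m != 0 & eff_p != 0 & sign(eff_m) == sign(eff_p),
                "concordant",
         ifelse(eff_m != 0 & eff_p != 0, "discordant",
         ifelse(eff_m != 0, "mRNA-specific", "protein-specific")))
  gate_var <- model$gamma^2 * model$size_sdlog^2 *
    truncnorm_var(sort$fsc_gate[1], sort$fsc_gate[2])
  daf <- function(effects, sigma) {
    vapply(seq_along(effects), function(k) {
      other_var <- sum(effects[-k]^2) / 4
      sd_within <- sqrt(other_var + gate_var + sigma^2)
      expected_delta_af(effects[k], sd_within, sort$tail_fraction)
    }, numeric(1))
  }
  data.frame(chrom = model$markers$chrom[idx],
             pos = model$markers$pos[idx],
             class = cls,
             effect_mrna = eff_m,
             effect_protein = eff_p,
             expected_daf_mrna = daf(eff_m, model$sigma_r),
             expected_daf_protein = daf(eff_p, model$sigma_g))
}

#' Expected delta-AF of a single locus under two-sided tail sorting
#'
#' For a biallelic locus shifting a Gaussian trait by `effect` (BY minus
#' RM genotype means) with within-genotype SD `sd_within`, cells in the
#' upper tail of fraction `q` of the balanced mixture are enriched for
#' the increasing allele.  The expected BY allele frequency in the high
#' pool minus the low pool is returned; by symmetry it equals
#' `2 * AF_high - 1`.
#'
#' @param effect difference between BY and RM genotype means.
#' @param sd_within within-genotype trait SD.
#' @param q sorted tail fraction (0 < q < 0.5).
#' @return expected delta-AF in `[-1, 1]`.
#' @export
expected_delta_af <- function(effect, sd_within, q = 0.03) {
  stopifnot(q > 0, q < 0.5, sd_within >= 0)
  if (effect == 0) return(0)
  if (sd_within == 0) return(sign(effect))
  h <- abs(effect) / 2
  f <- function(c) {
    0.5 * (stats::pnorm((c - h) / sd_within, lower.tail = FALSE) +
           stats::pnorm((c + h) / sd_within, lower.tail = FALSE)) - q
  }
  upper <- stats::qnorm(q, lower.tail = FALSE) * sd_within + h
  cc <- stats::uniroot(f, lower = 0, upper = upper + 10 * sd_within,
                       extendInt = "downX")$root
  af_high <- stats::pnorm((cc - h) / sd_within, lower.tail = FALSE) / (2 * q)
  sign(effect) * (2 * af_high - 1)
}

#' Simulate single-cell dual-reporter phenotypes
#'
#' Draws cell sizes and reporter noise and combines them with the
#' genetic values implied by the genotypes and the [trait_model()].
#'
#' @param genotypes a `genotype_matrix`.
#' @param model a `trait_model` defined on the same marker map.
#' @param seed integer seed.
#' @return object of class `cell_phenotypes`: data frame with columns
#'   `R` (mRNA reporter, log scale), `G` (protein reporter), `FSC`
#'   (cell size), and the latent values `t` and `s`.
#' @export
simulate_phenotypes <- function(genotypes, model, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(model, "trait_model"))
  if (length(model$a) != ncol(genotypes$geno)) {
    stop_input("trait model and genotypes have different marker counts")
  }
  n <- nrow(genotypes$geno)
  nz_a <- which(model$a != 0)
  nz_b <- which(model$b != 0)
  t_i <- rep(sum(model$a) / 2, n)
  if (length(nz_a)) {
    t_i <- t_i - as.vector(genotypes$geno[, nz_a, drop = FALSE] %*%
                             model$a[nz_a])
  }
  s_i <- rep(sum(model$b) / 2, n)
  if (length(nz_b)) {
    s_i <- s_i - as.vector(genotypes$geno[, nz_b, drop = FALSE] %*%
                             model$b[nz_b])
  }
  out <- with_seed(seed, {
    fsc <- stats::rlnorm(n, model$size_meanlog, model$size_sdlog)
    size_term <- model$gamma * log(fsc)
    R <- t_i + size_term + stats::rnorm(n, 0, model$sigma_r)
    G <- model$kappa * t_i + s_i + size_term +
      stats::rnorm(n, 0, model$sigma_g)
    data.frame(R = R, G = G, FSC = fsc, t = t_i, s = s_i)
  })
  if (any(!is.finite(out$R)) || any(!is.finite(out$G))) {
    stop_input("non-finite phenotype values")
  }
  class(out) <- c("cell_phenotypes", "data.frame")
  out
}

#' FACS sorting configuration
#'
#' @param tail_fraction fraction of gated cells collected in each
#'   fluorescence tail (the experiment sorted 3% tails).
#' @param pool_size maximum number of cells per sorted pool.
#' @param fsc_gate FSC quantile band retained before sorting (the
#'   central 60% band emulates the narrow cell-size gate).
#' @return object of class `sort_config`.
#' @export
sort_config <- function(tail_fraction = 0.03, pool_size = 10000,
                        fsc_gate = c(0.2, 0.8)) {
  if (tail_fraction <= 0 || tail_fraction >= 0.5) {
    stop_input("tail_fraction must be in (0, 0.5)")
  }
  if (pool_size < 1) stop_input("pool_size must be >= 1")
  stopifnot(length(fsc_gate) == 2, fsc_gate[1] < fsc_gate[2],
            fsc_gate[1] >= 0, fsc_gate[2] <= 1)
  structure(list(tail_fraction = tail_fraction,
                 pool_size = as.integer(pool_size),
                 fsc_gate = fsc_gate),
            class = "sort_config")
}

#' Sort cells into high / low / unsorted pools on one channel
#'
#' Cells are first gated to the central FSC band, then the
#' `min(pool_size, floor(q * n_gated))` cells with the largest (high
#' pool) and smallest (low pool) value of the chosen channel are
#' collected; the unsorted control pool is a random sample of the
#' remaining gated cells of the same size.  Pools are disjoint.
#'
#' @param phenotypes a `cell_phenotypes` data frame.
#' @param sort a [sort_config()].
#' @param channel `"mRNA"` (reporter R) or `"protein"` (reporter G).
#' @param seed seed for the unsorted control sample.
#' @return object of class `sorted_pools`: list of integer index vectors
#'   `high`, `low`, `unsorted`, `gate`.
#' @export
sort_pools <- function(phenotypes, sort = sort_config(),
                       channel = c("mRNA", "protein"), seed = 1) {
  channel <- match.arg(channel)
  stopifnot(inherits(phenotypes, "cell_phenotypes"))
  q <- sort$tail_fraction
  gate_q <- stats::quantile(phenotypes$FSC, sort$fsc_gate, names = FALSE)
  gate <- which(phenotypes$FSC >= gate_q[1] & phenotypes$FSC <= gate_q[2])
  k <- min(sort$pool_size, floor(q * length(gate)))
  if (k < 1) {
    stop_input("too few gated cells (", length(gate), "): at least ",
               ceiling(1 / q), " are required for a ", q, " tail")
  }
  value <- if (channel == "mRNA") phenotypes$R[gate] else phenotypes$G[gate]
  ord <- order(value)
  low <- gate[ord[seq_len(k)]]
  high <- gate[ord[seq.int(length(ord) - k + 1L, length(ord))]]
  rest <- setdiff(gate, c(high, low))
  unsorted <- with_seed(seed, sample(rest, min(k, length(rest))))
  structure(list(high = high, low = low, unsorted = unsorted, gate = gate,
                 channel = channel, pool_size = k),
            class = "sorted_pools")
}

#' Sequencing depth model for pooled whole-genome sequencing
#'
#' @param mean_depth mean per-marker read depth (Poisson lambda); the
#'   study's pools had a median of 13-fold coverage.
#' @param error_rate per-read allele miscall rate.
#' @return object of class `depth_model`.
#' @export
depth_model <- function(mean_depth = 13, error_rate = 0.001) {
  if (mean_depth < 0) stop_input("mean_depth must be >= 0")
  if (error_rate < 0 || error_rate >= 0.5) {
    stop_input("error_rate must be in [0, 0.5)")
  }
  structure(list(mean_depth = mean_depth, error_rate = error_rate),
            class = "depth_model")
}

#' Simulate pooled sequencing of a set of segregants
#'
#' Per marker the read depth is Poisson(`mean_depth`) and the number of
#' BY (reference) reads is binomial with success probability
#' `p * (1 - e) + (1 - p) * e`, where `p` is the BY allele frequency
#' among the pool members and `e` the per-read error rate.
#'
#' @param genotypes a `genotype_matrix`.
#' @param members integer indices of the pooled segregants.
#' @param depth a [depth_model()].
#' @param seed integer seed.
#' @param ... metadata passed to [pooled_counts()] (gene, channel, gate,
#'   replicate, batch).
#' @return a `pooled_counts` data frame.
#' @export
sequence_pool <- function(genotypes, members, depth = depth_model(),
                          seed = 1, ...) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(depth, "depth_model"))
  if (!length(members)) stop_input("members must be nonempty")
  p_by <- 1 - colMeans(genotypes$geno[members, , drop = FALSE])
  e <- depth$error_rate
  p_read <- p_by * (1 - e) + (1 - p_by) * e
  m <- length(p_by)
  with_seed(seed, {
    n <- stats::rpois(m, depth$mean_depth)
    k <- stats::rbinom(m, n, p_read)
    pooled_counts(chrom = genotypes$markers$chrom,
                  pos = genotypes$markers$pos,
                  ref_count = k, alt_count = n - k, ...)
  })
}

#' Construct a pooled allele-count table
#'
#' The canonical container for per-marker reference/alternate read
#' counts of one sorted pool, with the pool's experimental metadata
#' stored as attributes.
#'
#' @param chrom,pos marker coordinates (1-based).
#' @param ref_count,alt_count non-negative read counts of the reference
#'   (BY) and alternate (RM) allele.
#' @param gene,channel,gate,replicate,batch pool metadata; `channel` is
#'   `"GFP"`/`"mCherry"` (or `"protein"`/`"mRNA"`), `gate` one of
#'   `"high"`, `"low"`, `"unsorted"`.
#' @return data frame of class `pooled_counts`.
#' @export
pooled_counts <- function(chrom, pos, ref_count, alt_count,
                          gene = NA_character_, channel = NA_character_,
                          gate = NA_character_, replicate = NA,
                          batch = NA) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE)) {
    stop_input("read counts must be >= 0")
  }
  out <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    ref_count = as.integer(ref_count),
                    alt_count = as.integer(alt_count))
  attr(out, "metadata") <- list(gene = gene, channel = channel, gate = gate,
                                replicate = replicate, batch = batch)
  class(out) <- c("pooled_counts", "data.frame")
  out
}

#' Pool metadata accessor
#' @param counts a `pooled_counts` object.
#' @return named list with gene, channel, gate, replicate, batch.
#' @export
pool_metadata <- function(counts) {
  attr(counts, "metadata") %||%
    list(gene = NA, channel = NA, gate = NA, replicate = NA, batch = NA)
}

#' Simulate a complete sorting-and-sequencing experiment for one gene
#'
#' For each biological replicate an independent segregant population is
#' generated (replicates in the study were independent sporulations),
#' phenotyped, gated, tail-sorted on both channels and the five pools
#' (unsorted control plus high/low per channel) sequenced.
#'
#' @param config a [cross_config()].
#' @param model a [trait_model()]; defaults to [default_trait_model()] on
#'   the configured marker map.
#' @param sort a [sort_config()].
#' @param depth a [depth_model()].
#' @param n_replicates number of biological replicates.
#' @param gene gene label recorded in the pool metadata.
#' @param batch sequencing batch label (single batch by default).
#' @param seed master seed; all stages derive child seeds from it.
#' @return list with `counts` (list of `pooled_counts`), `manifest`
#'   (data frame describing every pool), `truth` (planted QTL table from
#'   [planted_qtls()]), and the generating `config`/`model`.
#' @export
simulate_experiment <- function(config = default_cross_config(),
                                model = NULL, sort = sort_config(),
                                depth = depth_model(), n_replicates = 2,
                                gene = "GENE1", batch = 1L, seed = 1) {
  seeds <- derive_seeds(seed, n_replicates * 12L)
  counts <- list()
  manifest <- NULL
  truth <- NULL
  si <- 0L
  for (rep_i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seeds[si <- si + 1L]
    genotypes <- simulate_segregants(cfg)
    if (is.null(model)) model <- default_trait_model(genotypes$markers)
    if (is.null(truth)) truth <- planted_qtls(model, sort)
    phen <- simulate_phenotypes(genotypes, model, seed = seeds[si <- si + 1L])
    for (channel in c("mRNA", "protein")) {
      pools <- sort_pools(phen, sort, channel, seed = seeds[si <- si + 1L])
      for (gate in c("high", "low")) {
        pc <- sequence_pool(genotypes, pools[[gate]], depth,
                            seed = seeds[si <- si + 1L],
                            gene = gene, channel = channel, gate = gate,
                            replicate = rep_i, batch = batch)
        counts[[length(counts) + 1L]] <- pc
      }
    }
    # one unsorted control per replicate, from the mRNA sort's gate
    pools <- sort_pools(phen, sort, "mRNA", seed = seeds[si <- si + 1L])
    counts[[length(counts) + 1L]] <-
      sequence_pool(genotypes, pools$unsorted, depth,
                    seed = seeds[si <- si + 1L], gene = gene,
                    channel = NA_character_, gate = "unsorted",
                    replicate = rep_i, batch = batch)
  }
  manifest <- do.call(rbind, lapply(counts, function(pc) {
    md <- pool_metadata(pc)
    data.frame(gene = md$gene, channel = md$channel, gate = md$gate,
               replicate = md$replicate, batch = md$batch)
  }))
  list(counts = counts, manifest = manifest, truth = truth,
       config = config, model = model, sort = sort, depth = depth)
}

#' Simulate matched null pools (no selection)
#'
#' Under zero planted effects, selecting a fluorescence tail is a
#' uniformly random draw of independent segregants, so a pair of null
#' pools of `pool_size` cells each is generated directly by simulating
#' `2 * pool_size` segregants and splitting them -- distributionally
#' identical to sorting a full-size population on a pure-noise trait,
#' at a fraction of the cost.  Used for null calibration of the LOD
#' scan and for inter-replicate false-discovery comparisons.
#'
#' @param config a [cross_config()]; its `n_segregants` is ignored.
#' @param pool_size cells per pool (default 10,000, the FACS pool size).
#' @param depth a [depth_model()].
#' @param seed integer seed.
#' @return list of two `pooled_counts` objects (`high`, `low` labels are
#'   arbitrary: both pools are unselected).
#' @export
simulate_null_pools <- function(config = default_cross_config(),
                                pool_size = 10000, depth = depth_model(),
                                seed = 1) {
  seeds <- derive_seeds(seed, 3L)
  cfg <- config
  cfg$n_segregants <- as.integer(2 * pool_size)
  cfg$seed <- seeds[1]
  genotypes <- simulate_segregants(cfg)
  idx <- seq_len(2 * pool_size)
  list(high = sequence_pool(genotypes, idx[seq_len(pool_size)], depth,
                            seed = seeds[2], gate = "high"),
       low = sequence_pool(genotypes, idx[-seq_len(pool_size)], depth,
                           seed = seeds[3], gate = "low"))
}

#' Convert simulated phenotypes to a cytometry event table
#'
#' Produces the four standard channels: `FSC`, an `SSC` proxy strongly
#' correlated with FSC, and the fluorescence intensities
#' `GFP = exp(G)` (protein reporter) and `mCherry = exp(R)` (mRNA
#' reporter), i.e. natural-scale fluorescence multiplicative in cell
#' size.
#'
#' @param phenotypes a `cell_phenotypes` data frame.
#' @param seed seed for the SSC jitter.
#' @return data frame with columns FSC, SSC, GFP, mCherry.
#' @export
as_event_table <- function(phenotypes, seed = 1) {
  stopifnot(inherits(phenotypes, "cell_phenotypes"))
  with_seed(seed, {
    data.frame(FSC = phenotypes$FSC,
               SSC = phenotypes$FSC *
                 stats::rlnorm(nrow(phenotypes), 0, 0.05),
               GFP = exp(phenotypes$G),
               mCherry = exp(phenotypes$R))
  })
}
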