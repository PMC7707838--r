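# Binned hidden-frequency contrast model (MULTIPOOL-style).  The latent
# BY allele frequency of a pool follows a Markov chain along each
# chromosome; binned read counts are binomial (optionally beta-binomial)
# emissions.  The per-bin LOD contrasts the hypothesis that the two
# pools' latent frequencies are equal at that bin against independence,
# using the full smoothing posteriors of the two chains.

#' Parameters of the binned LOD model
#'
#' @param bin_size genomic bin width in bp (default 100).
#' @param bp_per_cM physical-to-genetic scaling (default 2,200).
#' @param effective_pool_size effective number of independent segregants
#'   `N` in a pool (default 1,000); enters the transition variance
#'   `r (1 - r) / N`, i.e. how fast the latent frequency may drift along
#'   the genome.
#' @param grid_points number of points of the uniform frequency grid on
#'   `[0, 1]` (default 201, resolving delta-AF of 0.01).
#' @param rho emission overdispersion; 0 (default) gives pure binomial
#'   emissions, `0 < rho < 1` beta-binomial with intra-class
#'   correlation `rho`.
#' @return object of class `lod_params`.
#' @export
lod_params <- function(bin_size = 100, bp_per_cM = 2200,
                       effective_pool_size = 1000, grid_points = 201,
                       rho = 0) {
  if (bin_size < 1) stop_input("bin_size must be >= 1")
  if (effective_pool_size < 2) stop_input("effective_pool_size must be >= 2")
  if (grid_points < 11) stop_input("grid_points must be >= 11")
  if (bp_per_cM <= 0) stop_input("bp_per_cM must be > 0")
  if (rho < 0 || rho >= 1) stop_input("rho must be in [0, 1)")
  structure(list(bin_size = as.integer(bin_size), bp_per_cM = bp_per_cM,
                 effective_pool_size = effective_pool_size,
                 grid_points = as.integer(grid_points), rho = rho),
            class = "lod_params")
}

freq_grid <- function(params) {
  seq(0, 1, length.out = params$grid_points)
}

#' Sum pooled counts into fixed-width genomic bins
#'
#' Bin `b` covers positions `[(b-1)*w + 1, b*w]`; the marker at position
#' `p` belongs to bin `ceiling(p / w)`.  Bins tile each chromosome from
#' its start to the last occupied bin; empty bins carry zero counts.
#'
#' @param counts a `pooled_counts` data frame (markers sorted by
#'   position within chromosome).
#' @param params a [lod_params()].
#' @return object of class `binned_counts`: data frame with `chrom`,
#'   `bin_start`, `bin_end`, `ref_count`, `alt_count`.
#' @export
bin_counts <- function(counts, params = lod_params()) {
  check_columns(counts, c("chrom", "pos", "ref_count", "alt_count"),
                "counts")
  w <- params$bin_size
  pieces <- lapply(unique(counts$chrom), function(chr) {
    sub <- counts[counts$chrom == chr, ]
    if (is.unsorted(sub$pos)) stop_input("markers not sorted on ", chr)
    bin <- ceiling(sub$pos / w)
    nb <- max(bin)
    ref <- alt <- integer(nb)
    agg_r <- tapply(sub$ref_count, bin, sum)
    agg_a <- tapply(sub$alt_count, bin, sum)
    idx <- as.integer(names(agg_r))
    ref[idx] <- as.integer(agg_r)
    alt[idx] <- as.integer(agg_a)
    data.frame(chrom = chr, bin_start = (seq_len(nb) - 1L) * w + 1L,
               bin_end = seq_len(nb) * w, ref_count = ref, alt_count = alt)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "metadata") <- attr(counts, "metadata")
  class(out) <- c("binned_counts", "data.frame")
  out
}

# --- transition kernel -------------------------------------------------

.transition_cache <- new.env(parent = emptyenv())

# Markov transition over a gap with recombination fraction r: mean
# p + r (1 - 2p), variance r (1 - r) / N, discretized on the grid with
# row-wise renormalization (computed in log space to survive tiny r).
make_transition <- function(r, N, grid) {
  G <- length(grid)
  if (r <= 0) return(diag(G))
  key <- paste(signif(r, 12), N, G, sep = "_")
  hit <- .transition_cache[[key]]
  if (!is.null(hit)) return(hit)
  mu <- grid + r * (1 - 2 * grid)
  sd <- sqrt(r * (1 - r) / N)
  logd <- stats::dnorm(matrix(grid, G, G, byrow = TRUE), mean = mu,
                       sd = sd, log = TRUE)
  logd <- logd - apply(logd, 1, max)
  tr <- exp(logd)
  tr <- tr / rowSums(tr)
  if (length(.transition_cache) > 256) {
    rm(list = ls(.transition_cache), envir = .transition_cache)
  }
  .transition_cache[[key]] <- tr
  tr
}

gap_recomb <- function(pos, params) {
  pmin(0.5, diff(pos) / (params$bp_per_cM * 100))
}

# --- emissions ---------------------------------------------------------

# Emission matrix (bins x grid): probability of ref_count successes in
# depth draws at each grid frequency.  Zero-depth bins emit 1.
emission_matrix <- function(ref, alt, grid, rho = 0) {
  n <- ref + alt
  B <- length(n)
  G <- length(grid)
  E <- matrix(1, B, G)
  occ <- which(n > 0)
  for (i in occ) {
    if (rho <= 0) {
      E[i, ] <- stats::dbinom(ref[i], n[i], grid)
    } else {
      s <- (1 - rho) / rho
      a <- grid * s
      b <- (1 - grid) * s
      v <- exp(lchoose(n[i], ref[i]) + lbeta(ref[i] + a, n[i] - ref[i] + b) -
                 lbeta(a, b))
      # degenerate endpoints: frequency exactly 0 or 1
      v[grid == 0] <- as.numeric(ref[i] == 0)
      v[grid == 1] <- as.numeric(ref[i] == n[i])
      E[i, ] <- v
    }
  }
  E
}

# --- forward/backward --------------------------------------------------

# Scaled forward-backward over one chromosome's bins.  Returns, per bin,
# the smoothing posterior (all emissions) and the leave-one-out
# predictive (all emissions except the bin's own), both normalized.
hmm_chain <- function(E, r_gaps, params) {
  B <- nrow(E)
  G <- ncol(E)
  grid <- freq_grid(params)
  prior <- rep(1 / G, G)
  trans <- lapply(r_gaps, make_transition, N = params$effective_pool_size,
                  grid = grid)
  alpha_pred <- matrix(0, B, G)
  alpha_pred[1, ] <- prior
  if (B > 1) {
    for (i in seq_len(B - 1)) {
      post <- alpha_pred[i, ] * E[i, ]
      s <- sum(post)
      if (s <= 0) post <- alpha_pred[i, ] else post <- post / s
      alpha_pred[i + 1, ] <- as.vector(post %*% trans[[i]])
    }
  }
  beta <- matrix(1 / G, B, G)
  if (B > 1) {
    for (i in seq.int(B - 1, 1)) {
      v <- as.vector(trans[[i]] %*% (E[i + 1, ] * beta[i + 1, ]))
      s <- sum(v)
      if (s <= 0) v <- rep(1, G)
      beta[i, ] <- v / sum(v)
    }
  }
  loo <- alpha_pred * beta
  loo <- loo / pmax(rowSums(loo), .Machine$double.xmin)
  post <- loo * E
  post <- post / pmax(rowSums(post), .Machine$double.xmin)
  list(posterior = post, loo = loo)
}

#' Per-bin hidden-frequency distributions of one pool
#'
#' Runs the forward-backward recursion of the hidden-frequency Markov
#' chain over the informative bins of each chromosome (runs of empty
#' bins are collapsed analytically: the recombination fraction of a gap
#' is `min(0.5, d / (bp_per_cM * 100))` for the full gap distance `d`)
#' and returns per-bin distributions over the frequency grid: the
#' smoothing posterior and the leave-one-out predictive (the
#' distribution of the bin's frequency given every other bin's counts),
#' the latter being the uniform prior when no other bin is informative.
#' Zero-depth bins, which carry no evidence, report the uniform prior.
#'
#' @param binned a `binned_counts` data frame.
#' @param params a [lod_params()].
#' @param type `"loo"` (leave-one-out predictive, default) or
#'   `"posterior"`.
#' @return matrix (bins x grid points) of the requested distributions,
#'   rows aligned with `binned`; the grid is in `attr(, "grid")`.
#' @export
hmm_posteriors <- function(binned, params = lod_params(),
                           type = c("loo", "posterior")) {
  type <- match.arg(type)
  check_columns(binned, c("chrom", "bin_start", "bin_end", "ref_count",
                          "alt_count"), "binned")
  if (nrow(binned) < 1) stop_input("need at least one bin")
  grid <- freq_grid(params)
  out <- matrix(1 / length(grid), nrow(binned), length(grid))
  depth <- binned$ref_count + binned$alt_count
  for (chr in unique(binned$chrom)) {
    i <- which(binned$chrom == chr & depth > 0)
    if (!length(i)) next
    mid <- (binned$bin_start[i] + binned$bin_end[i]) / 2
    E <- emission_matrix(binned$ref_count[i], binned$alt_count[i], grid,
                         params$rho)
    ch <- hmm_chain(E, gap_recomb(mid, params), params)
    out[i, ] <- if (type == "loo") ch$loo else ch$posterior
  }
  if (any(!is.finite(out))) stop("non-finite posterior values")
  attr(out, "grid") <- grid
  out
}

#' Binned LOD track contrasting two pools
#'
#' For each bin the LOD score is the log10 Bayes factor against equality
#' of the two pools' latent frequencies at that bin:
#' \deqn{LOD(x) = -\log_{10} \sum_v P_h(v \mid D_h)\, P_l(v \mid D_l) / \pi(v)}
#' where \eqn{P_h, P_l} are the smoothing posteriors of the two
#' independent chains and \eqn{\pi} the uniform grid prior.  Evidence
#' against equality accumulates across all linked bins through the
#' posteriors, so the score reaches the tens at a strong QTL while
#' statistically identical pools give values near zero (the score is
#' floored at 0).  Bins with zero depth in both pools get LOD 0.
#'
#' @param high,low `binned_counts` on identical bins.
#' @param params a [lod_params()].
#' @param delta optional per-bin delta-AF values to carry in the track
#'   (e.g. loess-smoothed marker delta-AF); by default the difference of
#'   the two chains' posterior-mean frequencies is used.
#' @return object of class `lod_track`: data frame with `chrom`,
#'   `bin_start`, `bin_end`, `lod`, `delta_af`, `depth_high`,
#'   `depth_low`.
#' @export
lod_track <- function(high, low, params = lod_params(), delta = NULL) {
  check_columns(high, c("chrom", "bin_start", "bin_end", "ref_count",
                        "alt_count"), "high")
  check_columns(low, c("chrom", "bin_start", "bin_end", "ref_count",
                       "alt_count"), "low")
  if (nrow(high) != nrow(low) ||
      any(high$chrom != low$chrom) ||
      any(high$bin_start != low$bin_start)) {
    stop_input("high and low pools are binned differently")
  }
  if (!is.null(delta) && length(delta) != nrow(high)) {
    stop_input("delta must have one value per bin")
  }
  grid <- freq_grid(params)
  G <- length(grid)
  depth_h <- high$ref_count + high$alt_count
  depth_l <- low$ref_count + low$alt_count
  lod <- numeric(nrow(high))
  dmean <- rep(NA_real_, nrow(high))
  for (chr in unique(high$chrom)) {
    i <- which(high$chrom == chr)
    occ <- i[depth_h[i] + depth_l[i] > 0]
    if (!length(occ)) next
    mid <- (high$bin_start[occ] + high$bin_end[occ]) / 2
    r_gaps <- gap_recomb(mid, params)
    Eh <- emission_matrix(high$ref_count[occ], high$alt_count[occ], grid,
                          params$rho)
    El <- emission_matrix(low$ref_count[occ], low$alt_count[occ], grid,
                          params$rho)
    Ph <- hmm_chain(Eh, r_gaps, params)$posterior
    Pl <- hmm_chain(El, r_gaps, params)$posterior
    overlap <- pmax(G * rowSums(Ph * Pl), 1e-300)
    lod[occ] <- pmax(0, -log10(overlap))
    dmean[occ] <- as.vector(Ph %*% grid) - as.vector(Pl %*% grid)
  }
  if (any(!is.finite(lod))) stop("non-finite LOD values")
  out <- data.frame(chrom = high$chrom, bin_start = high$bin_start,
                    bin_end = high$bin_end, lod = lod,
                    delta_af = if (is.null(delta)) dmean else delta,
                    depth_high = depth_h, depth_low = depth_l)
  attr(out, "params") <- params
  attr(out, "provenance") <- list(high = attr(high, "metadata"),
                                  low = attr(low, "metadata"))
  class(out) <- c("lod_track", "data.frame")
  out
}
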