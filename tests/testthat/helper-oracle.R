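# Independent brute-force oracle for the binned hidden-frequency
# contrast LOD: enumerates every joint trajectory of the latent
# frequency over the grid (feasible for <= 3 bins), computes the exact
# marginal posteriors of each pool's chain and evaluates the equality
# Bayes factor directly.  Shares only the model definition (kernel and
# emissions), not the forward-backward code path.

bf_transition <- function(r, N, grid) {
  G <- length(grid)
  if (r <= 0) return(diag(G))
  mu <- grid + r * (1 - 2 * grid)
  sd <- sqrt(r * (1 - r) / N)
  tr <- matrix(0, G, G)
  for (i in seq_len(G)) {
    logd <- dnorm(grid, mu[i], sd, log = TRUE)
    w <- exp(logd - max(logd))
    tr[i, ] <- w / sum(w)
  }
  tr
}

# Exact marginal posteriors of one chain by trajectory enumeration.
bf_chain_posterior <- function(ref, alt, mids, params) {
  grid <- seq(0, 1, length.out = params$grid_points)
  G <- length(grid)
  B <- length(ref)
  E <- matrix(1, B, G)
  for (b in seq_len(B)) {
    n <- ref[b] + alt[b]
    if (n > 0) E[b, ] <- dbinom(ref[b], n, grid)
  }
  r <- pmin(0.5, diff(mids) / (params$bp_per_cM * 100))
  trans <- lapply(r, bf_transition, N = params$effective_pool_size,
                  grid = grid)
  states <- as.matrix(do.call(expand.grid, rep(list(seq_len(G)), B)))
  w <- rep(1 / G, nrow(states))
  for (b in seq_len(B)) w <- w * E[b, ][states[, b]]
  if (B > 1) {
    for (b in seq_len(B - 1)) {
      w <- w * trans[[b]][cbind(states[, b], states[, b + 1])]
    }
  }
  post <- matrix(0, B, G)
  for (b in seq_len(B)) {
    post[b, ] <- vapply(seq_len(G), function(v) sum(w[states[, b] == v]),
                        numeric(1))
    post[b, ] <- post[b, ] / sum(post[b, ])
  }
  post
}

# Brute-force per-bin contrast LOD for two pools on shared bins.
bf_lod <- function(ref_h, alt_h, ref_l, alt_l, mids, params) {
  grid <- seq(0, 1, length.out = params$grid_points)
  G <- length(grid)
  Ph <- bf_chain_posterior(ref_h, alt_h, mids, params)
  Pl <- bf_chain_posterior(ref_l, alt_l, mids, params)
  overlap <- pmax(G * rowSums(Ph * Pl), 1e-300)
  pmax(0, -log10(overlap))
}

# Exact two-sided binomial p-value by enumeration (sum of outcome
# probabilities no larger than the observed one).
bf_binom_two_sided <- function(k, n, p = 0.5) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[k + 1] * (1 + 1e-12)])
}
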