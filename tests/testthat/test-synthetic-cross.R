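# Synthetic cross: meiosis, phenotypes, sorting and pooled sequencing.

test_that("recombination follows the linear map", {
  # identical positions are disallowed by the config (strictly
  # increasing), so zero-distance behaviour is checked via an
  # arbitrarily small gap: r = 1 bp / 220,000 ~ 0
  cfg <- cross_config(c(chr1 = 1e4), marker_positions = list(chr1 = c(5000, 5001)),
                      n_segregants = 2000, seed = 11)
  g <- simulate_segregants(cfg)
  expect_lt(mean(g$geno[, 1] != g$geno[, 2]), 0.005)

  # 2,200 bp apart = 1 cM: switch fraction ~ 0.01 within 3 binomial SE
  cfg <- cross_config(c(chr1 = 1e4),
                      marker_positions = list(chr1 = c(2000, 4200)),
                      n_segregants = 10000, seed = 12)
  g <- simulate_segregants(cfg)
  sw <- mean(g$geno[, 1] != g$geno[, 2])
  expect_lt(abs(sw - 0.01), 3 * sqrt(0.01 * 0.99 / 10000))

  # unlinked after 110 kb (r capped at 0.5)
  cfg <- cross_config(c(chr1 = 3e5),
                      marker_positions = list(chr1 = c(1000, 150000)),
                      n_segregants = 10000, seed = 13)
  g <- simulate_segregants(cfg)
  expect_lt(abs(mean(g$geno[, 1] != g$geno[, 2]) - 0.5),
            3 * sqrt(0.25 / 10000))
})

test_that("allele frequencies are balanced without selection", {
  cfg <- cross_config(c(chr1 = 5e4), n_markers = 50,
                      n_segregants = 10000, seed = 21)
  g <- simulate_segregants(cfg)
  af <- 1 - colMeans(g$geno)   # BY allele frequency
  se3 <- 3 * sqrt(0.25 / 10000)
  expect_lt(abs(mean(af) - 0.5), se3)
  expect_gte(mean(abs(af - 0.5) < se3), 0.95)
})

test_that("segregant simulation is deterministic given the seed and skips empty chromosomes", {
  cfg <- tiny_config(seed = 5)
  expect_identical(simulate_segregants(cfg)$geno,
                   simulate_segregants(cfg)$geno)
  cfg2 <- cross_config(c(chrA = 1e5, chrB = 1e5),
                       marker_positions = list(chrA = c(1000, 2000),
                                               chrB = numeric(0)),
                       n_segregants = 10, seed = 1)
  expect_warning(g <- simulate_segregants(cfg2), "zero markers")
  expect_identical(unique(g$markers$chrom), "chrA")
})

test_that("marker positions must be strictly increasing", {
  expect_error(cross_config(c(chr1 = 1e4),
                            marker_positions = list(chr1 = c(100, 100))),
               "strictly increasing")
  expect_error(cross_config(c(chr1 = 1e4),
                            marker_positions = list(chr1 = c(200, 100))),
               "strictly increasing")
})

test_that("phenotypes follow the additive dual-reporter model", {
  cfg <- cross_config(c(chr1 = 1e4),
                      marker_positions = list(chr1 = c(2000, 8000)),
                      n_segregants = 2000, seed = 31)
  g <- simulate_segregants(cfg)
  markers <- g$markers

  # all effects zero, zero noise, no size coupling: all cells identical
  m0 <- trait_model(markers,
                    data.frame(chrom = "chr1", pos = 2000, a = 0, b = 0),
                    sigma_r = 0, sigma_g = 0, gamma = 0)
  ph <- simulate_phenotypes(g, m0, seed = 1)
  expect_equal(var(ph$R), 0)
  expect_equal(var(ph$G), 0)

  # single concordant locus, zero noise: R and G split by genotype and
  # correlate perfectly
  m1 <- trait_model(markers,
                    data.frame(chrom = "chr1", pos = 2000, a = 1, b = 0),
                    kappa = 1, sigma_r = 0, sigma_g = 0, gamma = 0)
  ph <- simulate_phenotypes(g, m1, seed = 1)
  expect_equal(length(unique(ph$R)), 2)
  expect_equal(cor(ph$R, ph$G), 1)
  # BY genotype (0) carries the higher trait value for a > 0
  expect_gt(mean(ph$R[g$geno[, 1] == 0]), mean(ph$R[g$geno[, 1] == 1]))

  # mismatched marker map is rejected
  expect_error(simulate_phenotypes(g, trait_model(markers[1, ],
    data.frame(chrom = "chr1", pos = 2000, a = 1, b = 0))),
    "marker counts")
})

test_that("perfect buffering cancels the protein effect (Monte Carlo)", {
  cfg <- cross_config(c(chr1 = 1e4),
                      marker_positions = list(chr1 = c(5000, 9000)),
                      n_segregants = 50000, seed = 41)
  g <- simulate_segregants(cfg)
  m <- trait_model(g$markers,
                   data.frame(chrom = "chr1", pos = 5000, a = 1, b = -1),
                   kappa = 1, sigma_r = 0.5, sigma_g = 0.5, gamma = 0)
  ph <- simulate_phenotypes(g, m, seed = 2)
  x <- g$geno[, 1]
  expect_lt(abs(cor(ph$G, x)), 0.02)
  r_m <- cor(ph$R, x)
  # RM allele (1) decreases the trait for a > 0
  expect_lt(r_m, -0.5)
})

test_that("tail sorting selects exact extremes and enriches causal alleles", {
  # exact tails with a full FSC gate
  cfg <- cross_config(c(chr1 = 1e4),
                      marker_positions = list(chr1 = c(2000, 8000)),
                      n_segregants = 1000, seed = 51)
  g <- simulate_segregants(cfg)
  m <- trait_model(g$markers,
                   data.frame(chrom = "chr1", pos = 2000, a = 0.5, b = 0.5),
                   sigma_r = 1, sigma_g = 1, gamma = 0)
  ph <- simulate_phenotypes(g, m, seed = 3)
  sc <- sort_config(tail_fraction = 0.1, pool_size = 100,
                    fsc_gate = c(0, 1))
  pools <- sort_pools(ph, sc, "mRNA")
  expect_length(pools$high, 100)
  expect_length(pools$low, 100)
  expect_identical(sort(pools$high),
                   sort(order(ph$R, decreasing = TRUE)[1:100]))
  expect_gte(min(ph$R[pools$high]), max(ph$R[pools$low]))
  expect_length(intersect(pools$high, pools$low), 0)
  expect_length(intersect(pools$unsorted, c(pools$high, pools$low)), 0)

  # planted BY-increasing QTL: BY frequency above 0.5 in the high pool,
  # below in the low pool (truncation selection Monte Carlo)
  af_by <- function(idx) mean(g$geno[idx, 1] == 0)
  expect_gt(af_by(pools$high), 0.5)
  expect_lt(af_by(pools$low), 0.5)

  # too few gated cells
  expect_error(sort_pools(ph[1:5, ], sort_config(tail_fraction = 0.03)),
               "at least")
})

test_that("pooled sequencing follows the Poisson-binomial read model", {
  cfg <- cross_config(c(chr1 = 1e4),
                      marker_positions = list(chr1 = c(2000, 5000, 8000)),
                      n_segregants = 200, seed = 61)
  g <- simulate_segregants(cfg)

  expect_error(sequence_pool(g, integer(0)), "nonempty")
  expect_error(depth_model(mean_depth = -1), ">= 0")

  # lambda = 0: zero depth everywhere
  pc <- sequence_pool(g, 1:200, depth_model(mean_depth = 0), seed = 1)
  expect_true(all(pc$ref_count + pc$alt_count == 0))

  # pure-BY pool without errors: every read is a reference read
  g0 <- g
  g0$geno[] <- 0L
  pc <- sequence_pool(g0, 1:200, depth_model(13, error_rate = 0), seed = 2)
  expect_true(all(pc$alt_count == 0))

  # balanced pool at high depth: frequency near 0.5 within 3 SE
  gh <- g
  gh$geno[] <- rep(c(0L, 1L), length.out = length(gh$geno))
  pc <- sequence_pool(gh, 1:200, depth_model(1000, error_rate = 0),
                      seed = 3)
  af <- pc$ref_count / (pc$ref_count + pc$alt_count)
  n <- pc$ref_count + pc$alt_count
  expect_true(all(abs(af - 0.5) < 3 * sqrt(0.25 / n)))

  # deterministic given seed
  expect_identical(sequence_pool(g, 1:100, seed = 9),
                   sequence_pool(g, 1:100, seed = 9))
})

test_that("unselected pools stay at allele frequency 0.5", {
  sim <- simulate_null_pools(tiny_config(n_markers = 200),
                             pool_size = 2000,
                             depth = depth_model(50), seed = 71)
  af <- compute_af(sim$high)
  se <- sqrt(0.25 / 2000 + 0.25 / pmax(af$depth, 1))
  z <- abs(af$af - 0.5) / se
  # 3-SE coverage per marker, allowing the expected ~0.3% exceedances
  expect_gte(mean(z < 3, na.rm = TRUE), 0.97)
})

test_that("expected delta-AF matches truncation-selection simulation", {
  # analytic prediction vs direct Monte Carlo of tail sorting
  effect <- 0.5
  sdw <- 1
  q <- 0.05
  pred <- expected_delta_af(effect, sdw, q)
  set.seed(77)
  geno <- rbinom(2e5, 1, 0.5)          # 1 = RM
  trait <- ifelse(geno == 0, effect / 2, -effect / 2) + rnorm(2e5, 0, sdw)
  k <- floor(q * 2e5)
  hi <- order(trait, decreasing = TRUE)[1:k]
  lo <- order(trait)[1:k]
  obs <- mean(geno[hi] == 0) - mean(geno[lo] == 0)
  expect_lt(abs(pred - obs), 0.02)
  expect_equal(expected_delta_af(0, 1), 0)
  expect_equal(expected_delta_af(-effect, sdw, q), -pred)
})
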