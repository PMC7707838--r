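# Binned hidden-frequency model: binning, forward-backward
# distributions and the contrast LOD, validated against brute-force
# trajectory enumeration.

test_that("markers are assigned to tiling 100-bp bins and counts summed", {
  pc <- counts_1chr(c(50, 149), c(3, 2), c(1, 4))
  b <- bin_counts(pc)
  expect_equal(nrow(b), 2L)
  expect_equal(b$bin_start, c(1L, 101L))
  expect_equal(b$ref_count, c(3L, 2L))

  # two markers in one bin: counts summed; empty bins carry zeros
  pc2 <- counts_1chr(c(120, 180, 350), c(3, 2, 1), c(1, 4, 0))
  b2 <- bin_counts(pc2)
  expect_equal(nrow(b2), 4L)
  expect_equal(b2$ref_count, c(0L, 5L, 0L, 1L))
  expect_equal(b2$alt_count, c(0L, 5L, 0L, 0L))
})

test_that("a lone uninformative bin has the uniform prior as predictive", {
  b <- bin_counts(counts_1chr(50, 0, 0))
  params <- lod_params(grid_points = 21)
  q <- hmm_posteriors(b, params, type = "loo")
  expect_equal(as.vector(q), rep(1 / 21, 21))
})

test_that("a tightly linked informative neighbour concentrates the predictive", {
  # neighbour at 1 bp (r ~ 0) with counts k = n = 50: the first bin's
  # leave-one-out predictive (its own single read removed) concentrates
  # above frequency 0.9
  pc <- counts_1chr(c(50, 51), c(1, 50), c(0, 0))
  params <- lod_params(bin_size = 1, grid_points = 201)
  b <- bin_counts(pc, params)
  q <- hmm_posteriors(b, params, type = "loo")
  grid <- attr(q, "grid")
  occ <- which(b$ref_count + b$alt_count > 0)
  expect_gt(sum(q[occ[1], grid > 0.9]), 0.95)
  # matches a direct grid computation of the neighbour's posterior
  # propagated through the near-identity kernel
  direct <- dbinom(50, 50, grid) / sum(dbinom(50, 50, grid))
  expect_lt(max(abs(q[occ[1], ] - direct)), 0.02)
})

test_that("unlinked bins (r = 0.5) have predictives independent of each other's counts", {
  params <- lod_params(bin_size = 100, grid_points = 21)
  # 120 kb apart: r capped at 0.5
  mk <- function(k2, n2) {
    bin_counts(counts_1chr(c(50, 120050), c(30, k2), c(20, n2 - k2)),
               params)
  }
  q_a <- hmm_posteriors(mk(50, 50), params, type = "loo")
  q_b <- hmm_posteriors(mk(0, 50), params, type = "loo")
  q_c <- hmm_posteriors(mk(25, 50), params, type = "loo")
  expect_equal(q_a[1, ], q_b[1, ], tolerance = 1e-12)
  expect_equal(q_a[1, ], q_c[1, ], tolerance = 1e-12)
  # and the forward-backward marginals match brute-force enumeration
  post <- hmm_posteriors(mk(30, 50), params, type = "posterior")
  occ <- c(1L, nrow(post))
  bf <- bf_chain_posterior(c(30, 30), c(20, 20), c(50.5, 120050.5),
                           params)
  expect_equal(unclass(post)[occ, ], bf, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the contrast LOD equals brute-force enumeration on small instances", {
  params <- lod_params(grid_points = 21)
  cases <- list(
    list(pos = c(150, 250), h = rbind(c(12, 1), c(10, 3)),
         l = rbind(c(2, 11), c(3, 9))),
    list(pos = c(150, 5150, 80150), h = rbind(c(5, 5), c(9, 1), c(0, 0)),
         l = rbind(c(5, 5), c(2, 8), c(7, 7))),
    list(pos = c(150, 300450, 300550),
         h = rbind(c(20, 0), c(4, 4), c(13, 13)),
         l = rbind(c(0, 20), c(4, 4), c(26, 0))),
    list(pos = c(150, 250, 350), h = rbind(c(7, 6), c(6, 7), c(7, 7)),
         l = rbind(c(7, 6), c(6, 7), c(7, 7))))
  for (cs in cases) {
    hi <- counts_1chr(cs$pos, cs$h[, 1], cs$h[, 2])
    lo <- counts_1chr(cs$pos, cs$l[, 1], cs$l[, 2])
    tr <- lod_track(bin_counts(hi, params), bin_counts(lo, params),
                    params)
    occ <- tr$depth_high + tr$depth_low > 0
    mids <- (tr$bin_start[occ] + tr$bin_end[occ]) / 2
    expected <- bf_lod(cs$h[, 1], cs$h[, 2], cs$l[, 1], cs$l[, 2],
                       mids, params)
    expect_equal(tr$lod[occ], expected, tolerance = 1e-6)
    # zero-depth bins carry LOD 0
    expect_true(all(tr$lod[!occ] == 0))
  }
})

test_that("identical pools give LOD near zero along the track", {
  set.seed(5)
  pos <- seq(500, 50000, by = 500)
  ref <- rbinom(length(pos), 13, 0.5)
  alt <- 13 - ref
  pc <- counts_1chr(pos, ref, alt)
  tr <- lod_track(bin_counts(pc), bin_counts(pc))
  expect_lte(max(abs(tr$lod)), 0.2)
})

test_that("doubling the depth of a fixed contrast increases the LOD", {
  params <- lod_params(grid_points = 61)
  mk <- function(mult) {
    pos <- seq(500, 20000, by = 500)
    n <- length(pos)
    h_ref <- rep(13, n); h_alt <- rep(7, n)     # AF 0.65
    l_ref <- rep(7, n); l_alt <- rep(13, n)     # AF 0.35
    hi <- counts_1chr(pos, h_ref * mult, h_alt * mult)
    lo <- counts_1chr(pos, l_ref * mult, l_alt * mult)
    lod_track(bin_counts(hi, params), bin_counts(lo, params), params)
  }
  lod1 <- max(mk(1)$lod)
  lod2 <- max(mk(2)$lod)
  expect_gt(lod2, lod1)
})

test_that("the LOD track is symmetric in the pools and separable by chromosome", {
  set.seed(6)
  pos <- seq(500, 30000, by = 1000)
  n <- length(pos)
  mk <- function(p) {
    ref <- rbinom(n, 15, p)
    list(ref = ref, alt = 15 - ref)
  }
  a <- mk(0.7); b <- mk(0.3)
  hi2 <- pooled_counts(rep(c("chrI", "chrII"), each = n), rep(pos, 2),
                       c(a$ref, b$ref), c(a$alt, b$alt))
  lo2 <- pooled_counts(rep(c("chrI", "chrII"), each = n), rep(pos, 2),
                       c(b$ref, a$ref), c(b$alt, a$alt))
  t_ab <- lod_track(bin_counts(hi2), bin_counts(lo2))
  t_ba <- lod_track(bin_counts(lo2), bin_counts(hi2))
  expect_equal(t_ab$lod, t_ba$lod, tolerance = 1e-9)

  # per-chromosome computation matches the joint call
  one <- function(chr, h, l) {
    hi <- counts_1chr(pos, h$ref, h$alt, chrom = chr)
    lo <- counts_1chr(pos, l$ref, l$alt, chrom = chr)
    lod_track(bin_counts(hi), bin_counts(lo))$lod
  }
  expect_equal(t_ab$lod, c(one("chrI", a, b), one("chrII", b, a)),
               tolerance = 1e-9)
})

test_that("extreme counts stay numerically finite", {
  pos <- seq(100, 2000, by = 100)
  n <- length(pos)
  hi <- counts_1chr(pos, rep(200, n), rep(0, n))
  lo <- counts_1chr(pos, rep(0, n), rep(200, n))
  tr <- lod_track(bin_counts(hi), bin_counts(lo))
  expect_true(all(is.finite(tr$lod)))
  expect_gt(max(tr$lod), 10)
})

test_that("beta-binomial emissions temper the evidence of overdispersed counts", {
  pos <- seq(500, 20000, by = 500)
  n <- length(pos)
  hi <- counts_1chr(pos, rep(13, n), rep(7, n))
  lo <- counts_1chr(pos, rep(7, n), rep(13, n))
  p0 <- lod_params()
  p1 <- lod_params(rho = 0.2)
  lod0 <- max(lod_track(bin_counts(hi, p0), bin_counts(lo, p0), p0)$lod)
  lod1 <- max(lod_track(bin_counts(hi, p1), bin_counts(lo, p1), p1)$lod)
  expect_gt(lod0, lod1)
  expect_true(all(is.finite(lod1)))
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(lod_params(bin_size = 0), "bin_size")
  expect_error(lod_params(effective_pool_size = 1), "pool_size")
  expect_error(lod_params(grid_points = 5), "grid_points")
  expect_error(lod_params(rho = 1), "rho")
  hi <- bin_counts(counts_1chr(c(100, 200), c(1, 1), c(1, 1)))
  lo <- bin_counts(counts_1chr(c(100, 300), c(1, 1), c(1, 1)))
  expect_error(lod_track(hi, lo), "binned differently")
})
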