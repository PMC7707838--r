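# Cross-channel locus pairing, exclusion, curation, classification and
# direction agreement.

mrow <- function(gene, chrom, pos, lod, delta, ci_lo = pos - 25000,
                 ci_hi = pos + 25000, det = 2, tot = 2) {
  out <- merged_row(gene, chrom, pos, lod, delta, det = det, tot = tot)
  out$ci_lo <- ci_lo
  out$ci_hi <- ci_hi
  out
}

test_that("the exclusion region removes peaks inside inclusive bounds", {
  mg <- as_merged(
    mrow("G1", "chrXIV", 450000, 6, 0.3),
    mrow("G1", "chrXIV", 300000, 6, 0.3),
    mrow("G1", "chrXII", 450000, 6, 0.3),
    mrow("G1", "chrXIV", 350000, 6, 0.3),   # boundary, inclusive
    mrow("G1", "chrXIV", 550001, 6, 0.3))
  expect_message(out <- exclude_region(mg), "excluding 2")
  expect_equal(attr(out, "n_removed"), 2L)
  expect_false(any(out$chrom == "chrXIV" &
                     out$pos >= 350000 & out$pos <= 550000))
  expect_true(300000 %in% out$pos)
  expect_true(any(out$chrom == "chrXII"))
})

test_that("pairing follows CI overlap with a highest-LOD tie-break", {
  m <- as_merged(mrow("G1", "chrI", 150000, 6, 0.3,
                      ci_lo = 100000, ci_hi = 200000))
  p_overlap <- as_merged(mrow("G1", "chrI", 200000, 8, 0.25,
                              ci_lo = 150000, ci_hi = 250000))
  pr <- pair_qtls(m, p_overlap)
  expect_equal(pr$basis, "ci_overlap")
  expect_equal(nrow(pr), 1L)

  p_apart <- as_merged(mrow("G1", "chrI", 260000, 8, 0.25,
                            ci_lo = 210000, ci_hi = 300000))
  pr2 <- pair_qtls(m, p_apart)
  expect_equal(nrow(pr2), 2L)
  expect_true(all(pr2$basis == "single"))

  # one mRNA QTL overlapping two protein QTLs: the higher LOD wins
  p_two <- as_merged(
    mrow("G1", "chrI", 120000, 5, 0.25, ci_lo = 90000, ci_hi = 160000),
    mrow("G1", "chrI", 180000, 12, 0.25, ci_lo = 140000, ci_hi = 220000))
  pr3 <- pair_qtls(m, p_two)
  paired <- pr3[pr3$basis == "ci_overlap", ]
  expect_equal(paired$lod_protein, 12)
  expect_equal(sum(pr3$basis == "single"), 1L)

  # different genes never pair
  p_other <- as_merged(mrow("G2", "chrI", 150000, 8, 0.25))
  expect_true(all(pair_qtls(m, p_other)$basis == "single"))
})

test_that("curation overrides force pairs and specificity and must match a locus", {
  m <- as_merged(mrow("ARO8", "chrXV", 100000, 6, 0.3,
                      ci_lo = 80000, ci_hi = 120000))
  p <- as_merged(mrow("ARO8", "chrXV", 300000, 8, 0.25,
                      ci_lo = 280000, ci_hi = 320000))
  # no CI overlap: singles without curation, a pair with it
  expect_true(all(pair_qtls(m, p)$basis == "single"))
  ov <- data.frame(gene = "ARO8", chrom = "chrXV", status = "pair")
  pr <- pair_qtls(m, p, overrides = ov)
  expect_equal(pr$basis, "curation")
  expect_equal(nrow(pr), 1L)

  # forced mRNA-specific breaks an automatic pair
  m2 <- as_merged(mrow("GPD1", "chrV", 150000, 6, 0.3))
  p2 <- as_merged(mrow("GPD1", "chrV", 160000, 8, 0.25))
  ov2 <- data.frame(gene = "GPD1", chrom = "chrV",
                    status = "mRNA-specific")
  pr2 <- pair_qtls(m2, p2, overrides = ov2)
  expect_equal(nrow(pr2), 2L)
  expect_true(all(is.na(pr2$pos_protein) | is.na(pr2$pos_mrna)))

  expect_error(pair_qtls(m2, p2, overrides = data.frame(
    gene = "CYC1", chrom = "chrXIII", status = "pair")),
    "references no locus")
  # the packaged overrides list the six curated cases
  expect_equal(nrow(curation_overrides()), 6L)
  expect_equal(sum(curation_overrides()$status == "pair"), 4L)
})

test_that("classification keeps pairs with one sub-threshold member and splits by sign", {
  m <- as_merged(
    mrow("G1", "chrI", 150000, 6, 0.1),     # concordant with p1
    mrow("G1", "chrII", 150000, 6, -0.1),   # discordant with p2
    mrow("G1", "chrIII", 150000, 6, 0.3),   # mRNA-specific
    mrow("OLE1", "chrXI", 150000, 4.4, 0.2))  # below stringent alone
  p <- as_merged(
    mrow("G1", "chrI", 160000, 7, 0.2),
    mrow("G1", "chrII", 160000, 7, 0.2),
    mrow("G1", "chrIV", 150000, 6, -0.4),   # protein-specific
    mrow("OLE1", "chrXI", 160000, 15.5, 0.3))
  loci <- classify_loci(pair_qtls(m, p))
  expect_equal(nrow(loci), 5L)
  got <- loci$class[order(loci$chrom)]
  expect_setequal(loci$class, c("concordant", "discordant",
                                "mRNA-specific", "protein-specific"))
  # the OLE1-style pair (4.4 / 15.5) is retained as a pair
  ole <- loci[loci$gene == "OLE1", ]
  expect_equal(ole$class, "concordant")
  expect_false(is.na(ole$pos_mrna))
  # class counts partition the loci
  expect_equal(sum(table(loci$class)), nrow(loci))
  # order invariance
  pr <- pair_qtls(m, p)
  loci2 <- classify_loci(pr[rev(seq_len(nrow(pr))), ])
  expect_equal(sort(table(loci2$class)), sort(table(loci$class)))
})

test_that("weak loci are dropped and zero effects flagged", {
  m <- as_merged(mrow("G1", "chrI", 150000, 3.2, 0.1))
  p <- as_merged(mrow("G1", "chrI", 160000, 3.8, 0.2))
  expect_equal(nrow(classify_loci(pair_qtls(m, p))), 0L)

  m0 <- as_merged(mrow("G1", "chrI", 150000, 6, 0))
  expect_warning(loci <- classify_loci(pair_qtls(m0, p)),
                 "zero delta-AF")
  expect_true(is.na(loci$class[1]))
})

test_that("effects are extracted from the other channel at the locus peak", {
  m <- as_merged(mrow("G1", "chrI", 2550, 6, 0.35, ci_lo = 2000,
                      ci_hi = 3000))
  p <- as_merged(mrow("G1", "chrII", 1050, 6, -0.3, ci_lo = 500,
                      ci_hi = 1500))
  loci <- classify_loci(pair_qtls(m, p))
  # protein tracks flat at 0 on chrI; mRNA track 0.05 on chrII
  p_tracks <- list(`1` = rbind(toy_track(rep(1, 30), delta = rep(0, 30)),
                               toy_track(rep(1, 30), chrom = "chrII")))
  m_tracks <- list(`1` = rbind(toy_track(rep(1, 30)),
                               toy_track(rep(1, 30), chrom = "chrII",
                                         delta = rep(0.05, 30))))
  out <- effect_at_peak(loci, m_tracks, p_tracks)
  mrna_specific <- out[out$class == "mRNA-specific", ]
  expect_equal(mrna_specific$delta_af_protein, 0)
  expect_true(mrna_specific$extracted_protein)
  protein_specific <- out[out$class == "protein-specific", ]
  expect_equal(protein_specific$delta_af_mrna, 0.05)
  # identical tracks in both channels: the extracted value equals the
  # locus's own delta-AF
  id_tracks <- list(`1` = rbind(toy_track(rep(1, 30),
                                          delta = rep(0.35, 30)),
                                toy_track(rep(1, 30), chrom = "chrII",
                                          delta = rep(0.35, 30))))
  same <- effect_at_peak(loci, id_tracks, id_tracks)
  i <- same$class == "mRNA-specific"
  expect_equal(same$delta_af_protein[i], same$delta_af_mrna[i])
  # outside the track errors
  far <- loci
  far$pos_mrna <- 1e9
  far$chrom <- "chrZZ"
  expect_error(effect_at_peak(far, m_tracks, p_tracks), "outside")
})

test_that("direction agreement matches exact binomial enumeration", {
  mk_loci <- function(signs_m, signs_p) {
    n <- length(signs_m)
    structure(data.frame(
      gene = "G1", chrom = "chrI", class = "concordant",
      delta_af_mrna = signs_m * 0.2, delta_af_protein = signs_p * 0.2),
      class = c("classified_loci", "data.frame"))
  }
  all_same <- mk_loci(rep(1, 6), rep(1, 6))
  expect_equal(direction_agreement(all_same)$proportion, 1.0)

  half <- mk_loci(rep(1, 10), c(rep(1, 5), rep(-1, 5)))
  da <- direction_agreement(half)
  expect_equal(da$proportion, 0.5)
  expect_equal(da$p_value, 1.0)

  eight <- mk_loci(rep(1, 10), c(rep(1, 8), rep(-1, 2)))
  da8 <- direction_agreement(eight)
  expect_equal(da8$proportion, 0.8)
  expect_equal(da8$n, 10L)
  expect_equal(da8$p_value, bf_binom_two_sided(8, 10), tolerance = 1e-12)
  expect_equal(round(da8$p_value, 3), 0.109)

  none <- mk_loci(1, 1)[0, ]
  expect_warning(da0 <- direction_agreement(none), "no locus")
  expect_equal(da0$n, 0L)
})

test_that("effect correlations are strongest among concordant loci", {
  set.seed(12)
  n <- 20
  conc <- data.frame(gene = "G", chrom = "chrI", class = "concordant",
                     delta_af_mrna = rnorm(n, 0, 0.2))
  conc$delta_af_protein <- conc$delta_af_mrna + rnorm(n, 0, 0.02)
  spec <- data.frame(gene = "G", chrom = "chrI",
                     class = "protein-specific",
                     delta_af_mrna = rnorm(n, 0, 0.02),
                     delta_af_protein = rnorm(n, 0, 0.2))
  loci <- structure(rbind(conc, spec),
                    class = c("classified_loci", "data.frame"))
  ec <- effect_correlations(loci)
  r_conc <- ec$r[ec$group == "concordant"]
  r_spec <- ec$r[ec$group == "protein-specific"]
  expect_gt(r_conc, 0.9)
  expect_lt(abs(r_spec), 0.5)
})
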