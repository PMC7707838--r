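# IO: marker lists, count tables (TSV and VCF), BED regions, manifests,
# and the novel-variant screen.

test_that("TSV counts align to the marker list with zero-fill and drops", {
  ml <- marker_list(chrom = rep("chrI", 3), pos = c(100, 200, 300))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(counts_1chr(c(100, 200, 300), c(5, 9, 0), c(5, 1, 0)),
               path)
  pc <- read_counts(path, ml, min_median_depth = 0)
  expect_equal(pc$ref_count + pc$alt_count, c(10, 10, 0))

  # marker present in the file but absent from the list is dropped,
  # missing markers get zero depth
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(counts_1chr(c(100, 250), c(5, 7), c(5, 3)), path2)
  expect_warning(pc2 <- read_counts(path2, ml, min_median_depth = 0),
                 "not in the marker list")
  expect_equal(attr(pc2, "n_dropped"), 1L)
  expect_equal(pc2$pos, ml$pos)
  expect_equal(pc2$ref_count, c(5L, 0L, 0L))
})

test_that("VCF and TSV encodings round-trip to identical counts", {
  ml <- marker_list(chrom = rep(c("chrI", "chrII"), each = 3),
                    pos = rep(c(150, 900, 2500), 2),
                    ref = "A", alt = "G")
  set.seed(1)
  pc0 <- pooled_counts(ml$chrom, ml$pos, rbinom(6, 20, 0.5),
                       rbinom(6, 20, 0.5))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_counts(pc0, tsv, "tsv")
  write_counts(pc0, vcf, "vcf", markers = ml)
  from_tsv <- read_counts(tsv, ml, min_median_depth = 0)
  from_vcf <- read_counts(vcf, ml, min_median_depth = 0)
  expect_identical(from_tsv$ref_count, pc0$ref_count)
  expect_identical(from_tsv$alt_count, pc0$alt_count)
  expect_identical(from_vcf$ref_count, pc0$ref_count)
  expect_identical(from_vcf$alt_count, pc0$alt_count)
  expect_identical(from_vcf[, 1:4], from_tsv[, 1:4])
})

test_that("allele mismatches against the marker list are dropped with a warning", {
  ml <- marker_list(chrom = rep("chrI", 2), pos = c(100, 200),
                    ref = c("A", "T"), alt = c("G", "C"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  wrong <- marker_list(chrom = rep("chrI", 2), pos = c(100, 200),
                       ref = c("A", "G"), alt = c("G", "C"))
  write_counts(counts_1chr(c(100, 200), c(4, 6), c(6, 4)), vcf, "vcf",
               markers = wrong)
  expect_warning(pc <- read_counts(vcf, ml, min_median_depth = 0),
                 "alleles differing")
  expect_equal(pc$ref_count, c(4L, 0L))
})

test_that("malformed counts are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref_count\talt_count",
               "chrI\t100\t5\t5",
               "chrI\t200\t-3\t5"), path)
  expect_error(read_counts(path, min_median_depth = 0), "line 3")
})

test_that("low-coverage pools are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(counts_1chr(c(100, 200, 300), c(1, 0, 0), c(0, 1, 0)),
               path)
  expect_error(read_counts(path), "median depth")
})

test_that("BED regions convert between 0-based and 1-based coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_region_bed(region("chrXIV", 350000, 550000), path)
  raw <- read.table(path, sep = "\t")
  expect_equal(raw[[2]], 349999)
  rg <- read_region_bed(path)
  expect_equal(rg$start, 350000)
  expect_equal(rg$end, 550000)
})

test_that("marker lists and manifests round-trip", {
  ml <- marker_list(chrom = c("chrI", "chrI", "chrII"),
                    pos = c(10, 20, 5), ref = c("A", "C", "G"),
                    alt = c("T", "G", "A"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_marker_list(ml, p)
  expect_equal(read_marker_list(p), ml)
  expect_error(marker_list(c("chrI", "chrI"), c(20, 10)), "sorted")
  expect_error(marker_list(c("chrI", "chrI"), c(10, 10)), "duplicate")

  mf <- data.frame(file = "a.tsv", gene = "GPD1", channel = "mRNA",
                   gate = "high", replicate = 1, batch = 1)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(mf, p2)
  expect_equal(read_manifest(p2), mf)
})

make_pvm <- function() {
  # 10 sites x 8 populations; groups: A (pops 1-5), B (pops 6-8)
  sites <- data.frame(chrom = "chrX", pos = seq(1000, 10000, by = 1000),
                      ref = "G", alt = "A",
                      quality = c(50, 50, 20, 50, 50, 50, 50, 50, 10, 60))
  af <- matrix(0, 10, 8)
  af[1, ] <- 0.5            # known variant, everywhere
  af[2, 1:2] <- 0.4         # in exactly 2 populations: error
  af[3, ] <- 0.5            # low quality
  af[4, 1:5] <- 0.6         # planted: all of group A, none of B
  af[5, c(1, 4, 7)] <- 0.3  # 3 populations, mixed groups
  af[9, 1:6] <- 0.5         # low quality
  cov <- matrix(20L, 10, 8)
  population_variant_matrix(sites, af, cov)
}

test_that("the novel-variant screen applies the full filter cascade", {
  pvm <- make_pvm()
  known <- marker_list("chrX", 1000)
  groups <- rep(c("A", "B"), c(5, 3))
  out <- novel_variant_screen(pvm, known, design_groups = groups)
  expect_false(1000 %in% out$pos)            # known excluded
  expect_false(2000 %in% out$pos)            # 2-population error excluded
  expect_false(3000 %in% out$pos)            # below quality 30
  expect_true(all(c(4000, 5000) %in% out$pos))
  # the planted group-private variant is the unique candidate with
  # group-A fraction 1.0 and group-B fraction 0
  hit <- out[out$frac_A == 1 & out$frac_B == 0, ]
  expect_equal(hit$pos, 4000)
  expect_equal(hit$n_populations, 5L)
})

test_that("the screen is monotone in the quality cutoff", {
  pvm <- make_pvm()
  known <- marker_list("chrX", 1000)
  qs <- c(0, 15, 30, 55, 70)
  ns <- vapply(qs, function(q)
    nrow(novel_variant_screen(pvm, known, min_quality = q)), 0L)
  expect_true(all(diff(ns) <= 0))
  # raising the cutoff never adds variants
  lower <- novel_variant_screen(pvm, known, min_quality = 30)
  higher <- novel_variant_screen(pvm, known, min_quality = 55)
  expect_true(all(higher$pos %in% lower$pos))
})

test_that("an empty matrix screens to an empty result", {
  sites <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      quality = numeric())
  pvm <- population_variant_matrix(sites, matrix(0, 0, 3),
                                   matrix(0L, 0, 3))
  out <- novel_variant_screen(pvm, marker_list("chrX", 1))
  expect_equal(nrow(out), 0L)
})
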