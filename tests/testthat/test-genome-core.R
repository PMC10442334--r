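test_that("layout validation rejects duplicates and non-positive lengths", {
  expect_error(genome_layout(c("chr1", "chr1"), c(10, 20)), "unique")
  expect_error(genome_layout("chr1", 0), "positive")
  expect_s3_class(default_layout(), "genome_layout")
})

test_that("peak normalization validates coordinates and names chromosomes", {
  lay <- toy_layout(1000)
  expect_error(normalize_peaks(peaks("chrX", 0, 10), lay), "chrX")
  expect_error(normalize_peaks(peaks("chr1", 0, 2000), lay), "length")
  p <- normalize_peaks(peaks("chr1", c(500, 0), c(600, 100)), lay)
  expect_equal(p$start, c(0, 500))
})

test_that("overlap components match the spec examples", {
  lay <- toy_layout(100)
  a <- peaks("chr1", c(0, 20), c(10, 30))
  b <- peaks("chr1", c(5, 25, 40), c(15, 28, 50))
  ov <- peak_intersect(a, b, lay)
  expect_equal(length(unique(ov$component)), 2)
  expect_false(3 %in% ov$.row[ov$set == "b"]) # [40,50) unmatched
  # empty set -> no components
  expect_equal(nrow(peak_intersect(a[0, ], b, lay)), 0)
  # identical 3-peak sets -> 3 components, all matched
  p3 <- peaks("chr1", c(0, 20, 40), c(10, 30, 50))
  ov3 <- peak_intersect(p3, p3, lay)
  expect_equal(length(unique(ov3$component)), 3)
  expect_equal(sort(unique(ov3$.row)), 1:3)
  expect_error(peak_intersect(peaks("chrZ", 0, 5), b, lay), "chrZ")
})

test_that("overlap components equal the union-find oracle on random sets", {
  lay <- toy_layout(10000)
  withr::with_seed(42, {
    for (i in 1:60) {
      a <- random_peaks(sample(0:12, 1))
      b <- random_peaks(sample(0:12, 1))
      ov <- peak_intersect(a, b, lay)
      oc <- oracle_components(a, b)
      expect_equal(length(unique(ov$component)), oc$n_components)
      expect_equal(sort(unique(ov$.row[ov$set == "a"])), oc$a_matched)
      expect_equal(sort(unique(ov$.row[ov$set == "b"])), oc$b_matched)
    }
  })
})

test_that("merge obeys its contract and the per-base oracle", {
  lay <- toy_layout(100)
  expect_equal(peak_merge(peaks("chr1", c(0, 5), c(10, 20)), lay)$end, 20)
  d <- peaks("chr1", c(0, 50), c(10, 60))
  expect_equal(peak_merge(d, lay), d[, c("chrom", "start", "end")])
  g <- peak_merge(peaks("chr1", c(0, 12), c(10, 20)), lay, gap = 2)
  expect_equal(g, peaks("chr1", 0, 20))
  expect_error(peak_merge(d, lay, gap = -1), "non-negative")
  lay10k <- toy_layout(10000)
  withr::with_seed(7, {
    for (i in 1:40) {
      x <- random_peaks(sample(1:10, 1))
      gap <- sample(0:30, 1)
      expect_equal(peak_merge(x, lay10k, gap = gap), oracle_merge(x, gap))
    }
  })
})

test_that("merge is idempotent and coverage ignores ordering/duplication", {
  lay <- toy_layout(10000)
  withr::with_seed(11, {
    x <- random_peaks(15)
    m1 <- peak_merge(x, lay)
    expect_equal(peak_merge(m1, lay), m1)
    shuffled <- x[sample(nrow(x)), ]
    dup <- rbind(x, x[1:5, ])
    expect_equal(peak_coverage_fraction(x, lay),
                 peak_coverage_fraction(shuffled, lay))
    expect_equal(peak_coverage_fraction(x, lay),
                 peak_coverage_fraction(dup, lay))
  })
})

test_that("coverage fraction handles empty, tiling and partial sets", {
  lay <- toy_layout(1000)
  expect_equal(peak_coverage_fraction(peaks(character(), numeric(),
                                            numeric())[0, ], lay), 0)
  expect_equal(peak_coverage_fraction(peaks("chr1", 0, 1000), lay), 1)
  expect_equal(peak_coverage_fraction(peaks("chr1", 0, 100), lay), 0.1)
})

test_that("mean signal is the length-weighted bin mean", {
  lay <- toy_layout(20)
  tr <- binned_track(lay, 10, values = list(chr1 = c(1, 3)))
  expect_equal(mean_signal(tr, peaks("chr1", 5, 15)), 2.0)
  expect_equal(mean_signal(tr, peaks("chr1", 10, 20)), 3)
  const <- binned_track(lay, 10, values = list(chr1 = c(4, 4)))
  expect_equal(mean_signal(const, peaks("chr1", 3, 17)), 4)
  # whole genome equals the bin-weighted global mean
  lay2 <- toy_layout(25)
  tr2 <- binned_track(lay2, 10, values = list(chr1 = c(1, 5, 9)))
  expect_equal(mean_signal(tr2, peaks("chr1", 0, 25)),
               (1 * 10 + 5 * 10 + 9 * 5) / 25)
  # random intervals vs per-base oracle
  withr::with_seed(3, {
    vals <- rpois(1000, 5)
    tr3 <- binned_track(toy_layout(10000), 10, values = list(chr1 = vals))
    for (i in 1:25) {
      s <- sample(0:9900, 1); w <- sample(1:99, 1)
      expect_equal(mean_signal(tr3, peaks("chr1", s, s + w)),
                   oracle_mean_signal(vals, 10, s, s + w))
    }
  })
})

test_that("random region sampling is deterministic, valid and uniform", {
  lay <- toy_layout(10000)
  r1 <- sample_random_regions(lay, 50, c(100, 200), seed = 5)
  r2 <- sample_random_regions(lay, 50, c(100, 200), seed = 5)
  expect_identical(r1, r2)
  expect_true(all((r1$end - r1$start) %in% c(100, 200)))
  expect_true(all(r1$start >= 0 & r1$end <= 10000))
  # forced placement
  one <- genome_layout("chr1", 1000)
  expect_equal(sample_random_regions(one, 1, 1000, seed = 1),
               peaks("chr1", 0, 1000))
  # n = 0 is an empty set, not an error
  expect_equal(nrow(sample_random_regions(lay, 0, 100, seed = 1)), 0)
  # uniformity of unit-length starts (chi-square GOF)
  u <- sample_random_regions(lay, 10000, 1, seed = 9)
  cnt <- table(cut(u$start, breaks = seq(0, 10000, by = 1000),
                   include.lowest = TRUE, right = FALSE))
  expect_gt(stats::chisq.test(as.vector(cnt))$p.value, 0.001)
})

test_that("subtraction matches the per-base oracle", {
  lay <- toy_layout(10000)
  expect_equal(peak_subtract(peaks("chr1", 0, 100),
                             peaks("chr1", 50, 150), lay),
               peaks("chr1", 0, 50))
  withr::with_seed(13, {
    for (i in 1:40) {
      x <- random_peaks(sample(1:8, 1))
      y <- random_peaks(sample(0:8, 1))
      expect_equal(peak_subtract(x, y, lay), oracle_subtract(x, y, 10000))
    }
  })
})

test_that("standard formats round-trip through the readers", {
  lay <- default_layout(2, 50000)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.chrom.sizes")
  write_chrom_sizes(lay, f1)
  expect_equal(read_chrom_sizes(f1), lay)
  pk <- peaks(c("chr1", "chr2"), c(100, 0), c(400, 900),
              name = c("p1", "p2"), score = c(1.5, 2))
  f2 <- file.path(dir, "a.bed")
  write_bed(pk, f2)
  expect_equal(read_bed(f2), pk)
  tr <- binned_track(lay, 1000)
  withr::with_seed(1, tr$value <- rpois(nrow(tr), 3))
  f3 <- file.path(dir, "a.bedgraph")
  write_bedgraph(tr, f3)
  back <- read_bedgraph(f3, lay, 1000)
  expect_equal(back$value, tr$value)
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 10000,
                        clone = "clone_1", copy_number = 3.5)
  f4 <- file.path(dir, "a.seg")
  write_seg(seg, f4)
  expect_equal(read_seg(f4), seg)
})
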