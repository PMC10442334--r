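mk_comp <- function(pc1, density = NULL, reps = 2) {
  n <- length(pc1)
  x <- tibble::tibble(chrom = "chr1", start = (0:(n - 1)) * 250000,
                      end = (1:n) * 250000,
                      gene_density = density %||% pmax(0, 3 + 2 * pc1))
  for (r in seq_len(reps)) x[[paste0("ctrl_rep", r)]] <- pc1
  for (r in seq_len(reps)) x[[paste0("kd_rep", r)]] <- pc1
  x
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("PC1 orientation flips only anti-correlated chromosomes", {
  pc1 <- c(0.8, 0.6, -0.5, -0.9, 0.4)
  x <- mk_comp(pc1)
  # already positively correlated -> unchanged
  o1 <- orient_pc1(x)
  expect_equal(o1$ctrl_rep1, pc1)
  expect_equal(attr(o1, "flipped"), character(0))
  # negated input restores the original (involution)
  neg <- x
  for (cc in c("ctrl_rep1", "ctrl_rep2", "kd_rep1", "kd_rep2")) {
    neg[[cc]] <- -neg[[cc]]
  }
  o2 <- orient_pc1(neg)
  expect_equal(o2$ctrl_rep1, pc1)
  expect_equal(attr(o2, "flipped"), "chr1")
  # errors: no usable gene density, zero-variance PC1
  bad <- x
  bad$gene_density <- 0
  expect_error(orient_pc1(bad), "gene_density")
  flat <- mk_comp(rep(0.5, 5), density = runif(5, 1, 5))
  expect_error(orient_pc1(flat), "zero-variance")
})

test_that("post-orientation correlation is non-negative on every chromosome", {
  withr::with_seed(41, {
    for (i in 1:15) {
      n <- 12
      base <- rnorm(n)
      x <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = n / 2),
                          start = rep((0:(n / 2 - 1)) * 250000, 2),
                          end = rep((1:(n / 2)) * 250000, 2),
                          gene_density = pmax(0, 3 + sample(c(-2, 2), 1) * base +
                                                rnorm(n, 0, 0.2)))
      x$ctrl_rep1 <- base + rnorm(n, 0, 0.05)
      x$ctrl_rep2 <- base + rnorm(n, 0, 0.05)
      o <- orient_pc1(x, pc1_cols = c("ctrl_rep1", "ctrl_rep2"))
      for (ch in unique(o$chrom)) {
        i2 <- o$chrom == ch
        m <- rowMeans(o[i2, c("ctrl_rep1", "ctrl_rep2")])
        expect_gte(cor(m, o$gene_density[i2]), 0)
      }
    }
  })
})

test_that("bin classification reproduces the hand-computed t-tests", {
  x <- tibble::tibble(chrom = "chr1", start = 0, end = 250000,
                      gene_density = 5,
                      c1 = 2.0, c2 = 2.2, k1 = 1.0, k2 = 1.1)
  out <- classify_bins(x, c("c1", "c2"), c("k1", "k2"))
  expect_equal(out$p_ttest, 0.0111, tolerance = 0.01)
  expect_equal(out$category, "A-weakened")
  x2 <- x
  x2[, c("c1", "c2", "k1", "k2")] <- list(1.5, 1.6, -1.0, -1.2)
  expect_equal(classify_bins(x2, c("c1", "c2"), c("k1", "k2"))$category,
               "A-to-B")
  # knockdown identical to control -> every bin unchanged
  x3 <- mk_comp(c(0.8, -0.5, 0.3, -0.9))
  out3 <- classify_bins(x3, c("ctrl_rep1", "ctrl_rep2"),
                        c("kd_rep1", "kd_rep2"))
  expect_true(all(out3$category == "unchanged"))
})

test_that("bin categories partition and match t.test on random tables", {
  withr::with_seed(43, {
    n <- 30
    x <- tibble::tibble(chrom = "chr1", start = (0:(n - 1)) * 250000,
                        end = (1:n) * 250000, gene_density = runif(n, 1, 6))
    base <- rnorm(n)
    for (cc in c("c1", "c2", "c3")) x[[cc]] <- base + rnorm(n, 0, 0.3)
    shift <- base + rnorm(n, 0, 0.8)
    for (cc in c("k1", "k2", "k3")) x[[cc]] <- shift + rnorm(n, 0, 0.3)
    out <- classify_bins(x, c("c1", "c2", "c3"), c("k1", "k2", "k3"))
    expect_equal(sum(table(out$category)), n)
    for (i in seq_len(n)) {
      tt <- t.test(unlist(x[i, c("c1", "c2", "c3")]),
                   unlist(x[i, c("k1", "k2", "k3")]), var.equal = TRUE)
      expect_equal(out$p_ttest[i], tt$p.value)
      if (tt$p.value >= 0.05) expect_equal(out$category[i], "unchanged")
    }
  })
})

test_that("classification is equivariant under sign flip plus reorientation", {
  withr::with_seed(44, {
    n <- 20
    base <- rnorm(n, 0, 1)
    x <- tibble::tibble(chrom = "chr1", start = (0:(n - 1)) * 250000,
                        end = (1:n) * 250000,
                        gene_density = pmax(0, 3 + 2 * base))
    x$ctrl_rep1 <- base + rnorm(n, 0, 0.1)
    x$ctrl_rep2 <- base + rnorm(n, 0, 0.1)
    x$kd_rep1 <- base * 0.5 + rnorm(n, 0, 0.1)
    x$kd_rep2 <- base * 0.5 + rnorm(n, 0, 0.1)
  })
  cols <- c("ctrl_rep1", "ctrl_rep2", "kd_rep1", "kd_rep2")
  a <- classify_bins(orient_pc1(x), cols[1:2], cols[3:4])
  flipped <- x
  flipped[, cols] <- -flipped[, cols]
  b <- classify_bins(orient_pc1(flipped), cols[1:2], cols[3:4])
  expect_equal(a$category, b$category)
  expect_equal(a$p_ttest, b$p_ttest)
})

test_that("N1 counting per bin matches a brute-force membership oracle", {
  lay <- toy_layout(2e6)
  n <- 8
  change <- tibble::tibble(chrom = "chr1", start = (0:(n - 1)) * 250000,
                           end = (1:n) * 250000, mean_ctrl = 0.5,
                           mean_kd = 0.5, p_ttest = 1,
                           category = rep(c("unchanged", "A-weakened"),
                                          each = 4))
  class(change) <- c("compartment_change", class(change))
  withr::with_seed(45, {
    n1 <- peaks("chr1", s <- sample(0:(2e6 - 5000), 40), s + 4000)
  })
  enr <- n1_enrichment(change, n1, lay)
  for (i in seq_len(n)) {
    want <- sum(n1$start < change$end[i] & n1$end > change$start[i])
    expect_equal(enr$n1_count[i], want)
  }
  # a boundary-spanning peak is counted in both bins it overlaps
  span <- peaks("chr1", 249000, 251000)
  enr2 <- n1_enrichment(change, span, lay)
  expect_equal(enr2$n1_count[1:2], c(1L, 1L))
  # midpoint assignment conserves the total count
  enr3 <- n1_enrichment(change, n1, lay, midpoint = TRUE)
  expect_equal(sum(enr3$n1_count), nrow(n1))
  # empty N1 set: all-zero distributions, nothing significant
  enr4 <- n1_enrichment(change, n1[0, ], lay)
  expect_true(all(enr4$n1_count == 0))
  tests <- attr(enr4, "tests")
  expect_true(all(tests$p_vs_unchanged[tests$tested] == 1 |
                    is.na(tests$p_vs_unchanged)))
})

test_that("planted weakened-A enrichment of N1 peaks is detected", {
  study <- simulate_study(simulation_config(seed = 6))
  res <- analyze_study(study, stages = c(colocalization = FALSE,
                                         differential = TRUE, origins = FALSE,
                                         compartments = TRUE, aux = FALSE))
  tests <- attr(res$compartments$enrichment, "tests")
  p <- tests$p_vs_unchanged[tests$category == "A-weakened"]
  expect_lt(p, 0.05)
  # planted weakened bins are recovered as A-weakened
  ch <- res$compartments$change
  planted <- study$truth$weakened_bins
  hit <- paste(ch$chrom, ch$start) %in% paste(planted$chrom, planted$start)
  expect_gte(mean(ch$category[hit] == "A-weakened"), 0.8)
})
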