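#' Merge intervals closer than a gap
#'
#' Collapses a peak table so that output intervals are pairwise disjoint
#' with separation greater than `gap` bp. With `gap = 0`, touching or
#' overlapping intervals merge and the base-pair union is preserved.
#'
#' @param x A peak data frame.
#' @param layout Optional [genome_layout()] for validation/ordering.
#' @param gap Non-negative separation (bp) at or below which intervals merge.
#' @return A sorted peak tibble of disjoint intervals.
#' @export
#' @examples
#' peak_merge(peaks("chr1", c(0, 12), c(10, 20)), gap = 2)
peak_merge <- function(x, layout = NULL, gap = 0) {
  if (gap < 0) stop("gap must be non-negative", call. = FALSE)
  if (nrow(x) == 0) return(tibble::as_tibble(x)[, c("chrom", "start", "end")])
  gr <- peaks_to_gr(x, layout)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1)
  gr_to_peaks(red)
}

#' Overlap components between two peak sets
#'
#' Builds the graph whose vertices are the intervals of both sets and whose
#' edges join any two intervals sharing at least 1 bp, and returns its
#' connected components that contain at least one member of each set. This
#' is the unit in which co-binding ("overlapping peaks") is counted, so one
#' number serves against both set sizes.
#'
#' @param a,b Peak data frames on the same layout.
#' @param layout A [genome_layout()].
#' @return A tibble with one row per matched interval: `component` (id),
#'   `set` ("a"/"b"), `.row` (row index in the originating table), `chrom`,
#'   `start`, `end`. Intervals of either set overlapping nothing in the
#'   other set are absent.
#' @export
peak_intersect <- function(a, b, layout) {
  check_chroms(a$chrom, layout)
  check_chroms(b$chrom, layout)
  all <- dplyr::bind_rows(
    tibble::tibble(set = "a", .row = seq_len(nrow(a)),
                   chrom = a$chrom, start = a$start, end = a$end),
    tibble::tibble(set = "b", .row = seq_len(nrow(b)),
                   chrom = b$chrom, start = b$start, end = b$end)
  )
  if (nrow(all) == 0) {
    return(tibble::tibble(component = integer(), set = character(),
                          .row = integer(), chrom = character(),
                          start = numeric(), end = numeric()))
  }
  gr <- peaks_to_gr(all, layout)
  # connected components of the >=1 bp overlap graph are exactly the
  # overlap-only (min.gapwidth = 0) reduction blobs
  blobs <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, blobs, minoverlap = 1L)
  comp <- integer(nrow(all))
  comp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  all$component <- comp
  keep <- all |>
    dplyr::group_by(.data$component) |>
    dplyr::filter(dplyr::n_distinct(.data$set) == 2) |>
    dplyr::ungroup()
  # renumber components consecutively in genomic order
  keep$component <- match(keep$component, sort(unique(keep$component)))
  keep[order(keep$component, keep$set, keep$.row),
       c("component", "set", ".row", "chrom", "start", "end")]
}

#' Base-pair subtraction of one peak set from another
#'
#' @param x,y Peak data frames; the merged base pairs of `y` are removed
#'   from the merged base pairs of `x`.
#' @param layout A [genome_layout()].
#' @return Peak tibble of residual intervals.
#' @export
peak_subtract <- function(x, y, layout) {
  if (nrow(x) == 0) return(tibble::as_tibble(x)[, c("chrom", "start", "end")])
  grx <- GenomicRanges::reduce(peaks_to_gr(x, layout))
  if (nrow(y) == 0) return(gr_to_peaks(grx))
  gry <- GenomicRanges::reduce(peaks_to_gr(y, layout))
  gr_to_peaks(GenomicRanges::setdiff(grx, gry))
}

#' Fraction of the genome covered by a peak set
#'
#' Merged covered base pairs divided by total genome size.
#'
#' @param x A peak data frame.
#' @param layout A [genome_layout()].
#' @return A number in \[0, 1\].
#' @export
peak_coverage_fraction <- function(x, layout) {
  if (nrow(x) == 0) return(0)
  merged <- peak_merge(x, layout)
  sum(merged$end - merged$start) / sum(layout$length)
}

#' Sample random genomic regions
#'
#' Draws `n` intervals whose lengths come from `lengths` (with replacement
#' by default; with `replace = FALSE` the supplied multiset is used exactly,
#' in shuffled order) and whose start positions are uniform over all valid
#' placements across the genome. Deterministic given `seed`.
#'
#' @param layout A [genome_layout()].
#' @param n Number of regions.
#' @param lengths Candidate region lengths (bp).
#' @param seed Integer seed.
#' @param replace Sample lengths with replacement (default TRUE).
#' @return A peak tibble with `n` rows.
#' @export
sample_random_regions <- function(layout, n, lengths, seed, replace = TRUE) {
  if (n == 0) return(peaks(character(), numeric(), numeric())[0, ])
  if (max(lengths) > max(layout$length)) {
    stop("region length exceeds the longest chromosome", call. = FALSE)
  }
  lengths <- as.numeric(lengths)
  withr::with_seed(seed, {
    if (replace) {
      len <- lengths[sample.int(length(lengths), n, replace = TRUE)]
    } else {
      stopifnot(length(lengths) == n)
      len <- lengths[sample.int(n)]
    }
    chrom <- character(n)
    start <- numeric(n)
    for (u in unique(len)) {
      idx <- which(len == u)
      valid <- pmax(0, layout$length - u + 1)
      total <- sum(valid)
      if (total == 0) stop("no valid placement for length ", u, call. = FALSE)
      pos <- ceiling(stats::runif(length(idx)) * total) # 1..total uniform
      cum <- cumsum(valid)
      ci <- findInterval(pos - 1, cum) + 1 # chromosome index
      offset <- pos - c(0, cum)[ci] - 1 # 0-based start within chrom
      chrom[idx] <- layout$chrom[ci]
      start[idx] <- offset
    }
    peaks(chrom, start, start + len)
  })
}
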