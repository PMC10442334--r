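#' Venn-style overlap counts between two peak sets
#'
#' Counts the overlap components (connected components of the pairwise
#' >= 1 bp overlap graph that contain members of both sets) together with
#' the number of matched peaks per set. The single component count is the
#' figure reported against both set sizes.
#'
#' @param a,b Peak data frames on a shared layout.
#' @param layout A [genome_layout()].
#' @return A one-row tibble of class `venn_counts`: `n_a`, `n_b`,
#'   `n_overlap_components`, `n_a_matched`, `n_b_matched`.
#' @export
overlap_venn <- function(a, b, layout) {
  ov <- peak_intersect(a, b, layout)
  out <- tibble::tibble(
    n_a = nrow(a),
    n_b = nrow(b),
    n_overlap_components = dplyr::n_distinct(ov$component),
    n_a_matched = dplyr::n_distinct(ov$.row[ov$set == "a"]),
    n_b_matched = dplyr::n_distinct(ov$.row[ov$set == "b"])
  )
  class(out) <- c("venn_counts", class(out))
  out
}

#' Overlap percentages of a Venn count
#'
#' Reports `100 * n_overlap_components / n_a` (and `/ n_b`) both at full
#' precision and truncated at the displayed precision — truncation, not
#' rounding, is the reporting convention (62.84 prints as 62).
#'
#' @param v A `venn_counts` row from [overlap_venn()].
#' @param digits Decimal digits kept by truncation (default 0).
#' @return A one-row tibble: `pct_a`, `pct_b` (truncated), `pct_a_full`,
#'   `pct_b_full`.
#' @export
#' @examples
#' v <- tibble::tibble(n_a = 27579, n_b = 22915, n_overlap_components = 14400)
#' venn_percentages(v) # 52, 62
venn_percentages <- function(v, digits = 0) {
  if (v$n_a == 0 || v$n_b == 0) {
    stop("venn percentages need non-empty peak sets", call. = FALSE)
  }
  pa <- 100 * v$n_overlap_components / v$n_a
  pb <- 100 * v$n_overlap_components / v$n_b
  tibble::tibble(pct_a = truncate_pct(pa, digits),
                 pct_b = truncate_pct(pb, digits),
                 pct_a_full = pa, pct_b_full = pb)
}

#' Random-region permutation null for peak overlap
#'
#' For each draw, samples as many random regions as there are reference
#' peaks — reusing the reference length multiset exactly, placed uniformly
#' over the genome — and records the percentage of sampled regions
#' overlapping the target set by >= 1 bp. The empirical median over draws
#' is the null expectation quoted against the observed overlap.
#'
#' @param reference Peak data frame whose size and length multiset are
#'   matched by each null draw.
#' @param target Peak data frame overlapped against.
#' @param layout A [genome_layout()].
#' @param n_draws Number of null draws (default 10).
#' @param seed Integer seed; draw `i` uses an independent substream.
#' @return A tibble of class `null_overlap` with columns `draw`,
#'   `pct_overlap`, and attribute `median_pct`.
#' @export
permutation_overlap_null <- function(reference, target, layout,
                                     n_draws = 10, seed = 1) {
  stopifnot(n_draws >= 1)
  lens <- reference$end - reference$start
  tgr <- if (nrow(target) > 0) peaks_to_gr(target, layout) else NULL
  pct <- vapply(seq_len(n_draws), function(i) {
    rs <- sample_random_regions(layout, length(lens), lens,
                                seed = substream_seed(seed, i),
                                replace = FALSE)
    if (is.null(tgr)) return(0)
    hits <- GenomicRanges::countOverlaps(peaks_to_gr(rs, layout), tgr,
                                         minoverlap = 1L)
    100 * mean(hits > 0)
  }, numeric(1))
  out <- tibble::tibble(draw = seq_len(n_draws), pct_overlap = pct)
  attr(out, "median_pct") <- stats::median(pct)
  class(out) <- c("null_overlap", class(out))
  out
}

#' @method glance null_overlap
#' @export
glance.null_overlap <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x),
                 median_pct = attr(x, "median_pct"),
                 min_pct = min(x$pct_overlap),
                 max_pct = max(x$pct_overlap))
}

#' @method tidy venn_counts
#' @export
tidy.venn_counts <- function(x, ...) {
  p <- venn_percentages(x)
  tibble::as_tibble(cbind(as.data.frame(x), as.data.frame(p)))
}

#' @method glance venn_counts
#' @export
glance.venn_counts <- function(x, ...) tidy.venn_counts(x)

#' Plot the null overlap distribution
#'
#' Histogram of per-draw null overlap percentages with the median marked.
#'
#' @param object A `null_overlap` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot null_overlap
#' @export
autoplot.null_overlap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pct_overlap)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = attr(object, "median_pct"),
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "random-region overlap (%)", y = "draws",
                  title = "Permutation overlap null")
}
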