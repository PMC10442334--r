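#' Nucleosome-occupancy R-value of an EM trace
#'
#' The R-value of a stretched DNA molecule imaged by electron microscopy is
#' the combined contour length of all nucleosome bubbles divided by the
#' overall contour length of the same DNA stretch; a reduced R-value means
#' reduced nucleosome density. The statistic is scale-invariant: nm and
#' bp-equivalent contour units give the same value.
#'
#' @param bubble_lengths Numeric vector (or list of vectors, one per trace)
#'   of bubble contour lengths; each length > 0.
#' @param total_length Total contour length per trace.
#' @return Numeric R-value(s) in \[0, 1\].
#' @export
#' @examples
#' r_value(c(50, 25), 200) # 0.375
r_value <- function(bubble_lengths, total_length) {
  if (!is.list(bubble_lengths)) bubble_lengths <- list(bubble_lengths)
  s <- vapply(bubble_lengths, sum, numeric(1))
  total_length <- rep_len(total_length, length(s))
  if (any(s > total_length + 1e-9)) {
    stop("combined bubble length exceeds total contour length", call. = FALSE)
  }
  unname(s / total_length)
}

#' Add R-values to a table of EM traces
#'
#' @param traces Tibble with a `bubble_lengths` list-column and a
#'   `total_length` column (as produced by [simulate_em_traces()]).
#' @return `traces` with an `r_value` column.
#' @export
em_r_values <- function(traces) {
  traces$r_value <- r_value(traces$bubble_lengths, traces$total_length)
  traces
}

#' Label copy-number segments as gain/loss/neutral
#'
#' Diploid baseline 2; thresholds are configuration, not biology: the
#' defaults call > 2.3 a gain and < 1.7 a loss.
#'
#' @param seg Segment tibble: `chrom`, `start`, `end`, `clone`,
#'   `copy_number`.
#' @param gain_threshold,loss_threshold Copy-number call thresholds.
#' @return `seg` with a `class` column (`"gain"`, `"loss"`, `"neutral"`).
#' @export
classify_cna_segments <- function(seg, gain_threshold = 2.3,
                                  loss_threshold = 1.7) {
  seg$class <- dplyr::case_when(
    seg$copy_number > gain_threshold ~ "gain",
    seg$copy_number < loss_threshold ~ "loss",
    TRUE ~ "neutral"
  )
  seg
}

#' Subtract spontaneous control gains from sample gains
#'
#' Removes, at base-pair resolution, the merged gain intervals of the
#' control from each clone's gain intervals, leaving only gains attributable
#' to the perturbation.
#'
#' @param sample_seg Classified segment tibble (see
#'   [classify_cna_segments()]) for the perturbed clones.
#' @param control_seg Classified segment tibble for control cells.
#' @param layout A [genome_layout()].
#' @return Tibble of residual gain intervals with a `clone` column.
#' @export
subtract_control_gains <- function(sample_seg, control_seg, layout) {
  if (!"class" %in% names(sample_seg)) {
    stop("segments must be classified first (classify_cna_segments)",
         call. = FALSE)
  }
  ctrl_gain <- control_seg[control_seg$class == "gain", , drop = FALSE]
  out <- sample_seg[sample_seg$class == "gain", , drop = FALSE] |>
    dplyr::group_by(.data$clone) |>
    dplyr::group_modify(function(d, key) {
      peak_subtract(d, ctrl_gain, layout)
    }) |>
    dplyr::ungroup()
  out[, c("chrom", "start", "end", "clone")]
}

#' Recurrent amplification regions across clones
#'
#' Maximal regions gained in at least `min_clones` clones (per-clone gains
#' are merged first so a clone counts at most once per base).
#'
#' @param gains Tibble of gain intervals with a `clone` column (e.g. the
#'   output of [subtract_control_gains()]).
#' @param layout A [genome_layout()].
#' @param min_clones Minimum number of clones sharing a gain (default 2).
#' @return Peak tibble of recurrent regions (empty, with a warning, when
#'   `min_clones` exceeds the number of clones).
#' @export
recurrent_amplifications <- function(gains, layout, min_clones = 2) {
  clones <- unique(gains$clone)
  if (min_clones > length(clones)) {
    warning("min_clones exceeds the number of clones; returning empty set")
    return(peaks(character(), numeric(), numeric())[0, ])
  }
  per_clone <- lapply(clones, function(cl) {
    peaks_to_gr(peak_merge(gains[gains$clone == cl, , drop = FALSE], layout),
                layout)
  })
  cov <- Reduce(`+`, lapply(per_clone, GenomicRanges::coverage))
  sl <- IRanges::slice(cov, lower = min_clones, rangesOnly = TRUE)
  res <- GenomicRanges::GRanges(sl)
  gr_to_peaks(res)
}

#' Co-occurrence of locus amplifications with NFIB amplification
#'
#' Per locus, a one-sided Fisher exact test (alternative: co-amplification)
#' on the 2x2 table of locus amplification vs NFIB amplification across
#' patients, with BH adjustment across loci.
#'
#' @param m Cohort matrix tibble: one row per patient, a logical
#'   `nfib_amplified` column (name via `nfib_col`), and one logical column
#'   per locus.
#' @param nfib_col Name of the NFIB amplification flag column.
#' @return A tibble of class `cooccurrence_table`: `locus`, `n_both`,
#'   `odds_direction` (+1 co-occurring, -1 mutually exclusive, 0 neutral),
#'   `p_fisher`, `q_bh`.
#' @export
cooccurrence_with_nfib <- function(m, nfib_col = "nfib_amplified") {
  nfib <- as.logical(m[[nfib_col]])
  if (all(nfib) || !any(nfib)) {
    stop("degenerate margins: need both NFIB-amplified and non-amplified patients",
         call. = FALSE)
  }
  loci <- setdiff(names(m)[vapply(m, is.logical, logical(1))], nfib_col)
  N <- length(nfib); K <- sum(nfib)
  res <- purrr::map_dfr(loci, function(lc) {
    x <- as.logical(m[[lc]])
    a <- sum(x & nfib); b <- sum(x & !nfib)
    c_ <- sum(!x & nfib); d <- sum(!x & !nfib)
    p <- stats::phyper(a - 1, m = K, n = N - K, k = a + b,
                       lower.tail = FALSE)
    lor <- log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5)))
    tibble::tibble(locus = lc, n_both = a,
                   odds_direction = sign(lor), p_fisher = p)
  })
  res$q_bh <- bh_adjust(res$p_fisher)
  class(res) <- c("cooccurrence_table", class(res))
  res
}

#' @method tidy cooccurrence_table
#' @export
tidy.cooccurrence_table <- function(x, ...) tibble::as_tibble(x)

#' @method glance cooccurrence_table
#' @export
glance.cooccurrence_table <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x),
                 n_significant = sum(x$q_bh < 0.05 & x$odds_direction > 0))
}

#' Fraction of sample regions validated in patient cohorts
#'
#' Fraction of sample amplification regions overlapping at least one
#' significant locus in at least one cohort (the cohort union).
#'
#' @param sample_regions Peak tibble of sample amplification regions.
#' @param cohort_loci List of peak tibbles, one per cohort, holding the
#'   significant loci.
#' @param layout A [genome_layout()].
#' @return A fraction in \[0, 1\] (`NA`, with a warning, for an empty
#'   sample set).
#' @export
cohort_validation_fraction <- function(sample_regions, cohort_loci, layout) {
  if (nrow(sample_regions) == 0) {
    warning("empty sample region set; validation fraction undefined")
    return(NA_real_)
  }
  if (length(cohort_loci) == 0) return(0)
  union_loci <- dplyr::bind_rows(
    lapply(cohort_loci, function(x) x[, c("chrom", "start", "end")])
  )
  if (nrow(union_loci) == 0) return(0)
  hits <- GenomicRanges::countOverlaps(
    peaks_to_gr(sample_regions, layout),
    peaks_to_gr(union_loci, layout), minoverlap = 1L
  )
  mean(hits > 0)
}

#' Read and write SEG-like copy-number tables
#'
#' Tab-separated with header: `chrom`, `start`, `end`, `clone`,
#' `copy_number`.
#'
#' @param path File path.
#' @return `read_seg()` returns a segment tibble.
#' @export
read_seg <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      colClasses = c("character", "numeric",
                                                     "numeric", "character",
                                                     "numeric")))
}

#' @rdname read_seg
#' @param seg Segment tibble.
#' @export
write_seg <- function(seg, path) {
  utils::write.table(
    as.data.frame(seg)[, c("chrom", "start", "end", "clone", "copy_number")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
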