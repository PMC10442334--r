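#' Orient PC1 eigenvectors by gene density
#'
#' The sign of a contact-matrix eigenvector is arbitrary per chromosome;
#' the active (A) compartment is conventionally the gene-dense one. For
#' each chromosome, if the correlation between the mean PC1 (across all
#' replicate columns) and gene density is negative, every PC1 column on
#' that chromosome is flipped, so that positive PC1 = A = gene-dense.
#'
#' @param x Compartment tibble: `chrom`, `start`, `end`, `gene_density`,
#'   plus one numeric PC1 column per replicate x condition.
#' @param pc1_cols Character vector of PC1 column names; by default every
#'   numeric column other than `start`, `end`, `gene_density`.
#' @return `x` with PC1 columns oriented; attribute `flipped` lists the
#'   chromosomes whose sign was flipped.
#' @export
orient_pc1 <- function(x, pc1_cols = NULL) {
  if (is.null(x$gene_density) || all(x$gene_density == 0)) {
    stop("orient_pc1 requires a non-zero gene_density column", call. = FALSE)
  }
  if (is.null(pc1_cols)) {
    num <- vapply(x, is.numeric, logical(1))
    pc1_cols <- setdiff(names(x)[num], c("start", "end", "gene_density"))
  }
  flipped <- character(0)
  for (ch in unique(x$chrom)) {
    i <- x$chrom == ch
    m <- rowMeans(as.data.frame(x[i, pc1_cols, drop = FALSE]))
    if (stats::sd(m) == 0) {
      stop("zero-variance PC1 on chromosome ", ch, call. = FALSE)
    }
    r <- stats::cor(m, x$gene_density[i])
    if (!is.na(r) && r < 0) {
      x[i, pc1_cols] <- -x[i, pc1_cols]
      flipped <- c(flipped, ch)
    }
  }
  attr(x, "flipped") <- flipped
  x
}

#' Classify per-bin compartment changes between conditions
#'
#' Per 250-kb bin, replicate PC1 values of the two conditions are compared
#' by a two-sided two-sample t-test (pooled variance by default; Welch via
#' `var_equal = FALSE`). Bins with `p >= alpha` are `unchanged`; otherwise
#' the category follows the condition means: both positive with the
#' knockdown magnitude smaller is `A-weakened` (larger: `A-strengthened`),
#' both negative analogously `B-weakened`/`B-strengthened`, and a sign
#' change is `A-to-B` or `B-to-A`.
#'
#' @param x Oriented compartment tibble (see [orient_pc1()]).
#' @param cols_control,cols_kd Names of the replicate PC1 columns for the
#'   control and knockdown conditions (>= 2 each).
#' @param alpha Significance cutoff (default 0.05).
#' @param var_equal Pooled-variance t-test (default TRUE).
#' @return A tibble of class `compartment_change`: bin coordinates,
#'   `mean_ctrl`, `mean_kd`, `p_ttest`, `category`.
#' @export
classify_bins <- function(x, cols_control, cols_kd, alpha = 0.05,
                          var_equal = TRUE) {
  stopifnot(length(cols_control) >= 2, length(cols_kd) >= 2)
  mc <- as.matrix(as.data.frame(x[, cols_control, drop = FALSE]))
  mk <- as.matrix(as.data.frame(x[, cols_kd, drop = FALSE]))
  m1 <- rowMeans(mc); m2 <- rowMeans(mk)
  v1 <- apply(mc, 1, stats::var); v2 <- apply(mk, 1, stats::var)
  n1 <- ncol(mc); n2 <- ncol(mk)
  if (var_equal) {
    p <- pooled_t(m1, m2, v1, v2, n1, n2)$p
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    t <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(t), df)
    p[se == 0 & m1 == m2] <- 1
    p[se == 0 & m1 != m2] <- 0
  }
  category <- dplyr::case_when(
    p >= alpha ~ "unchanged",
    m1 > 0 & m2 < 0 ~ "A-to-B",
    m1 < 0 & m2 > 0 ~ "B-to-A",
    m1 > 0 & abs(m2) < abs(m1) ~ "A-weakened",
    m1 > 0 ~ "A-strengthened",
    m1 < 0 & abs(m2) < abs(m1) ~ "B-weakened",
    m1 < 0 ~ "B-strengthened",
    TRUE ~ "unchanged"
  )
  out <- tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                        mean_ctrl = m1, mean_kd = m2, p_ttest = p,
                        category = category)
  class(out) <- c("compartment_change", class(out))
  out
}

#' N1-peak enrichment across compartment-change categories
#'
#' Counts N1 peaks per compartment bin (a peak spanning a bin boundary
#' counts in every bin it overlaps; `midpoint = TRUE` assigns it to the
#' single bin holding its midpoint) and compares each category's per-bin
#' count distribution to the `unchanged` category with a two-sided
#' Mann-Whitney U test.
#'
#' @param change A `compartment_change` table from [classify_bins()].
#' @param n1 N1 peak data frame.
#' @param layout A [genome_layout()].
#' @param midpoint Assign peaks by midpoint instead of any-overlap.
#' @return A tibble of class `n1_enrichment`: per bin `chrom`, `start`,
#'   `end`, `category`, `n1_count`; attribute `tests` holds per-category
#'   `n_bins`, `median_count`, `p_vs_unchanged` (`NA`, flagged via
#'   `tested`, for categories with < 2 bins).
#' @export
n1_enrichment <- function(change, n1, layout, midpoint = FALSE) {
  bins_gr <- peaks_to_gr(change, layout)
  if (nrow(n1) == 0) {
    cnt <- integer(nrow(change))
  } else if (midpoint) {
    mid <- floor((n1$start + n1$end) / 2)
    pk <- peaks(n1$chrom, mid, mid + 1)
    cnt <- GenomicRanges::countOverlaps(bins_gr, peaks_to_gr(pk, layout))
  } else {
    cnt <- GenomicRanges::countOverlaps(bins_gr, peaks_to_gr(n1, layout),
                                        minoverlap = 1L)
  }
  out <- tibble::tibble(chrom = change$chrom, start = change$start,
                        end = change$end, category = change$category,
                        n1_count = as.integer(cnt))
  base <- out$n1_count[out$category == "unchanged"]
  tests <- out |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_bins = dplyr::n(),
                     median_count = stats::median(.data$n1_count),
                     mean_count = mean(.data$n1_count),
                     .groups = "drop")
  tests$tested <- tests$category != "unchanged" & tests$n_bins >= 2 &
    length(base) >= 2
  tests$p_vs_unchanged <- NA_real_
  for (i in which(tests$tested)) {
    cc <- out$n1_count[out$category == tests$category[i]]
    tests$p_vs_unchanged[i] <- suppressWarnings(
      stats::wilcox.test(cc, base, exact = FALSE)$p.value
    )
  }
  attr(out, "tests") <- tests
  class(out) <- c("n1_enrichment", class(out))
  out
}

#' @method glance n1_enrichment
#' @export
glance.n1_enrichment <- function(x, ...) attr(x, "tests")

#' @method tidy compartment_change
#' @export
tidy.compartment_change <- function(x, ...) tibble::as_tibble(x)

#' @method glance compartment_change
#' @export
glance.compartment_change <- function(x, ...) {
  x |>
    dplyr::count(.data$category, name = "n_bins") |>
    tidyr::pivot_wider(names_from = "category", values_from = "n_bins",
                       values_fill = 0L)
}

#' Scatter plot of PC1 change classification
#'
#' Control vs knockdown mean PC1 per bin, significant bins coloured by
#' category.
#'
#' @param object A `compartment_change` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot compartment_change
#' @export
autoplot.compartment_change <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_ctrl, y = .data$mean_kd,
                                   colour = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::labs(x = "PC1 (control)", y = "PC1 (knockdown)",
                  title = "Compartment change per 250-kb bin")
}

#' Violin plot of N1 counts by compartment category
#'
#' @param object An `n1_enrichment` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot n1_enrichment
#' @export
autoplot.n1_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n1_count)) +
    ggplot2::geom_violin(fill = "grey80", scale = "width") +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 0.5, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "N1 peaks per 250-kb bin",
                  title = "N1 enrichment by compartment change")
}
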