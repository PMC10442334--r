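#' One-sided Fisher exact test for RNase sensitivity
#'
#' For each nascent-strand peak, tests enrichment of the untreated library
#' over the RNase-treated library with a one-sided Fisher exact test on the
#' 2x2 table `[(count_untreated, lib_untreated - count_untreated),
#' (count_treated, lib_treated - count_treated)]`. The one-sided p-value is
#' the upper hypergeometric tail; signal surviving RNase digestion is the
#' non-nascent noise the filter removes.
#'
#' @param count_untreated,count_treated Per-peak read counts.
#' @param lib_untreated,lib_treated Library totals (scalars or vectors).
#' @return Vector of one-sided p-values in (0, 1].
#' @export
#' @examples
#' fisher_rnase_test(30, 10, 1000, 1000)
fisher_rnase_test <- function(count_untreated, count_treated,
                              lib_untreated, lib_treated) {
  n <- length(count_untreated)
  lib_untreated <- rep_len(lib_untreated, n)
  lib_treated <- rep_len(lib_treated, n)
  if (any(count_untreated > lib_untreated) ||
      any(count_treated > lib_treated)) {
    stop("library total smaller than peak count", call. = FALSE)
  }
  stats::phyper(count_untreated - 1,
                m = lib_untreated, n = lib_treated,
                k = count_untreated + count_treated,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up BH with monotonicity enforcement, order-preserving
#' under permutation of the input.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Filter true nascent-strand peaks against the RNase control
#'
#' Keeps a peak iff its BH q-value is at most `fdr` and its
#' library-normalized, pseudocounted `log2(untreated / treated)` ratio is
#' at least `log2(fc)` — both conditions must hold.
#'
#' @param records Tibble with columns `count_untreated`, `count_treated`,
#'   `lib_untreated`, `lib_treated` (other columns pass through).
#' @param fdr FDR cutoff (default 0.05).
#' @param fc Fold cutoff (default 1.2).
#' @param pseudocount Added to counts before the normalized ratio
#'   (default 0.5).
#' @return `records` of class `ns_peak_table` with `p_fisher`, `q_bh`,
#'   `log2_ratio`, `is_true_ns` columns added.
#' @export
filter_true_ns <- function(records, fdr = 0.05, fc = 1.2, pseudocount = 0.5) {
  stopifnot(fdr > 0, fdr < 1, fc > 1)
  records <- tibble::as_tibble(records)
  records$p_fisher <- fisher_rnase_test(records$count_untreated,
                                        records$count_treated,
                                        records$lib_untreated,
                                        records$lib_treated)
  records$q_bh <- bh_adjust(records$p_fisher)
  records$log2_ratio <- log2(
    ((records$count_untreated + pseudocount) / records$lib_untreated) /
      ((records$count_treated + pseudocount) / records$lib_treated)
  )
  records$is_true_ns <- records$q_bh <= fdr &
    records$log2_ratio >= log2(fc)
  class(records) <- c("ns_peak_table", class(records))
  records
}

#' Classify origin response to knockdown (S1/S2/S3)
#'
#' Partitions true nascent-strand peaks by knockdown response using the
#' same fold-change rule engine as [classify_fold_change()]: S1 = signal
#' decreased, S2 = signal increased, S3 = unaltered (fold change below the
#' cutoff either way).
#'
#' @param x Data frame with `signal_control` and `signal_kd` columns.
#' @inheritParams classify_fold_change
#' @return `x` of class `origin_class_table` with `log2fc` and `class`
#'   (`"S1"`, `"S2"`, `"S3"`) columns.
#' @export
classify_s123 <- function(x, fc_cutoff = 1.2, pseudocount = 0.5) {
  out <- classify_fold_change(x, fc_cutoff = fc_cutoff,
                              pseudocount = pseudocount)
  out$class <- c(decreased = "S1", increased = "S2",
                 unchanged = "S3")[out$label]
  out$label <- NULL
  class(out) <- c("origin_class_table",
                  setdiff(class(out), c("origin_class_table",
                                        "differential_table")))
  out
}

#' Assign replication timing from early/mid/late fraction tracks
#'
#' Each peak is labelled by the S-phase fraction (early, mid, late) whose
#' library-normalized mean signal over the peak is highest; ties break
#' toward the earlier class. Peaks with zero signal in all three fractions
#' are `"unassigned"`.
#'
#' @param x A peak data frame.
#' @param early,mid,late [binned_track()]s for the three S-phase fractions.
#' @param normalize Scale each track to unit mean before comparison
#'   (default TRUE), removing library-size differences.
#' @return `x` with a `timing` column.
#' @export
assign_timing <- function(x, early, mid, late, normalize = TRUE) {
  tr <- list(early = early, mid = mid, late = late)
  if (normalize) {
    tr <- purrr::map(tr, function(t) {
      m <- mean(t$value)
      if (m > 0) t$value <- t$value / m
      t
    })
  }
  sig <- vapply(tr, mean_signal, numeric(nrow(x)), query = x)
  if (nrow(x) == 1) sig <- matrix(sig, nrow = 1,
                                  dimnames = list(NULL, names(tr)))
  lab <- c("early", "mid", "late")[max.col(sig, ties.method = "first")]
  lab[rowSums(sig) == 0] <- "unassigned"
  x$timing <- lab
  x
}

#' Timing distribution per origin category
#'
#' Fractions of peaks labelled early/mid/late within each category
#' (e.g. S1.N1, S1.non-N1, S2, all). Fractions are over assigned peaks and
#' sum to 1 per non-empty category; unassigned peaks are counted
#' separately. Empty categories are flagged with `NA` fractions.
#'
#' @param x Tibble with `category` and `timing` columns (one row per peak
#'   per category membership).
#' @return A tibble of class `timing_distribution`: `category`, `n`,
#'   `n_unassigned`, and `frac_early`, `frac_mid`, `frac_late`.
#' @export
timing_distribution <- function(x) {
  out <- x |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n = sum(.data$timing != "unassigned"),
      n_unassigned = sum(.data$timing == "unassigned"),
      frac_early = if (n == 0) NA_real_ else sum(.data$timing == "early") / n,
      frac_mid = if (n == 0) NA_real_ else sum(.data$timing == "mid") / n,
      frac_late = if (n == 0) NA_real_ else sum(.data$timing == "late") / n,
      .groups = "drop"
    )
  class(out) <- c("timing_distribution", class(out))
  out
}

#' Stacked-bar plot of timing distributions
#'
#' @param object A `timing_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot timing_distribution
#' @export
autoplot.timing_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::starts_with("frac_"),
                        names_to = "timing", values_to = "fraction",
                        names_prefix = "frac_")
  df$timing <- factor(df$timing, levels = c("early", "mid", "late"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction,
                                   fill = .data$timing)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = NULL, y = "fraction of peaks",
                  title = "Replication timing by origin category")
}
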