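#' Classify peaks by knockdown fold change
#'
#' Labels each peak `decreased`, `increased`, or `unchanged` from its
#' control and knockdown signals. With pseudocount `pc`:
#' decreased iff `(control + pc) / (kd + pc) > fc_cutoff`, increased iff
#' `(kd + pc) / (control + pc) > fc_cutoff`, otherwise unchanged. The three
#' labels partition every table.
#'
#' @param x Data frame with numeric columns `signal_control`, `signal_kd`.
#' @param fc_cutoff Fold-change cutoff (> 1; default 1.2).
#' @param pseudocount Added to both signals before the ratio (default 0.5),
#'   so zero signal never yields an infinite fold change.
#' @return `x` of class `differential_table` with `log2fc` (knockdown vs
#'   control) and `label` columns added.
#' @export
#' @examples
#' tbl <- tibble::tibble(signal_control = c(10, 5, 7),
#'                       signal_kd = c(5, 10, 7))
#' classify_fold_change(tbl)
classify_fold_change <- function(x, fc_cutoff = 1.2, pseudocount = 0.5) {
  if (fc_cutoff <= 1) stop("fc_cutoff must be > 1", call. = FALSE)
  stopifnot(all(x$signal_control >= 0), all(x$signal_kd >= 0))
  ctrl <- x$signal_control + pseudocount
  kd <- x$signal_kd + pseudocount
  x$log2fc <- log2(kd / ctrl)
  x$label <- dplyr::case_when(
    ctrl / kd > fc_cutoff ~ "decreased",
    kd / ctrl > fc_cutoff ~ "increased",
    TRUE ~ "unchanged"
  )
  if (!inherits(x, "differential_table")) {
    class(x) <- c("differential_table", class(x))
  }
  x
}

#' Derive factor-dependent licensing (N1) peaks
#'
#' N1 peaks are the overlapped ORC1 peaks whose own signal and whose
#' overlapping NFIB partner's signal both decrease upon NFIB knockdown.
#' Membership is expressed on the ORC1 peak intervals, the licensing
#' substrate. The consistency percentage is
#' `100 * |N1| / |overlapped ORC1 peaks labelled decreased|` — the fraction
#' of diminished co-bound ORC1 peaks that coincide with diminished NFIB.
#'
#' @param nfib_tbl,orc1_tbl `differential_table`s whose rows correspond
#'   one-to-one (and in order) to the peak tables that produced `overlap`.
#' @param overlap Output of [peak_intersect()] between the NFIB (`a`) and
#'   ORC1 (`b`) peak sets.
#' @return A tibble of class `n1_peaks`: the N1 rows of `orc1_tbl`, with
#'   attribute `consistency_pct` (full precision; `NA` when no overlapped
#'   ORC1 peak is decreased).
#' @export
derive_n1 <- function(nfib_tbl, orc1_tbl, overlap) {
  stopifnot(all(c("label") %in% names(nfib_tbl)),
            all(c("label") %in% names(orc1_tbl)))
  ov_a <- overlap[overlap$set == "a", c("component", ".row")]
  ov_b <- overlap[overlap$set == "b", c("component", ".row")]
  ov_a$nfib_decreased <- nfib_tbl$label[ov_a$.row] == "decreased"
  comp_dec <- ov_a |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(partner_decreased = any(.data$nfib_decreased))
  ov_b <- dplyr::left_join(ov_b, comp_dec, by = "component")
  orc1_rows <- unique(ov_b$.row)
  dec_rows <- orc1_rows[orc1_tbl$label[orc1_rows] == "decreased"]
  n1_rows <- sort(unique(
    ov_b$.row[ov_b$partner_decreased &
                orc1_tbl$label[ov_b$.row] == "decreased"]
  ))
  out <- tibble::as_tibble(orc1_tbl[n1_rows, , drop = FALSE])
  out$.row <- n1_rows
  attr(out, "n_overlapped_decreased") <- length(dec_rows)
  attr(out, "consistency_pct") <-
    if (length(dec_rows) == 0) NA_real_ else 100 * nrow(out) / length(dec_rows)
  class(out) <- c("n1_peaks", class(out))
  out
}

#' @method glance n1_peaks
#' @export
glance.n1_peaks <- function(x, ...) {
  tibble::tibble(n_n1 = nrow(x),
                 n_overlapped_decreased = attr(x, "n_overlapped_decreased"),
                 consistency_pct = attr(x, "consistency_pct"))
}

#' Classify accessibility changes from replicate counts
#'
#' Simplified differential-accessibility call: counts are library-size
#' normalized (scaled to the mean library size), compared by a two-sided
#' pooled-variance t-test on `log2(normalized + pseudocount)` across
#' replicates. Peaks whose accessibility falls upon depletion — i.e. the
#' factor is required to open them — are grouped `open`; peaks whose
#' accessibility rises are `close`; both require
#' `|log2fc| > log2(fc_cutoff)` and `p < alpha`.
#'
#' @param counts Long-format tibble with columns `peak` (id), `condition`
#'   (`"control"`/`"knockdown"`), `replicate`, `count`. At least two
#'   replicates per condition are required.
#' @param fc_cutoff Fold-change cutoff (default 1.2).
#' @param alpha Significance cutoff (default 0.01).
#' @param pseudocount Added before the log (default 0.5).
#' @return One row per peak of class `accessibility_table`: normalized
#'   means, `log2fc` (knockdown vs control), `p_value`, `group`.
#' @export
classify_accessibility <- function(counts, fc_cutoff = 1.2, alpha = 0.01,
                                   pseudocount = 0.5) {
  stopifnot(all(counts$count >= 0))
  libs <- counts |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::summarise(lib = sum(.data$count), .groups = "drop")
  n_rep <- table(libs$condition)
  if (any(n_rep < 2) || length(n_rep) != 2) {
    stop("classify_accessibility needs >= 2 replicates per condition",
         call. = FALSE)
  }
  counts <- dplyr::left_join(counts, libs, by = c("condition", "replicate"))
  counts$norm <- counts$count / counts$lib * mean(libs$lib)
  counts$lognorm <- log2(counts$norm + pseudocount)
  wide <- counts |>
    dplyr::group_by(.data$peak, .data$condition) |>
    dplyr::summarise(m = mean(.data$lognorm), v = stats::var(.data$lognorm),
                     n = dplyr::n(), mean_norm = mean(.data$norm),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("m", "v", "n", "mean_norm"))
  t_res <- pooled_t(wide$m_control, wide$m_knockdown,
                    wide$v_control, wide$v_knockdown,
                    wide$n_control, wide$n_knockdown)
  out <- tibble::tibble(
    peak = wide$peak,
    mean_control = wide$mean_norm_control,
    mean_kd = wide$mean_norm_knockdown,
    log2fc = wide$m_knockdown - wide$m_control,
    p_value = t_res$p
  )
  out$group <- dplyr::case_when(
    abs(out$log2fc) > log2(fc_cutoff) & out$p_value < alpha & out$log2fc < 0 ~ "open",
    abs(out$log2fc) > log2(fc_cutoff) & out$p_value < alpha & out$log2fc > 0 ~ "close",
    TRUE ~ "unchanged"
  )
  class(out) <- c("accessibility_table", class(out))
  out
}

# Vectorised two-sided pooled-variance two-sample t-test.
# Zero pooled variance: equal means -> p = 1; unequal means -> p = 0
# (flagged significant; degenerate but informative).
pooled_t <- function(m1, m2, v1, v2, n1, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero <- !is.na(se) & se == 0
  p[zero & m1 == m2] <- 1
  p[zero & m1 != m2] <- 0
  list(t = t, p = p, df = df)
}

#' MA-style plot of a differential table
#'
#' @param object A `differential_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot differential_table
#' @export
autoplot.differential_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mean_signal <- (df$signal_control + df$signal_kd) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_signal, y = .data$log2fc,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(decreased = "#2166AC",
                                            increased = "#B2182B",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "mean signal", y = "log2 fold change (kd / control)")
}
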