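#' Run every analysis stage on a simulated study
#'
#' Executes the full integrative analysis in dependency order on an
#' `origin_study`: peak colocalization with the random-region permutation
#' null; knockdown-differential classification of NFIB/ORC1 binding and
#' derivation of N1 peaks; ATAC accessibility grouping; RNase-filtered
#' nascent-strand origin classification (S1/S2/S3) with replication-timing
#' assignment; PC1 compartment-change classification with N1 enrichment;
#' and the EM / CNA auxiliary statistics. Because the study carries its
#' truth ledger, the result also reports planted-label recovery rates.
#'
#' @param study An `origin_study` from [simulate_study()].
#' @param stages Named logical vector toggling
#'   `colocalization`, `differential`, `origins`, `compartments`, `aux`.
#'   Disabling a stage an enabled stage depends on is an error.
#' @param fc_cutoff,pseudocount Fold-change rule parameters (1.2, 0.5).
#' @param accessibility_alpha ATAC significance cutoff (0.01).
#' @param ns_fdr,ns_fc Nascent-strand filter thresholds (0.05, 1.2).
#' @param compartment_alpha Compartment t-test cutoff (0.05).
#' @param n_null_draws Permutation-null draws (10).
#' @param gain_threshold,loss_threshold CNA call thresholds (2.3, 1.7).
#' @param min_clones Recurrence threshold (2).
#' @param cooccurrence_fdr Cohort co-occurrence FDR cutoff (0.05).
#' @param em_occupancies Planted occupancies for the EM stage.
#' @param em_traces Traces per occupancy (500).
#' @return A list of class `study_analysis` with one element per enabled
#'   stage plus `recovery`.
#' @export
analyze_study <- function(study,
                          stages = c(colocalization = TRUE,
                                     differential = TRUE,
                                     origins = TRUE,
                                     compartments = TRUE,
                                     aux = TRUE),
                          fc_cutoff = 1.2, pseudocount = 0.5,
                          accessibility_alpha = 0.01,
                          ns_fdr = 0.05, ns_fc = 1.2,
                          compartment_alpha = 0.05,
                          n_null_draws = 10,
                          gain_threshold = 2.3, loss_threshold = 1.7,
                          min_clones = 2, cooccurrence_fdr = 0.05,
                          em_occupancies = c(0, 0.4, 1),
                          em_traces = 500) {
  stopifnot(inherits(study, "origin_study"))
  layout <- study$layout
  seed <- study$config$seed
  on <- function(s) isTRUE(stages[[s]])
  need <- function(s, by) {
    if (!on(s)) {
      stop("stage `", by, "` requires stage `", s, "`, which is disabled",
           call. = FALSE)
    }
  }
  res <- list()

  if (on("colocalization")) {
    venn <- overlap_venn(study$nfib_peaks, study$orc1_peaks, layout)
    res$colocalization <- list(
      venn = venn,
      percentages = venn_percentages(venn),
      null = permutation_overlap_null(study$nfib_peaks, study$orc1_peaks,
                                      layout, n_draws = n_null_draws,
                                      seed = substream_seed(seed, 101))
    )
  }

  if (on("differential")) {
    nfib_tbl <- study$nfib_peaks |>
      dplyr::mutate(
        signal_control = mean_signal(study$tracks$nfib_control, study$nfib_peaks),
        signal_kd = mean_signal(study$tracks$nfib_kd, study$nfib_peaks)
      ) |>
      classify_fold_change(fc_cutoff, pseudocount)
    orc1_tbl <- study$orc1_peaks |>
      dplyr::mutate(
        signal_control = mean_signal(study$tracks$orc1_control, study$orc1_peaks),
        signal_kd = mean_signal(study$tracks$orc1_kd, study$orc1_peaks)
      ) |>
      classify_fold_change(fc_cutoff, pseudocount)
    overlap <- peak_intersect(study$nfib_peaks, study$orc1_peaks, layout)
    n1 <- derive_n1(nfib_tbl, orc1_tbl, overlap)
    res$differential <- list(
      nfib = nfib_tbl, orc1 = orc1_tbl, overlap = overlap, n1 = n1,
      accessibility = classify_accessibility(study$atac_counts, fc_cutoff,
                                             accessibility_alpha, pseudocount)
    )
  }

  if (on("origins")) {
    need("differential", "origins")
    ns_kd <- study$ns_counts[study$ns_counts$condition == "knockdown", ]
    ns_ctrl <- study$ns_counts[study$ns_counts$condition == "control", ]
    filtered <- filter_true_ns(ns_kd, fdr = ns_fdr, fc = ns_fc,
                               pseudocount = pseudocount)
    true_ns <- filtered[filtered$is_true_ns, ]
    ctrl_cnt <- ns_ctrl$count_untreated[match(true_ns$name, ns_ctrl$name)]
    cls <- true_ns |>
      dplyr::mutate(signal_control = ctrl_cnt,
                    signal_kd = .data$count_untreated) |>
      classify_s123(fc_cutoff, pseudocount) |>
      assign_timing(study$tracks$early, study$tracks$mid, study$tracks$late)
    # S1.N1: S1 peaks overlapping an N1 peak
    s1 <- cls[cls$class == "S1", ]
    n1_pk <- res$differential$n1
    in_n1 <- rep(FALSE, nrow(s1))
    if (nrow(s1) > 0 && nrow(n1_pk) > 0) {
      in_n1 <- GenomicRanges::countOverlaps(
        peaks_to_gr(s1, layout), peaks_to_gr(n1_pk, layout),
        minoverlap = 1L) > 0
    }
    cats <- dplyr::bind_rows(
      dplyr::mutate(s1[in_n1, ], category = "S1.N1"),
      dplyr::mutate(s1[!in_n1, ], category = "S1.non-N1"),
      dplyr::mutate(cls[cls$class == "S2", ], category = "S2"),
      dplyr::mutate(cls, category = "all")
    )
    res$origins <- list(
      filtered = filtered, classes = cls,
      s1_n1_names = s1$name[in_n1],
      class_counts = table(cls$class),
      timing = timing_distribution(cats[, c("category", "timing")])
    )
  }

  if (on("compartments")) {
    need("differential", "compartments")
    reps <- study$config$n_replicates
    oriented <- orient_pc1(study$pc1)
    change <- classify_bins(oriented,
                            cols_control = paste0("ctrl_rep", seq_len(reps)),
                            cols_kd = paste0("kd_rep", seq_len(reps)),
                            alpha = compartment_alpha)
    res$compartments <- list(
      change = change,
      enrichment = n1_enrichment(change, res$differential$n1, layout)
    )
  }

  if (on("aux")) {
    em <- purrr::map_dfr(seq_along(em_occupancies), function(i) {
      tr <- simulate_em_traces(em_occupancies[i], n_traces = em_traces,
                               seed = substream_seed(seed, 200 + i))
      tibble::tibble(occupancy = em_occupancies[i],
                     mean_r = mean(em_r_values(tr)$r_value),
                     n_traces = em_traces)
    })
    seg <- classify_cna_segments(study$cna_segments, gain_threshold,
                                 loss_threshold)
    ctrl_seg <- seg[seg$clone == "control", ]
    samp_seg <- seg[seg$clone != "control", ]
    residual <- subtract_control_gains(samp_seg, ctrl_seg, layout)
    recurrent <- recurrent_amplifications(residual, layout, min_clones)
    cooc <- purrr::map(study$cohorts, cooccurrence_with_nfib)
    sig_loci <- purrr::map(cooc, function(tb) {
      keep <- tb$locus[tb$q_bh < cooccurrence_fdr & tb$odds_direction > 0]
      loci <- study$truth$cohort_loci
      loci[loci$name %in% keep, c("chrom", "start", "end")]
    })
    res$aux <- list(
      em = em, residual_gains = residual, recurrent = recurrent,
      cooccurrence = cooc,
      validation_fraction = cohort_validation_fraction(recurrent, sig_loci,
                                                       layout)
    )
  }

  res$recovery <- recovery_rates(study, res)
  class(res) <- "study_analysis"
  res
}

# Planted-truth recovery: fraction of dependent origins recovered as S1.N1
# (and entering N1), false inclusion of independent origins, and detection
# of the planted weakened-A enrichment.
recovery_rates <- function(study, res) {
  out <- list()
  truth <- study$truth
  if (!is.null(res$differential)) {
    n1 <- res$differential$n1
    dep <- truth$orc1_sites$name[truth$orc1_sites$dependent]
    indep <- truth$orc1_sites$name[!truth$orc1_sites$dependent]
    out$n1_dependent_pct <-
      if (length(dep)) 100 * mean(dep %in% n1$name) else NA_real_
    out$n1_independent_pct <-
      if (length(indep)) 100 * mean(indep %in% n1$name) else NA_real_
  }
  if (!is.null(res$origins)) {
    dep <- truth$origins$name[truth$origins$class == "S1-dependent"]
    indep <- truth$origins$name[truth$origins$class %in%
                                  c("S2-compensatory", "S3-stable")]
    s1n1 <- res$origins$s1_n1_names
    out$s1n1_dependent_pct <-
      if (length(dep)) 100 * mean(dep %in% s1n1) else NA_real_
    out$s1n1_independent_pct <-
      if (length(indep)) 100 * mean(indep %in% s1n1) else NA_real_
  }
  if (!is.null(res$compartments)) {
    tests <- attr(res$compartments$enrichment, "tests")
    p <- tests$p_vs_unchanged[tests$category == "A-weakened"]
    out$weakened_A_enrichment_p <- if (length(p)) p else NA_real_
  }
  out
}

#' Run the pipeline from a configuration
#'
#' Config-driven entry point: simulates the study described by the
#' `simulate` block, runs the enabled stages, and (optionally) writes
#' per-stage TSV/BED artifacts plus a deterministic JSON report whose
#' numbers are re-derivable from the emitted tables.
#'
#' @param config Path to a YAML file or an R list with optional blocks
#'   `simulate` (fields of [simulation_config()]), `stages` (logical
#'   toggles), `analysis` (arguments of [analyze_study()]), and `seed`.
#' @param seed Overrides the config seed.
#' @param outdir If non-NULL, artifacts and `report.json` are written here.
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: `", config, "`", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  sim_args <- config$simulate %||% list()
  if (!is.null(config$seed)) sim_args$seed <- config$seed
  if (!is.null(seed)) sim_args$seed <- seed
  bad <- setdiff(names(sim_args), names(formals(simulation_config)))
  if (length(bad)) abort_field(bad[1], "unknown simulate field")
  cfg <- do.call(simulation_config, sim_args)

  stages <- c(colocalization = TRUE, differential = TRUE, origins = TRUE,
              compartments = TRUE, aux = TRUE)
  for (nm in names(config$stages %||% list())) {
    if (!nm %in% names(stages)) abort_field(nm, "unknown stage")
    stages[nm] <- isTRUE(config$stages[[nm]])
  }
  an_args <- config$analysis %||% list()
  bad <- setdiff(names(an_args),
                 setdiff(names(formals(analyze_study)), c("study", "stages")))
  if (length(bad)) abort_field(bad[1], "unknown analysis field")

  study <- simulate_study(cfg)
  res <- do.call(analyze_study, c(list(study = study, stages = stages),
                                  an_args))
  report <- build_report(study, res, stages)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_study(study, file.path(outdir, "study"))
    write_artifacts(res, outdir)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  structure(list(report = report, analysis = res, study = study),
            class = "run_report")
}

# Condense analysis results into plain-number report sections.
build_report <- function(study, res, stages) {
  rep <- list(provenance = list(
    package = "replilicense",
    version = as.character(utils::packageVersion("replilicense")),
    seed = study$config$seed,
    stages = as.list(stages)
  ))
  if (!is.null(res$colocalization)) {
    co <- res$colocalization
    rep$colocalization <- list(
      n_a = co$venn$n_a, n_b = co$venn$n_b,
      n_overlap_components = co$venn$n_overlap_components,
      n_a_matched = co$venn$n_a_matched,
      n_b_matched = co$venn$n_b_matched,
      pct_a = co$percentages$pct_a, pct_b = co$percentages$pct_b,
      pct_a_full = co$percentages$pct_a_full,
      pct_b_full = co$percentages$pct_b_full,
      null_draw_pcts = co$null$pct_overlap,
      null_median_pct = attr(co$null, "median_pct")
    )
  }
  if (!is.null(res$differential)) {
    d <- res$differential
    rep$differential <- list(
      n_n1 = nrow(d$n1),
      n_overlapped_decreased = attr(d$n1, "n_overlapped_decreased"),
      consistency_pct = attr(d$n1, "consistency_pct"),
      accessibility = as.list(table(d$accessibility$group))
    )
  }
  if (!is.null(res$origins)) {
    o <- res$origins
    td <- as.data.frame(o$timing)
    rep$origins <- list(
      n_candidate = nrow(o$filtered),
      n_true_ns = sum(o$filtered$is_true_ns),
      class_counts = as.list(o$class_counts),
      timing = td
    )
  }
  if (!is.null(res$compartments)) {
    ch <- res$compartments$change
    tests <- attr(res$compartments$enrichment, "tests")
    rep$compartments <- list(
      category_counts = as.list(table(ch$category)),
      enrichment = as.data.frame(tests)
    )
  }
  if (!is.null(res$aux)) {
    rep$aux <- list(
      em = as.data.frame(res$aux$em),
      n_residual_gain_intervals = nrow(res$aux$residual_gains),
      n_recurrent_regions = nrow(res$aux$recurrent),
      n_significant_loci = vapply(res$aux$cooccurrence, function(tb) {
        sum(tb$q_bh < 0.05 & tb$odds_direction > 0)
      }, numeric(1)),
      validation_fraction = res$aux$validation_fraction
    )
  }
  rep$recovery <- res$recovery
  rep
}

# Per-stage TSV/BED artifacts.
write_artifacts <- function(res, outdir) {
  fp <- function(...) file.path(outdir, ...)
  if (!is.null(res$colocalization)) {
    readr::write_tsv(tidy.venn_counts(res$colocalization$venn),
                     fp("colocalization_venn.tsv"))
    readr::write_tsv(tibble::as_tibble(res$colocalization$null),
                     fp("colocalization_null.tsv"))
  }
  if (!is.null(res$differential)) {
    readr::write_tsv(tibble::as_tibble(res$differential$nfib),
                     fp("differential_nfib.tsv"))
    readr::write_tsv(tibble::as_tibble(res$differential$orc1),
                     fp("differential_orc1.tsv"))
    write_bed(res$differential$n1, fp("n1_peaks.bed"))
    readr::write_tsv(tibble::as_tibble(res$differential$accessibility),
                     fp("accessibility.tsv"))
  }
  if (!is.null(res$origins)) {
    readr::write_tsv(tibble::as_tibble(res$origins$classes),
                     fp("origin_classes.tsv"))
    readr::write_tsv(tibble::as_tibble(res$origins$timing),
                     fp("timing_distribution.tsv"))
  }
  if (!is.null(res$compartments)) {
    readr::write_tsv(tibble::as_tibble(res$compartments$change),
                     fp("compartment_change.tsv"))
    wk <- res$compartments$change
    write_bed(wk[wk$category == "A-weakened", c("chrom", "start", "end")],
              fp("weakened_A_bins.bed"))
    readr::write_tsv(attr(res$compartments$enrichment, "tests"),
                     fp("n1_enrichment_tests.tsv"))
  }
  if (!is.null(res$aux)) {
    readr::write_tsv(res$aux$em, fp("em_r_values.tsv"))
    if (nrow(res$aux$recurrent)) {
      write_bed(res$aux$recurrent, fp("recurrent_amplifications.bed"))
    }
    for (nm in names(res$aux$cooccurrence)) {
      readr::write_tsv(tibble::as_tibble(res$aux$cooccurrence[[nm]]),
                       fp(paste0("cooccurrence_", nm, ".tsv")))
    }
  }
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat("replilicense run (seed ", r$provenance$seed, ")\n", sep = "")
  if (!is.null(r$colocalization)) {
    cat(sprintf("  colocalization: %d components; %s%% of set A, %s%% of set B; null median %.2f%%\n",
                r$colocalization$n_overlap_components,
                r$colocalization$pct_a, r$colocalization$pct_b,
                r$colocalization$null_median_pct))
  }
  if (!is.null(r$differential)) {
    cat(sprintf("  N1 peaks: %d (consistency %.1f%%)\n",
                r$differential$n_n1, r$differential$consistency_pct))
  }
  if (!is.null(r$origins)) {
    cc <- r$origins$class_counts
    cat(sprintf("  origins: %d true NS peaks (S1 %s / S2 %s / S3 %s)\n",
                r$origins$n_true_ns, cc$S1 %||% 0, cc$S2 %||% 0, cc$S3 %||% 0))
  }
  if (!is.null(r$compartments)) {
    aw <- r$compartments$category_counts[["A-weakened"]] %||% 0
    cat(sprintf("  compartments: %s A-weakened bins\n", aw))
  }
  if (!is.null(r$aux)) {
    cat(sprintf("  aux: %d recurrent amplification regions; validation fraction %.2f\n",
                r$aux$n_recurrent_regions, r$aux$validation_fraction))
  }
  invisible(x)
}
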