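#' Configuration for the synthetic origin-licensing study
#'
#' Defines the study conditions emulated by [simulate_study()]: a toy
#' genome carrying planted NFIB binding sites, ORC1 sites partially
#' dependent on NFIB, knockdown fold changes, nascent-strand counts with an
#' RNase background, three S-phase-fraction timing tracks, replicate PC1
#' compartment tracks with planted weakened-A bins, and clone copy-number
#' segments with planted co-amplifications. Every sequencing-count readout
#' is drawn per signal bin from a negative binomial with overdispersion
#' `noise_dispersion` (variance `mu + phi * mu^2`; `phi = 0` is the exact
#' zero-noise limit); backgrounds are Poisson; PC1 replicate noise is
#' Gaussian.
#'
#' @param layout Genome layout (default three 10-Mb chromosomes).
#' @param track_bin Signal bin width in bp (default 1000).
#' @param n_nfib_sites Number of planted NFIB sites (default 300).
#' @param n_orc1_sites Number of ORC1 sites (default: equal to
#'   `n_nfib_sites`).
#' @param frac_orc1_dependent Probability that an ORC1 site is
#'   NFIB-dependent (placed on an NFIB site; default 0.5).
#' @param site_width Width of planted binding sites in bp (default 4000,
#'   i.e. four signal bins, so per-peak fold-change estimates average over
#'   bin-level dispersion).
#' @param knockdown_fc True knockdown fold change at dependent sites
#'   (> 1; default 2).
#' @param noise_dispersion Negative-binomial overdispersion for count
#'   tracks (default 0.1).
#' @param ns_fragment_range Nascent-strand size-selection window in bp
#'   (default c(500, 2000)); decoy nascent-strand peaks draw their widths
#'   from this window.
#' @param rnase_background_rate Poisson background mean per signal bin in
#'   the nascent-strand libraries (default 2).
#' @param ns_signal_per_bin Mean nascent-strand signal per bin at an active
#'   origin (default 50).
#' @param ns_lib_size Library total for each nascent-strand library
#'   (default 1e6).
#' @param n_ns_decoys Non-origin decoy peaks in the nascent-strand tables
#'   (default 100).
#' @param chip_background,chip_signal_per_bin CUT&Tag track baseline and
#'   per-bin site signal (defaults 2 and 60).
#' @param atac_signal_per_bin ATAC per-bin signal at accessible peaks
#'   (default 25).
#' @param n_atac_decoys Unchanged decoy peaks in the ATAC count table
#'   (default 100).
#' @param n_replicates Replicates per condition for ATAC and PC1
#'   (default 2).
#' @param timing_domains Tibble (`chrom`, `start`, `end`, `class`) of
#'   early/mid/late replication domains; default: each chromosome split
#'   into consecutive thirds.
#' @param timing_signal Named vector `c(high=, low=)`: mean per-bin
#'   Repli-seq signal inside/outside a fraction's domain (default 20 / 1).
#' @param compartment_bin Compartment bin width in bp (default 250,000).
#' @param n_weakened_A_bins Planted weakened-A compartment bins
#'   (default 8), chosen among A bins inside early domains.
#' @param pc1_amplitude Baseline |PC1| of A/B blocks (default 0.8).
#' @param weakened_delta PC1 reduction at weakened-A bins upon knockdown
#'   (default 0.5).
#' @param frac_dependent_in_weakened Fraction of dependent sites planted
#'   inside weakened-A bins (default 0.6); the remainder are uniform, so
#'   dependent sites are also enriched in early domains.
#' @param pc1_noise_sd Gaussian sd of replicate PC1 noise (default 0.05).
#' @param n_clones Perturbed clones for the CNA stage (default 4).
#' @param n_planted_cnas Co-amplified regions planted in >= 2 clones
#'   (default 6).
#' @param n_null_loci Cohort loci with no co-occurrence signal
#'   (default 20).
#' @param n_cohorts Patient cohorts (default 4).
#' @param n_patients Patients per cohort (default 120).
#' @param frac_dormant Dormant origins as a fraction of ORC1 sites
#'   (default 0.1); silent in control, firing upon knockdown.
#' @param seed Integer master seed; all outputs draw from per-output
#'   substreams, so adding an output never perturbs earlier ones.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(layout = default_layout(),
                              track_bin = 1000,
                              n_nfib_sites = 300,
                              n_orc1_sites = NULL,
                              frac_orc1_dependent = 0.5,
                              site_width = 4000,
                              knockdown_fc = 2,
                              noise_dispersion = 0.1,
                              ns_fragment_range = c(500, 2000),
                              rnase_background_rate = 2,
                              ns_signal_per_bin = 50,
                              ns_lib_size = 1e6,
                              n_ns_decoys = 100,
                              chip_background = 2,
                              chip_signal_per_bin = 60,
                              atac_signal_per_bin = 25,
                              n_atac_decoys = 100,
                              n_replicates = 2,
                              timing_domains = NULL,
                              timing_signal = c(high = 20, low = 1),
                              compartment_bin = 250000,
                              n_weakened_A_bins = 8,
                              pc1_amplitude = 0.8,
                              weakened_delta = 0.5,
                              frac_dependent_in_weakened = 0.6,
                              pc1_noise_sd = 0.05,
                              n_clones = 4,
                              n_planted_cnas = 6,
                              n_null_loci = 20,
                              n_cohorts = 4,
                              n_patients = 120,
                              frac_dormant = 0.1,
                              seed = 1) {
  if (!inherits(layout, "genome_layout")) abort_field("layout", "not a genome_layout")
  if (knockdown_fc <= 1) abort_field("knockdown_fc", "must be > 1")
  if (noise_dispersion < 0) abort_field("noise_dispersion", "must be >= 0")
  for (f in c("frac_orc1_dependent", "frac_dependent_in_weakened",
              "frac_dormant")) {
    v <- get(f)
    if (v < 0 || v > 1) abort_field(f, "must lie in [0, 1]")
  }
  if (length(ns_fragment_range) != 2 || ns_fragment_range[1] <= 0 ||
      ns_fragment_range[1] > ns_fragment_range[2]) {
    abort_field("ns_fragment_range", "must be an increasing positive pair")
  }
  if (rnase_background_rate < 0) abort_field("rnase_background_rate", "must be >= 0")
  if (pc1_noise_sd < 0) abort_field("pc1_noise_sd", "must be >= 0")
  if (track_bin <= 0) abort_field("track_bin", "must be positive")
  if (site_width %% track_bin != 0) {
    abort_field("site_width", "must be a multiple of track_bin")
  }
  if (is.null(n_orc1_sites)) n_orc1_sites <- n_nfib_sites
  if (is.null(timing_domains)) {
    timing_domains <- purrr::map2_dfr(layout$chrom, layout$length,
      function(ch, len) {
        br <- round(seq(0, len, length.out = 4))
        tibble::tibble(chrom = ch, start = br[1:3], end = br[2:4],
                       class = c("early", "mid", "late"))
      })
  }
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

# Timing-domain class of positions (vectorised); positions are midpoints.
domain_class_at <- function(domains, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(domains))) {
    j <- chrom == domains$chrom[i] & pos >= domains$start[i] &
      pos < domains$end[i]
    out[j] <- domains$class[i]
  }
  out
}

#' Simulate nascent-strand count tables
#'
#' Draws per-peak untreated and RNase-treated counts. Each peak's untreated
#' count is the sum of per-bin negative-binomial draws whose means combine
#' the peak's origin activity (spread over its bins) with the Poisson
#' RNase background; the treated count is background only — RNase destroys
#' the RNA-primed nascent signal. Decoys (zero activity) draw both counts
#' from the background.
#'
#' @param x Peak data frame with an `activity` column (total expected
#'   nascent signal per peak; 0 for decoys).
#' @param cfg A [simulation_config()] (fields used:
#'   `rnase_background_rate`, `noise_dispersion`, `track_bin`,
#'   `ns_lib_size`).
#' @param seed Integer seed.
#' @return `x` with `count_untreated`, `count_treated`, `lib_untreated`,
#'   `lib_treated` columns.
#' @export
simulate_ns_counts <- function(x, cfg, seed = cfg$seed) {
  bg <- cfg$rnase_background_rate
  phi <- cfg$noise_dispersion
  withr::with_seed(seed, {
    nb <- pmax(1, ceiling((x$end - x$start) / cfg$track_bin))
    cu <- ct <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      cu[i] <- sum(rnb(nb[i], x$activity[i] / nb[i] + bg, phi))
      ct[i] <- if (bg == 0) 0 else sum(stats::rpois(nb[i], bg))
    }
    x$count_untreated <- cu
    x$count_treated <- ct
    x$lib_untreated <- cfg$ns_lib_size
    x$lib_treated <- cfg$ns_lib_size
    x
  })
}

#' Simulate electron-microscopy nucleosome traces
#'
#' Each trace is a DNA stretch of `total_len` contour units divided into
#' nucleosome-sized slots (147 units); every slot independently carries a
#' nucleosome bubble with probability `occupancy`, so the expected R-value
#' of a trace equals the planted occupancy.
#'
#' @param occupancy True nucleosome occupancy in \[0, 1\].
#' @param n_traces Number of traces (default 500).
#' @param total_len Contour length per trace (default 5,000 units).
#' @param seed Integer seed.
#' @param bubble_len Contour length of one nucleosome bubble (default 147).
#' @return Tibble with `trace`, `total_length` and a `bubble_lengths`
#'   list-column.
#' @export
simulate_em_traces <- function(occupancy, n_traces = 500, total_len = 5000,
                               seed = 1, bubble_len = 147) {
  stopifnot(occupancy >= 0, occupancy <= 1)
  n_slots <- floor(total_len / bubble_len)
  withr::with_seed(seed, {
    bubbles <- lapply(seq_len(n_traces), function(i) {
      k <- stats::rbinom(1, n_slots, occupancy)
      rep(bubble_len, k)
    })
  })
  tibble::tibble(trace = seq_len(n_traces),
                 total_length = n_slots * bubble_len,
                 bubble_lengths = bubbles)
}

#' Simulate the full synthetic origin-licensing study
#'
#' Generates, deterministically for a given seed, every input the analysis
#' pipeline consumes — CUT&Tag control/knockdown coverage tracks for NFIB
#' and ORC1 (dependent sites attenuated by the knockdown fold change), an
#' ATAC replicate count table, nascent-strand untreated/RNase count tables
#' for both conditions, early/mid/late Repli-seq tracks, replicate PC1
#' compartment tables with planted weakened-A bins, per-clone CNA segments
#' with planted co-amplifications, and patient cohort amplification
#' matrices — together with the `truth` ledger of planted labels used by
#' recovery tests. Internal consistency (every dependent ORC1 site overlaps
#' an NFIB site) is asserted at generation time.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `origin_study`; see Details in the package
#'   vignette for the component tables.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  layout <- cfg$layout
  seed <- cfg$seed

  ## --- compartment scaffold -------------------------------------------
  comp <- binned_track(layout, cfg$compartment_bin)[, c("chrom", "start", "end")]
  comp$bin_id <- seq_len(nrow(comp))
  block <- floor((comp$start / cfg$compartment_bin) / 5)
  comp$pc1_base <- ifelse(block %% 2 == 0, cfg$pc1_amplitude,
                          -cfg$pc1_amplitude)
  mid <- (comp$start + comp$end) / 2
  comp$timing <- domain_class_at(cfg$timing_domains, comp$chrom, mid)
  candidates <- comp$bin_id[comp$pc1_base > 0 & comp$timing == "early"]
  n_weak <- min(cfg$n_weakened_A_bins, length(candidates))
  weak_ids <- withr::with_seed(substream_seed(seed, 11),
                               sort(sample(candidates, n_weak)))
  comp$weakened <- comp$bin_id %in% weak_ids

  ## --- site placement on a slot grid ----------------------------------
  slot_w <- 2 * cfg$site_width
  slots <- purrr::map2_dfr(layout$chrom, layout$length, function(ch, len) {
    n <- floor(len / slot_w)
    tibble::tibble(chrom = ch, start = (seq_len(n) - 1) * slot_w)
  })
  slots$mid <- slots$start + cfg$site_width / 2
  slots$timing <- domain_class_at(cfg$timing_domains, slots$chrom, slots$mid)
  slots$comp_bin <- match(paste(slots$chrom,
                                floor(slots$start / cfg$compartment_bin)),
                          paste(comp$chrom, comp$start / cfg$compartment_bin))
  slots$in_weakened <- comp$weakened[slots$comp_bin]
  # a site must not spill into the next compartment bin's territory edge
  slots <- slots[!is.na(slots$timing), ]

  withr::with_seed(substream_seed(seed, 12), {
    n_dep <- stats::rbinom(1, cfg$n_orc1_sites, cfg$frac_orc1_dependent)
    n_indep <- cfg$n_orc1_sites - n_dep
    n_dormant <- round(cfg$frac_dormant * cfg$n_orc1_sites)
    avail <- seq_len(nrow(slots))
    take <- function(idx_pool, n) {
      pick <- sample(idx_pool, min(n, length(idx_pool)))
      avail <<- setdiff(avail, pick)
      pick
    }
    # dependent hosts: a fraction inside weakened-A bins, rest uniform
    n_w <- round(cfg$frac_dependent_in_weakened * n_dep)
    pool_w <- intersect(avail, which(slots$in_weakened))
    host_w <- take(pool_w, n_w)
    host_u <- take(avail, n_dep - length(host_w))
    host_idx <- c(host_w, host_u)
    free_nfib_idx <- take(avail, cfg$n_nfib_sites - n_dep)
    indep_idx <- take(avail, n_indep)
    dormant_idx <- take(avail, n_dormant)
    ns_decoy_idx <- take(avail, cfg$n_ns_decoys)
    atac_decoy_idx <- take(avail, cfg$n_atac_decoys)
  })

  site_tbl <- function(idx, prefix) {
    s <- slots$start[idx]
    peaks(slots$chrom[idx], s, s + cfg$site_width,
          name = paste0(prefix, seq_along(idx)))
  }
  nfib_host <- site_tbl(host_idx, "nfib_host_")
  nfib_free <- site_tbl(free_nfib_idx, "nfib_")
  nfib_peaks <- normalize_peaks(dplyr::bind_rows(nfib_host, nfib_free), layout)
  orc1_dep <- site_tbl(host_idx, "orc1_dep_")
  orc1_indep <- site_tbl(indep_idx, "orc1_indep_")
  orc1_peaks <- normalize_peaks(dplyr::bind_rows(orc1_dep, orc1_indep), layout)
  dormant_peaks <- site_tbl(dormant_idx, "dormant_")

  dep_flag <- startsWith(orc1_peaks$name, "orc1_dep_")

  ## --- truth ledger ----------------------------------------------------
  n_dep <- length(host_idx); n_indep <- length(indep_idx)
  indep_class <- rep(c("S2-compensatory", "S3-stable"), length.out = n_indep)
  origins <- dplyr::bind_rows(
    dplyr::mutate(orc1_peaks[dep_flag, ], class = "S1-dependent"),
    dplyr::mutate(orc1_peaks[!dep_flag, ], class = indep_class),
    dplyr::mutate(dormant_peaks, class = "dormant")
  )
  origins$timing <- domain_class_at(cfg$timing_domains, origins$chrom,
                                    (origins$start + origins$end) / 2)
  act <- cfg$ns_signal_per_bin * cfg$site_width / cfg$track_bin
  origins$activity_control <- dplyr::case_when(
    origins$class == "dormant" ~ 0, TRUE ~ act
  )
  origins$activity_kd <- dplyr::case_when(
    origins$class == "S1-dependent" ~ act / cfg$knockdown_fc,
    origins$class == "S2-compensatory" ~ act * cfg$knockdown_fc,
    origins$class == "S3-stable" ~ act,
    origins$class == "dormant" ~ act
  )

  # internal consistency: dependent => overlapping an NFIB site
  dep_gr <- peaks_to_gr(origins[origins$class == "S1-dependent", ], layout)
  if (!all(GenomicRanges::countOverlaps(dep_gr,
                                        peaks_to_gr(nfib_peaks, layout)) > 0)) {
    stop("internal error: a dependent ORC1 site does not overlap an NFIB site")
  }

  ## --- CUT&Tag coverage tracks ----------------------------------------
  bw <- cfg$track_bin
  bins_per_chrom <- ceiling(layout$length / bw)
  bin_offset <- stats::setNames(cumsum(c(0, bins_per_chrom[-nrow(layout)])),
                                layout$chrom)
  site_track <- function(sites, per_bin, seed_off) {
    tr <- binned_track(layout, bw)
    mean_v <- rep(cfg$chip_background, nrow(tr))
    if (nrow(sites) > 0) {
      nb <- (sites$end - sites$start) / bw
      idx <- unlist(purrr::map2(bin_offset[sites$chrom] + sites$start / bw,
                                nb, function(o, n) o + seq_len(n)))
      mean_v[idx] <- mean_v[idx] + rep(per_bin, times = nb)
    }
    tr$value <- withr::with_seed(substream_seed(seed, seed_off),
                                 rnb(nrow(tr), mean_v, cfg$noise_dispersion))
    tr
  }
  sig <- cfg$chip_signal_per_bin
  fc <- cfg$knockdown_fc
  tracks <- list(
    nfib_control = site_track(nfib_peaks, rep(sig, nrow(nfib_peaks)), 21),
    nfib_kd = site_track(nfib_peaks, rep(sig / fc, nrow(nfib_peaks)), 22),
    orc1_control = site_track(orc1_peaks, rep(sig, nrow(orc1_peaks)), 23),
    orc1_kd = site_track(orc1_peaks,
                         ifelse(dep_flag, sig / fc, sig), 24)
  )

  ## --- Repli-seq fraction tracks --------------------------------------
  for (frac in c("early", "mid", "late")) {
    tr <- binned_track(layout, cfg$track_bin)
    m <- (tr$start + tr$end) / 2
    dom <- domain_class_at(cfg$timing_domains, tr$chrom, m)
    mu <- ifelse(dom == frac, cfg$timing_signal[["high"]],
                 cfg$timing_signal[["low"]])
    off <- match(frac, c("early", "mid", "late")) + 24
    tr$value <- withr::with_seed(substream_seed(seed, off),
                                 rnb(nrow(tr), mu, cfg$noise_dispersion))
    tracks[[frac]] <- tr
  }

  ## --- nascent-strand count tables -------------------------------------
  ns_decoys <- withr::with_seed(substream_seed(seed, 30), {
    w <- round(stats::runif(cfg$n_ns_decoys, cfg$ns_fragment_range[1],
                            cfg$ns_fragment_range[2]))
    s <- slots$start[ns_decoy_idx]
    peaks(slots$chrom[ns_decoy_idx], s, s + w,
          name = paste0("ns_decoy_", seq_along(ns_decoy_idx)))
  })
  ns_base <- dplyr::bind_rows(
    origins[, c("chrom", "start", "end", "name", "class")],
    dplyr::mutate(ns_decoys, class = "decoy")
  )
  ns_ctrl <- simulate_ns_counts(
    dplyr::mutate(ns_base, activity = c(origins$activity_control,
                                        rep(0, nrow(ns_decoys)))),
    cfg, seed = substream_seed(seed, 31)
  )
  ns_kd <- simulate_ns_counts(
    dplyr::mutate(ns_base, activity = c(origins$activity_kd,
                                        rep(0, nrow(ns_decoys)))),
    cfg, seed = substream_seed(seed, 32)
  )
  ns_counts <- dplyr::bind_rows(
    dplyr::mutate(ns_ctrl, condition = "control"),
    dplyr::mutate(ns_kd, condition = "knockdown")
  )

  ## --- ATAC replicate counts ------------------------------------------
  atac_decoys <- site_tbl(atac_decoy_idx, "atac_decoy_")
  atac_peaks <- dplyr::bind_rows(
    dplyr::mutate(nfib_peaks, open_truth = TRUE),
    dplyr::mutate(atac_decoys, open_truth = FALSE)
  )
  nb_site <- cfg$site_width / cfg$track_bin
  atac_counts <- withr::with_seed(substream_seed(seed, 41), {
    purrr::map_dfr(c("control", "knockdown"), function(cond) {
      purrr::map_dfr(seq_len(cfg$n_replicates), function(rep_i) {
        mu <- ifelse(atac_peaks$open_truth & cond == "knockdown",
                     cfg$atac_signal_per_bin / fc, cfg$atac_signal_per_bin)
        cnt <- vapply(seq_len(nrow(atac_peaks)), function(i) {
          sum(rnb(nb_site, mu[i], cfg$noise_dispersion))
        }, numeric(1))
        tibble::tibble(peak = atac_peaks$name, condition = cond,
                       replicate = rep_i, count = cnt)
      })
    })
  })

  ## --- PC1 compartment table ------------------------------------------
  pc1 <- comp[, c("chrom", "start", "end")]
  base_ctrl <- comp$pc1_base
  base_kd <- ifelse(comp$weakened, comp$pc1_base - cfg$weakened_delta,
                    comp$pc1_base)
  pc1$gene_density <- withr::with_seed(substream_seed(seed, 50),
    pmax(0, 3 + 2 * base_ctrl + stats::rnorm(nrow(comp), 0, 0.3)))
  withr::with_seed(substream_seed(seed, 51), {
    for (r in seq_len(cfg$n_replicates)) {
      pc1[[paste0("ctrl_rep", r)]] <- base_ctrl +
        rnorm0(nrow(comp), cfg$pc1_noise_sd)
      pc1[[paste0("kd_rep", r)]] <- base_kd +
        rnorm0(nrow(comp), cfg$pc1_noise_sd)
    }
  })

  ## --- CNA segments and cohorts ---------------------------------------
  cna <- simulate_cna(cfg, layout, substream_seed(seed, 61))
  cohorts <- simulate_cohorts(cfg, cna$planted, layout,
                              substream_seed(seed, 71))

  truth <- list(
    nfib_sites = nfib_peaks,
    orc1_sites = dplyr::mutate(orc1_peaks, dependent = dep_flag),
    origins = origins,
    weakened_bins = comp[comp$weakened, c("chrom", "start", "end", "bin_id")],
    open_peaks = atac_peaks[atac_peaks$open_truth,
                            c("chrom", "start", "end", "name")],
    cna_planted = cna$planted,
    cohort_loci = cohorts$loci
  )

  structure(list(
    layout = layout, config = cfg, truth = truth,
    nfib_peaks = nfib_peaks, orc1_peaks = orc1_peaks,
    tracks = tracks, ns_counts = ns_counts, atac_counts = atac_counts,
    pc1 = pc1, cna_segments = cna$segments, cohorts = cohorts$matrices
  ), class = "origin_study")
}

# Clone CNA segments: planted co-amplifications shared by >= 2 clones,
# spontaneous gains present in control and inherited by every clone,
# private gains/losses per clone; neutral copy 2 elsewhere.
simulate_cna <- function(cfg, layout, seed) {
  withr::with_seed(seed, {
    needed <- cfg$n_planted_cnas + 3 + cfg$n_clones * 5
    # event grid scaled to the genome so every event gets a distinct slot
    grid_w <- min(1e6, 1e4 * floor(sum(layout$length) / needed / 1e4))
    make_grid <- function(w) {
      purrr::map2_dfr(layout$chrom, layout$length, function(ch, len) {
        tibble::tibble(chrom = ch, start = (seq_len(floor(len / w)) - 1) * w)
      })
    }
    while (grid_w >= 5e4 && nrow(make_grid(grid_w)) < needed) {
      grid_w <- grid_w - 1e4
    }
    if (grid_w < 5e4) stop("genome too small for the configured CNA events",
                           call. = FALSE)
    grid <- make_grid(grid_w)
    pick <- sample(nrow(grid), needed)
    ptr <- 0
    next_regions <- function(n, width) {
      idx <- pick[ptr + seq_len(n)]; ptr <<- ptr + n
      peaks(grid$chrom[idx], grid$start[idx], grid$start[idx] + width)
    }
    clones <- paste0("clone_", seq_len(cfg$n_clones))
    w_unit <- grid_w / 5
    planted <- next_regions(cfg$n_planted_cnas, w_unit)
    planted$region <- paste0("coamp_", seq_len(nrow(planted)))
    planted$clones <- purrr::map(seq_len(nrow(planted)), function(i) {
      sample(clones, sample(2:cfg$n_clones, 1))
    })
    spont <- next_regions(3, round(0.75 * w_unit))
    events <- list()
    for (cl in clones) {
      gains <- next_regions(3, round(0.5 * w_unit)); gains$copy_number <- 3.5
      losses <- next_regions(2, round(0.5 * w_unit)); losses$copy_number <- 1
      shared <- planted[purrr::map_lgl(planted$clones, ~ cl %in% .x),
                        c("chrom", "start", "end")]
      if (nrow(shared)) shared$copy_number <- 4
      sp <- spont; sp$copy_number <- 3.5
      ev <- dplyr::bind_rows(gains[, c("chrom", "start", "end", "copy_number")],
                             losses[, c("chrom", "start", "end", "copy_number")],
                             shared, sp)
      ev$clone <- cl
      events[[cl]] <- ev
    }
    ctrl <- spont; ctrl$copy_number <- 3.5; ctrl$clone <- "control"
    events[["control"]] <- ctrl[, c("chrom", "start", "end", "copy_number", "clone")]
    seg <- dplyr::bind_rows(events)
    # neutral fill so each clone tiles the genome
    genome <- peaks(layout$chrom, rep(0, nrow(layout)), layout$length)
    seg <- purrr::map_dfr(unique(seg$clone), function(cl) {
      ev <- seg[seg$clone == cl, ]
      fill <- peak_subtract(genome, ev, layout)
      fill$copy_number <- 2; fill$clone <- cl
      dplyr::bind_rows(ev, fill) |>
        dplyr::arrange(match(.data$chrom, layout$chrom), .data$start)
    })
    list(segments = seg,
         planted = planted[, c("chrom", "start", "end", "region", "clones")])
  })
}

# Patient cohort amplification matrices: planted co-amplified loci are
# enriched in NFIB-amplified patients; null loci are independent.
simulate_cohorts <- function(cfg, planted, layout, seed) {
  withr::with_seed(seed, {
    grid_w <- min(1e6, 1e4 * floor(sum(layout$length) / cfg$n_null_loci / 2 / 1e4))
    grid <- purrr::map2_dfr(layout$chrom, layout$length, function(ch, len) {
      tibble::tibble(chrom = ch,
                     start = (seq_len(floor((len - grid_w / 2) / grid_w)) - 1) *
                       grid_w + grid_w / 2)
    })
    null_idx <- sample(nrow(grid), cfg$n_null_loci)
    null_loci <- peaks(grid$chrom[null_idx], grid$start[null_idx],
                       grid$start[null_idx] + grid_w / 5,
                       name = paste0("null_", seq_len(cfg$n_null_loci)))
    loci <- dplyr::bind_rows(
      peaks(planted$chrom, planted$start, planted$end, name = planted$region),
      null_loci
    )
    loci$co_occurring <- startsWith(loci$name, "coamp_")
    matrices <- lapply(seq_len(cfg$n_cohorts), function(co) {
      nfib <- stats::runif(cfg$n_patients) < 0.3
      m <- tibble::tibble(patient = paste0("p", seq_len(cfg$n_patients)),
                          nfib_amplified = nfib)
      for (i in seq_len(nrow(loci))) {
        p <- if (loci$co_occurring[i]) ifelse(nfib, 0.5, 0.05) else 0.08
        m[[loci$name[i]]] <- stats::runif(cfg$n_patients) < p
      }
      m
    })
    names(matrices) <- paste0("cohort_", seq_len(cfg$n_cohorts))
    list(matrices = matrices, loci = loci)
  })
}

#' Write a simulated study to files
#'
#' Emits every study table in its standard on-disk format — BED for peak
#' sets, bedGraph for tracks, TSV for count/PC1 tables, SEG-like TSV for
#' CNA segments, TSV per cohort, JSON for the truth ledger — all of which
#' round-trip through the package readers.
#'
#' @param study An `origin_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_chrom_sizes(study$layout, fp("genome.chrom.sizes"))
  write_bed(study$nfib_peaks, fp("nfib_peaks.bed"))
  write_bed(study$orc1_peaks, fp("orc1_peaks.bed"))
  for (nm in names(study$tracks)) {
    write_bedgraph(study$tracks[[nm]], fp(paste0(nm, ".bedgraph")))
  }
  readr::write_tsv(study$ns_counts, fp("ns_counts.tsv"))
  readr::write_tsv(study$atac_counts, fp("atac_counts.tsv"))
  readr::write_tsv(study$pc1, fp("pc1_compartments.tsv"))
  write_seg(study$cna_segments, fp("cna_segments.seg"))
  for (nm in names(study$cohorts)) {
    readr::write_tsv(study$cohorts[[nm]], fp(paste0(nm, ".tsv")))
  }
  truth <- study$truth
  truth$cna_planted$clones <- purrr::map_chr(truth$cna_planted$clones,
                                             paste, collapse = ",")
  jsonlite::write_json(truth, fp("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
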