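#' Build a peak table
#'
#' Peaks are plain tibbles with at least `chrom`, `start`, `end` (0-based
#' half-open) and optional `name` and `score` columns, so they pipe through
#' dplyr verbs like any other data frame.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer coordinates, 0-based half-open (`start < end`).
#' @param name Optional peak names.
#' @param score Optional numeric scores.
#' @return A tibble with columns `chrom`, `start`, `end` (+ `name`, `score`).
#' @export
#' @examples
#' peaks("chr1", c(0, 500), c(100, 900))
peaks <- function(chrom, start, end, name = NULL, score = NULL) {
  out <- tibble::tibble(chrom = as.character(chrom),
                        start = as.numeric(start),
                        end = as.numeric(end))
  if (!is.null(name)) out$name <- as.character(name)
  if (!is.null(score)) out$score <- as.numeric(score)
  if (any(out$start < 0) || any(out$start >= out$end)) {
    stop("peaks require 0 <= start < end", call. = FALSE)
  }
  out
}

#' Normalize a peak table against a genome layout
#'
#' Validates coordinates, orders rows by layout chromosome order then start,
#' and errors on chromosomes absent from the layout (naming them).
#'
#' @param x A peak data frame (`chrom`, `start`, `end`).
#' @param layout A [genome_layout()].
#' @return The sorted, validated peak tibble.
#' @export
normalize_peaks <- function(x, layout) {
  x <- tibble::as_tibble(x)
  check_chroms(x$chrom, layout)
  if (nrow(x) == 0) return(x)
  if (any(x$start < 0) || any(x$start >= x$end)) {
    stop("peaks require 0 <= start < end", call. = FALSE)
  }
  len <- layout_seqlengths(layout)[x$chrom]
  if (any(x$end > len)) {
    stop("peak end exceeds chromosome length", call. = FALSE)
  }
  ord <- order(match(x$chrom, layout$chrom), x$start, x$end)
  x[ord, , drop = FALSE]
}

# Convert a peak tibble to GRanges (1-based closed internally).
peaks_to_gr <- function(x, layout = NULL) {
  if (!is.null(layout)) check_chroms(x$chrom, layout)
  seqlev <- if (is.null(layout)) unique(x$chrom) else layout$chrom
  gr <- GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlev),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
  if (!is.null(layout)) {
    GenomeInfoDb::seqlengths(gr) <- layout_seqlengths(layout)[seqlev]
  }
  gr
}

gr_to_peaks <- function(gr) {
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1,
                 end = GenomicRanges::end(gr))
}

#' Read and write BED files
#'
#' BED3/BED6, tab-separated, no header; coordinates stay 0-based half-open.
#'
#' @param path File path.
#' @return `read_bed()` returns a peak tibble.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character")
  out <- peaks(x[[1]], as.numeric(x[[2]]), as.numeric(x[[3]]))
  if (ncol(x) >= 4) out$name <- x[[4]]
  if (ncol(x) >= 5) out$score <- suppressWarnings(as.numeric(x[[5]]))
  out
}

#' @rdname read_bed
#' @param x A peak data frame.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(x))
  # BED6 needs name before score; drop score-only without name
  if ("score" %in% cols && !"name" %in% cols) {
    x$name <- "."
    cols <- c("chrom", "start", "end", "name", "score")
  }
  df <- as.data.frame(x)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
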