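#' Define a genome layout
#'
#' A genome layout is the ordered table of chromosome names and lengths that
#' anchors every interval operation in the package. Coordinates throughout
#' are 0-based half-open (BED convention).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Positive integer vector of chromosome lengths in bp.
#' @return A tibble of class `genome_layout` with columns `chrom`, `length`.
#' @export
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
genome_layout <- function(chrom, length) {
  if (anyDuplicated(chrom)) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(length <= 0) || any(length != round(length))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  out <- tibble::tibble(chrom = as.character(chrom), length = as.numeric(length))
  class(out) <- c("genome_layout", class(out))
  out
}

#' Default toy genome layout
#'
#' Three 10-Mb chromosomes: large enough that 250-kb compartment bins,
#' kb-scale signal bins and thousands of peaks coexist, small enough that
#' every pipeline stage runs in seconds.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @return A [genome_layout()].
#' @export
default_layout <- function(n_chrom = 3, chrom_length = 1e7) {
  genome_layout(paste0("chr", seq_len(n_chrom)), rep(chrom_length, n_chrom))
}

#' Read/write a two-column chrom-sizes table
#'
#' @param path File path; tab-separated `chrom<TAB>length`, no header.
#' @return `read_chrom_sizes()` returns a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  genome_layout(x$chrom, x$length)
}

#' @rdname read_chrom_sizes
#' @param layout A [genome_layout()].
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(as.data.frame(layout)[, c("chrom", "length")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Named vector of chromosome lengths.
layout_seqlengths <- function(layout) {
  stats::setNames(layout$length, layout$chrom)
}

check_chroms <- function(chrom, layout) {
  bad <- setdiff(unique(chrom), layout$chrom)
  if (length(bad) > 0) {
    stop("unknown chromosome name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
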