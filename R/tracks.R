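#' Build a fixed-bin-width signal track
#'
#' A binned track is a tibble with one row per genomic bin (`chrom`, `start`,
#' `end`, `value`) tiling the whole layout at a fixed bin width; the final
#' bin of each chromosome is clipped to the chromosome length. Coverage-type
#' tracks carry non-negative values; PC1-type tracks may be negative.
#'
#' @param layout A [genome_layout()].
#' @param bin_width Bin width in bp.
#' @param values Either a single number (constant track), a named list of
#'   per-chromosome numeric vectors (length `ceiling(length / bin_width)`),
#'   or `NULL` for an all-zero track.
#' @return A tibble of class `binned_track` with attribute `bin_width`.
#' @export
#' @examples
#' binned_track(default_layout(1, 5000), 1000, values = list(chr1 = 1:5))
binned_track <- function(layout, bin_width, values = NULL) {
  stopifnot(bin_width > 0)
  grid <- purrr::map2_dfr(layout$chrom, layout$length, function(ch, len) {
    n <- ceiling(len / bin_width)
    s <- (seq_len(n) - 1) * bin_width
    tibble::tibble(chrom = ch, start = s, end = pmin(s + bin_width, len))
  })
  if (is.null(values)) {
    grid$value <- 0
  } else if (is.list(values)) {
    n_per <- ceiling(layout$length / bin_width)
    v <- purrr::map2(layout$chrom, n_per, function(ch, n) {
      vv <- values[[ch]]
      if (is.null(vv) || length(vv) != n) {
        stop("values for ", ch, " must have length ", n, call. = FALSE)
      }
      as.numeric(vv)
    })
    grid$value <- unlist(v, use.names = FALSE)
  } else {
    grid$value <- as.numeric(values)
  }
  attr(grid, "bin_width") <- bin_width
  class(grid) <- c("binned_track", class(grid))
  grid
}

track_bin_width <- function(track) {
  bw <- attr(track, "bin_width")
  if (is.null(bw)) bw <- max(track$end - track$start)
  bw
}

#' Mean signal of a track over intervals
#'
#' Length-weighted mean of the bin values overlapping each query interval:
#' each overlapping bin contributes its value weighted by the number of
#' bases it shares with the interval.
#'
#' @param track A [binned_track()].
#' @param query A peak data frame (`chrom`, `start`, `end`).
#' @return Numeric vector, one mean per row of `query`.
#' @export
mean_signal <- function(track, query) {
  if (nrow(query) == 0) return(numeric(0))
  bw <- track_bin_width(track)
  # split track values per chromosome for O(1) bin lookup
  vals <- split(track$value, track$chrom)
  n_bins <- vapply(vals, length, integer(1))
  out <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    ch <- query$chrom[i]
    v <- vals[[ch]]
    if (is.null(v)) stop("unknown chromosome name: ", ch, call. = FALSE)
    s <- query$start[i]; e <- query$end[i]
    b0 <- floor(s / bw); b1 <- floor((e - 1) / bw)
    b1 <- min(b1, n_bins[[ch]] - 1)
    idx <- b0:b1
    bs <- idx * bw; be <- bs + bw
    w <- pmin(e, be) - pmax(s, bs)
    out[i] <- sum(v[idx + 1] * w) / sum(w)
  }
  out
}

#' Add a mean-signal column to a peak table
#'
#' Pipe-friendly wrapper around [mean_signal()].
#'
#' @param x A peak data frame.
#' @param track A [binned_track()].
#' @param col Name of the column to add.
#' @return `x` with the new signal column.
#' @export
add_signal <- function(x, track, col = "signal") {
  x[[col]] <- mean_signal(track, x)
  x
}

#' Read and write bedGraph tracks
#'
#' Reads a 4-column bedGraph (no header) onto the full bin grid of `layout`;
#' bins absent from the file get value 0. A fixed bin width is enforced on
#' read: every record must align to the `bin_width` grid.
#'
#' @param path File path.
#' @param layout A [genome_layout()].
#' @param bin_width Bin width in bp.
#' @return `read_bedgraph()` returns a [binned_track()].
#' @export
read_bedgraph <- function(path, layout, bin_width) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "numeric", "numeric", "numeric"))
  check_chroms(x$chrom, layout)
  len <- layout_seqlengths(layout)[x$chrom]
  ok <- x$start %% bin_width == 0 &
    (x$end - x$start == bin_width | x$end == len)
  if (!all(ok)) {
    stop("bedGraph records do not align to a fixed ", bin_width,
         "-bp bin grid", call. = FALSE)
  }
  tr <- binned_track(layout, bin_width)
  key_tr <- paste(tr$chrom, tr$start)
  m <- match(paste(x$chrom, x$start), key_tr)
  tr$value[m] <- x$value
  tr
}

#' @rdname read_bedgraph
#' @param track A [binned_track()].
#' @param drop_zero Omit zero-value bins on write (default TRUE).
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  df <- as.data.frame(track)[, c("chrom", "start", "end", "value")]
  if (drop_zero) df <- df[df$value != 0, , drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
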