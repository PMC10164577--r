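#' Stranded per-bin signal track
#'
#' Container for forward/reverse per-bin read counts (or normalized signal)
#' on one reference sequence with a fixed bin width. Bin `i` (0-based) covers
#' `[i * bin_width, (i + 1) * bin_width)`.
#'
#' @param reference Reference (chromosome/plasmid) name.
#' @param bin_width Bin width in bp (> 0).
#' @param fwd,rev Equal-length nonnegative numeric vectors of per-bin
#'   forward- and reverse-strand signal.
#' @param units `"counts"` or `"CPM"`.
#' @return An object of class `StrandedBinTrack` with fields `reference`,
#'   `bin_width`, `F`, `R`, `units`.
#' @export
stranded_bin_track <- function(reference, bin_width, fwd, rev,
                               units = c("counts", "CPM")) {
  units <- match.arg(units)
  fwd <- as.numeric(fwd); rev <- as.numeric(rev)
  if (length(fwd) != length(rev)) {
    stop("forward and reverse vectors must have equal length")
  }
  if (length(fwd) == 0L) stop("track must contain at least one bin")
  if (anyNA(fwd) || anyNA(rev)) stop("track signal must not contain NA")
  if (any(fwd < 0) || any(rev < 0)) stop("track signal must be nonnegative")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  structure(
    list(reference = as.character(reference), bin_width = as.numeric(bin_width),
         F = fwd, R = rev, units = units),
    class = "StrandedBinTrack"
  )
}

#' @export
print.StrandedBinTrack <- function(x, ...) {
  cat(sprintf(
    "StrandedBinTrack: %s, %d bins x %g bp [%s]\n  total F = %.4g, total R = %.4g\n",
    x$reference, length(x$F), x$bin_width, x$units, sum(x$F), sum(x$R)))
  invisible(x)
}

#' @export
length.StrandedBinTrack <- function(x) length(x$F)

#' Per-bin partition (or RFD) score track
#'
#' Holds a per-bin score in `[-1, 1]`, with a logical validity mask; bins
#' that are masked out (or had zero coverage) carry `NA`.
#'
#' @param reference Reference name.
#' @param bin_width Bin width in bp.
#' @param value Numeric vector of scores; `NA` where undefined.
#' @param mask Logical vector, `TRUE` where the bin is valid.
#' @return An object of class `PartitionTrack`.
#' @export
partition_track <- function(reference, bin_width, value, mask) {
  if (length(value) != length(mask)) stop("value and mask lengths differ")
  mask <- as.logical(mask)
  value <- as.numeric(value)
  value[!mask] <- NA_real_
  ok <- value[!is.na(value)]
  if (any(ok < -1 | ok > 1)) stop("partition values must lie in [-1, 1]")
  structure(
    list(reference = as.character(reference), bin_width = as.numeric(bin_width),
         value = value, mask = mask),
    class = "PartitionTrack"
  )
}

#' @export
print.PartitionTrack <- function(x, ...) {
  cat(sprintf(
    "PartitionTrack: %s, %d bins x %g bp (%d valid)\n  range [%.3f, %.3f]\n",
    x$reference, length(x$value), x$bin_width, sum(x$mask),
    suppressWarnings(min(x$value, na.rm = TRUE)),
    suppressWarnings(max(x$value, na.rm = TRUE))))
  invisible(x)
}

track_to_granges <- function(reference, bin_width, score) {
  n <- length(score)
  GenomicRanges::GRanges(
    seqnames = reference,
    ranges = IRanges::IRanges(start = (seq_len(n) - 1L) * bin_width + 1L,
                              width = bin_width),
    score = as.numeric(score)
  )
}

#' Write a stranded track as a pair of bedGraph files
#'
#' One bedGraph per strand, 0-based half-open intervals, one record per bin.
#'
#' @param track A [stranded_bin_track()].
#' @param fwd_file,rev_file Output paths for the forward/reverse strand.
#' @return Invisibly, the two paths.
#' @export
write_stranded_bedgraph <- function(track, fwd_file, rev_file) {
  stopifnot(inherits(track, "StrandedBinTrack"))
  rtracklayer::export(track_to_granges(track$reference, track$bin_width, track$F),
                      fwd_file, format = "bedGraph")
  rtracklayer::export(track_to_granges(track$reference, track$bin_width, track$R),
                      rev_file, format = "bedGraph")
  invisible(c(fwd_file, rev_file))
}

#' Read a stranded track from a pair of bedGraph files
#'
#' Expects the bin layout written by [write_stranded_bedgraph()]: contiguous
#' fixed-width bins on a single reference, identical in both files.
#'
#' @param fwd_file,rev_file bedGraph paths for forward/reverse strand.
#' @param units Signal units of the stored values.
#' @return A [stranded_bin_track()].
#' @export
read_stranded_bedgraph <- function(fwd_file, rev_file,
                                   units = c("counts", "CPM")) {
  units <- match.arg(units)
  gf <- rtracklayer::import(fwd_file, format = "bedGraph")
  gr <- rtracklayer::import(rev_file, format = "bedGraph")
  if (length(gf) != length(gr)) stop("strand files disagree on bin count")
  ref <- as.character(GenomicRanges::seqnames(gf)[1L])
  bw <- IRanges::width(gf)[1L]
  stranded_bin_track(ref, bw, gf$score, gr$score, units = units)
}

#' Read initiation zones from a BED file
#'
#' Interval midpoints are converted to bin indices; an optional BED name
#' field of `"-"` (or strand `"-"`) marks orientation -1, anything else +1.
#'
#' @param file BED path.
#' @param bin_width Bin width of the track the zones refer to.
#' @return A data.frame with columns `reference`, `center_bin`, `orientation`.
#' @export
read_iz_bed <- function(file, bin_width) {
  g <- rtracklayer::import(file, format = "BED")
  mid <- (GenomicRanges::start(g) + GenomicRanges::end(g)) %/% 2L
  ori <- rep(1L, length(g))
  strand <- as.character(GenomicRanges::strand(g))
  ori[strand == "-"] <- -1L
  data.frame(reference = as.character(GenomicRanges::seqnames(g)),
             center_bin = as.integer((mid - 1L) %/% bin_width),
             orientation = ori)
}
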