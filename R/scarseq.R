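## Strand-partition analysis for SCAR-seq style stranded tracks:
## CPM -> uniform blur -> input subtraction -> coverage filter -> partition.

#' Counts-per-million normalization of a stranded track
#'
#' Scales both strands by `1e6 / library_total`. The denominator is the
#' sample's total mapped target-genome reads (both strands of one library),
#' not the per-strand or per-region sum.
#'
#' @param track A [stranded_bin_track()] in counts.
#' @param library_total Total mapped reads of the library (> 0). Defaults to
#'   the track's own total, appropriate when the track covers the whole
#'   mapped reference space.
#' @return The track in CPM units.
#' @export
cpm_normalize <- function(track, library_total = NULL) {
  stopifnot(inherits(track, "StrandedBinTrack"))
  if (track$units != "counts") stop("track must be in counts")
  if (is.null(library_total)) library_total <- sum(track$F) + sum(track$R)
  if (!is.numeric(library_total) || library_total <= 0) {
    stop("library_total must be > 0")
  }
  k <- 1e6 / library_total
  stranded_bin_track(track$reference, track$bin_width,
                     track$F * k, track$R * k, units = "CPM")
}

running_mean_truncated <- function(x, h) {
  if (h == 0L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Uniform (boxcar) smoothing of a stranded track
#'
#' Replaces each bin by the mean over the window of `halfwidth` bins on each
#' side. Windows at the track edges are truncated to the track and
#' renormalized by their actual size, so no signal is fabricated beyond the
#' ends. `halfwidth = 0` is the identity.
#'
#' @param track A [stranded_bin_track()].
#' @param halfwidth Bins on each side of the window (default 30).
#' @return Smoothed track, same units.
#' @export
uniform_blur <- function(track, halfwidth = 30L) {
  stopifnot(inherits(track, "StrandedBinTrack"))
  if (halfwidth < 0L) stop("halfwidth must be >= 0")
  h <- as.integer(halfwidth)
  stranded_bin_track(track$reference, track$bin_width,
                     running_mean_truncated(track$F, h),
                     running_mean_truncated(track$R, h),
                     units = track$units)
}

#' Subtract the input track from a pulldown track, clipping at zero
#'
#' Per strand and per bin, `max(pulldown - input, 0)`. Both tracks must be
#' in the same units (CPM) and have identical shape; both are expected to
#' have been smoothed the same way.
#'
#' @param pulldown,input [stranded_bin_track()]s in CPM.
#' @return Input-corrected track.
#' @export
input_correct <- function(pulldown, input) {
  stopifnot(inherits(pulldown, "StrandedBinTrack"),
            inherits(input, "StrandedBinTrack"))
  if (length(pulldown$F) != length(input$F) ||
      pulldown$bin_width != input$bin_width) {
    stop("pulldown and input tracks must have the same shape")
  }
  if (pulldown$units != input$units) stop("units mismatch")
  stranded_bin_track(pulldown$reference, pulldown$bin_width,
                     pmax(pulldown$F - input$F, 0),
                     pmax(pulldown$R - input$R, 0),
                     units = pulldown$units)
}

#' Low-coverage mask for an input-corrected track
#'
#' A bin is masked out when the signal is below `threshold_cpm` on both
#' strands; a bin with adequate coverage on either strand is kept, so
#' legitimately one-sided bins near strong asymmetry survive.
#'
#' @param track Input-corrected track in CPM.
#' @param threshold_cpm Coverage threshold (default 0.3 CPM).
#' @return Logical vector, `TRUE` where the bin is kept. Bins with zero
#'   signal on both strands are always masked (the partition is undefined
#'   there).
#' @export
coverage_filter <- function(track, threshold_cpm = 0.3) {
  stopifnot(inherits(track, "StrandedBinTrack"))
  keep <- !(track$F < threshold_cpm & track$R < threshold_cpm)
  keep & (track$F + track$R > 0)
}

#' Strand partition score
#'
#' `partition = (F - R) / (F + R)` per kept bin: +1 when all signal is on
#' the nascent forward strand, -1 when all on the reverse.
#'
#' @param track Input-corrected [stranded_bin_track()].
#' @param mask Logical keep-mask, e.g. from [coverage_filter()]; defaults to
#'   keeping every bin with nonzero total.
#' @return A [partition_track()]; masked and zero-total bins are `NA`.
#' @export
partition <- function(track, mask = NULL) {
  stopifnot(inherits(track, "StrandedBinTrack"))
  tot <- track$F + track$R
  if (is.null(mask)) mask <- tot > 0 else mask <- mask & tot > 0
  val <- rep(NA_real_, length(tot))
  val[mask] <- (track$F[mask] - track$R[mask]) / tot[mask]
  partition_track(track$reference, track$bin_width, val, mask)
}

#' Replication fork directionality score
#'
#' `RFD = (R - F) / (F + R)`, the exact negative of [partition()] on the
#' same input (the convention used for Okazaki-fragment strand counts).
#'
#' @inheritParams partition
#' @return A [partition_track()] holding RFD values.
#' @export
rfd <- function(track, mask = NULL) {
  p <- partition(track, mask)
  partition_track(p$reference, p$bin_width, -p$value, p$mask)
}

#' Meta-profile of partition scores around initiation zones
#'
#' Averages the partition track at each signed bin offset in
#' `[-window, window]` across initiation zones. Zones with orientation -1
#' are mirrored and sign-flipped before averaging, so leading-strand bias
#' appears on a consistent side regardless of each zone's RFD polarity.
#'
#' @param ptrack A [partition_track()].
#' @param izs data.frame with columns `center_bin` (0-based) and
#'   `orientation` (+1/-1), e.g. from [read_iz_bed()].
#' @param window Half-width of the profile in bins (> 0).
#' @return data.frame with columns `offset` (bins), `offset_bp`,
#'   `mean_partition`, `n` (zones contributing a non-missing value).
#' @export
iz_metaprofile <- function(ptrack, izs, window) {
  stopifnot(inherits(ptrack, "PartitionTrack"), window > 0)
  if (NROW(izs) == 0L) stop("initiation zone list is empty")
  if (is.null(izs$orientation)) izs$orientation <- rep(1L, NROW(izs))
  offsets <- seq.int(-window, window)
  nb <- length(ptrack$value)
  acc <- numeric(length(offsets)); cnt <- integer(length(offsets))
  for (i in seq_len(NROW(izs))) {
    ori <- izs$orientation[i]
    bins <- izs$center_bin[i] + ori * offsets        # mirror for ori = -1
    ok <- bins >= 0L & bins < nb
    v <- rep(NA_real_, length(offsets))
    v[ok] <- ptrack$value[bins[ok] + 1L] * ori       # sign-flip for ori = -1
    use <- !is.na(v)
    acc[use] <- acc[use] + v[use]
    cnt <- cnt + use
  }
  data.frame(offset = offsets, offset_bp = offsets * ptrack$bin_width,
             mean_partition = ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_),
             n = cnt)
}

#' Spike-in normalization of per-sample read totals
#'
#' Scales each sample's target-genome total by its exogenous spike-in count
#' and expresses the result relative to a reference sample:
#' `(target_s / spikein_s) / (target_ref / spikein_ref)`.
#'
#' @param sample_totals Named list (or data.frame with rownames) mapping each
#'   sample to `c(target, spikein)` read counts, all > 0.
#' @param reference_sample Name of the reference sample (maps to 1.0).
#' @return Named numeric vector of normalized relative abundances.
#' @export
spikein_normalize <- function(sample_totals, reference_sample) {
  if (is.data.frame(sample_totals)) {
    sample_totals <- stats::setNames(
      lapply(seq_len(nrow(sample_totals)),
             function(i) c(sample_totals$target[i], sample_totals$spikein[i])),
      rownames(sample_totals))
  }
  if (!reference_sample %in% names(sample_totals)) {
    stop("reference sample not present")
  }
  ratios <- vapply(sample_totals, function(v) {
    if (v[2L] <= 0) stop("spike-in count must be > 0")
    if (v[1L] <= 0) stop("target count must be > 0")
    v[1L] / v[2L]
  }, numeric(1))
  ratios / ratios[[reference_sample]]
}

#' Full SCAR partition pipeline for one pulldown/input sample
#'
#' Runs CPM normalization, uniform blur, input subtraction with zero
#' clipping, coverage filtering and the partition computation, in that
#' order, on raw count tracks.
#'
#' @param pulldown,input Count [stranded_bin_track()]s.
#' @param pulldown_total,input_total Library totals for CPM (default: track
#'   sums).
#' @param blur_halfwidth Smoothing half-width in bins (default 30).
#' @param min_cpm Coverage threshold (default 0.3 CPM).
#' @return List with `partition` and `rfd` ([partition_track()]s), the
#'   input-corrected `track`, and the keep `mask`.
#' @export
scar_pipeline <- function(pulldown, input, pulldown_total = NULL,
                          input_total = NULL, blur_halfwidth = 30L,
                          min_cpm = 0.3) {
  pd <- uniform_blur(cpm_normalize(pulldown, pulldown_total), blur_halfwidth)
  ip <- uniform_blur(cpm_normalize(input, input_total), blur_halfwidth)
  corrected <- input_correct(pd, ip)
  mask <- coverage_filter(corrected, min_cpm)
  list(partition = partition(corrected, mask),
       rfd = rfd(corrected, mask),
       track = corrected, mask = mask)
}

#' Write an initiation-zone meta-profile as TSV
#' @param profile data.frame from [iz_metaprofile()].
#' @param file Output path.
#' @export
write_metaprofile_tsv <- function(profile, file) {
  utils::write.table(profile, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
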