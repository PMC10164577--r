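## Gel densitometry: background subtraction, ladder calibration, band-front
## detection, maximum replication-rate regression and lane-intensity ratios.

#' One-dimensional gel lane profile
#'
#' @param position Strictly increasing migration coordinate (arbitrary
#'   units; larger = migrated farther, i.e. smaller species).
#' @param intensity Per-position signal (same length as `position`).
#' @param lane_length Total migration span used as the Rf denominator
#'   (default: the largest position).
#' @return A `LaneProfile` object.
#' @export
lane_profile <- function(position, intensity, lane_length = max(position)) {
  position <- as.numeric(position); intensity <- as.numeric(intensity)
  if (length(position) != length(intensity)) stop("length mismatch")
  if (length(position) < 2L) stop("a lane needs at least 2 positions")
  if (any(diff(position) <= 0)) stop("positions must be strictly increasing")
  if (lane_length <= 0) stop("lane_length must be > 0")
  structure(list(position = position, intensity = intensity,
                 lane_length = as.numeric(lane_length)),
            class = "LaneProfile")
}

#' @export
print.LaneProfile <- function(x, ...) {
  cat(sprintf("LaneProfile: %d positions over %.3g units, peak %.4g\n",
              length(x$position), x$lane_length, max(x$intensity)))
  invisible(x)
}

#' Read a lane profile from TSV (columns `position`, `intensity`)
#' @param file TSV path.
#' @param lane_length Optional Rf denominator override.
#' @export
read_lane_tsv <- function(file, lane_length = NULL) {
  tab <- utils::read.delim(file)
  lane_profile(tab$position, tab$intensity,
               lane_length = lane_length %||% max(tab$position))
}

running_min <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    min(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Minimum-profile background subtraction
#'
#' Estimates the lane background as the lower envelope of the profile — the
#' running minimum over a window — and subtracts it, clamping at zero. A
#' constant lane maps to zero; output never exceeds the input.
#'
#' @param profile A [lane_profile()].
#' @param window_fraction Envelope window as a fraction of the number of
#'   positions (default 0.1).
#' @return Background-subtracted `LaneProfile`.
#' @export
subtract_background_minprofile <- function(profile, window_fraction = 0.1) {
  stopifnot(inherits(profile, "LaneProfile"))
  half <- max(1L, as.integer(window_fraction * length(profile$position) / 2))
  env <- running_min(profile$intensity, half)
  lane_profile(profile$position, pmax(profile$intensity - env, 0),
               lane_length = profile$lane_length)
}

#' Fit a log-linear molecular-weight calibration from ladder bands
#'
#' Least-squares fit of `log10(size_bp) = slope * Rf + intercept`, with
#' `Rf = position / lane_length` (retardation factor). Requires at least 3
#' bands; slope must come out negative (larger fragments migrate less).
#'
#' @param band_positions Migration positions of the ladder bands.
#' @param band_sizes Known band sizes in bp (same order).
#' @param lane_length Rf denominator.
#' @return A `LadderCalibration` with `slope`, `intercept`, `r_squared`,
#'   `lane_length`.
#' @export
fit_ladder <- function(band_positions, band_sizes, lane_length) {
  if (length(band_positions) != length(band_sizes)) stop("length mismatch")
  if (length(band_positions) < 3L) stop("need at least 3 ladder bands")
  if (any(band_sizes <= 0)) stop("band sizes must be > 0")
  if (lane_length <= 0) stop("lane_length must be > 0")
  rf <- band_positions / lane_length
  if (stats::sd(rf) == 0) stop("degenerate band positions")
  fit <- stats::lm(log10(band_sizes) ~ rf)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 lane_length = as.numeric(lane_length)),
            class = "LadderCalibration")
}

#' @export
print.LadderCalibration <- function(x, ...) {
  cat(sprintf(
    "LadderCalibration: log10(bp) = %.4f * Rf + %.4f (R^2 = %.4f)\n",
    x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert a migration position to fragment size
#'
#' `size = 10 ^ (slope * Rf + intercept)`.
#'
#' @param calib A [fit_ladder()] calibration.
#' @param position Migration position(s).
#' @return Fragment size(s) in bp.
#' @export
position_to_bp <- function(calib, position) {
  stopifnot(inherits(calib, "LadderCalibration"))
  10^(calib$slope * position / calib$lane_length + calib$intercept)
}

#' Detect the high-molecular-weight front of a product smear
#'
#' Returns the smallest migration position (least-migrated, largest-product
#' side) at which the intensity first exceeds `fraction_of_max` of the lane
#' maximum, linearly interpolated between samples. The threshold is relative,
#' so the front is invariant to exposure scaling. The band edge must be
#' sustained: the crossing counts only when the signal stays above the
#' threshold for `min_run` consecutive positions, so isolated noise specks
#' on the high-molecular-weight side are ignored.
#'
#' @param profile Background-subtracted [lane_profile()] with a detectable
#'   peak (`max > 0`).
#' @param fraction_of_max Relative threshold (default 0.05).
#' @param min_run Consecutive above-threshold positions required (default 5).
#' @return Front migration position.
#' @export
detect_front <- function(profile, fraction_of_max = 0.05, min_run = 5L) {
  stopifnot(inherits(profile, "LaneProfile"),
            fraction_of_max > 0, fraction_of_max <= 1, min_run >= 1L)
  y <- profile$intensity
  peak <- max(y)
  if (peak <= 0) stop("profile has no signal")
  thr <- fraction_of_max * peak
  above <- y >= thr
  run <- 0L; i <- NA_integer_
  for (j in seq_along(above)) {
    run <- if (above[j]) run + 1L else 0L
    if (run == min_run) { i <- j - min_run + 1L; break }
  }
  if (is.na(i)) stop("no sustained band edge above the threshold")
  x <- profile$position
  if (i == 1L || y[i] <= y[i - 1L]) return(x[i])
  x[i - 1L] + (thr - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
}

#' Maximum replication rate from time-resolved product fronts
#'
#' Ordinary least-squares regression of front size (bp) on chase time over
#' the earliest `use_first` timepoints; the slope is the maximum
#' leading-strand synthesis rate.
#'
#' @param front_bp_by_time Named numeric vector: names are chase times in
#'   minutes, values are front sizes in bp.
#' @param use_first Number of earliest timepoints used (default 3).
#' @return A `RateEstimate` with `rate` (kb/min), `intercept` (kb),
#'   `n_points` and `residual` (RMS, kb).
#' @export
max_replication_rate <- function(front_bp_by_time, use_first = 3L) {
  t <- as.numeric(names(front_bp_by_time))
  if (anyNA(t)) stop("front_bp_by_time must be named by time (minutes)")
  ord <- order(t)
  t <- t[ord]; bp <- as.numeric(front_bp_by_time)[ord]
  if (length(t) < use_first) stop("fewer timepoints than use_first")
  t <- t[seq_len(use_first)]; bp <- bp[seq_len(use_first)]
  if (length(t) < 2L) stop("need at least 2 timepoints")
  fit <- stats::lm(bp ~ t)
  res <- stats::residuals(fit)
  structure(list(rate = unname(stats::coef(fit)[2L]) / 1000,
                 intercept = unname(stats::coef(fit)[1L]) / 1000,
                 n_points = length(t),
                 residual = sqrt(mean(res^2)) / 1000),
            class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("RateEstimate: %.3f kb/min (%d points, RMS %.3g kb)\n",
              x$rate, x$n_points, x$residual))
  invisible(x)
}

#' Normalize a replication rate to a reference condition
#'
#' @param rate Rate estimate (kb/min) or `RateEstimate`.
#' @param reference_rate Reference condition's rate (> 0), e.g. the
#'   clamp-loaded reaction without chaperone.
#' @return Dimensionless relative rate; the reference maps to 1.
#' @export
normalize_rate <- function(rate, reference_rate) {
  if (inherits(rate, "RateEstimate")) rate <- rate$rate
  if (inherits(reference_rate, "RateEstimate")) {
    reference_rate <- reference_rate$rate
  }
  if (reference_rate <= 0) stop("reference_rate must be > 0")
  rate / reference_rate
}

#' EMSA percent bound from unbound-band depletion
#'
#' `%bound = 100 - 100 * unbound / unbound_reference`, where the reference
#' is the unbound-band intensity of the no-protein lane; clamped to
#' `[0, 100]`.
#'
#' @param unbound_intensity Unbound-band intensity of the titrated lane(s).
#' @param unbound_reference Unbound-band intensity of the no-protein lane.
#' @return Percent bound in `[0, 100]`.
#' @export
emsa_percent_bound <- function(unbound_intensity, unbound_reference) {
  if (any(unbound_reference <= 0)) stop("reference intensity must be > 0")
  pmin(pmax(100 - 100 * unbound_intensity / unbound_reference, 0), 100)
}

#' Full-length product fraction of a primer-extension lane
#'
#' `100 * (intensity inside the full-length band window) / (total lane
#' intensity)`.
#'
#' @param profile A [lane_profile()].
#' @param band_window Numeric `c(lo, hi)` migration-position interval of the
#'   full-length band.
#' @return Percentage in `[0, 100]`.
#' @export
fulllength_fraction <- function(profile, band_window) {
  stopifnot(inherits(profile, "LaneProfile"), length(band_window) == 2L)
  lo <- min(band_window); hi <- max(band_window)
  if (lo < min(profile$position) - 1e-9 ||
      hi > max(profile$position) + 1e-9) {
    stop("band window outside the lane")
  }
  total <- sum(profile$intensity)
  if (total <= 0) stop("lane has no signal")
  inside <- profile$position >= lo & profile$position <= hi
  100 * sum(profile$intensity[inside]) / total
}
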