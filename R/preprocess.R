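# Count-conversion constants (package convention, documented in the
# methods vignette): clip at +/- 2.13 g, quantization resolution 1/32 g,
# deadband of 2 quantization units, 10 Hz decimation before the 1 s epoch
# sum.
.count_clip_g <- 2.13
.count_resolution_g <- 1 / 32
.count_deadband_units <- 2L
.count_decimated_hz <- 10L

#' Construct a 1 Hz activity-count series
#'
#' @param counts Non-negative integer counts, one per 1 s epoch.
#' @param limb `"preferred"` or `"non_preferred"`.
#' @param valid Logical wear-validity flag per epoch.
#' @return Tibble with columns `epoch` (0-based second), `counts`, `valid`;
#'   attribute `limb`.
#' @export
new_counts_series <- function(counts, limb = "preferred",
                              valid = rep(TRUE, length(counts))) {
  if (any(counts < 0)) abort("activity counts must be non-negative.")
  out <- tibble(epoch = seq_along(counts) - 1L,
                counts = as.integer(counts), valid = valid)
  attr(out, "limb") <- limb
  class(out) <- c("ul_counts", class(out))
  out
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-4 Butterworth applied forward and backward (zero phase), the
#' realization used for both the 0.25–2.5 Hz counts path and the 0.2–12 Hz
#' raw path.
#'
#' @param x Numeric signal.
#' @param sample_rate Sampling rate in Hz.
#' @param low,high Band edges in Hz; must satisfy 0 < low < high < Nyquist.
#' @param order Filter order per pass (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, sample_rate, low, high, order = 4) {
  nyq <- sample_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    abort(sprintf("band edges must satisfy 0 < low < high < %.3g Hz (Nyquist).", nyq))
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # the passband excludes DC, so remove the mean up front; reflective
  # padding keeps the remaining filtfilt edge transients off the data
  x <- x - mean(x)
  pad <- min(length(x) - 1, 3 * sample_rate)
  xp <- c(rev(x[seq_len(pad) + 1]), x, x[length(x) - seq_len(pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + length(x))]
}

#' Euclidean vector magnitude of triaxial acceleration
#'
#' @param x,y,z Per-axis values (vectors allowed).
#' @return `sqrt(x^2 + y^2 + z^2)`.
#' @export
vector_magnitude <- function(x, y, z) sqrt(x^2 + y^2 + z^2)

#' Band-limited vector magnitude of a raw recording (raw processing path)
#'
#' Applies the 0.2–12 Hz zero-phase bandpass per axis, then takes the
#' per-sample vector magnitude. This is the series the jerk asymmetry and
#' spectral arc length variables are computed from.
#'
#' @param recording Tibble from [simulate_limb_signal()] or
#'   [read_raw_csv()] (columns `x_g`, `y_g`, `z_g`; attr `sample_rate`).
#' @param low,high Band edges in Hz (defaults 0.2 and 12).
#' @return Tibble with columns `time`, `vm`; attributes `limb`,
#'   `sample_rate`.
#' @export
filter_raw <- function(recording, low = 0.2, high = 12) {
  fs <- attr(recording, "sample_rate")
  if (is.null(fs)) abort("`recording` must carry a `sample_rate` attribute.")
  out <- tibble(
    time = recording$time,
    vm = vector_magnitude(
      bandpass(recording$x_g, fs, low, high),
      bandpass(recording$y_g, fs, low, high),
      bandpass(recording$z_g, fs, low, high)
    )
  )
  attr(out, "limb") <- attr(recording, "limb")
  attr(out, "sample_rate") <- fs
  out
}

# quantized, rectified, deadbanded per-axis count path
axis_counts <- function(x, fs, low, high) {
  y <- bandpass(x, fs, low, high)
  y <- clamp(y, -.count_clip_g, .count_clip_g)
  q <- floor(abs(y) / .count_resolution_g)          # integer quantization units
  q[q < .count_deadband_units] <- 0
  dec <- fs / .count_decimated_hz
  q <- q[seq(1, length(q), by = dec)]               # decimate to 10 Hz
  n_ep <- floor(length(q) / .count_decimated_hz)
  ep <- matrix(q[seq_len(n_ep * .count_decimated_hz)], nrow = .count_decimated_hz)
  as.integer(colSums(ep))
}

#' Convert a raw triaxial recording to 1 Hz activity counts
#'
#' Open-replication count conversion: per axis, the 0.25–2.5 Hz zero-phase
#' bandpass is applied, the signal is clipped to ±2.13 g, quantized to
#' 1/32 g units, rectified, deadbanded (units below 2 are zeroed),
#' decimated to 10 Hz and summed over each 1 s epoch; the per-epoch vector
#' magnitude across the three axis counts (floored to an integer) is the
#' reported count. Static wear (gravity only) therefore produces zero
#' counts.
#'
#' @param recording Raw recording tibble (columns `x_g`, `y_g`, `z_g`,
#'   attrs `sample_rate`, `limb`); sample rate must be >= 20 Hz. Rates
#'   other than 30 Hz are linearly resampled to 30 Hz first.
#' @param low,high Count-path band edges in Hz (defaults 0.25, 2.5).
#' @return A counts series tibble (see [new_counts_series()]).
#' @export
to_activity_counts <- function(recording, low = 0.25, high = 2.5) {
  fs <- attr(recording, "sample_rate")
  if (is.null(fs) || fs < 20) abort("`recording` sample rate must be >= 20 Hz.")
  if (nrow(recording) < fs) abort("recording shorter than one 1 s epoch.")
  xyz <- recording[, c("x_g", "y_g", "z_g")]
  if (fs != 30) {
    t_old <- recording$time
    t_new <- seq(t_old[1], t_old[length(t_old)], by = 1 / 30)
    xyz <- as_tibble(lapply(xyz, function(v) stats::approx(t_old, v, t_new)$y))
    fs <- 30
  }
  cx <- axis_counts(xyz$x_g, fs, low, high)
  cy <- axis_counts(xyz$y_g, fs, low, high)
  cz <- axis_counts(xyz$z_g, fs, low, high)
  vm <- floor(vector_magnitude(cx, cy, cz))
  new_counts_series(as.integer(vm), limb = attr(recording, "limb") %||% "preferred")
}

#' Mark device-off intervals in a counts series as invalid
#'
#' Epochs whose start falls inside any `[off_start, off_end)` interval are
#' flagged invalid and excluded from all downstream sums, medians and SDs.
#'
#' @param counts Counts series tibble.
#' @param wear_log Tibble with columns `off_start`, `off_end` (seconds from
#'   recording start); intervals must be non-overlapping and within the
#'   recording span.
#' @return The counts series with updated `valid`.
#' @export
apply_wear_log <- function(counts, wear_log) {
  if (is.null(wear_log) || nrow(wear_log) == 0) return(counts)
  if (any(wear_log$off_end <= wear_log$off_start)) {
    abort("wear-log intervals must have off_end > off_start.")
  }
  span <- nrow(counts)
  if (any(wear_log$off_start < 0) || any(wear_log$off_end > span)) {
    abort("wear-log intervals must lie within the recording span.")
  }
  ord <- order(wear_log$off_start)
  if (any(wear_log$off_start[ord][-1] < wear_log$off_end[ord][-nrow(wear_log)])) {
    abort("wear-log intervals must be non-overlapping.")
  }
  for (i in seq_len(nrow(wear_log))) {
    off <- counts$epoch >= wear_log$off_start[i] & counts$epoch < wear_log$off_end[i]
    counts$valid[off] <- FALSE
  }
  counts
}

#' Bilateral valid-day check
#'
#' A subject's recording is analyzable iff both limbs carry at least 24 h
#' (86,400 valid 1 s epochs, boundary inclusive); accumulation need not be
#' contiguous.
#'
#' @param counts_preferred,counts_non_preferred Counts series tibbles (pass
#'   `NULL` for a missing limb).
#' @param min_hours Inclusion threshold in hours (default 24).
#' @return List with `valid` (flag), `valid_hours` (bilateral minimum) and
#'   `reason` (`NA`, `"unilateral"` or `"insufficient_wear"`).
#' @export
check_valid_day <- function(counts_preferred, counts_non_preferred, min_hours = 24) {
  if (is.null(counts_preferred) || is.null(counts_non_preferred)) {
    return(list(valid = FALSE, valid_hours = 0, reason = "unilateral"))
  }
  h_p <- sum(counts_preferred$valid) / 3600
  h_n <- sum(counts_non_preferred$valid) / 3600
  vh <- min(h_p, h_n)
  ok <- vh >= min_hours
  list(valid = ok, valid_hours = vh,
       reason = if (ok) NA_character_ else "insufficient_wear")
}
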