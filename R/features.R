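# The 12 upper-limb activity performance variables, computed per subject
# from the bilateral 1 Hz count series (duration/intensity/variability
# constructs) and the 0.2-12 Hz filtered raw vector magnitude (jerk
# asymmetry, spectral arc length).

valid_counts <- function(counts) counts$counts[counts$valid]

#' Hours of limb movement
#'
#' An epoch counts as movement when its activity count is strictly greater
#' than the threshold (default 2 counts per second).
#'
#' @param counts Counts series tibble.
#' @param threshold Movement threshold in counts (strict inequality).
#' @return Hours of moving epochs among valid epochs.
#' @export
movement_time <- function(counts, threshold = 2) {
  v <- valid_counts(counts)
  if (length(v) == 0) abort("counts series has no valid epochs.")
  sum(v > threshold) / 3600
}

#' Hours during which only the target limb moves
#'
#' @param target,other Time-aligned counts series of equal length.
#' @inheritParams movement_time
#' @return Hours of epochs where `target > threshold` and
#'   `other <= threshold`.
#' @export
only_time <- function(target, other, threshold = 2) {
  if (nrow(target) != nrow(other)) abort("counts series are misaligned.")
  ok <- target$valid & other$valid
  sum(target$counts[ok] > threshold & other$counts[ok] <= threshold) / 3600
}

#' Median movement-epoch magnitude
#'
#' Median of the counts over epochs where the limb is moving (non-movement
#' time excluded). With no moving epochs the variable is missing and the
#' subject is later dropped from PCA/clustering.
#'
#' @inheritParams movement_time
#' @return Median counts, or `NA` if no epoch exceeds the threshold.
#' @export
median_magnitude <- function(counts, threshold = 2) {
  v <- valid_counts(counts)
  mv <- v[v > threshold]
  if (length(mv) == 0) return(NA_real_)
  median(mv)
}

#' Bilateral magnitude
#'
#' @param pref_median,nonpref_median Per-limb median moving magnitudes.
#' @return Their sum (NA if either is missing).
#' @export
bilateral_magnitude <- function(pref_median, nonpref_median) {
  pref_median + nonpref_median
}

#' Standard deviation of movement-epoch magnitude
#'
#' Sample SD (n − 1 denominator) of the counts over moving epochs.
#'
#' @inheritParams movement_time
#' @return SD in counts, or `NA` with fewer than two moving epochs.
#' @export
magnitude_sd <- function(counts, threshold = 2) {
  v <- valid_counts(counts)
  mv <- v[v > threshold]
  if (length(mv) < 2) return(NA_real_)
  sd(mv)
}

#' Use ratio
#'
#' Hours of non-preferred movement divided by hours of preferred movement;
#' values near 1 indicate equal integration of both limbs.
#'
#' @param nonpref_time,pref_time Movement times in hours.
#' @return Dimensionless ratio (NA when the preferred limb never moves).
#' @export
use_ratio <- function(nonpref_time, pref_time) {
  if (is.na(pref_time) || pref_time == 0) return(NA_real_)
  nonpref_time / pref_time
}

#' Magnitude ratio
#'
#' Ratio of the non-preferred to preferred median moving magnitudes, by
#' default on the natural-log scale (0 = equal intensity).
#'
#' @param nonpref_median,pref_median Per-limb median moving magnitudes.
#' @param transform `"natural_log"` (default) or `"raw"`.
#' @return Dimensionless ratio (NA when a required median is zero or
#'   missing).
#' @export
magnitude_ratio <- function(nonpref_median, pref_median,
                            transform = c("natural_log", "raw")) {
  transform <- match.arg(transform)
  if (is.na(nonpref_median) || is.na(pref_median)) return(NA_real_)
  if (transform == "raw") {
    if (pref_median == 0) return(NA_real_)
    return(nonpref_median / pref_median)
  }
  if (nonpref_median <= 0 || pref_median <= 0) return(NA_real_)
  log(nonpref_median / pref_median)
}

# per-limb scalar jerk: mean absolute central-difference derivative of the
# filtered vector magnitude, per unit time
scalar_jerk <- function(filtered, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  fs <- attr(filtered, "sample_rate")
  v <- filtered$vm
  if (length(v) < 3) abort("filtered series too short for a jerk estimate.")
  d <- (v[3:length(v)] - v[1:(length(v) - 2)]) * fs / 2
  if (aggregate == "mean") mean(abs(d)) else median(abs(d))
}

#' Jerk asymmetry index
#'
#' Normalized difference of the per-limb scalar jerks,
#' (J_np − J_p) / (J_np + J_p), bounded in \[−1, +1\]: 0 means similar
#' smoothness, +1 all jerk on the non-preferred limb, −1 all on the
#' preferred limb.
#'
#' @param raw_non_preferred,raw_preferred Filtered raw series from
#'   [filter_raw()].
#' @param aggregate How per-sample jerk becomes a per-limb scalar
#'   (`"mean"`, the convention used here, or `"median"`).
#' @return Index in \[−1, 1\], or `NA` when both limbs carry zero jerk.
#' @export
jerk_asymmetry <- function(raw_non_preferred, raw_preferred,
                           aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  jn <- scalar_jerk(raw_non_preferred, aggregate)
  jp <- scalar_jerk(raw_preferred, aggregate)
  if (jn + jp == 0) return(NA_real_)
  (jn - jp) / (jn + jp)
}

#' Spectral arc length (SPARC) smoothness metric
#'
#' Negative arc length of the peak-normalized Fourier magnitude spectrum of
#' the filtered vector magnitude, up to an adaptive cutoff (the last
#' frequency below `freq_cutoff` whose normalized magnitude is at least
#' `amplitude_threshold`). Amplitude- and duration-invariant; more negative
#' values mean less smooth movement.
#'
#' @param filtered Filtered raw series from [filter_raw()].
#' @param freq_cutoff Maximum frequency considered, Hz (default 10).
#' @param amplitude_threshold Normalized-magnitude threshold for the
#'   adaptive cutoff (default 0.05).
#' @param pad_level Zero-padding exponent for the FFT grid (default 4).
#' @return Non-positive smoothness value, or `NA` for an all-zero signal.
#' @export
sparc <- function(filtered, freq_cutoff = 10, amplitude_threshold = 0.05,
                  pad_level = 4) {
  fs <- attr(filtered, "sample_rate")
  v <- filtered$vm
  if (length(v) < 2) return(NA_real_)
  if (all(v == 0)) return(NA_real_)
  nfft <- 2^(ceiling(log2(length(v))) + pad_level)
  f <- (0:(nfft - 1)) * fs / nfft
  Mf <- Mod(fft(c(v, numeric(nfft - length(v)))))
  sel <- f <= freq_cutoff
  f <- f[sel]; Mf <- Mf[sel]
  Mf <- Mf / max(Mf)
  above <- which(Mf >= amplitude_threshold)
  rng <- above[1]:above[length(above)]
  f_s <- f[rng]; m_s <- Mf[rng]
  if (length(f_s) < 2) return(NA_real_)
  -sum(sqrt((diff(f_s) / (f_s[length(f_s)] - f_s[1]))^2 + diff(m_s)^2))
}

#' Assemble the 12-variable performance vector for one subject
#'
#' Enforces the bilateral valid-day rule, then computes all duration,
#' intensity, variability, symmetry and movement-quality variables.
#' Variables whose preconditions fail (e.g. no moving epochs) are returned
#' as `NA` and the subject is later excluded from PCA/clustering for sets
#' containing them.
#'
#' @param counts_preferred,counts_non_preferred Bilateral 1 Hz counts
#'   series.
#' @param raw_preferred,raw_non_preferred Filtered raw series
#'   ([filter_raw()]); `NULL` leaves the jerk/SPARC variables `NA`.
#' @param threshold Movement threshold in counts.
#' @param magnitude_transform Transform for the magnitude ratio.
#' @param enforce_valid_day Refuse subjects failing the bilateral >= 24 h
#'   rule (default TRUE).
#' @return One-row tibble with the 12 performance variables.
#' @export
compute_performance_vector <- function(counts_preferred, counts_non_preferred,
                                       raw_preferred = NULL,
                                       raw_non_preferred = NULL,
                                       threshold = 2,
                                       magnitude_transform = c("natural_log", "raw"),
                                       enforce_valid_day = TRUE) {
  magnitude_transform <- match.arg(magnitude_transform)
  if (enforce_valid_day) {
    chk <- check_valid_day(counts_preferred, counts_non_preferred)
    if (!chk$valid) {
      abort(paste0("subject fails the bilateral valid-day rule (",
                   chk$reason, ", ", round(chk$valid_hours, 2), " h)."))
    }
  }
  pt <- movement_time(counts_preferred, threshold)
  nt <- movement_time(counts_non_preferred, threshold)
  pm <- median_magnitude(counts_preferred, threshold)
  nm <- median_magnitude(counts_non_preferred, threshold)
  have_raw <- !is.null(raw_preferred) && !is.null(raw_non_preferred)
  tibble(
    preferred_time = pt,
    non_preferred_time = nt,
    preferred_only_time = only_time(counts_preferred, counts_non_preferred, threshold),
    non_preferred_only_time = only_time(counts_non_preferred, counts_preferred, threshold),
    non_preferred_magnitude = nm,
    bilateral_magnitude = bilateral_magnitude(pm, nm),
    non_preferred_variance = magnitude_sd(counts_non_preferred, threshold),
    use_ratio = use_ratio(nt, pt),
    magnitude_ratio = magnitude_ratio(nm, pm, magnitude_transform),
    jerk_asymmetry_index = if (have_raw) jerk_asymmetry(raw_non_preferred, raw_preferred) else NA_real_,
    sparc_preferred = if (have_raw) sparc(raw_preferred) else NA_real_,
    sparc_non_preferred = if (have_raw) sparc(raw_non_preferred) else NA_real_
  )
}

#' The nested 12/9/7/5 accelerometry input variable sets
#'
#' v9 drops the raw-path symmetry/smoothness variables; v7 additionally
#' drops the only-time durations; v5 keeps preferred time, non-preferred
#' time, non-preferred magnitude, non-preferred variance and the use ratio.
#'
#' @return Named list of character vectors (`v12`, `v9`, `v7`, `v5`).
#' @export
variable_sets <- function() {
  v12 <- c("preferred_time", "non_preferred_time", "preferred_only_time",
           "non_preferred_only_time", "non_preferred_magnitude",
           "bilateral_magnitude", "non_preferred_variance", "use_ratio",
           "magnitude_ratio", "jerk_asymmetry_index", "sparc_preferred",
           "sparc_non_preferred")
  v9 <- setdiff(v12, c("jerk_asymmetry_index", "sparc_preferred", "sparc_non_preferred"))
  v7 <- setdiff(v9, c("preferred_only_time", "non_preferred_only_time"))
  v5 <- setdiff(v7, c("bilateral_magnitude", "magnitude_ratio"))
  list(v12 = v12, v9 = v9, v7 = v7, v5 = v5)
}

#' Extract per-subject performance variables from a realized cohort
#'
#' @param cohort A cohort tibble from [simulate_cohort()] (with signal
#'   list-columns) or any tibble with the same list-columns.
#' @inheritParams compute_performance_vector
#' @return The cohort metadata joined with the 12 performance variables.
#' @export
extract_features <- function(cohort, threshold = 2,
                             magnitude_transform = c("natural_log", "raw")) {
  magnitude_transform <- match.arg(magnitude_transform)
  needed <- c("counts_preferred", "counts_non_preferred")
  if (!all(needed %in% names(cohort))) {
    abort("`cohort` must carry counts_preferred / counts_non_preferred list-columns.")
  }
  have_raw <- all(c("raw_preferred", "raw_non_preferred") %in% names(cohort))
  feats <- lapply(seq_len(nrow(cohort)), function(i) {
    compute_performance_vector(
      counts_preferred = cohort$counts_preferred[[i]],
      counts_non_preferred = cohort$counts_non_preferred[[i]],
      raw_preferred = if (have_raw) filter_raw(cohort$raw_preferred[[i]]) else NULL,
      raw_non_preferred = if (have_raw) filter_raw(cohort$raw_non_preferred[[i]]) else NULL,
      threshold = threshold, magnitude_transform = magnitude_transform
    )
  }) |> list_rbind()
  bind_cols(
    cohort[, setdiff(names(cohort), c("counts_preferred", "counts_non_preferred",
                                      "raw_preferred", "raw_non_preferred"))],
    feats
  )
}
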