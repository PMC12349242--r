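# Plain-CSV interchange: raw recordings, count series, wear logs and the
# tidy per-subject feature table.

#' Read a raw triaxial recording from CSV
#'
#' Expected columns: `time` (seconds from start) or `timestamp_iso8601`,
#' plus `x_g`, `y_g`, `z_g`.
#'
#' @param path CSV path.
#' @param sample_rate Sampling rate in Hz.
#' @param limb Limb label.
#' @return Raw recording tibble (see [simulate_limb_signal()]).
#' @export
read_raw_csv <- function(path, sample_rate = 30, limb = "preferred") {
  d <- as_tibble(utils::read.csv(path))
  if (!"time" %in% names(d)) {
    if ("timestamp_iso8601" %in% names(d)) {
      ts <- as.POSIXct(d$timestamp_iso8601, tz = "UTC",
                       format = "%Y-%m-%dT%H:%M:%OS")
      d$time <- as.numeric(ts) - as.numeric(ts[1])
    } else {
      abort("raw CSV needs a `time` or `timestamp_iso8601` column.")
    }
  }
  need <- c("x_g", "y_g", "z_g")
  if (!all(need %in% names(d))) abort("raw CSV needs x_g, y_g, z_g columns.")
  out <- d[, c("time", need)]
  attr(out, "sample_rate") <- sample_rate
  attr(out, "limb") <- limb
  out
}

#' Write a raw recording to CSV
#'
#' @param recording Raw recording tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(recording, path) {
  utils::write.csv(recording[, c("time", "x_g", "y_g", "z_g")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a 1 Hz counts series from CSV
#'
#' Accepts either a `counts_vm` column or per-axis `counts_x/y/z` columns
#' (combined by per-epoch vector magnitude, floored).
#'
#' @param path CSV path.
#' @param limb Limb label.
#' @return Counts series tibble.
#' @export
read_counts_csv <- function(path, limb = "preferred") {
  d <- utils::read.csv(path)
  counts <- if ("counts_vm" %in% names(d)) {
    d$counts_vm
  } else if (all(c("counts_x", "counts_y", "counts_z") %in% names(d))) {
    floor(vector_magnitude(d$counts_x, d$counts_y, d$counts_z))
  } else {
    abort("counts CSV needs `counts_vm` or `counts_x/counts_y/counts_z`.")
  }
  valid <- if ("valid" %in% names(d)) as.logical(d$valid) else rep(TRUE, length(counts))
  new_counts_series(as.integer(counts), limb = limb, valid = valid)
}

#' Write a counts series to CSV
#'
#' @param counts Counts series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  utils::write.csv(
    data.frame(epoch = counts$epoch, counts_vm = counts$counts,
               valid = counts$valid),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a wear log (device-off intervals) from CSV
#'
#' Expected columns: `off_start`, `off_end` in seconds from recording
#' start.
#'
#' @param path CSV path.
#' @return Tibble usable by [apply_wear_log()].
#' @export
read_wear_log_csv <- function(path) {
  d <- as_tibble(utils::read.csv(path))
  if (!all(c("off_start", "off_end") %in% names(d))) {
    abort("wear-log CSV needs off_start and off_end columns.")
  }
  d[, c("off_start", "off_end")]
}
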