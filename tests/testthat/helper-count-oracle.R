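# Straight-line re-implementation of the open activity-count algorithm,
# kept independent of the package's vectorized path; used as the exact
# integer oracle for to_activity_counts().

oracle_counts <- function(rec) {
  fs <- attr(rec, "sample_rate")
  stopifnot(fs == 30)
  one_axis <- function(v) {
    bf <- signal::butter(4, c(0.25, 2.5) / (fs / 2), type = "pass")
    v <- v - mean(v)
    pad <- min(length(v) - 1, 3 * fs)
    padded <- c(v[(pad + 1):2], v, v[(length(v) - 1):(length(v) - pad)])
    y <- signal::filtfilt(bf, padded)
    y <- y[(pad + 1):(pad + length(v))]
    y[y > 2.13] <- 2.13
    y[y < -2.13] <- -2.13
    q <- floor(abs(y) * 32)           # 1/32 g resolution
    q[q < 2] <- 0                     # deadband of 2 units
    q10 <- q[seq(1, length(q), by = 3)]  # 30 -> 10 Hz
    n_ep <- floor(length(q10) / 10)
    out <- integer(n_ep)
    for (e in seq_len(n_ep)) {
      out[e] <- sum(q10[((e - 1) * 10 + 1):(e * 10)])
    }
    out
  }
  cx <- one_axis(rec$x_g)
  cy <- one_axis(rec$y_g)
  cz <- one_axis(rec$z_g)
  as.integer(floor(sqrt(cx^2 + cy^2 + cz^2)))
}

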