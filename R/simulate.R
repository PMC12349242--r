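# Bout-level movement model shared by the raw-signal and count generators.
#
# Daily wrist movement is modeled as an alternation of rest and movement
# bouts. Movement-bout lengths are lognormal (median ~5 s); rest lengths are
# scaled so that the long-run moving fraction equals `frac_moving`. The
# non-preferred limb's bout frequency and amplitude shrink with impairment
# (1 - latent_performance) and with asymmetry, which is what pushes the
# downstream use ratio and non-preferred time below the preferred limb's.

# long-run fraction of the day the preferred limb moves
preferred_moving_fraction <- function(activity_level) {
  clamp(0.12 + 0.25 * activity_level, 0.02, 0.80)
}

# multiplicative shrinkage applied to the non-preferred limb; 1 when the
# profile is symmetric and unimpaired, 0 in the fully asymmetric limit
non_preferred_scale <- function(profile) {
  (1 - profile$asymmetry) * (0.4 + 0.6 * profile$latent_performance)
}

limb_parameters <- function(profile, limb) {
  f_pref <- preferred_moving_fraction(profile$activity_level)
  if (limb == "preferred") {
    list(
      frac_moving = f_pref,
      amp_scale = 1,
      jerk_frac = 0.05 + 0.10 * (1 - profile$latent_performance)
    )
  } else {
    s <- non_preferred_scale(profile)
    list(
      frac_moving = f_pref * s,
      amp_scale = 0.3 + 0.7 * s,
      jerk_frac = 0.05 + 0.45 * (1 - profile$latent_performance)
    )
  }
}

# draw alternating rest/move bout lengths covering `total_s` seconds;
# returns an integer vector of bout lengths and a parallel logical `moving`
draw_bout_structure <- function(total_s, frac_moving, mean_move_s = 5) {
  if (frac_moving <= 0) {
    return(list(lengths = total_s, moving = FALSE))
  }
  mean_rest_s <- max(mean_move_s * (1 - frac_moving) / frac_moving, 1)
  n_guess <- ceiling(total_s / (mean_move_s + mean_rest_s)) + 25
  repeat {
    move_len <- pmax(1, round(rlnorm(n_guess, log(mean_move_s), 0.5)))
    rest_len <- pmax(1, round(rlnorm(n_guess, log(mean_rest_s), 0.7)))
    lengths <- as.vector(rbind(rest_len, move_len))
    if (sum(lengths) >= total_s) break
    n_guess <- n_guess * 2
  }
  moving <- rep(c(FALSE, TRUE), n_guess)
  cum <- cumsum(lengths)
  keep <- which(cum - lengths < total_s)
  lengths <- lengths[keep]
  moving <- moving[keep]
  lengths[length(lengths)] <- total_s - sum(head(lengths, -1))
  list(lengths = lengths, moving = moving)
}

#' Simulate a raw triaxial recording for one limb
#'
#' Generates a continuous 30 Hz (by default) triaxial series in
#' gravitational units: rest bouts are gravity on the z axis plus low sensor
#' noise, movement bouts are Hann-windowed oscillatory bursts with carriers
#' in 0.5–3 Hz plus a 6–10 Hz "jerky" component whose relative amplitude
#' grows as latent performance falls. Non-preferred-limb bout frequency and
#' amplitude scale down with impairment and asymmetry. Deterministic given
#' `seed`.
#'
#' @param profile A [subject_profile()] row.
#' @param limb `"preferred"` or `"non_preferred"`.
#' @param wear_hours Positive duration to simulate.
#' @param sample_rate Sampling rate in Hz; must be >= 24 Hz so the 12 Hz
#'   band edge used by the raw processing path is below Nyquist.
#' @param seed Integer seed (defaults to a limb-specific child of the
#'   profile seed).
#' @return Tibble with columns `time` (s), `x_g`, `y_g`, `z_g`; attributes
#'   `limb` and `sample_rate`.
#' @export
simulate_limb_signal <- function(profile, limb = c("preferred", "non_preferred"),
                                 wear_hours = 24, sample_rate = 30,
                                 seed = NULL) {
  limb <- match.arg(limb)
  if (wear_hours <= 0) abort("`wear_hours` must be positive.")
  if (sample_rate < 24) {
    abort("`sample_rate` must be >= 24 Hz so the 12 Hz band edge is representable.")
  }
  seed <- seed %||% child_seed(profile$seed, if (limb == "preferred") 1L else 2L)
  par <- limb_parameters(profile, limb)
  total_s <- round(wear_hours * 3600)
  fs <- sample_rate
  n <- total_s * fs

  withr::with_seed(seed, {
    x <- rnorm(n, 0, 0.004)
    y <- rnorm(n, 0, 0.004)
    z <- 1 + rnorm(n, 0, 0.004)
    bouts <- draw_bout_structure(total_s, par$frac_moving)
    if (any(bouts$moving)) {
      starts_s <- cumsum(c(0, head(bouts$lengths, -1)))
      mv <- which(bouts$moving)
      amp <- 0.35 * profile$activity_level * par$amp_scale *
        rlnorm(length(mv), 0, 0.3)
      f0 <- runif(length(mv), 0.5, 3)
      fj <- runif(length(mv), 6, 10)
      ph <- runif(length(mv), 0, 2 * pi)
      phj <- runif(length(mv), 0, 2 * pi)
      w <- matrix(rnorm(3 * length(mv)), ncol = 3)
      w <- w / sqrt(rowSums(w^2))
      for (i in seq_along(mv)) {
        len <- bouts$lengths[mv[i]]
        idx <- (starts_s[mv[i]] * fs + 1):((starts_s[mv[i]] + len) * fs)
        tt <- (seq_along(idx) - 1) / fs
        env <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / (length(idx) + 1)))
        burst <- amp[i] * env *
          (sin(2 * pi * f0[i] * tt + ph[i]) +
             par$jerk_frac * sin(2 * pi * fj[i] * tt + phj[i]))
        x[idx] <- x[idx] + w[i, 1] * burst
        y[idx] <- y[idx] + w[i, 2] * burst
        z[idx] <- z[idx] + w[i, 3] * burst
      }
    }
    out <- tibble(time = (seq_len(n) - 1) / fs, x_g = x, y_g = y, z_g = z)
  })
  attr(out, "limb") <- limb
  attr(out, "sample_rate") <- fs
  out
}

# Direct 1 Hz count-series generator: the same bout model realized at epoch
# resolution. Moving epochs draw lognormal counts around a limb-specific
# median; rest epochs are 0 or an occasional 1-2 (below the movement
# threshold). Used by the cohort generator so full-day bilateral series are
# cheap to produce.
simulate_limb_counts <- function(profile, limb = c("preferred", "non_preferred"),
                                 wear_hours = 24, seed = NULL) {
  limb <- match.arg(limb)
  if (wear_hours <= 0) abort("`wear_hours` must be positive.")
  seed <- seed %||% child_seed(profile$seed, if (limb == "preferred") 3L else 4L)
  par <- limb_parameters(profile, limb)
  total_s <- round(wear_hours * 3600)
  med <- 35 * profile$activity_level * par$amp_scale
  withr::with_seed(seed, {
    bouts <- draw_bout_structure(total_s, par$frac_moving)
    moving <- rep(bouts$moving, bouts$lengths)
    counts <- integer(total_s)
    n_mv <- sum(moving)
    if (n_mv > 0) counts[moving] <- pmax(3L, as.integer(round(rlnorm(n_mv, log(med), 0.6))))
    n_rest <- total_s - n_mv
    if (n_rest > 0) {
      low <- sample(0:2, n_rest, replace = TRUE, prob = c(0.85, 0.10, 0.05))
      counts[!moving] <- low
    }
  })
  new_counts_series(counts, limb = limb)
}

# realize all signals for one subject (shared by simulate_cohort and the
# streaming feature path)
realize_subject <- function(profile, wear_hours, sample_rate, raw_minutes, seed) {
  list(
    counts_preferred = simulate_limb_counts(profile, "preferred", wear_hours,
                                            seed = child_seed(seed, 3L)),
    counts_non_preferred = simulate_limb_counts(profile, "non_preferred", wear_hours,
                                                seed = child_seed(seed, 4L)),
    raw_preferred = simulate_limb_signal(profile, "preferred", raw_minutes / 60,
                                         sample_rate, seed = child_seed(seed, 1L)),
    raw_non_preferred = simulate_limb_signal(profile, "non_preferred", raw_minutes / 60,
                                             sample_rate, seed = child_seed(seed, 2L))
  )
}

#' Generate a synthetic six-group cohort
#'
#' Draws per-subject profiles from the per-diagnosis hyperparameters, then
#' realizes for every subject a full-duration 1 Hz activity-count series per
#' limb, a raw 30 Hz excerpt per limb (for the jerk/smoothness variables),
#' and a correlated synthetic self-report. Deterministic given the spec
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @param signals If `FALSE`, only profiles and self-reports are returned
#'   (no signal list-columns); use [simulate_features()] to go straight to
#'   the per-subject performance variables.
#' @return Tibble with one row per subject: `subject`, `diagnosis`, profile
#'   columns, self-report columns and (if `signals`) list-columns
#'   `counts_preferred`, `counts_non_preferred`, `raw_preferred`,
#'   `raw_non_preferred`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), signals = TRUE) {
  stopifnot(inherits(spec, "ul_cohort_spec"))
  sizes <- spec$group_sizes[spec$group_sizes > 0]
  profiles <- imap(as.list(sizes), function(n, dx) {
    draw_profiles(dx, n, spec$profile_hyperparameters,
                  seed = child_seed(spec$seed, match(dx, diagnosis_levels())))
  }) |> list_rbind()
  profiles$subject <- sprintf("S%03d", seq_len(nrow(profiles)))
  profiles$seed <- vapply(seq_len(nrow(profiles)), function(i) {
    child_seed(spec$seed, 100L + i)
  }, integer(1))
  sr <- lapply(seq_len(nrow(profiles)), function(i) {
    simulate_self_report(profiles[i, ], noise_sd = 1,
                         seed = child_seed(profiles$seed[i], 5L))
  }) |> list_rbind()
  out <- bind_cols(profiles[, c("subject", "diagnosis", "latent_performance",
                                "asymmetry", "activity_level",
                                "dominant_is_affected", "seed")], sr)
  if (signals) {
    sig <- lapply(seq_len(nrow(out)), function(i) {
      realize_subject(out[i, ], spec$wear_hours, spec$sample_rate,
                      spec$raw_minutes, seed = out$seed[i])
    })
    out$counts_preferred <- map(sig, "counts_preferred")
    out$counts_non_preferred <- map(sig, "counts_non_preferred")
    out$raw_preferred <- map(sig, "raw_preferred")
    out$raw_non_preferred <- map(sig, "raw_non_preferred")
  }
  class(out) <- c("ul_cohort", class(out))
  out
}

#' Simulate a cohort and extract its performance variables in one pass
#'
#' Streams subject by subject (generate signals, compute the 12 variables,
#' discard signals), so memory stays flat for large cohorts.
#'
#' @inheritParams simulate_cohort
#' @inheritParams compute_performance_vector
#' @return Tibble: one row per subject with metadata, self-report columns
#'   and the 12 performance variables.
#' @export
simulate_features <- function(spec = cohort_spec(), threshold = 2,
                              magnitude_transform = c("natural_log", "raw")) {
  magnitude_transform <- match.arg(magnitude_transform)
  meta <- simulate_cohort(spec, signals = FALSE)
  feats <- lapply(seq_len(nrow(meta)), function(i) {
    sig <- realize_subject(meta[i, ], spec$wear_hours, spec$sample_rate,
                           spec$raw_minutes, seed = meta$seed[i])
    compute_performance_vector(
      counts_preferred = sig$counts_preferred,
      counts_non_preferred = sig$counts_non_preferred,
      raw_preferred = filter_raw(sig$raw_preferred),
      raw_non_preferred = filter_raw(sig$raw_non_preferred),
      threshold = threshold, magnitude_transform = magnitude_transform
    )
  }) |> list_rbind()
  bind_cols(meta, feats)
}
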