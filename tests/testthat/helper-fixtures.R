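# In-code fixtures shared across test files.

# counts series straight from an integer vector
cs <- function(counts, limb = "preferred") new_counts_series(counts, limb = limb)

# raw recording from per-axis vectors (defaults: gravity on z)
raw_rec <- function(x, y = numeric(length(x)), z = rep(1, length(x)),
                    fs = 30, limb = "preferred") {
  out <- tibble::tibble(time = (seq_along(x) - 1) / fs, x_g = x, y_g = y, z_g = z)
  attr(out, "sample_rate") <- fs
  attr(out, "limb") <- limb
  out
}

# pre-filtered vm series (bypasses filter_raw) for jerk/SPARC unit tests
vm_series <- function(vm, fs = 30, limb = "preferred") {
  out <- tibble::tibble(time = (seq_along(vm) - 1) / fs, vm = vm)
  attr(out, "sample_rate") <- fs
  attr(out, "limb") <- limb
  out
}

sine_rec <- function(freq, amp = 1, secs = 20, fs = 30, axis = "x") {
  t <- (0:(secs * fs - 1)) / fs
  s <- amp * sin(2 * pi * freq * t)
  raw_rec(x = if (axis == "x") s else numeric(length(t)),
          y = if (axis == "y") s else numeric(length(t)),
          z = if (axis == "z") 1 + s else rep(1, length(t)),
          fs = fs)
}

# steady-state amplitude of a filtered sinusoid (middle third of the trace)
steady_amp <- function(y) {
  n <- length(y)
  max(abs(y[floor(n / 3):floor(2 * n / 3)]))
}

# a small complete feature table with self-reports, used by categorization
# and validity tests (cached per session)
small_cohort_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(
        group_sizes = c(control = 30, stroke = 10, ms = 5, distal_fracture = 8,
                        proximal_pain = 12, breast_cancer = 5),
        raw_minutes = 5, seed = 7L)
      cache <<- simulate_features(spec)
    }
    cache
  }
})
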