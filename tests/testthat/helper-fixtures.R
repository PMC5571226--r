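# Shared fixtures, built in code and cached per test session.

fixture_env <- new.env(parent = emptyenv())

## memoize expensive fixtures across test files
fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_env))
    assign(name, force(expr), envir = fixture_env)
  get(name, envir = fixture_env)
}

## a mixed-class record rich enough for filter design
mixed_record <- function() fixture("mixed_record",
  gen_record(42L, 120, class_mix = c(N = 0.8, S = 0.08, V = 0.08,
                                     F = 0.02, Q = 0.02)))

## a small two-subject training partition + one test subject
small_cohort <- function() fixture("small_cohort",
  gen_cohort(n_train = 2, n_test = 1, seed = 1, train_beats = 250,
             test_normal_beats = 380, test_tail_beats = 120))

## both mode libraries over the small cohort
small_libraries <- function() fixture("small_libraries", {
  co <- small_cohort()
  lapply(c(single = "single", trio = "trio"), function(mode)
    build_library(co$train, filter_design_config(32, 1e-3, mode)))
})

## a flatline record with evenly spaced identical Gaussian-bump beats
## (narrow bumps rather than single-sample spikes: a spike can fall
## entirely between output grid points under strong downsampling)
flat_record <- function(n_beats = 5, spacing = 300, amplitude = 0,
                        subject_id = "flat", bump_sd = 5) {
  r <- spacing * seq_len(n_beats)
  sig <- numeric(max(r) + spacing)
  if (amplitude != 0) {
    idx <- 0:(length(sig) - 1L)
    for (ri in r)
      sig <- sig + amplitude * exp(-(idx - ri)^2 / (2 * bump_sd^2))
  }
  ecg_record(subject_id, sig, fs = 360,
             data.frame(r_sample = r, label = rep("N", n_beats)))
}

## independent linear-interpolation oracle used against resample_to_128
interp_oracle <- function(segment, n_out = 128) {
  n <- length(segment)
  x_out <- seq(0, n - 1, length.out = n_out)
  vapply(x_out, function(x) {
    lo <- floor(x); hi <- ceiling(x)
    if (lo == hi) return(segment[lo + 1])
    w <- x - lo
    (1 - w) * segment[lo + 1] + w * segment[hi + 1]
  }, 1)
}

## independent straight-loop centered convolution oracle
conv_oracle <- function(a, h) {
  n <- length(a); M <- length(h); ctr <- M %/% 2
  out <- numeric(n)
  for (t in 0:(n - 1)) {
    acc <- 0
    for (k in 0:(M - 1)) {
      src <- t - k + ctr
      if (src >= 0 && src < n) acc <- acc + h[k + 1] * a[src + 1]
    }
    out[t + 1] <- acc
  }
  out
}

## random beat_vector helper
random_beat <- function(label = "V", mode = "single", seed = 1,
                        subject_id = "rnd", beat_index = 1L) {
  withr::with_seed(seed,
    beat_vector(stats::rnorm(128), mode = mode, label = label,
                subject_id = subject_id, beat_index = beat_index))
}

## a linearly separable two-class toy dataset: well-separated Gaussian
## bumps at different positions/widths in both channels
toy_two_class <- function(n_per_class = 20, seed = 99) {
  withr::with_seed(seed, {
    bump <- function(center, width)
      exp(-((1:128) - center)^2 / (2 * width^2))
    X <- array(0, c(2 * n_per_class, 2, 128))
    labels <- character(2 * n_per_class)
    for (i in seq_len(2 * n_per_class)) {
      cls_n <- i <= n_per_class
      c0 <- if (cls_n) 64 else 40
      w0 <- if (cls_n) 5 else 15
      X[i, 1, ] <- bump(c0 + rnorm(1, 0, 1), w0) + rnorm(128, 0, 0.01)
      X[i, 2, ] <- bump(c0 + rnorm(1, 0, 1), w0 * 1.5) + rnorm(128, 0, 0.01)
      labels[i] <- if (cls_n) "N" else "V"
    }
    list(X = X, labels = labels)
  })
}
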