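# Seeded synthetic ECG cohort generator.  Beats are sums of five Gaussian
# bumps (P, Q, R, S, T); subjects differ by a one-time jitter of the wave
# parameters (inter-patient variation), beats differ by a smaller per-beat
# jitter plus additive noise.  Abnormal classes follow standard AAMI
# phenomenology: V widens the QRS and suppresses the P wave, S keeps
# near-normal morphology but arrives prematurely (with a compensatory
# pause), F is a convex blend of the subject's N and V shapes, Q has
# randomized morphology.  Everything is deterministic given the seed.

#' Default beat morphology parameters
#'
#' Five Gaussian waves with amplitudes in mV, centers in seconds relative
#' to the R peak and widths in seconds, plus heart rate and noise levels.
#' Defaults sketch a modified-lead-II normal beat: small upright P, sharp
#' dominant R flanked by narrow Q/S troughs, broad T.
#'
#' @param heart_rate_bpm mean heart rate (default 70).
#' @param noise_sd additive Gaussian noise, mV (default 0.01).
#' @param subject_jitter_sd fractional one-time jitter of amplitudes and
#'   widths per subject (default 0.10).
#' @param beat_jitter_sd fractional per-beat jitter (default 0.02).
#' @param waves data frame with columns `wave, a, mu, sigma`.
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(heart_rate_bpm = 70, noise_sd = 0.01,
                              subject_jitter_sd = 0.10,
                              beat_jitter_sd = 0.02,
                              waves = data.frame(
                                wave = c("P", "Q", "R", "S", "T"),
                                a = c(0.15, -0.10, 1.00, -0.18, 0.35),
                                mu = c(-0.20, -0.040, 0.00, 0.040, 0.25),
                                sigma = c(0.025, 0.010, 0.016, 0.012, 0.055))) {
  stopifnot(all(waves$sigma > 0), heart_rate_bpm > 0, noise_sd >= 0)
  structure(list(heart_rate_bpm = heart_rate_bpm, noise_sd = noise_sd,
                 subject_jitter_sd = subject_jitter_sd,
                 beat_jitter_sd = beat_jitter_sd, waves = waves),
            class = "morphology_params")
}

#' Default class degradation parameters
#'
#' @param s_premature RR fraction of a premature S beat (default 0.70;
#'   must stay below 0.85 for the timing anomaly to register in the trio
#'   channel).
#' @param v_premature RR fraction of a premature V beat (default 0.78).
#' @param v_qrs_width_mult QRS (Q, R, S wave) width multiplier for V beats
#'   (default 2.5; must be >= 2).
#' @param f_blend convex blend weight of the N shape in an F beat
#'   (default 0.5).
#' @return Named list of per-class transforms.
#' @export
class_degradations <- function(s_premature = 0.70, v_premature = 0.78,
                               v_qrs_width_mult = 2.5, f_blend = 0.5) {
  stopifnot(s_premature < 0.85, v_qrs_width_mult >= 2,
            f_blend > 0, f_blend < 1)
  list(
    S = list(rr_premature_factor = s_premature, p_scale = 0.85),
    V = list(rr_premature_factor = v_premature,
             qrs_width_mult = v_qrs_width_mult, p_suppress = TRUE,
             r_amp_mult = 0.90, t_amp_mult = -1.10),
    F = list(rr_premature_factor = 0.90, blend = f_blend),
    Q = list(rr_premature_factor = 1.0,
             amp_range = c(0.3, 1.7), width_range = c(0.5, 2.0))
  )
}

## internal: evaluate the sum-of-Gaussians morphology at times t (s, R at 0)
eval_waves <- function(waves, t) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(waves)))
    out <- out + waves$a[i] *
      exp(-(t - waves$mu[i])^2 / (2 * waves$sigma[i]^2))
  out
}

## internal: subject-level morphology draw — one-time jitter of amplitudes,
## widths (multiplicative) and centers (additive), plus a heart-rate draw
draw_subject_morphology <- function(p) {
  w <- p$waves
  n <- nrow(w)
  w$a <- w$a * (1 + stats::rnorm(n, 0, p$subject_jitter_sd))
  w$sigma <- w$sigma * pmax(0.5, 1 + stats::rnorm(n, 0, p$subject_jitter_sd))
  w$mu <- w$mu + stats::rnorm(n, 0, 0.008)
  w$mu[w$wave == "R"] <- 0  # the R peak defines the beat's time origin
  hr <- max(55, min(90, stats::rnorm(1, p$heart_rate_bpm, 6)))
  list(waves = w, heart_rate_bpm = hr)
}

## internal: per-beat morphology — small jitter then the class transform.
## Returns one wave table, or a list of two tables plus a blend weight for
## fusion beats. Consumes RNG draws (call inside a seeded context).
beat_morphology <- function(subj_waves, label, p, deg) {
  w <- subj_waves
  n <- nrow(w)
  w$a <- w$a * (1 + stats::rnorm(n, 0, p$beat_jitter_sd))
  w$sigma <- w$sigma * pmax(0.5, 1 + stats::rnorm(n, 0, p$beat_jitter_sd))
  qrs <- w$wave %in% c("Q", "R", "S")
  make_v <- function(w) {
    w$sigma[qrs] <- w$sigma[qrs] * deg$V$qrs_width_mult
    if (isTRUE(deg$V$p_suppress)) w$a[w$wave == "P"] <- 0
    w$a[w$wave == "R"] <- w$a[w$wave == "R"] * deg$V$r_amp_mult
    w$a[w$wave == "T"] <- w$a[w$wave == "T"] * deg$V$t_amp_mult
    w
  }
  switch(label,
    N = list(w),
    S = {
      w$a[w$wave == "P"] <- w$a[w$wave == "P"] * deg$S$p_scale
      list(w)
    },
    V = list(make_v(w)),
    F = list(w, make_v(w), blend = deg$F$blend),
    Q = {
      w$a <- w$a * stats::runif(n, deg$Q$amp_range[1], deg$Q$amp_range[2])
      w$sigma <- w$sigma * stats::runif(n, deg$Q$width_range[1],
                                        deg$Q$width_range[2])
      list(w)
    },
    stop("unknown label ", label, call. = FALSE))
}

#' Generate one beat waveform
#'
#' Evaluates the sum-of-Gaussians morphology on a uniform grid spanning
#' `window_s` seconds either side of the R peak and adds white noise.
#' Deterministic given the seed.
#'
#' @param p a [morphology_params()].
#' @param fs sampling rate (Hz).
#' @param seed integer seed for the noise draw.
#' @param window_s half-window in seconds (default 0.5).
#' @return Numeric vector of `2 * window_s * fs + 1` samples.
#' @export
gen_beat_waveform <- function(p, fs = 360, seed = 1L, window_s = 0.5) {
  stopifnot(fs > 0)
  t <- seq(-window_s, window_s, by = 1 / fs)
  withr::with_seed(as.integer(seed),
    eval_waves(p$waves, t) + stats::rnorm(length(t), 0, p$noise_sd))
}

#' Generate a complete annotated synthetic record
#'
#' Draws a subject morphology, lays beats on an RR grid (normal RR from
#' the subject's heart rate with small jitter; premature classes shorten
#' their preceding interval by the class factor and the following interval
#' is lengthened so the two-beat span is conserved — the compensatory
#' pause), superimposes per-beat waveforms and white noise, and emits exact
#' R-peak annotations. Deterministic given `subject_seed`.
#'
#' @param subject_seed integer seed; also drives the subject morphology.
#' @param n_beats number of beats.
#' @param class_mix named numeric vector of class probabilities summing to
#'   1 (e.g. `c(N = .9, V = .1)`); ignored when `labels` is given.
#' @param fs sampling rate (default 360 Hz).
#' @param params a [morphology_params()].
#' @param degradations a [class_degradations()] list.
#' @param labels optional explicit label sequence of length `n_beats`
#'   (first and last are forced to N so every interior beat has a trio).
#' @param subject_id subject id (default derived from the seed).
#' @return An [ecg_record()].
#' @export
gen_record <- function(subject_seed, n_beats,
                       class_mix = c(N = 1.0), fs = 360,
                       params = morphology_params(),
                       degradations = class_degradations(),
                       labels = NULL,
                       subject_id = paste0("SYN", subject_seed)) {
  if (is.null(labels)) {
    if (abs(sum(class_mix) - 1) > 1e-8)
      stop("class_mix probabilities must sum to 1", call. = FALSE)
    if (!all(names(class_mix) %in% aami_classes()))
      stop("class_mix names must be AAMI classes", call. = FALSE)
  } else if (length(labels) != n_beats)
    stop("labels must have length n_beats", call. = FALSE)
  if (n_beats == 0L)
    return(ecg_record(subject_id, numeric(0), fs,
                      data.frame(r_sample = integer(), label = character())))
  withr::with_seed(as.integer(subject_seed), {
    subj <- draw_subject_morphology(params)
    if (is.null(labels))
      labels <- sample(names(class_mix), n_beats, replace = TRUE,
                       prob = class_mix)
    labels[1] <- "N"
    labels[n_beats] <- "N"
    base_rr <- 60 / subj$heart_rate_bpm
    rr <- base_rr * (1 + stats::rnorm(n_beats, 0, 0.02))
    i <- 2L
    while (i <= n_beats) {
      fac <- degradations[[labels[i]]]$rr_premature_factor
      if (!is.null(fac) && fac < 1) {
        normal_rr <- rr[i]
        rr[i] <- normal_rr * fac
        if (i < n_beats)                       # compensatory pause
          rr[i + 1L] <- 2 * base_rr - rr[i]
        i <- i + 2L
      } else i <- i + 1L
    }
    r_times <- 0.6 + cumsum(rr)
    n_samples <- as.integer(ceiling((r_times[n_beats] + 0.6) * fs))
    signal <- stats::rnorm(n_samples, 0, params$noise_sd)
    half <- as.integer(round(0.5 * fs))
    for (b in seq_len(n_beats)) {
      morph <- beat_morphology(subj$waves, labels[b], params, degradations)
      r_samp <- round(r_times[b] * fs)
      idx <- max(0L, r_samp - half):min(n_samples - 1L, r_samp + half)
      trel <- idx / fs - r_times[b]
      wav <- eval_waves(morph[[1]], trel)
      if (!is.null(morph$blend))
        wav <- morph$blend * wav + (1 - morph$blend) *
          eval_waves(morph[[2]], trel)
      signal[idx + 1L] <- signal[idx + 1L] + wav
    }
    ecg_record(subject_id, signal, fs,
               data.frame(r_sample = as.integer(round(r_times * fs)),
                          label = labels))
  })
}

#' Generate a train/test cohort of synthetic subjects
#'
#' Training-profile subjects carry abnormal beats throughout their record
#' (the raw material for the filter library). Test-profile subjects model
#' the monitoring scenario: an all-N first five minutes (the
#' patient-specific training window) followed by a tail in which abnormal
#' beats occur sparsely; the tail is guaranteed to contain at least
#' `min_abnormal` abnormal beats so detection statistics are well-defined.
#'
#' @param n_train,n_test subjects per partition (defaults 5 and 3).
#' @param seed master seed; subject seeds are derived deterministically.
#' @param train_beats beats per training record (default 600, about 8.5
#'   minutes at 70 bpm).
#' @param test_normal_beats leading all-N beats of a test record (default
#'   380 — comfortably past the 300 s mark at plausible heart rates).
#' @param test_tail_beats monitored tail length (default 240).
#' @param train_mix,test_tail_mix class mixes for the two profiles.
#' @param min_abnormal guaranteed abnormal beats in each test tail
#'   (default 20).
#' @param fs sampling rate.
#' @param params,degradations generator parameters.
#' @return List with elements `train` and `test`, each a named list of
#'   [ecg_record()]s (ids 101… and 201…).
#' @export
gen_cohort <- function(n_train = 5L, n_test = 3L, seed = 1L,
                       train_beats = 600L, test_normal_beats = 380L,
                       test_tail_beats = 240L,
                       train_mix = c(N = 0.82, S = 0.07, V = 0.08,
                                     F = 0.03),
                       test_tail_mix = c(N = 0.85, S = 0.05, V = 0.07,
                                         F = 0.03),
                       min_abnormal = 20L, fs = 360,
                       params = morphology_params(),
                       degradations = class_degradations()) {
  seed <- as.integer(seed)
  train <- lapply(seq_len(n_train), function(i)
    gen_record(seed + 1000L * i, train_beats, class_mix = train_mix,
               fs = fs, params = params, degradations = degradations,
               subject_id = sprintf("%d", 100L + i)))
  test <- lapply(seq_len(n_test), function(i) {
    sseed <- seed + 100000L + 1000L * i
    tail_labels <- withr::with_seed(sseed * 2L + 1L, {
      lab <- sample(names(test_tail_mix), test_tail_beats, replace = TRUE,
                    prob = test_tail_mix)
      lab[test_tail_beats] <- "N"  # the record's last beat has no trio
      ab <- which(lab != "N")
      if (length(ab) < min_abnormal) {     # top up deterministically
        pool <- setdiff(which(lab == "N"), c(1L, test_tail_beats))
        add <- sample(pool, min_abnormal - length(ab))
        lab[add] <- sample(setdiff(names(test_tail_mix), "N"),
                           length(add), replace = TRUE)
      }
      lab
    })
    gen_record(sseed, test_normal_beats + test_tail_beats,
               labels = c(rep("N", test_normal_beats), tail_labels),
               fs = fs, params = params, degradations = degradations,
               subject_id = sprintf("%d", 200L + i))
  })
  list(train = stats::setNames(train, vapply(train, `[[`, "", "subject_id")),
       test = stats::setNames(test, vapply(test, `[[`, "", "subject_id")))
}
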