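# Degradation-filter design and library curation.

test_that("convolution_matrix realizes centered convolution", {
  a <- rnorm(128)
  expect_equal(convolution_matrix(a, 1), matrix(a, 128, 1))
  # center-tap delta reproduces the input
  M <- 9
  h <- numeric(M); h[M %/% 2 + 1] <- 1
  expect_equal(as.numeric(convolution_matrix(a, M) %*% h), a)
})

test_that("convolution_matrix agrees with the straight-loop oracle", {
  withr::with_seed(3, {
    for (M in c(2, 7, 32)) {
      a <- rnorm(128); h <- rnorm(M)
      expect_lt(max(abs(convolution_matrix(a, M) %*% h - conv_oracle(a, h))),
                1e-12)
    }
  })
})

test_that("design_filter recovers pure gain in the M=1 limit", {
  anb <- random_beat("N", seed = 10)
  cfg0 <- filter_design_config(M = 1, lam = 0)
  same <- beat_vector(anb$samples, "single", "V", "x", beat_index = 1L)
  f1 <- design_filter(anb, same, cfg0)
  expect_equal(f1$h, 1.0, tolerance = 1e-10)
  expect_lt(f1$fit_residual, 1e-10)
  dbl <- beat_vector(2 * anb$samples, "single", "V", "x", beat_index = 2L)
  f2 <- design_filter(anb, dbl, cfg0)
  expect_equal(f2$h, 2.0, tolerance = 1e-10)
})

test_that("design_filter matches the explicit ridge normal-equations oracle", {
  withr::with_seed(21, {
    for (i in 1:20) {
      M <- sample(c(8, 16, 32, 64), 1)
      lam <- sample(c(0, 1e-4, 1e-3, 1e-1), 1)
      anb <- beat_vector(rnorm(128), "single", "N", "s")
      tgt <- beat_vector(rnorm(128), "single", "V", "s", beat_index = i)
      f <- design_filter(anb, tgt, filter_design_config(M, lam))
      A <- convolution_matrix(anb$samples, M)
      h_oracle <- solve(t(A) %*% A + lam * diag(M), t(A) %*% tgt$samples)
      expect_lt(max(abs(f$h - h_oracle)), 1e-8)
      expect_equal(f$coeff_variance, stats::var(f$h))
      expect_equal(f$fit_residual,
                   sqrt(mean((A %*% f$h - tgt$samples)^2)), tolerance = 1e-12)
    }
  })
})

test_that("fit residual is monotone: non-increasing in M, minimal at lambda 0", {
  withr::with_seed(33, {
    anb <- beat_vector(rnorm(128), "single", "N", "s")
    tgt <- beat_vector(rnorm(128), "single", "V", "s", beat_index = 1L)
    res <- vapply(c(1, 2, 4, 8, 16, 32, 64, 128), function(M)
      design_filter(anb, tgt, filter_design_config(M, 0))$fit_residual, 1)
    expect_true(all(diff(res) <= 1e-10))
    r0 <- design_filter(anb, tgt, filter_design_config(16, 0))$fit_residual
    for (lam in c(1e-3, 1e-1, 1))
      expect_gte(design_filter(anb, tgt,
                               filter_design_config(16, lam))$fit_residual,
                 r0 - 1e-12)
  })
})

test_that("residual monotonicity in nested M holds across random pairs", {
  withr::with_seed(44, {
    for (i in 1:20) {
      anb <- beat_vector(rnorm(128), "single", "N", "s")
      tgt <- beat_vector(rnorm(128), "single", "V", "s", beat_index = i)
      res <- vapply(2^(0:7), function(M)
        design_filter(anb, tgt, filter_design_config(M, 0))$fit_residual, 1)
      expect_true(all(diff(res) <= 1e-9))
    }
  })
})

test_that("design_filter enforces mode and label contracts", {
  anb <- random_beat("N", seed = 1)
  tgt_trio <- random_beat("V", mode = "trio", seed = 2)
  cfg <- filter_design_config(8, 1e-3, "single")
  expect_error(design_filter(anb, tgt_trio, cfg), "mode mismatch")
  tgt_n <- random_beat("N", seed = 3)
  expect_error(design_filter(anb, tgt_n, cfg), "label != N")
})

test_that("is_all_pass flags near-identical beats and not antiphase ones", {
  anb <- random_beat("N", seed = 5)
  same <- beat_vector(anb$samples, "single", "S", "x")
  expect_true(is_all_pass(anb, same, threshold = 0.01))
  anti <- beat_vector(-anb$samples, "single", "S", "x")
  expect_false(is_all_pass(anb, anti, threshold = 1.9))
  zero <- beat_vector(numeric(128), "single", "N", "x")
  expect_error(is_all_pass(zero, same), "zero norm")
})

test_that("timing-only S beats are all-pass in single mode but not in trio mode", {
  # slow heart rate keeps the premature beat's centered window clear of the
  # preceding beat's T wave, isolating the timing-only nature of the S beat
  rec <- gen_record(9L, 60, labels = c(rep("N", 29), "S", rep("N", 30)),
                    params = morphology_params(heart_rate_bpm = 55))
  anb <- select_anb(rec, duration_s = record_duration(rec))
  s_single <- segment_single_beat(rec, 30)
  s_trio <- segment_trio(rec, 30)
  expect_true(is_all_pass(anb$single, s_single))
  expect_false(is_all_pass(anb$trio, s_trio))
})

test_that("dedup_similar keeps the lowest-residual member of each cluster", {
  mk <- function(h, resid, id) {
    f <- abswarn:::new_abs_filter(h, "s", "V", id, "single", resid)
    f
  }
  h0 <- rnorm(16)
  f1 <- mk(h0, 0.5, 1L)
  f2 <- mk(h0, 0.1, 2L)
  out <- dedup_similar(list(f1, f2), 0.95)
  expect_length(out, 1)
  expect_equal(out[[1]]$source_beat_index, 2L)
  # orthogonal vectors all survive
  e <- diag(16)
  fs <- lapply(1:4, function(i) mk(e[, i], i / 10, i))
  expect_length(dedup_similar(fs, 0.5), 4)
})

test_that("dedup_similar recovers planted clusters against a brute-force oracle", {
  withr::with_seed(13, {
    centers <- list(rnorm(16), rnorm(16), rnorm(16))
    filters <- list()
    for (i in 1:10) {
      cl <- (i - 1) %% 3 + 1
      h <- centers[[cl]] + rnorm(16, 0, 0.01)
      filters[[i]] <- abswarn:::new_abs_filter(h, "s", "V", i, "single",
                                               runif(1))
    }
    out <- dedup_similar(filters, 0.95)
    expect_length(out, 3)
    # oracle: exhaustive pairwise clustering by correlation threshold
    sim <- outer(1:10, 1:10, Vectorize(function(i, j)
      stats::cor(filters[[i]]$h, filters[[j]]$h) > 0.95))
    comp <- seq_len(10)
    for (i in 1:10) for (j in 1:10)
      if (sim[i, j]) comp[comp == comp[j]] <- comp[i]
    expect_equal(length(unique(comp)), 3)
    for (g in unique(comp)) {
      members <- which(comp == g)
      best <- members[which.min(vapply(filters[members], `[[`, 1,
                                       "fit_residual"))]
      expect_true(any(vapply(out, function(f)
        f$source_beat_index == best, TRUE)))
    }
    # order independence
    out_rev <- dedup_similar(rev(filters), 0.95)
    ids <- function(l) sort(vapply(l, `[[`, 1L, "source_beat_index"))
    expect_identical(ids(out), ids(out_rev))
  })
})

test_that("select_distinct ranks by coefficient variance with deterministic ties", {
  mk <- function(h, id, subj = "s")
    abswarn:::new_abs_filter(h, subj, "V", id, "single", 0.1)
  withr::with_seed(2, {
    hs <- replicate(5, rnorm(16), simplify = FALSE)
    fs <- lapply(seq_along(hs), function(i) mk(hs[[i]], i))
    vars <- vapply(hs, stats::var, 1)
    out <- select_distinct(fs, 3)
    expect_equal(vapply(out, `[[`, 1L, "source_beat_index"),
                 order(vars, decreasing = TRUE)[1:3])
  })
  # a constant filter (variance 0) is never preferred over a varying one
  fc <- mk(rep(2, 16), 10L)
  fv <- mk(rnorm(16), 11L)
  expect_equal(select_distinct(list(fc, fv), 1)[[1]]$source_beat_index, 11L)
  # k >= n returns everything sorted
  expect_length(select_distinct(list(fc, fv), 99), 2)
  expect_error(select_distinct(list(fc), 0), ">= 1")
})

test_that("build_library applies ANB, all-pass, dedup and variance curation", {
  co <- small_cohort()
  lib <- small_libraries()$single
  expect_s3_class(lib, "filter_library")
  expect_gt(length(lib), 0)
  expect_setequal(names(lib$provenance),
                  vapply(co$train, `[[`, "", "subject_id"))
  # no retained filter is all-pass against its own subject's ANB
  for (f in lib$filters) expect_false(f$source_class == "N")
  # attrition bookkeeping is consistent
  att <- lib$attrition
  expect_true(all(att[, "abnormal_beats"] ==
                  att[, "all_pass_skipped"] + att[, "designed"]))
  expect_true(all(att[, "designed"] ==
                  att[, "dedup_removed"] + att[, "retained"]))
  # determinism
  lib2 <- build_library(co$train, filter_design_config(32, 1e-3, "single"))
  expect_equal(lib, lib2)
})

test_that("a cohort with no abnormal beats yields an empty library", {
  rec <- gen_record(77L, 60, class_mix = c(N = 1))
  lib <- build_library(list(rec), filter_design_config(16, 1e-3, "single"))
  expect_length(lib, 0)
})

test_that("identical abnormal beats collapse to a single filter", {
  # three copies of the same V morphology in a noiseless record
  p <- morphology_params(noise_sd = 0, subject_jitter_sd = 0,
                         beat_jitter_sd = 0)
  rec <- gen_record(3L, 40,
                    labels = c(rep("N", 10), "V", rep("N", 5), "V",
                               rep("N", 5), "V", rep("N", 17)),
                    params = p)
  lib <- build_library(list(rec), filter_design_config(32, 1e-3, "single"))
  expect_length(lib, 1)
  expect_identical(lib$filters[[1]]$source_class, "V")
})

test_that("exclude_subject removes exactly that subject's filters", {
  lib <- small_libraries()$single
  subjects <- names(lib$provenance)
  s <- subjects[1]
  sub <- exclude_subject(lib, s)
  expect_false(s %in% vapply(sub$filters, `[[`, "", "source_subject"))
  ids_expected <- setdiff(vapply(lib$filters, `[[`, "", "id"),
                          unlist(lib$provenance[[s]]))
  expect_setequal(vapply(sub$filters, `[[`, "", "id"), ids_expected)
  # unknown subject leaves the library unchanged; original untouched
  expect_length(exclude_subject(lib, "nobody"), length(lib))
  expect_length(lib, length(ids_expected) + length(lib$provenance[[s]]))
})

test_that("library serialization round-trips bit-exactly", {
  lib <- small_libraries()$single
  path <- file.path(withr::local_tempdir(), "lib")
  write_library(lib, path, config_hash = "abc")
  back <- read_library(path)
  expect_identical(length(back), length(lib))
  for (i in seq_along(lib$filters)) {
    expect_identical(back$filters[[i]]$h, lib$filters[[i]]$h)
    expect_identical(back$filters[[i]]$id, lib$filters[[i]]$id)
    expect_identical(back$filters[[i]]$source_class,
                     lib$filters[[i]]$source_class)
  }
  expect_identical(back$config_hash, "abc")
  expect_equal(back$design_config, lib$design_config)
})

test_that("a curated filter applied to its source ANB reproduces the stored residual", {
  co <- small_cohort()
  lib <- small_libraries()$single
  anbs <- lapply(co$train, select_anb)
  for (f in lib$filters) {
    anb <- anbs[[f$source_subject]]
    syn <- synthesize_beat(anb, f)
    src <- segment_single_beat(co$train[[f$source_subject]],
                               f$source_beat_index)
    expect_equal(sqrt(mean((syn$samples - src$samples)^2)), f$fit_residual,
                 tolerance = 1e-10)
  }
})
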