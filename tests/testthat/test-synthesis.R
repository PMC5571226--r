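# Abnormal beat synthesis and training-set assembly.

test_that("a center-delta filter acts as the identity with an abnormal label", {
  rec <- mixed_record()
  anb <- select_anb(rec, 300)
  M <- 15
  h <- numeric(M); h[M %/% 2 + 1] <- 1
  f <- abswarn:::new_abs_filter(h, "donor", "S", 1L, "single", 0)
  syn <- synthesize_beat(anb, f)
  expect_equal(syn$samples, anb$single$samples, tolerance = 1e-12)
  expect_identical(syn$label, "S")
  expect_true(syn$is_synthetic)
  expect_identical(syn$subject_id, rec$subject_id)
})

test_that("synthesis closes the design loop at the stored residual", {
  rec <- mixed_record()
  anb <- select_anb(rec, duration_s = record_duration(rec))
  i <- which(rec$annotations$label == "V")[1]
  tgt <- segment_single_beat(rec, i)
  f <- design_filter(anb$single, tgt, filter_design_config(32, 0))
  syn <- synthesize_beat(anb, f)
  expect_equal(sqrt(mean((syn$samples - tgt$samples)^2)), f$fit_residual,
               tolerance = 1e-10)
})

test_that("synthesis is linear in the filter coefficients", {
  rec <- mixed_record()
  anb <- select_anb(rec, 300)
  withr::with_seed(8, {
    h1 <- rnorm(16); h2 <- rnorm(16)
    mk <- function(h) abswarn:::new_abs_filter(h, "d", "V", 1L, "single", 0)
    a <- 0.3; b <- -1.7
    lhs <- synthesize_beat(anb, mk(a * h1 + b * h2))$samples
    rhs <- a * synthesize_beat(anb, mk(h1))$samples +
           b * synthesize_beat(anb, mk(h2))$samples
    expect_equal(lhs, rhs, tolerance = 1e-12)
  })
})

test_that("synthesize_beat refuses a mode mismatch", {
  rec <- mixed_record()
  anb <- select_anb(rec, 300)
  f <- abswarn:::new_abs_filter(rnorm(8), "d", "V", 1L, "trio", 0)
  expect_error(synthesize_beat(anb$single, f), "mode mismatch")
})

test_that("build_training_set counts real and synthetic parts correctly", {
  co <- small_cohort()
  libs <- small_libraries()
  subj <- co$test[[1]]
  ts <- build_training_set(subj, libs)
  ann <- subj$annotations
  in_win <- which(ann$r_sample < 300 * subj$fs)
  n_expected <- sum(ann$label[in_win] == "N" &
                    in_win > 1 & in_win < nrow(ann))
  expect_equal(ts$n_real_normal, n_expected)
  # synthetic count equals the union of filter ids across modes
  ids <- union(vapply(libs$single$filters, `[[`, "", "id"),
               vapply(libs$trio$filters, `[[`, "", "id"))
  expect_equal(sum(ts$n_synthetic_by_class), length(ids))
  # every synthetic item is synthetic in both channels, every N real
  for (it in ts$items) {
    if (it$label == "N") {
      expect_false(it$single$is_synthetic)
      expect_false(it$trio$is_synthetic)
    } else {
      expect_true(it$single$is_synthetic)
      expect_true(it$trio$is_synthetic)
    }
  }
})

test_that("leave-subject-out removes every trace of the excluded subject", {
  co <- small_cohort()
  libs <- small_libraries()
  donor <- names(libs$single$provenance)[1]
  rec <- co$train[[donor]]
  ts <- build_training_set(rec, libs, exclude = TRUE,
                           duration_s = record_duration(rec))
  excluded_ids <- unlist(libs$single$provenance[[donor]])
  expect_gt(length(excluded_ids), 0)
  # synthetic items come only from other subjects' filters
  kept <- exclude_subject(libs$single, donor)
  expect_equal(sum(ts$n_synthetic_by_class),
               length(union(vapply(kept$filters, `[[`, "", "id"),
                            vapply(exclude_subject(libs$trio, donor)$filters,
                                   `[[`, "", "id"))))
})

test_that("the training-set constructor enforces the no-real-abnormal invariant", {
  real_v <- random_beat("V", seed = 31)
  real_v$is_synthetic <- FALSE
  trio_v <- random_beat("V", mode = "trio", seed = 32)
  trio_v$is_synthetic <- TRUE
  expect_error(
    abswarn:::new_training_set(
      list(list(single = real_v, trio = trio_v, label = "V")), "x"),
    "real abnormal")
  syn_n <- random_beat("N", seed = 33)
  syn_n$is_synthetic <- TRUE
  real_n <- random_beat("N", mode = "trio", seed = 34)
  expect_error(
    abswarn:::new_training_set(
      list(list(single = syn_n, trio = real_n, label = "N")), "x"),
    "synthetic N")
})

test_that("an empty library yields a flagged single-class training set", {
  co <- small_cohort()
  empty <- build_library(list(), filter_design_config(32, 1e-3, "single"))
  expect_warning(
    ts <- build_training_set(co$test[[1]], empty),
    "only the N class")
  expect_true(ts$flagged_single_class)
  expect_equal(sum(ts$n_synthetic_by_class), 0)
})

test_that("nearest_synthetic matches the exhaustive scan oracle", {
  q <- random_beat("V", seed = 40)
  cands <- lapply(1:50, function(i) random_beat("V", seed = 100 + i,
                                                beat_index = i))
  res <- nearest_synthetic(q, cands)
  d <- vapply(cands, function(c) sqrt(sum((c$samples - q$samples)^2)), 1)
  expect_equal(res$index, which.min(d))
  expect_equal(res$distance, min(d))
  # the query itself at distance zero; singleton list
  expect_equal(nearest_synthetic(q, c(cands, list(q)))$distance, 0)
  expect_equal(nearest_synthetic(q, cands[2])$index, 1)
  expect_error(nearest_synthetic(q, list()), "empty")
})

test_that("synthetic beats land nearer their real counterparts than real N beats", {
  co <- small_cohort()
  libs <- small_libraries()
  subj <- co$test[[1]]
  ts <- build_training_set(subj, libs)
  ann <- subj$annotations
  # real abnormal beats of the monitored tail, single representation
  ab_idx <- which(ann$label %in% c("S", "V") &
                  seq_len(nrow(ann)) > 1 & seq_len(nrow(ann)) < nrow(ann))
  n_idx <- which(ann$label == "N" & ann$r_sample < 300 * subj$fs)
  n_mat <- t(vapply(n_idx[-c(1)], function(i)
    segment_single_beat(subj, i)$samples, numeric(128)))
  hits <- 0
  for (i in ab_idx) {
    b <- segment_single_beat(subj, i)
    if (b$label == "S") next  # timing-only anomalies are invisible here
    syn <- Filter(function(it) it$label == b$label, ts$items)
    if (!length(syn)) next
    d_syn <- min(vapply(syn, function(it)
      sqrt(sum((it$single$samples - b$samples)^2)), 1))
    d_n <- min(sqrt(rowSums(sweep(n_mat, 2, b$samples)^2)))
    hits <- hits + (d_syn < d_n)
  }
  checked <- sum(ann$label[ab_idx] %in% c("V"))
  expect_gte(hits / checked, 0.8)
})

test_that("common training data adds only real donor N beats, never the subject's", {
  co <- small_cohort()
  libs <- small_libraries()
  subj <- co$test[[1]]
  base <- build_training_set(subj, libs)
  with_common <- build_training_set(subj, libs, common_records = co$train,
                                    common_per_donor = 10L)
  added <- length(with_common) - length(base)
  expect_equal(added, 10L * length(co$train))
  expect_equal(with_common$n_real_normal, base$n_real_normal + added)
  extra <- with_common$items[(length(base) - sum(base$n_synthetic_by_class) +
                              1):(length(base) -
                                  sum(base$n_synthetic_by_class) + added)]
  # donor contributions are real N beats from donor records
  for (it in extra) {
    expect_identical(it$label, "N")
    expect_false(it$single$is_synthetic)
    expect_true(it$single$subject_id %in% names(co$train))
  }
  # a donor identical to the subject is skipped
  self_only <- build_training_set(subj, libs, common_records = list(subj),
                                  common_per_donor = 10L)
  expect_equal(length(self_only), length(base))
  # determinism
  again <- build_training_set(subj, libs, common_records = co$train,
                              common_per_donor = 10L)
  expect_identical(length(again), length(with_common))
  expect_identical(again$items[[length(again)]]$single$samples,
                   with_common$items[[length(with_common)]]$single$samples)
})

test_that("training sets serialize deterministically and round-trip", {
  co <- small_cohort()
  libs <- small_libraries()
  ts <- build_training_set(co$test[[1]], libs)
  dir <- withr::local_tempdir()
  write_training_set(ts, file.path(dir, "a"))
  write_training_set(ts, file.path(dir, "b"))
  expect_identical(readLines(file.path(dir, "a.beats.csv")),
                   readLines(file.path(dir, "b.beats.csv")))
  back <- read_training_set(file.path(dir, "a"),
                            subject_id = ts$subject_id)
  expect_equal(length(back), length(ts))
  expect_equal(back$n_real_normal, ts$n_real_normal)
  for (i in seq_along(ts$items)) {
    expect_identical(back$items[[i]]$single$samples,
                     ts$items[[i]]$single$samples)
    expect_identical(back$items[[i]]$trio$samples,
                     ts$items[[i]]$trio$samples)
    expect_identical(back$items[[i]]$label, ts$items[[i]]$label)
  }
})
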