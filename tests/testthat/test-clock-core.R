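# feature table with exact integer methylation percents (depth 100)
table_from_percents <- function(mat, ages, ids = sprintf("s%02d", seq_along(ages))) {
  callsets <- lapply(seq_len(nrow(mat)), function(i)
    make_callset(ids[i], pos = seq_len(ncol(mat)) * 10L,
                 meth = as.integer(round(mat[i, ])),
                 unmeth = 100L - as.integer(round(mat[i, ]))))
  build_feature_table(callsets, data.frame(sample_id = ids, age = ages))
}

test_that("intersect_sites matches a naive set-intersection oracle", {
  w <- small_world()
  set.seed(31)
  for (i in 1:30) {
    keep <- runif(500) < runif(1, 0.2, 0.9)
    test <- make_callset("t", pos = w$table$sites$pos[keep],
                         meth = rep(5L, sum(keep)), unmeth = rep(5L, sum(keep)))
    isect <- intersect_sites(w$table, test)
    # brute-force nested membership check
    oracle <- sort(intersect(paste0("chr1:", w$table$sites$pos),
                             paste0("chr1:", test$calls$pos)))
    expect_equal(sort(paste0(isect$sites$chrom, ":", isect$sites$pos)), oracle)
    expect_equal(isect$n_sites, length(oracle))
  }
  mism <- make_callset("t", 10, 5, 5, assembly = "hg19")
  expect_error(intersect_sites(w$table, mism), "configuration error")
})

test_that("restrict keeps exactly the requested columns, values unchanged", {
  w <- small_world()
  full <- restrict(w$table, w$table$sites)
  expect_equal(full$values, w$table$values)
  one <- restrict(w$table, w$table$sites[3])
  expect_equal(ncol(one$values), 1L)
  expect_equal(one$ages, w$table$ages)
  set.seed(77)
  idx <- sample(nrow(w$table$sites), 40)
  sub <- restrict(w$table, w$table$sites[idx])
  expect_equal(sub$values, w$table$values[, idx])
  absent <- data.frame(chrom = "chr9", pos = 1L)
  expect_error(restrict(w$table, absent), "contract violation")
})

test_that("fold assignment is near-equal and invariant to sample order", {
  ids <- sprintf("x%02d", 1:23)
  f1 <- icclock:::assign_folds(ids, 5, 42)
  expect_true(max(table(f1)) - min(table(f1)) <= 1)
  perm <- sample(seq_along(ids))
  f2 <- icclock:::assign_folds(ids[perm], 5, 42)
  expect_equal(f1[perm], f2)
})

test_that("a noiseless linear age signal is recovered by one fold's clock", {
  set.seed(5)
  mat <- matrix(sample(0:100, 60 * 30, replace = TRUE), 60, 30)
  ages <- 5 + 0.4 * mat[, 7]
  ft <- table_from_percents(mat, ages)
  cfg <- clock_config(min_intersection = 10)
  folds <- icclock:::assign_folds(ft$sample_ids, 5, 1)
  fit <- train_one_clock(ft, cfg, folds, 1L, seed = 2)
  expect_lt(median(abs(fit$holdout$prediction - fit$holdout$age)), 1)
  expect_gt(cor(fit$holdout$prediction, fit$holdout$age), 0.999)
})

test_that("degenerate designs are rejected", {
  set.seed(6)
  mat <- matrix(sample(0:100, 40 * 20, replace = TRUE), 40, 20)
  ft <- table_from_percents(mat, rep(33, 40))
  cfg <- clock_config(min_intersection = 10)
  folds <- icclock:::assign_folds(ft$sample_ids, 5, 1)
  expect_error(train_one_clock(ft, cfg, folds, 1L), "degenerate target")
  small <- table_from_percents(mat[1:8, ], seq_len(8))
  expect_error(train_one_clock(small, cfg,
                               icclock:::assign_folds(small$sample_ids, 5, 1), 1L),
               "too few samples")
})

test_that("samples below the intersection threshold are not admitted", {
  w <- small_world()
  pos <- w$table$sites$pos
  cfg <- clock_config(min_intersection = 100L, rng_seed = 3)
  below <- make_callset("below", pos[1:99], rep(5L, 99), rep(5L, 99))
  at <- make_callset("at", pos[1:100], rep(5L, 100), rep(5L, 100))
  r_below <- predict_sample(w$table, below, cfg)
  r_at <- predict_sample(w$table, at, cfg)
  expect_false(r_below$admitted)
  expect_true(is.na(r_below$predicted_age))
  expect_true(r_at$admitted)
  # monotone admission: lowering the threshold keeps the admitted sample admitted
  cfg_lo <- clock_config(min_intersection = 50L, rng_seed = 3)
  expect_true(predict_sample(w$table, at, cfg_lo)$admitted)
})

test_that("the prediction is exactly the mean of the five fold clocks", {
  w <- small_world()
  test <- filter_coverage(generate_test_sample(w$spec, age = 20,
                                               covered_fraction = 0.9,
                                               sample_id = "mean_check"))
  res <- predict_sample(w$table, test, clock_config(min_intersection = 100L))
  expect_true(res$admitted)
  expect_length(res$fold_predictions, 5L)
  expect_identical(res$predicted_age, mean(res$fold_predictions))
})

test_that("prediction is deterministic and invariant to training-row order", {
  w <- small_world()
  test <- filter_coverage(generate_test_sample(w$spec, age = 25,
                                               covered_fraction = 0.8,
                                               sample_id = "det"))
  cfg <- clock_config(min_intersection = 100L, rng_seed = 9)
  r1 <- predict_sample(w$table, test, cfg)
  r2 <- predict_sample(w$table, test, cfg)
  expect_identical(r1$fold_predictions, r2$fold_predictions)
  expect_identical(r1$predicted_age, r2$predicted_age)
  coh <- generate_training_cohort(w$spec)
  perm <- rev(seq_along(coh$callsets))
  ft_perm <- build_feature_table(coh$callsets[perm], coh$metadata)
  r3 <- predict_sample(ft_perm, test, cfg)
  expect_identical(r1$fold_predictions, r3$fold_predictions)
})

test_that("cohort predictions are per-sample independent and order-invariant", {
  w <- small_world()
  cfg <- clock_config(min_intersection = 100L, rng_seed = 4)
  tests <- lapply(c(10, 25, 35), function(a)
    filter_coverage(generate_test_sample(w$spec, a, 0.8,
                                         sprintf("coh_%d", a))))
  res <- predict_cohort(w$table, tests, cfg)
  res_perm <- predict_cohort(w$table, tests[c(3, 1, 2)], cfg)
  expect_identical(lapply(res, `[[`, "predicted_age")[c(3, 1, 2)],
                   lapply(res_perm, `[[`, "predicted_age"))
  # identical call sets give identical results
  twin <- predict_cohort(w$table, list(tests[[2]], tests[[2]]), cfg)
  expect_identical(twin[[1]]$fold_predictions, twin[[2]]$fold_predictions)
})

test_that("a tiny-overlap sample is flagged, the rest of the cohort admitted", {
  w <- small_world()
  cfg <- clock_config(min_intersection = 100L, rng_seed = 4)
  tests <- list(
    filter_coverage(generate_test_sample(w$spec, 20, 0.9, "ok1")),
    make_callset("tiny", w$table$sites$pos[1:5], rep(9L, 5), rep(1L, 5)),
    filter_coverage(generate_test_sample(w$spec, 30, 0.9, "ok2")))
  res <- predict_cohort(w$table, tests, cfg)
  expect_equal(vapply(res, `[[`, logical(1), "admitted"), c(TRUE, FALSE, TRUE))
})

test_that("predictions degrade gracefully, not catastrophically, with missingness", {
  w <- small_world()
  cfg <- clock_config(min_intersection = 50L, rng_seed = 12)
  preds <- vapply(c(1, 0.6, 0.3), function(f) {
    test <- filter_coverage(generate_test_sample(w$spec, 22, f, "miss",
                                                 min_depth = 5L))
    predict_sample(w$table, test, cfg)$predicted_age
  }, numeric(1))
  expect_true(all(abs(preds - 22) < 6))
  expect_lt(max(preds) - min(preds), 6)
})

test_that("higher latent age gives higher predicted age end to end", {
  spec <- generator_spec(n_samples = 40L, n_sites = 400L, n_informative = 80L,
                         noise_sd = 0, rng_seed = 777L)
  coh <- generate_training_cohort(spec)
  ft <- build_feature_table(coh$callsets, coh$metadata)
  cfg <- clock_config(min_intersection = 100L, rng_seed = 5)
  p10 <- predict_sample(ft, filter_coverage(
    generate_test_sample(spec, 10, 1, "y10", min_depth = 5L)), cfg)
  p35 <- predict_sample(ft, filter_coverage(
    generate_test_sample(spec, 35, 1, "y35", min_depth = 5L)), cfg)
  expect_lt(p10$predicted_age, p35$predicted_age)
  expect_lt(abs(p10$predicted_age - 10), 5)
  expect_lt(abs(p35$predicted_age - 35), 5)
})

test_that("prediction tables serialize with one row per sample", {
  w <- small_world()
  cfg <- clock_config(min_intersection = 100L, rng_seed = 4)
  tests <- list(filter_coverage(generate_test_sample(w$spec, 20, 0.9, "w1")),
                make_callset("w2", w$table$sites$pos[1:5], rep(9L, 5), rep(1L, 5)))
  path <- tempfile(fileext = ".tsv")
  dt <- write_predictions(predict_cohort(w$table, tests, cfg), path,
                          groups = c(w1 = "g1", w2 = "g2"))
  expect_equal(nrow(dt), 2L)
  expect_equal(dt$group, c("g1", "g2"))
  on_disk <- data.table::fread(path)
  expect_equal(nrow(on_disk), 2L)
  expect_true(all(c("fold_pred_1", "fold_pred_5", "predicted_age", "cv_r",
                    "cv_medae") %in% names(on_disk)))
})
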