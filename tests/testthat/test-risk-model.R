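test_that("preprocessing centers on medians and freezes its parameters", {
  fm <- make_toy_features(10, 10, seed = 4)
  prep <- fit_preprocessing(fm)
  x <- apply_preprocessing(prep, fm)
  expect_equal(unname(apply(x, 2, stats::median)), rep(0, 16),
               tolerance = 1e-12)

  # constant columns are floored, not NaN
  fm2 <- fm
  fm2$bin_7.5_8.0 <- 1e-4
  prep2 <- fit_preprocessing(fm2)
  x2 <- apply_preprocessing(prep2, fm2)
  expect_true(all(is.finite(x2)))
  expect_equal(unname(x2[, "bin_7.5_8.0"]), rep(0, 20))

  # test rows are transformed with the training parameters only
  probe <- make_toy_features(3, 3, seed = 5)
  xp <- apply_preprocessing(prep, probe)
  expect_equal(xp,
               sweep(sweep(edtar:::feature_columns(probe), 2,
                           prep$center, "-"), 2, prep$scale, "/"))

  single <- fm[fm$label == "normal", ]
  expect_error(fit_preprocessing(single), "both classes")
})

test_that("SVM tuning searches nine costs by LOOCV and is deterministic", {
  fm <- make_toy_features(12, 12, seed = 3)
  model <- tune_and_train_svm(fm, seed = 2)
  expect_length(model$cost_grid, 9)
  expect_equal(model$cost_grid, 2^(-2:6))
  expect_true(model$cost %in% model$cost_grid)
  expect_gt(model$sigma, 0)
  # separable toy classes reach perfect LOOCV accuracy somewhere
  expect_equal(max(model$loo_accuracy), 1.0)

  probe <- make_toy_features(4, 4, seed = 31)
  model2 <- tune_and_train_svm(fm, seed = 2)
  expect_equal(model2$cost, model$cost)
  expect_identical(compute_ocri(model2, probe)$ocri,
                   compute_ocri(model, probe)$ocri)

  expect_error(tune_and_train_svm(make_toy_features(4, 4, seed = 1)),
               "at least 10")
})

test_that("OCRI is a bounded probability that separates the profiles", {
  fm <- make_toy_features(15, 15, seed = 6)
  model <- tune_and_train_svm(fm, seed = 1)

  oscc_probe <- make_toy_features(0, 20, seed = 41)
  p <- compute_ocri(model, oscc_probe)$ocri
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(sum(p > 0.5), 18)

  # centroid of the normal training class scores low
  centroid <- colMeans(edtar:::feature_columns(
    fm[fm$label == "normal", ]))
  fv <- structure(centroid, class = "edtar_features",
                  case_id = "centroid")
  expect_lt(compute_ocri(model, fv)$ocri, 0.5)

  expect_error(compute_ocri(model, structure(rep(0.1, 15),
                                             class = "edtar_features")),
               "exactly 16")
})

test_that("OCRI stays within [0, 1] on randomized fuzz inputs", {
  fm <- make_toy_features(12, 12, seed = 13)
  model <- tune_and_train_svm(fm, seed = 1)
  withr::with_seed(123, {
    fuzz <- matrix(stats::runif(10000 * 16, 0, 5), ncol = 16,
                   dimnames = list(NULL, edtar:::feature_bin_names()))
  })
  fuzz_fm <- as.data.frame(fuzz)
  fuzz_fm$case_id <- sprintf("f%05d", seq_len(nrow(fuzz)))
  p <- compute_ocri(model, fuzz_fm)$ocri
  expect_true(all(p >= 0 & p <= 1))
})

test_that("cohort stratification sorts by risk and counts exceedances", {
  fm <- make_toy_features(12, 12, seed = 8)
  model <- tune_and_train_svm(fm, seed = 1)

  res <- stratify_cohort(model, fm)
  expect_true(!is.unsorted(rev(res$ocri)))
  expect_equal(attr(res, "n_above_threshold"), sum(res$ocri > 0.5))
  # training normals overwhelmingly stay below threshold
  expect_gte(mean(res$ocri[res$label == "normal"] < 0.5), 0.9)

  empty <- fm[0, ]
  res0 <- stratify_cohort(model, empty)
  expect_equal(nrow(res0), 0)
  expect_equal(attr(res0, "n_above_threshold"), 0L)
})

test_that("the benchmark runs six families over fifty shared resamples", {
  fm <- make_toy_features(20, 20, seed = 10)
  rep <- benchmark_models(fm, seed = 4)
  expect_equal(nrow(rep$resamples), 6 * 50)
  expect_equal(sort(unique(rep$resamples$model)),
               sort(c("svm", "rf", "plr", "nnet", "knn", "cart")))
  expect_length(rep$folds, 50)
  met <- rep$resamples[, c("roc", "sensitivity", "specificity")]
  expect_true(all(met >= 0 & met <= 1, na.rm = TRUE))
  expect_equal(rep$summary$rank, 1:6)

  expect_error(benchmark_models(make_toy_features(5, 20, seed = 1)),
               ">= 10 cases per class")
})

test_that("fold assignments and metrics are identical under one seed", {
  fm <- make_toy_features(15, 15, seed = 20)
  r1 <- benchmark_models(fm, seed = 11, models = c("svm", "cart"))
  r2 <- benchmark_models(fm, seed = 11, models = c("svm", "cart"))
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$resamples, r2$resamples)
  r3 <- benchmark_models(fm, seed = 12, models = c("svm", "cart"))
  expect_false(identical(r1$folds, r3$folds))
})

test_that("label permutation collapses every model to chance AUC", {
  fm <- make_toy_features(40, 40, seed = 30)
  fm$label <- withr::with_seed(17, sample(fm$label))
  rep <- benchmark_models(fm, seed = 5)
  med <- stats::aggregate(roc ~ model, data = rep$resamples,
                          FUN = stats::median)
  expect_true(all(med$roc >= 0.35 & med$roc <= 0.65))
})
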