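test_that("three observed populations are re-weighted onto the 0.9 budget", {
  dec <- fake_decomposition(c("diploid", "tetraploid", "aneuploid"),
                            means = c(1.0, 2.0, 3.0),
                            sds = c(0.19, 0.25, 0.4),
                            counts = c(893, 92, 5))
  am <- amplify(dec, seed = 1)
  w <- stats::setNames(am$components$weight, am$components$kind)
  # arithmetic oracle: R1 = 0.9 * 0.893 / (0.893 + 0.092)
  expect_equal(w[["diploid"]], 0.9 * 0.893 / 0.985, tolerance = 1e-12)
  expect_equal(w[["tetraploid"]], 0.9 * 0.092 / 0.985, tolerance = 1e-12)
  expect_equal(w[["aneuploid"]], 0.1, tolerance = 1e-12)
  expect_equal(w[["diploid"]] + w[["tetraploid"]], 0.9,
               tolerance = 1e-12)
  expect_true(all(am$components$provenance == "observed"))
})

test_that("diploid+tetraploid cases get the 0.995 split and a hypothetical aneuploid", {
  dec <- fake_decomposition(c("diploid", "tetraploid"),
                            means = c(1.0, 2.0), sds = c(0.19, 0.25),
                            counts = c(900, 100))
  am <- amplify(dec, seed = 1)
  w <- stats::setNames(am$components$weight, am$components$kind)
  expect_equal(w[["diploid"]], 0.8955, tolerance = 1e-12)
  expect_equal(w[["tetraploid"]], 0.0995, tolerance = 1e-12)
  expect_equal(w[["aneuploid"]], 0.005, tolerance = 1e-12)
  an <- am$components[am$components$kind == "aneuploid", ]
  expect_equal(an$provenance, "hypothetical")
  expect_equal(c(an$mean, an$sd), c(2.3, 0.3))
})

test_that("diploid-only cases draw R1 from Unif[0.75, 0.8] with R3 = 0.005", {
  dec <- fake_decomposition("diploid", 1.0, 0.19, 1000)
  for (seed in c(1, 7, 42)) {
    am <- amplify(dec, seed = seed)
    w <- stats::setNames(am$components$weight, am$components$kind)
    expect_gte(w[["diploid"]], 0.75)
    expect_lte(w[["diploid"]], 0.80)
    expect_equal(w[["diploid"]] + w[["tetraploid"]], 0.995,
                 tolerance = 1e-12)
    expect_equal(w[["aneuploid"]], 0.005, tolerance = 1e-12)
    hyp <- am$components[am$components$provenance == "hypothetical", ]
    expect_equal(hyp$mean, c(2.0, 2.3))
    expect_equal(hyp$sd, c(0.3, 0.3))
  }
  # the draw is seeded
  expect_identical(amplify(dec, seed = 3)$components$weight,
                   amplify(dec, seed = 3)$components$weight)
})

test_that("the weight constraint holds to 1e-9 on every amplification path", {
  decs <- list(
    fake_decomposition("diploid", 1.0, 0.2, 500),
    fake_decomposition(c("diploid", "tetraploid"), c(1, 2),
                       c(0.2, 0.25), c(450, 50)),
    fake_decomposition(c("diploid", "aneuploid"), c(1, 3.2),
                       c(0.2, 0.4), c(480, 20)),
    fake_decomposition(c("diploid", "tetraploid", "aneuploid"),
                       c(1, 2, 3.2), c(0.2, 0.25, 0.4),
                       c(400, 80, 20)))
  for (dec in decs) {
    for (seed in 1:5) {
      am <- amplify(dec, seed = seed)
      expect_equal(sum(am$components$weight), 1, tolerance = 1e-9)
      expect_true(all(am$components$weight > 0))
      expect_true(!is.unsorted(am$components$mean, strictly = TRUE))
    }
  }
})

test_that("amplification never attenuates a small aneuploid signal", {
  for (r3_obs in c(0.001, 0.01, 0.05, 0.09)) {
    n <- 1000
    k <- round(r3_obs * n)
    dec <- fake_decomposition(c("diploid", "tetraploid", "aneuploid"),
                              c(1, 2, 3.2), c(0.2, 0.25, 0.4),
                              c(n - 100 - k, 100, k))
    am <- amplify(dec, seed = 2)
    r3_amp <- am$components$weight[am$components$kind == "aneuploid"]
    expect_gte(r3_amp, dec$populations$ratio[3])
  }
})

test_that("reconstruction bins the mixture mass with filler and clamp", {
  # everything inside [0.5, 1.0)
  narrow <- fake_amplified(means = c(0.7, 0.75, 0.8),
                           sds = c(0.01, 0.01, 0.01),
                           weights = c(0.3, 0.3, 0.4))
  fv <- reconstruct(narrow)
  expect_length(fv, 16)
  expect_equal(names(fv), edtar:::feature_bin_names())
  expect_gt(fv[["bin_0.5_1.0"]], 0.99)
  expect_equal(unname(unclass(fv))[-2], rep(1e-4, 15))

  # high aneuploid mass clamps into the final bin
  high <- fake_amplified(means = c(1.0, 2.0, 9.0),
                         sds = c(0.19, 0.25, 0.3),
                         weights = c(0.5, 0.3, 0.2))
  fv2 <- reconstruct(high)
  expect_equal(fv2[["bin_7.5_8.0"]], 0.2, tolerance = 1e-3)

  # mass conservation with the filler allowance
  for (fv_i in list(fv, fv2)) {
    expect_gte(sum(fv_i), 1.0)
    expect_lte(sum(fv_i), 1.0 + 16 * 1e-4 + 0.01)
  }

  # component order does not matter
  perm <- narrow
  perm$components <- perm$components[c(3, 1, 2), ]
  expect_equal(as.numeric(reconstruct(perm)), as.numeric(fv))
})

test_that("the end-to-end transform is deterministic and risk-ordered", {
  cn <- simulate_case(case_profile("normal", n_cells = 1500, seed = 10),
                      "n", label = "normal")
  co <- simulate_case(case_profile("oscc", n_cells = 1500, seed = 10),
                      "o", label = "oscc")
  fn <- edtar_transform(cn, seed = 5)
  fo <- edtar_transform(co, seed = 5)

  expect_identical(as.numeric(edtar_transform(cn, seed = 5)),
                   as.numeric(fn))
  # dominant mass of a normal case sits in the diploid bins
  expect_true(names(fn)[which.max(fn)] %in%
                c("bin_1.0_1.5", "bin_0.5_1.0"))
  # carcinoma profile pushes mass into the high-DI bins: its amplified
  # aneuploid component sits well beyond the 2.3 cutoff, while any
  # amplified component of a normal case stays at the cutoff itself
  high_bins <- 6:16  # DI >= 2.5
  expect_gt(sum(fo[high_bins]), sum(fn[high_bins]))
})

test_that("feature matrices carry ids, labels and the filler floor", {
  co <- simulate_cohort(3, 0, 3, seed = 2, n_cells_range = c(300, 500))
  fm <- edtar_features(co, seed = 9)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm), 6)
  bins <- edtar:::feature_bin_names()
  expect_true(all(as.matrix(fm[, bins]) >= 1e-4))
  expect_identical(edtar_features(co, seed = 9), fm)
})
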