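test_that("mirror extraction recovers a pure normal population", {
  stats <- vapply(1:20, function(s) {
    withr::with_seed(s, v <- stats::rnorm(2000, 1.0, 0.2))
    v <- v[v > 0]
    dens <- estimate_density(v)
    peaks <- find_peaks(dens)
    top <- peaks[which.max(peaks$height), ]
    ext <- extract_population(v, top)
    p <- ext$summary$mean
    nl <- sum(ext$claimed & v <= p)
    nr <- sum(ext$claimed) - nl
    c(resid = length(ext$residual) / length(v), sd = ext$summary$sd,
      asym = abs(nl - nr))
  }, numeric(3))
  expect_true(all(stats["resid", ] <= 0.05))
  expect_true(all(stats["sd", ] >= 0.17 & stats["sd", ] <= 0.23))
  # mirror symmetry: left and right removals agree to sampling noise
  expect_lte(stats::median(stats["asym", ]), sqrt(2000))
  expect_true(all(stats["asym", ] <= 3 * sqrt(2000)))
})

test_that("extraction leaves a second population as residual", {
  fr <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      v <- c(stats::rnorm(1800, 1.0, 0.15), stats::rnorm(200, 2.0, 0.15))
      v <- v[v > 0]
    })
    peaks <- find_peaks(estimate_density(v))
    top <- peaks[which.max(peaks$height), ]
    length(extract_population(v, top)$residual) / length(v)
  }, numeric(1))
  expect_true(all(abs(fr - 0.1) <= 0.03))
})

test_that("a peak outside the data span is a contract error", {
  expect_error(
    extract_population(c(1, 1.1, 1.2), list(location = 5)),
    "outside the data span")
})

test_that("a pure diploid case decomposes to a single population", {
  cs <- simulate_case(mixture_spec(1.0, 0.19, 1, n_cells = 2000,
                                   seed = 3), "pure")
  dec <- decompose(cs)
  expect_true(dec$analyzable)
  expect_equal(nrow(dec$populations), 1)
  expect_equal(dec$populations$kind, "diploid")
  expect_equal(dec$populations$ratio, 1.0)
  expect_equal(dec$populations$count, 2000)
})

test_that("isolated high-DI cells form the aneuploid population untouched", {
  withr::with_seed(9, v <- c(stats::runif(200, 0.9, 1.1), rep(3, 7)))
  dec <- decompose(di_case("x", v))
  an <- dec$populations[dec$populations$kind == "aneuploid", ]
  expect_equal(an$count, 7)
  expect_equal(an$mean, 3.0)
  expect_equal(dec$aneuploid_max_di, 3.0)
})

test_that("population counts are conserved for every case", {
  for (profile in c("normal", "olk", "oscc")) {
    for (s in 1:3) {
      cs <- simulate_case(case_profile(profile, n_cells = 1500,
                                       seed = 500 + s), "c",
                          label = profile)
      dec <- decompose(cs)
      expect_equal(sum(dec$populations$count), dec$n_total)
      expect_equal(sum(dec$populations$ratio), 1, tolerance = 1e-6)
      expect_true(all(!is.na(dec$assignment)))
    }
  }
})

test_that("duplicating every cell leaves the ratios unchanged", {
  cs <- simulate_case(fig1d_spec(n_cells = 1500, seed = 77), "dup")
  dup <- di_case("dup2", rep(cs$di, 2))
  # fixed bandwidth: the density of the duplicated sample is identical
  d1 <- decompose(cs, bandwidth = 0.05)
  d2 <- decompose(dup, bandwidth = 0.05)
  r1 <- stats::setNames(d1$populations$ratio, d1$populations$kind)
  r2 <- stats::setNames(d2$populations$ratio, d2$populations$kind)
  expect_equal(sort(names(r1)), sort(names(r2)))
  expect_equal(r2[names(r1)], r1, tolerance = 1e-6)
})

test_that("ratios and cell assignments are recovered for separated mixtures", {
  truth <- c(diploid = 0.7, tetraploid = 0.2, aneuploid = 0.1)
  res <- vapply(1:10, function(s) {
    sp <- mixture_spec(c(1, 2, 3.5), c(0.15, 0.12, 0.25),
                       unname(truth), n_cells = 2000, seed = s)
    cs <- simulate_case(sp, "r")
    dec <- decompose(cs)
    r <- stats::setNames(dec$populations$ratio, dec$populations$kind)
    kinds <- c("diploid", "tetraploid", "aneuploid")[cs$true_component]
    c(within = all(abs(r[names(truth)] - truth) < 0.05),
      agree = mean(dec$assignment == kinds))
  }, numeric(2))
  expect_gte(mean(res["within", ]), 0.9)
  expect_gte(mean(res["agree", ] >= 0.9), 0.9)
})

test_that("cases without a diploid peak are flagged unanalyzable", {
  withr::with_seed(4, v <- stats::rnorm(500, 3.5, 0.3))
  dec <- decompose(di_case("noD", v[v > 0]))
  expect_false(dec$analyzable)
  expect_equal(nrow(dec$populations), 0)
  expect_error(amplify(dec), "unanalyzable")
})

test_that("tiny cases fall back to fixed DI windows", {
  dec <- decompose(di_case("small", c(1.0, 1.1, 1.2, 2.0, 3.0)))
  expect_true(dec$analyzable)
  pops <- stats::setNames(dec$populations$count, dec$populations$kind)
  expect_equal(pops[["diploid"]], 3)
  expect_equal(pops[["tetraploid"]], 1)
  expect_equal(pops[["aneuploid"]], 1)
  expect_equal(sum(dec$populations$ratio), 1)

  dec2 <- decompose(di_case("smallNoD", c(2.0, 2.1, 3.0)))
  expect_false(dec2$analyzable)
})

test_that("the printed three-population simulation is recovered", {
  # 5-seed sanity version of the full 20-seed recovery experiment
  means <- vapply(1:5, function(s) {
    cs <- simulate_case(fig1d_spec(seed = 600 + s), "f")
    dec <- decompose(cs)
    p <- dec$populations
    c(p$mean[p$kind == "diploid"],
      ifelse(any(p$kind == "tetraploid"),
             p$mean[p$kind == "tetraploid"], NA_real_))
  }, numeric(2))
  expect_equal(mean(means[1, ]), 1.001, tolerance = 0.05)
  expect_equal(mean(means[2, ], na.rm = TRUE), 2.002, tolerance = 0.08)
})
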