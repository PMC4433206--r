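# shared fixture builders; everything is generated in code at test time

# hand-built decomposition object for exercising the amplification paths
# without running the full extraction
fake_decomposition <- function(kinds, means, sds, counts,
                               case_id = "fake") {
  n <- sum(counts)
  pops <- data.frame(kind = kinds, mean = means, sd = sds,
                     count = counts, ratio = counts / n,
                     stringsAsFactors = FALSE)
  structure(list(case_id = case_id, analyzable = TRUE,
                 populations = pops, n_total = n,
                 peak_locations = means,
                 aneuploid_max_di = if ("aneuploid" %in% kinds)
                   max(means[kinds == "aneuploid"]) else NA_real_,
                 assignment = NULL, bw = 0.05, label = NULL),
            class = "di_decomposition")
}

fake_amplified <- function(means, sds, weights, case_id = "fake") {
  structure(list(
    components = data.frame(
      kind = c("diploid", "tetraploid", "aneuploid"),
      mean = means, sd = sds, weight = weights,
      provenance = "observed", stringsAsFactors = FALSE),
    seed = 1L, case_id = case_id, label = NULL,
    aneuploid_max_di = NA_real_),
    class = "amplified_mixture")
}

# synthetic 16-bin feature matrix with class-separated mass patterns;
# independent of the transformation pipeline, for risk-model unit tests
make_toy_features <- function(n_normal, n_oscc, seed = 1, sep = 1) {
  bins <- edtar:::feature_bin_names()
  withr::with_seed(seed, {
    make_row <- function(label, i) {
      m <- rep(1e-4, 16)
      if (label == "normal") {
        m[2:3] <- c(0.55, 0.40) + stats::rnorm(2, 0, 0.03)
      } else {
        m[2:3] <- c(0.45, 0.30) + stats::rnorm(2, 0, 0.03)
        m[6:8] <- sep * c(0.10, 0.08, 0.05) + stats::rnorm(3, 0, 0.02)
      }
      m <- pmax(m, 1e-4)
      stats::setNames(as.list(m), bins)
    }
    rows <- c(lapply(seq_len(n_normal), function(i)
                c(list(case_id = sprintf("normal_%03d", i),
                       label = "normal"), make_row("normal", i))),
              lapply(seq_len(n_oscc), function(i)
                c(list(case_id = sprintf("oscc_%03d", i),
                       label = "oscc"), make_row("oscc", i))))
    out <- do.call(rbind, lapply(rows, as.data.frame,
                                 stringsAsFactors = FALSE))
    class(out) <- c("feature_matrix", "data.frame")
    out
  })
}
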