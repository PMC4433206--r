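#' Specify a Gaussian mixture of cell populations on the DNA-index scale
#'
#' A `mixture_spec` describes the generating model for one synthetic
#' cytometry case: a finite Gaussian mixture on the DNA-index (DI) axis.
#' Each component is a cell population (diploid near DI 1, tetraploid near
#' DI 2, aneuploid at DI >= 2.3); components are labelled by the window
#' their mean falls in so that simulated cells carry a ground-truth
#' population identity.
#'
#' @param means numeric vector of component means (DI units, all > 0).
#' @param sds numeric vector of component standard deviations (all > 0).
#' @param weights numeric vector of mixing proportions; must sum to 1
#'   within `1e-9`.
#' @param n_cells number of cells to draw (>= 1).
#' @param seed integer seed making the draw reproducible.
#' @param kinds optional character vector of population kinds
#'   (`"diploid"`, `"tetraploid"`, `"aneuploid"`); inferred from the
#'   means when omitted (`< 1.5`, `[1.5, 2.3)`, `>= 2.3`).
#' @return an object of class `mixture_spec`.
#' @seealso [fig1d_spec()], [case_profile()], [simulate_case()]
#' @export
mixture_spec <- function(means, sds, weights, n_cells, seed = 1L,
                         kinds = NULL) {
  if (length(means) != length(sds) || length(means) != length(weights))
    stop("means, sds and weights must have equal length", call. = FALSE)
  if (length(means) < 1L)
    stop("at least one component is required", call. = FALSE)
  if (any(!is.finite(means)) || any(means <= 0))
    stop("all component means must be positive", call. = FALSE)
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("all component sds must be positive", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("all component weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("component weights must sum to 1 (within 1e-9), got ",
         format(sum(weights), digits = 12), call. = FALSE)
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L)
    stop("n_cells must be a positive integer", call. = FALSE)
  if (is.null(kinds)) kinds <- population_kind(means)
  kinds <- match.arg(kinds, c("diploid", "tetraploid", "aneuploid"),
                     several.ok = TRUE)
  structure(
    list(components = data.frame(kind = kinds, mean = as.numeric(means),
                                 sd = as.numeric(sds),
                                 weight = as.numeric(weights),
                                 stringsAsFactors = FALSE),
         n_cells = n_cells, seed = as.integer(seed)),
    class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("DI mixture spec:", nrow(x$components), "component(s),",
      x$n_cells, "cells, seed", x$seed, "\n")
  print(x$components, row.names = FALSE)
  invisible(x)
}

## Population windows on the DI axis used throughout: diploid below 1.5,
## tetraploid [1.5, 2.3), aneuploid at and beyond the 2.3 cutoff.
population_kind <- function(mean) {
  ifelse(mean < 1.5, "diploid",
         ifelse(mean < 2.3, "tetraploid", "aneuploid"))
}

#' Three-population mixture of a typical positive cytometry histogram
#'
#' The canonical simulation setting used for parameter-recovery checks:
#' diploid N(1.001, 0.19), tetraploid N(2.002, 0.25) and aneuploid
#' N(2.300, 0.5) populations merged at ratio 0.893 : 0.092 : 0.005.
#' The ratio is normalised to mixing proportions (it sums to 0.99 as
#' printed).
#'
#' @param n_cells number of cells (default 4000).
#' @param seed integer seed.
#' @return a [mixture_spec()].
#' @export
fig1d_spec <- function(n_cells = 4000L, seed = 1L) {
  w <- c(0.893, 0.092, 0.005)
  mixture_spec(means = c(1.001, 2.002, 2.300),
               sds = c(0.19, 0.25, 0.5),
               weights = w / sum(w),
               n_cells = n_cells, seed = seed)
}

#' Mixture templates for the three clinical case profiles
#'
#' Returns a [mixture_spec()] emulating the DI distribution of a typical
#' case of each diagnostic group:
#' \describe{
#'   \item{normal}{a dominant diploid population with a trace tetraploid
#'     shoulder and an aneuploid weight of at most 0.001 — such cases
#'     carry essentially no cells beyond the DI 2.3 aneuploidy cutoff.}
#'   \item{olk}{oral leukoplakia: the diploid peak plus secondary
#'     populations near DI 1.25, 1.75, 2.22 and 2.74, giving the
#'     multi-peak pattern of premalignant lesions.}
#'   \item{oscc}{oral squamous cell carcinoma: diploid and tetraploid
#'     populations plus a substantial high-DI aneuploid population
#'     (weight >= 0.02) centred well beyond DI 3.}
#' }
#'
#' @param name `"normal"`, `"olk"` or `"oscc"`.
#' @param n_cells number of cells to draw.
#' @param seed integer seed.
#' @param aneuploid_weight optional override of the total aneuploid
#'   weight; the remaining components are rescaled to keep the weights
#'   summing to one.
#' @return a [mixture_spec()].
#' @export
case_profile <- function(name = c("normal", "olk", "oscc"),
                         n_cells = 2000L, seed = 1L,
                         aneuploid_weight = NULL) {
  name <- match.arg(name)
  tpl <- switch(name,
    normal = list(means = c(1.001, 2.002, 2.300),
                  sds = c(0.19, 0.25, 0.5),
                  weights = c(0.9965, 0.0030, 0.0005)),
    olk = list(means = c(1.001, 1.25, 1.75, 2.22, 2.74),
               sds = c(0.19, 0.15, 0.18, 0.20, 0.25),
               weights = c(0.840, 0.060, 0.060, 0.036, 0.004)),
    oscc = list(means = c(1.001, 1.90, 3.40),
                sds = c(0.19, 0.25, 0.50),
                weights = c(0.80, 0.12, 0.08)))
  if (!is.null(aneuploid_weight)) {
    stopifnot(is.numeric(aneuploid_weight), aneuploid_weight >= 0,
              aneuploid_weight < 1)
    kinds <- population_kind(tpl$means)
    an <- kinds == "aneuploid"
    if (!any(an))
      stop("profile has no aneuploid component to re-weight", call. = FALSE)
    w <- tpl$weights
    w[an] <- aneuploid_weight * w[an] / sum(w[an])
    w[!an] <- (1 - aneuploid_weight) * w[!an] / sum(w[!an])
    tpl$weights <- w
  }
  mixture_spec(tpl$means, tpl$sds, tpl$weights, n_cells = n_cells,
               seed = seed)
}

#' A single case of DNA-index measurements
#'
#' Container for one subject's per-cell DI values, the raw unit of
#' analysis. Values must be strictly positive (DI is a ratio of optical
#' densities).
#'
#' @param case_id character scalar identifying the case.
#' @param di numeric vector of DI values, all > 0.
#' @param label optional diagnostic label: `"normal"`, `"olk"`,
#'   `"oscc"` or `"unknown"`.
#' @param true_component optional integer vector (same length as `di`)
#'   of ground-truth mixture components for simulated cases.
#' @param seed optional integer recording the generating seed.
#' @return an object of class `di_case`.
#' @export
di_case <- function(case_id, di, label = NULL, true_component = NULL,
                    seed = NULL) {
  stopifnot(is.character(case_id), length(case_id) == 1L)
  di <- as.numeric(di)
  if (length(di) < 1L)
    stop("a case must contain at least one DI value", call. = FALSE)
  if (any(!is.finite(di)))
    stop("non-finite DI value in case ", case_id, call. = FALSE)
  if (any(di <= 0))
    stop("non-positive DI value in case ", case_id, call. = FALSE)
  if (!is.null(label)) {
    label <- match.arg(label, c("normal", "olk", "oscc", "unknown"))
  }
  if (!is.null(true_component)) {
    stopifnot(length(true_component) == length(di))
    true_component <- as.integer(true_component)
  }
  structure(list(case_id = case_id, di = di, label = label,
                 true_component = true_component, seed = seed),
            class = "di_case")
}

#' @export
print.di_case <- function(x, ...) {
  cat(sprintf("DI case %s: %d cells%s, DI range [%.3f, %.3f]\n",
              x$case_id, length(x$di),
              if (is.null(x$label)) "" else paste0(" (", x$label, ")"),
              min(x$di), max(x$di)))
  invisible(x)
}

#' Simulate one case from a mixture specification
#'
#' Draws `n_cells` DI values from the Gaussian mixture. A component is
#' drawn for every cell, then a normal deviate; the rare negative draw is
#' rejected and redrawn, since DI is strictly positive. The ground-truth
#' component of every cell is retained for validation against the
#' decomposition, and generation is bit-reproducible under the spec seed
#' (the caller's RNG state is left untouched).
#'
#' @param spec a [mixture_spec()].
#' @param case_id identifier for the new case.
#' @param label optional diagnostic label to attach.
#' @return a [di_case()] with `true_component` filled in.
#' @export
simulate_case <- function(spec, case_id = "case_1", label = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  comp <- spec$components
  withr::with_seed(spec$seed, {
    k <- sample.int(nrow(comp), spec$n_cells, replace = TRUE,
                    prob = comp$weight)
    di <- stats::rnorm(spec$n_cells, comp$mean[k], comp$sd[k])
    bad <- which(di <= 0)
    while (length(bad) > 0L) {
      di[bad] <- stats::rnorm(length(bad), comp$mean[k[bad]],
                              comp$sd[k[bad]])
      bad <- bad[di[bad] <= 0]
    }
    di_case(case_id, di, label = label, true_component = k,
            seed = spec$seed)
  })
}

#' Simulate a labelled cohort of cytometry cases
#'
#' Generates `n_normal` + `n_olk` + `n_oscc` cases from the default
#' [case_profile()] templates. Per-case cell counts are drawn uniformly
#' from `n_cells_range` and per-case seeds are derived deterministically
#' from the cohort seed, so any single case can be regenerated from its
#' manifest row alone.
#'
#' @param n_normal,n_olk,n_oscc non-negative case counts per group.
#' @param seed integer cohort seed.
#' @param n_cells_range length-2 integer range of per-case cell counts
#'   (default 1000 to 4000).
#' @return an object of class `di_cohort`: a list with `cases` (list of
#'   [di_case()]) and `manifest` (data frame with case_id, label,
#'   n_cells, seed).
#' @export
simulate_cohort <- function(n_normal, n_olk, n_oscc, seed = 1L,
                            n_cells_range = c(1000L, 4000L)) {
  counts <- c(normal = n_normal, olk = n_olk, oscc = n_oscc)
  if (any(counts < 0)) stop("case counts must be >= 0", call. = FALSE)
  n_total <- sum(counts)
  if (n_total == 0L)
    stop("empty cohort: all case counts are zero", call. = FALSE)
  stopifnot(length(n_cells_range) == 2L,
            n_cells_range[1] >= 1, n_cells_range[1] <= n_cells_range[2])
  labels <- rep(names(counts), counts)
  withr::with_seed(as.integer(seed), {
    case_seeds <- sample.int(.Machine$integer.max, n_total)
    n_cells <- sample(seq(n_cells_range[1], n_cells_range[2]), n_total,
                      replace = TRUE)
  })
  case_ids <- sprintf("%s_%03d", labels, stats::ave(seq_len(n_total),
                                                    labels, FUN = seq_along))
  cases <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sp <- case_profile(labels[i], n_cells = n_cells[i],
                       seed = case_seeds[i])
    cases[[i]] <- simulate_case(sp, case_id = case_ids[i],
                                label = labels[i])
  }
  structure(list(
    cases = cases,
    manifest = data.frame(case_id = case_ids, label = labels,
                          n_cells = as.integer(n_cells),
                          seed = as.integer(case_seeds),
                          stringsAsFactors = FALSE)),
    class = "di_cohort")
}

#' @export
print.di_cohort <- function(x, ...) {
  cat("DI cohort:", length(x$cases), "cases (")
  cat(paste(sprintf("%s=%d", names(table(x$manifest$label)),
                    as.integer(table(x$manifest$label))), collapse = ", "))
  cat(")\n")
  invisible(x)
}
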