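#' Constants of the signal-amplification rules
#'
#' The rule-based re-weighting that inflates the aneuploid signal before
#' reconstruction uses a small set of fixed constants: the combined
#' diploid+tetraploid weight when all three populations are observed
#' (0.9) or when the aneuploid one is missing (0.995), the aneuploid
#' floor weight (0.005), the uniform range the diploid weight is drawn
#' from when it is the only observed population (`[0.75, 0.8]`), and the
#' shapes of the hypothetical tetraploid (`N(2.0, 0.3)`) and aneuploid
#' (`N(2.3, 0.3)`) populations. Overriding any of them departs from the
#' published procedure; [run_pipeline()] warns when a run does so.
#'
#' @param three_pop_dt_weight combined diploid+tetraploid weight when all
#'   three populations are observed.
#' @param two_pop_dt_weight combined diploid+tetraploid weight when the
#'   aneuploid population is missing.
#' @param r3_floor aneuploid weight in the one- and two-population paths.
#' @param r1_range range of the uniform draw for the diploid weight in
#'   the one-population path.
#' @param hyp_tetraploid,hyp_aneuploid `c(mean, sd)` of the hypothetical
#'   populations substituted for undetected ones.
#' @return a named list of class `amplify_constants`.
#' @export
amplify_constants <- function(three_pop_dt_weight = 0.9,
                              two_pop_dt_weight = 0.995,
                              r3_floor = 0.005,
                              r1_range = c(0.75, 0.8),
                              hyp_tetraploid = c(2.0, 0.3),
                              hyp_aneuploid = c(2.3, 0.3)) {
  structure(list(three_pop_dt_weight = three_pop_dt_weight,
                 two_pop_dt_weight = two_pop_dt_weight,
                 r3_floor = r3_floor, r1_range = r1_range,
                 hyp_tetraploid = hyp_tetraploid,
                 hyp_aneuploid = hyp_aneuploid),
            class = "amplify_constants")
}

# sd floor for observed populations entering the analytic mixture; an
# aneuploid "population" of one cell has sample sd 0
COMPONENT_SD_FLOOR <- 0.05

#' Amplify the aneuploid signal of a decomposition
#'
#' Re-weights the detected populations into a three-component mixture
#' whose weights R1 (diploid), R2 (tetraploid) and R3 (aneuploid) sum to
#' one:
#' \itemize{
#'   \item all three populations observed: the diploid:tetraploid ratio
#'     is retained, rescaled so R1 + R2 = 0.9, and R3 = 0.1;
#'   \item diploid + tetraploid observed: ratio retained with
#'     R1 + R2 = 0.995, R3 = 0.005, and the aneuploid component takes
#'     the hypothetical shape N(2.3, 0.3);
#'   \item diploid only: R1 is drawn from Unif\[0.75, 0.8\],
#'     R2 = 0.995 - R1, R3 = 0.005, with hypothetical tetraploid
#'     N(2.0, 0.3) and aneuploid N(2.3, 0.3).
#' }
#' A diploid + aneuploid case (tetraploid undetected) follows the
#' three-population weighting (R3 = 0.1) with the hypothetical
#' tetraploid shape and the diploid share of R1 + R2 drawn from the same
#' uniform rule, scaled to the 0.9 budget.
#'
#' @param dec a [decompose()] result with at least one population.
#' @param seed integer seed for the uniform draw (recorded even when the
#'   path is deterministic).
#' @param constants an [amplify_constants()] list.
#' @return an object of class `amplified_mixture`: data frame
#'   `components` (kind, mean, sd, weight, provenance) plus `seed` and
#'   `case_id`.
#' @export
amplify <- function(dec, seed = 1L, constants = amplify_constants()) {
  stopifnot(inherits(dec, "di_decomposition"))
  if (!dec$analyzable)
    stop("case ", dec$case_id, " is unanalyzable (no diploid population)",
         call. = FALSE)
  pops <- dec$populations
  if (nrow(pops) == 0L)
    stop("decomposition has no populations", call. = FALSE)

  get_pop <- function(k) pops[pops$kind == k, , drop = FALSE]
  dip <- get_pop("diploid"); tet <- get_pop("tetraploid")
  ane <- get_pop("aneuploid")
  if (nrow(dip) == 0L)
    stop("no diploid population in decomposition of ", dec$case_id,
         call. = FALSE)
  has_tet <- nrow(tet) == 1L
  has_ane <- nrow(ane) == 1L

  comp <- function(kind, mean, sd, weight, prov) {
    data.frame(kind = kind, mean = mean,
               sd = max(sd, COMPONENT_SD_FLOOR), weight = weight,
               provenance = prov, stringsAsFactors = FALSE)
  }
  hyp_t <- constants$hyp_tetraploid
  hyp_a <- constants$hyp_aneuploid

  withr::with_seed(as.integer(seed), {
    if (has_tet && has_ane) {
      dt <- constants$three_pop_dt_weight
      r1 <- dt * dip$ratio / (dip$ratio + tet$ratio)
      cmp <- rbind(
        comp("diploid", dip$mean, dip$sd, r1, "observed"),
        comp("tetraploid", tet$mean, tet$sd, dt - r1, "observed"),
        comp("aneuploid", ane$mean, ane$sd, 1 - dt, "observed"))
    } else if (has_tet) {
      dt <- constants$two_pop_dt_weight
      r1 <- dt * dip$ratio / (dip$ratio + tet$ratio)
      cmp <- rbind(
        comp("diploid", dip$mean, dip$sd, r1, "observed"),
        comp("tetraploid", tet$mean, tet$sd, dt - r1, "observed"),
        comp("aneuploid", hyp_a[1], hyp_a[2], 1 - dt, "hypothetical"))
    } else if (has_ane) {
      # tetraploid missing but aneuploid observed: amplified budget with
      # a hypothetical tetraploid; diploid share follows the uniform rule
      dt <- constants$three_pop_dt_weight
      u <- stats::runif(1, constants$r1_range[1], constants$r1_range[2])
      r1 <- dt * u / constants$two_pop_dt_weight
      cmp <- rbind(
        comp("diploid", dip$mean, dip$sd, r1, "observed"),
        comp("tetraploid", hyp_t[1], hyp_t[2], dt - r1, "hypothetical"),
        comp("aneuploid", ane$mean, ane$sd, 1 - dt, "observed"))
    } else {
      r1 <- stats::runif(1, constants$r1_range[1], constants$r1_range[2])
      r2 <- constants$two_pop_dt_weight - r1
      cmp <- rbind(
        comp("diploid", dip$mean, dip$sd, r1, "observed"),
        comp("tetraploid", hyp_t[1], hyp_t[2], r2, "hypothetical"),
        comp("aneuploid", hyp_a[1], hyp_a[2],
             1 - constants$two_pop_dt_weight, "hypothetical"))
    }
  })

  if (abs(sum(cmp$weight) - 1) > 1e-9)
    stop("amplified weights do not sum to 1", call. = FALSE)
  if (any(cmp$weight <= 0))
    stop("amplified weights must be strictly positive", call. = FALSE)
  if (is.unsorted(cmp$mean, strictly = TRUE))
    stop("amplified component means must be increasing ",
         "(diploid < tetraploid < aneuploid)", call. = FALSE)
  structure(list(components = cmp, seed = as.integer(seed),
                 case_id = dec$case_id, label = dec$label,
                 aneuploid_max_di = dec$aneuploid_max_di),
            class = "amplified_mixture")
}

#' @export
print.amplified_mixture <- function(x, ...) {
  cat("Amplified mixture for", x$case_id, "(seed", paste0(x$seed, ")\n"))
  print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}

BIN_BREAKS <- seq(0, 8, by = 0.5)
FEATURE_FILLER <- 1e-4

feature_bin_names <- function() {
  sprintf("bin_%.1f_%.1f", BIN_BREAKS[-17], BIN_BREAKS[-1])
}

#' Reconstruct the 16-bin feature vector of an amplified mixture
#'
#' Integrates the weighted three-Gaussian mixture over 16 half-open DI
#' intervals `[0, 0.5), ..., [7.5, 8.0]`. Mass beyond DI 8 is clamped
#' into the last bin and the negligible mass below 0 into the first, so
#' the bins carry the full unit mass of the mixture; any bin holding
#' less than 0.0001 is set to the 0.0001 filler.
#'
#' @param mix an [amplify()] result.
#' @return named numeric vector of length 16 (class `edtar_features`),
#'   with `case_id` and `label` attributes.
#' @export
reconstruct <- function(mix) {
  stopifnot(inherits(mix, "amplified_mixture"))
  cmp <- mix$components
  mass <- numeric(16)
  for (i in seq_len(nrow(cmp))) {
    p <- stats::pnorm(BIN_BREAKS, cmp$mean[i], cmp$sd[i])
    m <- cmp$weight[i] * diff(p)
    m[1] <- m[1] + cmp$weight[i] * p[1]              # fold mass below 0
    m[16] <- m[16] + cmp$weight[i] * (1 - p[17])     # clamp mass above 8
    mass <- mass + m
  }
  mass[mass < FEATURE_FILLER] <- FEATURE_FILLER
  structure(stats::setNames(mass, feature_bin_names()),
            case_id = mix$case_id, label = mix$label,
            class = "edtar_features")
}

#' @export
print.edtar_features <- function(x, ...) {
  cat("EdTAR features for", attr(x, "case_id"), "\n")
  print(unclass(stats::setNames(as.numeric(x), names(x))), digits = 4)
  invisible(x)
}

#' Full expert-guided transformation of one case
#'
#' Composition of [decompose()], [amplify()] and [reconstruct()]: DI
#' values in, 16-bin feature vector out. Deterministic under a fixed
#' seed. Unanalyzable cases (no diploid population) raise an error of
#' class `edtar_unanalyzable`.
#'
#' @param case a [di_case()].
#' @param seed integer seed for the amplification draw.
#' @param constants an [amplify_constants()] list.
#' @param min_prominence,bandwidth passed to [decompose()].
#' @return an `edtar_features` vector of length 16.
#' @export
edtar_transform <- function(case, seed = 1L,
                            constants = amplify_constants(),
                            min_prominence = 0.005, bandwidth = NULL) {
  dec <- decompose(case, min_prominence = min_prominence,
                   bandwidth = bandwidth)
  if (!dec$analyzable)
    stop(structure(class = c("edtar_unanalyzable", "error", "condition"),
                   list(message = paste0("case ", case$case_id,
                                         " is unanalyzable"),
                        call = sys.call())))
  reconstruct(amplify(dec, seed = seed, constants = constants))
}

#' Transform a cohort into a feature matrix
#'
#' Applies [edtar_transform()] to every case, deriving per-case
#' amplification seeds deterministically from `seed`. Unanalyzable cases
#' are dropped with a warning naming them.
#'
#' @param cases a `di_cohort`, or a list of [di_case()] objects.
#' @param seed integer seed.
#' @param constants an [amplify_constants()] list.
#' @return a data frame (class `feature_matrix`) with columns `case_id`,
#'   `label` and the 16 `bin_*` columns.
#' @export
edtar_features <- function(cases, seed = 1L,
                           constants = amplify_constants()) {
  if (inherits(cases, "di_cohort")) cases <- cases$cases
  if (inherits(cases, "di_case")) cases <- list(cases)
  case_seeds <- withr::with_seed(as.integer(seed),
    sample.int(.Machine$integer.max, length(cases)))
  rows <- vector("list", length(cases))
  dropped <- character(0)
  for (i in seq_along(cases)) {
    fv <- tryCatch(
      edtar_transform(cases[[i]], seed = case_seeds[i],
                      constants = constants),
      edtar_unanalyzable = function(e) NULL)
    if (is.null(fv)) {
      dropped <- c(dropped, cases[[i]]$case_id)
      next
    }
    lab <- cases[[i]]$label
    rows[[i]] <- cbind(
      data.frame(case_id = cases[[i]]$case_id,
                 label = if (is.null(lab)) NA_character_ else lab,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(as.numeric(fv)),
                    col.names = feature_bin_names()))
  }
  if (length(dropped) > 0L)
    warning("dropped ", length(dropped), " unanalyzable case(s): ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no analyzable cases", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("feature_matrix", "data.frame")
  out
}

feature_columns <- function(fm) {
  as.matrix(fm[, feature_bin_names(), drop = FALSE])
}
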