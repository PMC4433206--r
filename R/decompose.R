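## DI windows used to label populations and as the small-sample
## fallback: diploid below 1.5, tetraploid [1.5, 2.3), aneuploid >= 2.3.
DI_TETRAPLOID_LOWER <- 1.5
DI_ANEUPLOID_CUTOFF <- 2.3

#' Extract one cell population around a density peak by mirror subtraction
#'
#' Models the population under `peak` as symmetric about the peak
#' location: its spread is estimated from the cells left of the peak
#' (within the peak's bounds) under a half-normal assumption,
#' `sd = sqrt(mean((x - p)^2))` over `x <= p`, and the right flank is
#' then expected to mirror the left one. Cells are claimed for the
#' population as long as the right-tail count does not exceed the
#' mirrored left-tail count; the excess, plus everything beyond
#' `p + 4 sd` on the right, is returned as residual for the next
#' extraction round.
#'
#' @param values numeric vector of remaining DI values.
#' @param peak one row of a [find_peaks()] data frame (or a list with
#'   `location`, `left_bound`, `right_bound`). Must lie within the span
#'   of `values`.
#' @param kind population label to record (`"diploid"`, `"tetraploid"`).
#' @return list with `summary` (data frame: kind, mean, sd, count),
#'   `claimed` (logical index into `values`) and `residual`
#'   (the unclaimed values).
#' @export
extract_population <- function(values, peak, kind = "diploid") {
  values <- as.numeric(values)
  p <- peak$location
  if (p < min(values) || p > max(values))
    stop("peak location ", format(p), " lies outside the data span",
         call. = FALSE)
  lb <- if (!is.null(peak$left_bound)) peak$left_bound else -Inf
  rb <- if (!is.null(peak$right_bound)) peak$right_bound else Inf

  half_sd <- function(center) {
    left <- values[values <= center & values >= lb]
    s <- sqrt(mean((left - center)^2))
    if (!is.finite(s) || s < 1e-3) 1e-3 else s
  }
  # the KDE mode converges slowly, and an off-center `p` makes the
  # mirror systematically asymmetric; refine the symmetry center as the
  # median of the cells in a 2-sd neighbourhood of the mode (clipped to
  # the peak's bounds), then re-estimate the half-normal sd about it
  s0 <- half_sd(p)
  nb <- values[values >= max(lb, p - 2 * s0) &
               values <= min(rb, p + 2 * s0)]
  if (length(nb) > 0L) p <- stats::median(nb)
  s <- half_sd(p)

  lo <- p - 4 * s
  hi <- p + 4 * s
  claimed <- values >= lo & values <= p  # whole left flank within 4 sd

  # right flank: claim in increasing order while the running count stays
  # within the mirrored left count plus a sampling allowance. Without an
  # allowance the difference between the right count k and its mirrored
  # left expectation m is a mean-zero random walk and claiming would
  # stop far too early on symmetric data; systematic excess from an
  # overlapping population still accumulates past it and is left as
  # residual. The allowance (0.1 m + 0.05 nl) is proportional to the
  # population counts, so the extraction is scale-free: replicating
  # every cell scales every term and leaves the claim set, and hence
  # the ratios, exactly unchanged.
  left_vals <- values[claimed]
  nl <- length(left_vals)
  right_idx <- which(values > p & values <= hi)
  if (length(right_idx) > 0L) {
    ord <- order(values[right_idx])
    right_sorted <- right_idx[ord]
    rv <- values[right_sorted]
    # process tied values as one group so the rule depends only on the
    # multiset of values, never on how ties are ordered
    grp <- match(rv, unique(rv))
    grp_end <- cumsum(tabulate(grp))              # k at each group end
    grp_val <- unique(rv)
    # cells on the left at least as far from p as the mirror image
    mirror_avail <- vapply(grp_val, function(x)
      sum(left_vals >= 2 * p - x), numeric(1))
    grp_ok <- grp_end <= 1.1 * mirror_avail + 0.05 * nl
    # claiming is monotone: stop at the first significant excess
    first_bad <- which(!grp_ok)
    if (length(first_bad) > 0L)
      grp_ok[seq_along(grp_ok) >= first_bad[1]] <- FALSE
    claimed[right_sorted[grp_ok[grp]]] <- TRUE
  }

  list(summary = data.frame(kind = kind, mean = p, sd = s,
                            count = sum(claimed),
                            stringsAsFactors = FALSE),
       claimed = claimed,
       residual = values[!claimed])
}

#' Decompose a case's DI distribution into ploidy populations
#'
#' Runs the sequential extraction procedure on one case: (a) estimate the
#' DI density and its peaks; (b) extract the dominant peak below DI 1.5
#' as the diploid population; (c) if a remaining peak lies in
#' `[1.5, 2.3)`, extract it as the tetraploid population; (d) pool all
#' residual cells with DI >= 2.3 as the aneuploid population. Residual
#' cells below 2.3 after extraction are reassigned to the nearest
#' extracted population by standardised distance, so population counts
#' always sum to the case total. When only a diploid population is
#' detected no further processing occurs.
#'
#' Cases with fewer than 10 cells skip density estimation and are
#' decomposed by the fixed DI windows `[0, 1.5)`, `[1.5, 2.3)`,
#' `[2.3, Inf)` instead. A case with no identifiable diploid population
#' (no peak below DI 1.5) is flagged unanalyzable rather than silently
#' processed.
#'
#' @param case a [di_case()].
#' @param min_prominence passed to [find_peaks()].
#' @param bandwidth optional fixed KDE bandwidth.
#' @return an object of class `di_decomposition`: list with `case_id`,
#'   `analyzable`, `populations` (data frame: kind, mean, sd, count,
#'   ratio), `n_total`, `peak_locations`, `aneuploid_max_di`,
#'   `assignment` (per-cell population labels), `bw`, `label`.
#' @export
decompose <- function(case, min_prominence = 0.005, bandwidth = NULL) {
  stopifnot(inherits(case, "di_case"))
  v <- case$di
  n <- length(v)

  if (n < 10L) return(decompose_small(case))

  dens <- estimate_density(v, bandwidth = bandwidth)
  peaks <- find_peaks(dens, min_prominence = min_prominence)

  dip_cand <- peaks[peaks$location < DI_TETRAPLOID_LOWER, , drop = FALSE]
  if (nrow(dip_cand) == 0L) {
    return(new_decomposition(case, analyzable = FALSE,
                             populations = empty_populations(),
                             peaks = peaks$location, bw = dens$bw))
  }
  dip_peak <- dip_cand[which.max(dip_cand$height), ]

  assignment <- rep(NA_character_, n)
  ext_d <- extract_population(v, dip_peak, kind = "diploid")
  if (ext_d$summary$count == 0L) {
    # a diploid peak that claims no cells is no population at all
    return(new_decomposition(case, analyzable = FALSE,
                             populations = empty_populations(),
                             peaks = peaks$location, bw = dens$bw))
  }
  assignment[ext_d$claimed] <- "diploid"
  pops <- ext_d$summary
  res_idx <- which(!ext_d$claimed)

  tet_cand <- peaks[peaks$location >= DI_TETRAPLOID_LOWER &
                    peaks$location < DI_ANEUPLOID_CUTOFF, , drop = FALSE]
  if (nrow(tet_cand) > 0L && length(res_idx) > 0L) {
    tet_peak <- tet_cand[which.max(tet_cand$height), ]
    res_v <- v[res_idx]
    if (tet_peak$location >= min(res_v) && tet_peak$location <= max(res_v)) {
      ext_t <- extract_population(res_v, tet_peak, kind = "tetraploid")
      if (ext_t$summary$count > 0L) {
        assignment[res_idx[ext_t$claimed]] <- "tetraploid"
        pops <- rbind(pops, ext_t$summary)
        res_idx <- res_idx[!ext_t$claimed]
      }
    }
  }

  an_idx <- res_idx[v[res_idx] >= DI_ANEUPLOID_CUTOFF]
  aneuploid_max <- NA_real_
  if (length(an_idx) > 0L) {
    av <- v[an_idx]
    aneuploid_max <- max(av)
    pops <- rbind(pops, data.frame(
      kind = "aneuploid", mean = mean(av),
      sd = if (length(av) > 1L) stats::sd(av) else 0,
      count = length(av), stringsAsFactors = FALSE))
    assignment[an_idx] <- "aneuploid"
    res_idx <- setdiff(res_idx, an_idx)
  }

  # sub-cutoff residuals: nearest extracted population by |x - mean| / sd
  if (length(res_idx) > 0L) {
    host <- pops[pops$kind != "aneuploid", , drop = FALSE]
    for (i in res_idx) {
      z <- abs(v[i] - host$mean) / pmax(host$sd, 1e-6)
      k <- host$kind[which.min(z)]
      assignment[i] <- k
      pops$count[pops$kind == k] <- pops$count[pops$kind == k] + 1L
    }
  }

  pops$ratio <- pops$count / n
  new_decomposition(case, analyzable = TRUE, populations = pops,
                    peaks = peaks$location, aneuploid_max = aneuploid_max,
                    assignment = assignment, bw = dens$bw)
}

## windowed fallback for cases too small for density estimation
decompose_small <- function(case) {
  v <- case$di
  kinds <- population_kind(v)
  if (!any(kinds == "diploid")) {
    return(new_decomposition(case, analyzable = FALSE,
                             populations = empty_populations(),
                             peaks = numeric(0), bw = NA_real_))
  }
  pops <- do.call(rbind, lapply(intersect(
    c("diploid", "tetraploid", "aneuploid"), unique(kinds)),
    function(k) {
      x <- v[kinds == k]
      data.frame(kind = k, mean = mean(x),
                 sd = if (length(x) > 1L) stats::sd(x) else 0,
                 count = length(x), stringsAsFactors = FALSE)
    }))
  pops$ratio <- pops$count / length(v)
  an_max <- if (any(kinds == "aneuploid")) max(v[kinds == "aneuploid"])
            else NA_real_
  new_decomposition(case, analyzable = TRUE, populations = pops,
                    peaks = numeric(0), aneuploid_max = an_max,
                    assignment = kinds, bw = NA_real_)
}

empty_populations <- function() {
  data.frame(kind = character(0), mean = numeric(0), sd = numeric(0),
             count = integer(0), ratio = numeric(0),
             stringsAsFactors = FALSE)
}

new_decomposition <- function(case, analyzable, populations, peaks,
                              aneuploid_max = NA_real_,
                              assignment = NULL, bw = NA_real_) {
  if (nrow(populations) > 0L && is.null(populations$ratio))
    populations$ratio <- populations$count / length(case$di)
  structure(list(case_id = case$case_id, analyzable = analyzable,
                 populations = populations, n_total = length(case$di),
                 peak_locations = peaks,
                 aneuploid_max_di = aneuploid_max,
                 assignment = assignment, bw = bw, label = case$label),
            class = "di_decomposition")
}

#' @export
print.di_decomposition <- function(x, ...) {
  cat(sprintf("Decomposition of %s: %d cells, %d peak(s)%s\n",
              x$case_id, x$n_total, length(x$peak_locations),
              if (x$analyzable) "" else " [UNANALYZABLE]"))
  if (nrow(x$populations) > 0L)
    print(x$populations, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tabulate decomposition results across cases
#'
#' @param decs list of [decompose()] results.
#' @return data frame with one row per detected population per case
#'   (case_id, kind, mean, sd, count, ratio), suitable for audit export.
#' @export
decomposition_table <- function(decs) {
  if (inherits(decs, "di_decomposition")) decs <- list(decs)
  do.call(rbind, lapply(decs, function(d) {
    if (nrow(d$populations) == 0L) return(NULL)
    cbind(case_id = d$case_id, d$populations,
          stringsAsFactors = FALSE)
  }))
}
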