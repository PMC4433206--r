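#' Gaussian-kernel density estimate of a case's DI distribution
#'
#' Estimates the per-case DI density on a fixed grid (step 0.01 DI over
#' `[0, max(8, max(di)) + 1]`) with a Gaussian kernel. When no bandwidth
#' is supplied it is chosen by the Sheather-Jones plug-in selector — the
#' standard data-driven approximation to the MISE-minimising bandwidth —
#' falling back to Silverman's rule-of-thumb when the plug-in fails to
#' converge. The estimate is renormalised so its trapezoidal integral
#' over the grid is 1.
#'
#' @param values numeric vector of DI values; at least 10 are required
#'   (smaller cases are handled by the windowed small-sample path of
#'   [decompose()]).
#' @param bandwidth optional bandwidth in DI units; bypasses selection.
#' @return an object of class `di_density`: list with `grid`, `density`,
#'   `bw`, `bw_method` and `n`.
#' @export
estimate_density <- function(values, bandwidth = NULL) {
  values <- as.numeric(values)
  if (length(values) < 10L)
    stop("density estimation needs at least 10 values (got ",
         length(values), ")", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("DI values must be finite and positive", call. = FALSE)

  if (is.null(bandwidth)) {
    if (stats::sd(values) < 1e-8) {
      warning("zero-variance input: applying bandwidth floor 1e-3")
      h <- 1e-3
      method <- "floor"
    } else {
      h <- tryCatch(stats::bw.SJ(values), error = function(e) NA_real_)
      method <- "sheather-jones"
      if (!is.finite(h)) {
        h <- stats::bw.nrd0(values)
        method <- "silverman"
      }
    }
  } else {
    stopifnot(is.numeric(bandwidth), length(bandwidth) == 1L,
              bandwidth > 0)
    h <- bandwidth
    method <- "fixed"
  }
  if (h < 1e-3) h <- 1e-3  # numerical floor, degenerate inputs

  upper <- max(8, max(values)) + 1
  n_grid <- round(upper / 0.01) + 1L
  kde <- stats::density(values, bw = h, kernel = "gaussian",
                        from = 0, to = upper, n = n_grid)
  dens <- pmax(kde$y, 0)
  area <- trapz(kde$x, dens)
  structure(list(grid = kde$x, density = dens / area, bw = h,
                 bw_method = method, n = length(values)),
            class = "di_density")
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' @export
print.di_density <- function(x, ...) {
  cat(sprintf("DI density: n = %d, bandwidth = %.4f (%s), grid [0, %g]\n",
              x$n, x$bw, x$bw_method, max(x$grid)))
  invisible(x)
}

#' Identify candidate population peaks in a DI density
#'
#' Locates the modes of the estimated density as sign changes of its
#' first derivative (the density is lightly smoothed with a 5-point
#' moving average before differencing, so shoulder-level wiggles do not
#' spawn spurious modes), keeps those whose topographic prominence is at
#' least `min_prominence` of the maximum height, and assigns each peak
#' the flanking density minima (or grid edges) as its bounds — the split
#' points between overlapping populations.
#'
#' @param dens a [estimate_density()] result.
#' @param min_prominence minimum peak prominence, as a fraction of the
#'   maximum density height (default 0.005).
#' @return data frame with one row per retained peak, ordered by
#'   location: `location`, `height`, `prominence`, `left_bound`,
#'   `right_bound`.
#' @export
find_peaks <- function(dens, min_prominence = 0.005) {
  stopifnot(inherits(dens, "di_density"),
            is.numeric(min_prominence), min_prominence >= 0)
  g <- dens$grid
  d <- dens$density
  n <- length(d)

  sm <- smooth5(d)
  d1 <- diff(sm)
  s <- sign(d1)
  s[s == 0] <- 1  # flat runs break toward the left neighbour's trend
  cross <- diff(s)
  max_idx <- which(cross < 0) + 1L  # downward zero-crossings: modes
  if (length(max_idx) == 0L) max_idx <- which.max(d)

  # refine each mode on the raw (unsmoothed) density
  max_idx <- vapply(max_idx, function(i) {
    w <- max(1L, i - 5L):min(n, i + 5L)
    w[which.max(d[w])]
  }, integer(1))
  max_idx <- sort(unique(max_idx))

  prom <- vapply(max_idx, function(i) peak_prominence(d, i), numeric(1))
  keep <- prom >= min_prominence * max(d)
  if (!any(keep)) keep[which.max(prom)] <- TRUE
  max_idx <- max_idx[keep]
  prom <- prom[keep]

  # bounds: the density minimum between adjacent retained peaks is the
  # split point; the extreme peaks extend to the grid edges
  k <- length(max_idx)
  lb <- rb <- numeric(k)
  for (j in seq_len(k)) {
    lb[j] <- if (j == 1L) g[1] else {
      between <- max_idx[j - 1L]:max_idx[j]
      g[between[which.min(d[between])]]
    }
    rb[j] <- if (j == k) g[n] else {
      between <- max_idx[j]:max_idx[j + 1L]
      g[between[which.min(d[between])]]
    }
  }

  data.frame(location = g[max_idx], height = d[max_idx],
             prominence = prom, left_bound = lb, right_bound = rb)
}

smooth5 <- function(x) {
  sm <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

## Topographic prominence of the mode at index i: height above the
## higher of the two key saddles on the paths to higher terrain (or to
## the grid edges when no higher mode exists on a side).
peak_prominence <- function(d, i) {
  h <- d[i]
  n <- length(d)
  left_base <- {
    j <- i; m <- h
    while (j > 1L && d[j] <= h) { j <- j - 1L; m <- min(m, d[j]) }
    m
  }
  right_base <- {
    j <- i; m <- h
    while (j < n && d[j] <= h) { j <- j + 1L; m <- min(m, d[j]) }
    m
  }
  h - max(left_base, right_base)
}
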