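#' Detect and fit Gaussian peaks in a fluorescence histogram
#'
#' Counts are smoothed with a centered moving average, local maxima above a
#' height threshold are located, and each peak is refined by local Gaussian
#' least squares on a window of about three standard deviations around the
#' detected maximum. Windows of neighbouring peaks are kept disjoint by
#' splitting at the midpoint between their centers.
#'
#' @param hist an [fcm_histogram()].
#' @param n_expected number of peaks expected, 1 or 2 (sample alone, or
#'   sample plus internal standard).
#' @param smoothing_window odd number of bins for the moving average
#'   (default 5).
#' @param min_height_frac minimum smoothed height of a candidate maximum,
#'   as a fraction of the tallest smoothed bin (default 0.1).
#' @param min_separation minimum distance in bins between two reported
#'   maxima; closer candidates are merged into the taller one (default
#'   `3 * smoothing_window`). Guards against counting noise ripples on a
#'   single peak as separate peaks.
#' @return A list of `n_expected` objects of class `fcm_peakfit`, sorted by
#'   ascending mean. Each holds `mean`, `sd`, `cv_percent` (100 sd/mean),
#'   `area` (particles attributed to the peak window) and `window`
#'   (bin index range used).
#' @seealso [measure_histogram()] which uses the two-peak fit to form the
#'   sample/standard fluorescence ratio.
#' @export
fit_peaks <- function(hist, n_expected = 2, smoothing_window = 5,
                      min_height_frac = 0.1,
                      min_separation = 3 * smoothing_window) {
  stopifnot(inherits(hist, "fcm_histogram"))
  gs_assert(n_expected %in% c(1L, 2L), "invalid-argument",
            "n_expected must be 1 or 2")
  gs_assert(min_height_frac > 0 && min_height_frac < 1, "invalid-argument",
            "min_height_frac must be in (0,1)")
  gs_assert(smoothing_window >= 1 && smoothing_window %% 2 == 1,
            "invalid-argument", "smoothing_window must be odd")
  x <- hist$bin_centers
  y <- hist$counts
  if (sum(y) < 1) gs_error("empty-histogram", "histogram contains no particles")

  s <- smooth_counts(y, smoothing_window)
  peaks_idx <- local_maxima(s, min_height_frac * max(s))
  peaks_idx <- merge_close_maxima(peaks_idx, s, min_separation)
  if (length(peaks_idx) < n_expected)
    gs_error("peaks-not-found",
             sprintf("found %d peak(s), expected %d", length(peaks_idx), n_expected))

  # keep the n_expected tallest candidates, then restore channel order
  keep <- peaks_idx[order(s[peaks_idx], decreasing = TRUE)][seq_len(n_expected)]
  keep <- sort(keep)

  # disjoint windows: split halfway between adjacent peak centers
  lo_bound <- c(1L, if (n_expected > 1) floor((keep[-1] + keep[-n_expected]) / 2) + 1L)
  hi_bound <- c(if (n_expected > 1) floor((keep[-1] + keep[-n_expected]) / 2), length(y))

  fits <- vector("list", n_expected)
  for (k in seq_len(n_expected)) {
    i <- keep[k]
    sd0 <- half_max_sd(x, s, i)
    binw <- mean(diff(x))
    halfwin <- max(2L, ceiling(3 * sd0 / binw))
    win <- max(lo_bound[k], i - halfwin):min(hi_bound[k], i + halfwin)
    fits[[k]] <- fit_gaussian_window(x[win], y[win], mu0 = x[i], sd0 = sd0,
                                     window = range(win))
  }
  fits[order(vapply(fits, `[[`, 0, "mean"))]
}

smooth_counts <- function(y, w) {
  if (w == 1) return(y)
  s <- stats::filter(y, rep(1 / w, w), sides = 2)
  s[is.na(s)] <- y[is.na(s)]  # edges: fall back to raw counts
  as.numeric(s)
}

local_maxima <- function(s, min_height) {
  n <- length(s)
  if (n < 3) return(integer(0))
  idx <- which(s[2:(n - 1)] >= s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
  idx[s[idx] >= min_height]
}

# greedily keep the tallest candidate, drop any other within min_separation
merge_close_maxima <- function(idx, s, min_separation) {
  if (length(idx) < 2) return(idx)
  ord <- idx[order(s[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || all(abs(kept - i) >= min_separation))
      kept <- c(kept, i)
  sort(kept)
}

# initial sd guess from the half-width at half maximum of the smoothed curve
half_max_sd <- function(x, s, i) {
  half <- s[i] / 2
  r <- i
  while (r < length(s) && s[r] > half) r <- r + 1L
  l <- i
  while (l > 1 && s[l] > half) l <- l - 1L
  hwhm <- max(abs(x[r] - x[i]), abs(x[i] - x[l]), mean(diff(x)))
  hwhm / sqrt(2 * log(2))
}

fit_gaussian_window <- function(xw, yw, mu0, sd0, window) {
  fit <- tryCatch(
    nls(yw ~ A * exp(-(xw - m)^2 / (2 * s2^2)),
        start = list(A = max(yw), m = mu0, s2 = sd0),
        control = list(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit) && all(is.finite(coef(fit))) && coef(fit)[["s2"]] != 0) {
    cf <- coef(fit)
    m <- cf[["m"]]; sdv <- abs(cf[["s2"]])
  } else {
    # moment fallback on the window (robust when nls fails to converge)
    w <- yw / sum(yw)
    m <- sum(w * xw)
    sdv <- sqrt(sum(w * (xw - m)^2))
  }
  structure(list(mean = m, sd = sdv, cv_percent = 100 * sdv / m,
                 area = sum(yw), window = window),
            class = "fcm_peakfit")
}

#' @export
print.fcm_peakfit <- function(x, ...) {
  cat(sprintf("fcm_peakfit: mean %.2f, sd %.2f (CV %.2f%%), area %.0f\n",
              x$mean, x$sd, x$cv_percent, x$area))
  invisible(x)
}
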