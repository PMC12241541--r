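# Temporal dynamics: cross-correlation delay detection and the
# kernel-density energy landscape of time-resolved BOLD amplitude.

#' Lag-resolved cross-correlation of two FIR time courses
#'
#' Pearson correlation of the overlapping segments of `x` and `y` at every
#' integer lag in `-max_lag..max_lag`, each lag normalized by its own
#' overlap (no zero padding). A positive lag means `y` trails `x`: the peak
#' of `cross_correlate(x, shift(x, s))` is at `+s`. Lags whose overlap has
#' zero variance in either series are returned as NA (flagged undefined).
#'
#' @param x,y Equal-length numeric series (e.g. 15-point FIR betas).
#' @param max_lag Maximum lag in frames; overlaps keep at least 2 points.
#' @return Object of class `ccf_lags`: data.frame `lag`, `r`, `n_overlap`.
#' @export
cross_correlate <- function(x, y, max_lag = 7L) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length")
  if (n < max_lag + 2L) stop("series too short for max_lag")
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(l) {
    if (l >= 0) { xs <- x[seq_len(n - l)]; ys <- y[seq_len(n - l) + l] }
    else        { xs <- x[seq_len(n + l) - l]; ys <- y[seq_len(n + l)] }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  structure(data.frame(lag = lags, r = r, n_overlap = n - abs(lags)),
            class = c("ccf_lags", "data.frame"))
}

#' Detect a temporal delay from a cross-correlogram
#'
#' The peak lag is the argmax of the correlation over valid lags; ties are
#' broken toward the smallest absolute lag, then toward the positive sign.
#' A region is flagged delayed when its peak lag is at least
#' `threshold_lag` frames with positive peak correlation.
#'
#' @param ccf A `ccf_lags` object from [cross_correlate()].
#' @param threshold_lag Minimum peak lag (frames) to count as delayed.
#' @param tr Repetition time, seconds (converts lag frames to seconds).
#' @return List with `peak_lag` (seconds), `peak_r`, `delayed`.
#' @export
detect_delay <- function(ccf, threshold_lag = 1L, tr = 1) {
  valid <- !is.na(ccf$r)
  if (!any(valid)) stop("all lags undefined")
  best <- max(ccf$r[valid])
  cand <- ccf$lag[valid & ccf$r == best]
  cand <- cand[order(abs(cand), -sign(cand))]
  peak <- cand[1L]
  list(peak_lag = peak * tr, peak_r = best,
       delayed = peak >= threshold_lag && best > 0)
}

#' Per-region delay detection between two conditions
#'
#' Runs [cross_correlate()] + [detect_delay()] on the participant-mean FIR
#' time courses of two conditions for a region set.
#'
#' @param betas An `fir_study` array.
#' @param cond_x,cond_y Condition names; positive peak lag means `cond_y`
#'   trails `cond_x`.
#' @param regions Region labels or indices.
#' @param max_lag,threshold_lag,tr Passed to the per-region calls.
#' @return A `delay_result` data.frame: `region`, `peak_lag` (s), `peak_r`,
#'   `delayed`.
#' @export
condition_delays <- function(betas, cond_x = "hard_correct",
                             cond_y = "hard_incorrect", regions,
                             max_lag = 7L, threshold_lag = 1L, tr = 1) {
  dn <- dimnames(betas)
  if (is.numeric(regions)) regions <- dn$region[regions]
  mean_tc <- function(cond, rg)
    colMeans(matrix(betas[, cond, rg, ], ncol = dim(betas)[4L]), na.rm = TRUE)
  rows <- lapply(regions, function(rg) {
    d <- detect_delay(cross_correlate(mean_tc(cond_x, rg), mean_tc(cond_y, rg),
                                      max_lag),
                      threshold_lag, tr)
    data.frame(region = rg, peak_lag = d$peak_lag, peak_r = d$peak_r,
               delayed = d$delayed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("delay_result", "data.frame")
  out
}

#' Kernel-density energy landscape of BOLD amplitude
#'
#' For each timepoint, estimates the probability density of the pooled
#' `|beta|` samples on a grid over `[0, grid_max]` with a Gaussian kernel of
#' bandwidth `h`, `P(x) = 1/(h n) * sum_i K((x - x_i)/h)`, and converts it
#' to energy `E = -ln P`. Grid cells with `P = 0` carry infinite energy
#' (`Inf` sentinel).
#'
#' @param samples Matrix of samples x timepoints of (absolute) BOLD betas,
#'   or an `fir_study` array together with `condition` and `regions`.
#' @param condition,regions When `samples` is an `fir_study` array: the
#'   condition and region set whose `|beta|` values are pooled across
#'   participants and regions per timepoint.
#' @param grid_max,grid_step Evaluation grid `seq(0, grid_max, grid_step)`.
#' @param h Kernel bandwidth (same units as the betas).
#' @return Object of class `energy_landscape`: `grid`, `P` (grid x
#'   timepoints), `E`, `h`, `n` (samples per timepoint).
#' @export
energy_landscape <- function(samples, condition = NULL, regions = NULL,
                             grid_max = 1.8, grid_step = 0.01, h = 0.1) {
  if (h <= 0) stop("bandwidth h must be positive")
  if (grid_max < 0 || grid_step <= 0) stop("invalid grid specification")
  if (is.array(samples) && length(dim(samples)) == 4L) {
    stopifnot(!is.null(condition), !is.null(regions))
    dn <- dimnames(samples)
    if (is.numeric(regions)) regions <- dn$region[regions]
    tdim <- dim(samples)[4L]
    samples <- abs(matrix(samples[, condition, regions, ], ncol = tdim))
  }
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("need at least 2 samples per timepoint")
  grid <- seq(0, grid_max, by = grid_step)
  P <- apply(samples, 2L, function(xs) {
    xs <- xs[!is.na(xs)]
    if (length(xs) < 2L) stop("empty sample at a timepoint")
    rowMeans(stats::dnorm(outer(grid, xs, "-") / h)) / h
  })
  E <- -log(P)                   # P = 0 -> Inf sentinel
  structure(list(grid = grid, P = P, E = E, h = h,
                 n = colSums(!is.na(samples))),
            class = "energy_landscape")
}
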