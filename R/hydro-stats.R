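# Distributional statistics of PARCH values: Gaussian KDE, mode finding
# with a prominence criterion, two-group rank-sum comparisons with the
# violin-plot significance-star convention, and five-number summaries.

#' Kernel density estimate of a PARCH-value sample
#'
#' Gaussian-kernel estimate (via [stats::density()]) on a regular grid
#' covering [min - 4h, max + 4h] with step at most h/5, where h is the
#' bandwidth. Default bandwidth is Silverman's rule-of-thumb
#' ([stats::bw.nrd0()]); a fixed numeric bandwidth gives bit-reproducible
#' grids for archival runs.
#'
#' @param values numeric sample, length >= 2.
#' @param bandwidth "silverman" or a positive number.
#' @return a [DensityEstimate-class].
#' @export
parchKDE <- function(values, bandwidth = "silverman") {
  if (length(values) < 2L) stop("need at least 2 values")
  h <- if (is.numeric(bandwidth)) {
    if (bandwidth <= 0) stop("bandwidth must be > 0")
    bandwidth
  } else {
    if (stats::var(values) == 0)
      stop("zero-variance sample: rule-based bandwidth undefined; ",
           "supply a fixed bandwidth")
    stats::bw.nrd0(values)
  }
  lo <- min(values) - 4 * h
  hi <- max(values) + 4 * h
  n <- max(512L, ceiling((hi - lo) / (h / 5)) + 1L)
  d <- stats::density(values, bw = h, from = lo, to = hi, n = n,
                      kernel = "gaussian")
  new("DensityEstimate", grid = d$x, density = d$y, bandwidth = h,
      n = length(values))
}

setMethod("show", "DensityEstimate", function(object) {
  cat(sprintf("DensityEstimate: %d grid points, bandwidth %.4g, n = %d\n",
              length(object@grid), object@bandwidth, object@n))
})

#' Density estimate as a data frame
#'
#' @param x a [DensityEstimate-class].
#' @param ... ignored.
#' @return data.frame with columns `grid` and `density`.
#' @export
setMethod("as.data.frame", "DensityEstimate", function(x, ...) {
  data.frame(grid = x@grid, density = x@density)
})

#' Modes of a density estimate
#'
#' Local maxima of the density whose topographic prominence is at least
#' `minProminence` times the global maximum, in ascending location order.
#' Prominence of a peak is its height minus the higher of the lowest
#' valleys separating it from a higher peak (or from the grid edge).
#'
#' @param d a [DensityEstimate-class].
#' @param minProminence fraction of the maximum density (default 0.05).
#' @return numeric vector of mode locations (possibly empty).
#' @export
findModes <- function(d, minProminence = 0.05) {
  y <- d@density
  x <- d@grid
  n <- length(y)
  if (n < 3L) return(x[which.max(y)])
  # local maxima; plateaus collapse to their first point
  up <- c(TRUE, diff(y) > 0)
  dnOrFlat <- c(diff(y) <= 0, TRUE)
  peaks <- which(up & dnOrFlat & y > 0)
  if (!length(peaks)) return(numeric(0))
  thr <- minProminence * max(y)
  keySaddle <- function(p, idx) {
    # lowest density between the peak and the nearest strictly higher
    # point on one side; NA when no higher point exists on that side
    # (the grid edge does not limit prominence)
    h <- y[p]
    firstHigher <- which(y[idx] > h)
    if (!length(firstHigher)) return(NA_real_)
    span <- idx[seq_len(firstHigher[1] - 1L)]
    if (length(span)) min(y[span]) else h
  }
  keep <- vapply(peaks, function(p) {
    left <- keySaddle(p, rev(seq_len(p - 1L)))
    right <- keySaddle(p, if (p < n) (p + 1L):n else integer(0))
    saddle <- suppressWarnings(max(c(left, right), na.rm = TRUE))
    prom <- if (is.finite(saddle)) y[p] - saddle else y[p]
    prom >= thr
  }, logical(1))
  sort(x[peaks[keep]])
}

#' Two-group rank-sum comparison
#'
#' Two-sided Mann-Whitney U test via [stats::wilcox.test()]: exact
#' enumeration when both samples have at most 20 observations and no ties,
#' normal approximation with tie correction and continuity correction
#' otherwise. Stars follow the violin-annotation convention: `****`
#' p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, else `ns`.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return a [GroupComparison-class]; `uStatistic` is the U count for the
#'   first sample.
#' @export
compareGroups <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 values")
  useExact <- length(x) <= 20L && length(y) <= 20L &&
    !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = useExact, correct = TRUE)
  p <- wt$p.value
  stars <- if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 1e-2) "**" else if (p < 0.05) "*" else "ns"
  new("GroupComparison", uStatistic = unname(wt$statistic), pValue = p,
      stars = stars, n1 = length(x), n2 = length(y),
      medianShift = stats::median(x) - stats::median(y))
}

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison: U = %g, p = %.3g (%s), n = %d/%d, median shift %.3g\n",
              object@uStatistic, object@pValue, object@stars,
              object@n1, object@n2, object@medianShift))
})

#' Five-number summary for violin annotations
#'
#' Minimum, quartiles, median, maximum and n. Quartiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7),
#' so summaries are bit-reproducible.
#'
#' @param values non-empty numeric sample.
#' @return named numeric vector (min, q1, median, q3, max, n).
#' @export
violinSummary <- function(values) {
  if (!length(values)) stop("empty sample")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
    n = length(values))
}
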