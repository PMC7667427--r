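# Tumor-discrimination metrics: contrast-to-variability ratio and
# rank-based AUROC, per-frame metric series from image stacks, and the
# time-of-maximum-contrast window.

.cvrNumeric <- function(tumor, background) {
  if (length(tumor) < 2L || length(background) < 2L)
    stop("CVR needs at least 2 samples per region", call. = FALSE)
  if (any(!is.finite(tumor)) || any(!is.finite(background)))
    stop("sample values must be finite", call. = FALSE)
  pooled <- stats::var(tumor) + stats::var(background)
  if (pooled <= 0)
    stop("CVR undefined: zero pooled variance", call. = FALSE)
  abs(mean(tumor) - mean(background)) / sqrt(pooled)
}

#' @describeIn cvr tumor and background passed as two numeric vectors.
#' @param background background pixel values (numeric method).
#' @export
setMethod("cvr", "numeric", function(x, background, ...) {
  .cvrNumeric(x, background)
})

#' @describeIn cvr computed from a [RegionSamples-class].
#' @export
setMethod("cvr", "RegionSamples", function(x, ...) {
  .cvrNumeric(x@tumor, x@background)
})

.aurocNumeric <- function(tumor, background) {
  if (!length(tumor) || !length(background))
    stop("AUROC needs nonempty regions", call. = FALSE)
  if (any(!is.finite(tumor)) || any(!is.finite(background)))
    stop("sample values must be finite", call. = FALSE)
  r <- rank(c(tumor, background))
  nT <- length(tumor); nB <- length(background)
  u <- sum(r[seq_len(nT)]) - nT * (nT + 1) / 2
  u / (nT * nB)
}

#' @describeIn auroc tumor and background passed as two numeric vectors.
#' @param background background pixel values (numeric method).
#' @export
setMethod("auroc", "numeric", function(x, background, ...) {
  .aurocNumeric(x, background)
})

#' @describeIn auroc computed from a [RegionSamples-class].
#' @export
setMethod("auroc", "RegionSamples", function(x, ...) {
  .aurocNumeric(x@tumor, x@background)
})

#' Per-frame discrimination metrics from image stacks
#'
#' Computes CVR and AUROC per frame from tumor and background pixel
#' populations. The single-agent (`"SA"`) protocol uses the
#' targeted-channel pixel values directly; the paired-agent (`"PA"`)
#' protocol uses pixelwise BPratio values, `(T - C)/C`, and therefore
#' requires the control stack. Pixels whose control value is nonpositive at
#' a frame are excluded from that frame's PA populations.
#'
#' @param stackT targeted-channel stack, array `c(rows, cols, frames)`.
#' @param stackC control-channel stack (same shape), or `NULL` for SA.
#' @param tumorMask,bgMask disjoint, nonempty logical masks `c(rows, cols)`.
#' @param frameTimes frame times (min).
#' @param protocol `"SA"` or `"PA"`.
#' @return A [MetricTimeSeries-class]. Frames whose metric is undefined
#'   (fewer than 2 usable pixels in a region, or zero pooled variance)
#'   carry `NA`.
#' @export
metricTimeSeries <- function(stackT, stackC = NULL, tumorMask, bgMask,
                             frameTimes, protocol = c("SA", "PA")) {
  protocol <- match.arg(protocol)
  if (length(dim(stackT)) != 3L)
    stop("'stackT' must be a rows x cols x frames array", call. = FALSE)
  d <- dim(stackT)
  if (!identical(dim(tumorMask), d[1:2]) || !identical(dim(bgMask), d[1:2]))
    stop("masks must match the image dimensions", call. = FALSE)
  if (any(tumorMask & bgMask))
    stop("tumor and background masks overlap", call. = FALSE)
  if (!any(tumorMask) || !any(bgMask))
    stop("masks must be nonempty", call. = FALSE)
  if (length(frameTimes) != d[3])
    stop("'frameTimes' must match the number of frames", call. = FALSE)
  if (protocol == "PA") {
    if (is.null(stackC))
      stop("PA protocol requires the control stack", call. = FALSE)
    if (!identical(dim(stackC), d))
      stop("stacks must be co-registered on the same grid", call. = FALSE)
  }
  nF <- d[3]
  cvrs <- rep(NA_real_, nF); aucs <- rep(NA_real_, nF)
  for (f in seq_len(nF)) {
    frT <- stackT[, , f]
    if (protocol == "SA") {
      tu <- frT[tumorMask]; bg <- frT[bgMask]
    } else {
      frC <- stackC[, , f]
      ratio <- matrix(NA_real_, d[1], d[2])
      ok <- frC > 0
      ratio[ok] <- (frT[ok] - frC[ok]) / frC[ok]
      tu <- ratio[tumorMask]; bg <- ratio[bgMask]
      tu <- tu[is.finite(tu)]; bg <- bg[is.finite(bg)]
    }
    if (length(tu) >= 2L && length(bg) >= 2L) {
      pooled <- stats::var(tu) + stats::var(bg)
      if (is.finite(pooled) && pooled > 0)
        cvrs[f] <- abs(mean(tu) - mean(bg)) / sqrt(pooled)
      aucs[f] <- .aurocNumeric(tu, bg)
    }
  }
  new("MetricTimeSeries", time = as.numeric(frameTimes), cvr = cvrs,
      auroc = aucs, protocol = protocol)
}

# Core peak/window finder on a plain (time, value) series.
.findTmaxCore <- function(time, value, smooth = 0L) {
  keep <- is.finite(value)
  if (!any(keep)) stop("all metric values are undefined", call. = FALSE)
  t <- time[keep]; v <- value[keep]
  if (smooth > 1L) v <- .movingAverage(v, as.integer(smooth))
  i <- which.max(v)           # first index on exact ties
  vmax <- v[i]
  thr <- 0.98 * vmax
  n <- length(v)
  jl <- i
  while (jl > 1L && v[jl - 1L] >= thr) jl <- jl - 1L
  tStart <- if (jl == 1L) t[1] else
    t[jl - 1L] + (thr - v[jl - 1L]) / (v[jl] - v[jl - 1L]) * (t[jl] - t[jl - 1L])
  jr <- i
  while (jr < n && v[jr + 1L] >= thr) jr <- jr + 1L
  tEnd <- if (jr == n) t[n] else
    t[jr] + (v[jr] - thr) / (v[jr] - v[jr + 1L]) * (t[jr + 1L] - t[jr])
  new("ContrastWindow", tMax = t[i], cvrMax = vmax, tStart98 = tStart,
      tEnd98 = tEnd, atBoundary = (i == 1L && v[1] > v[min(2L, n)]) || i == n)
}

#' @describeIn findTmax peak of the CVR curve of a metric series.
#' @param smooth odd moving-average window (default 0, no smoothing).
#' @export
setMethod("findTmax", "MetricTimeSeries", function(x, smooth = 0L, ...) {
  .findTmaxCore(x@time, x@cvr, smooth)
})

#' @describeIn findTmax peak of a plain numeric metric curve; requires
#'   `time`.
#' @param time time grid for the numeric method (min).
#' @export
setMethod("findTmax", "numeric", function(x, time, smooth = 0L, ...) {
  if (length(time) != length(x))
    stop("'time' must match the series length", call. = FALSE)
  .findTmaxCore(time, x, smooth)
})
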