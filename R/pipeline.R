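# The dual-channel experiment analysis chain: pre-injection subtraction,
# early-time-point pixel-by-pixel normalization, plasma-kinetics
# correction, ROI metrics and BPratio maps, plus the plasma and Kety model
# fits.

#' Construct an analysis configuration
#'
#' @param earlyTime normalization time (min); `NULL` (default) selects the
#'   first post-injection frame at `>= 1` min.
#' @param smoothWindow odd moving-average window for peak location on noisy
#'   metric curves (default 0, off).
#' @param clampNegative clamp negative pixels to zero after pre-injection
#'   subtraction (count data; default `TRUE`).
#' @param bpFrames frames over which the BPratio map is averaged; `"last"`
#'   (default) uses the final frame.
#' @param bpMode ROI BPratio averaging: `"pixelwise"` (mean of pixel
#'   ratios, default) or `"roi-ratio"` (ratio of ROI means).
#' @param fitBounds lower/upper bounds for the Kety fit (1/min).
#' @return An object of class `AnalysisConfig` (a validated list).
#' @export
analysisConfig <- function(earlyTime = NULL, smoothWindow = 0L,
                           clampNegative = TRUE, bpFrames = "last",
                           bpMode = c("pixelwise", "roi-ratio"),
                           fitBounds = c(1e-6, 10)) {
  bpMode <- match.arg(bpMode)
  if (!is.null(earlyTime)) .assertScalarNonneg(earlyTime, "earlyTime")
  if (fitBounds[1] <= 0 || fitBounds[2] <= fitBounds[1])
    stop("'fitBounds' must be positive and increasing", call. = FALSE)
  structure(list(earlyTime = earlyTime, smoothWindow = as.integer(smoothWindow),
                 clampNegative = clampNegative, bpFrames = bpFrames,
                 bpMode = bpMode, fitBounds = fitBounds),
            class = "AnalysisConfig")
}

#' Subtract the pre-injection frame from an image stack
#'
#' Removes autofluorescence by subtracting the pre-injection frame from
#' every post-injection frame. Negative results are clamped to zero by
#' default (counts); pass `clamp = FALSE` for a diagnostic float mode.
#'
#' @param stack array `c(rows, cols, frames)`.
#' @param pre pre-injection frame, matrix `c(rows, cols)`.
#' @param clamp clamp negatives to zero (default `TRUE`).
#' @return Corrected stack, same shape.
#' @export
subtractPreinjection <- function(stack, pre, clamp = TRUE) {
  d <- dim(stack)
  if (length(d) != 3L || !identical(dim(pre), d[1:2]))
    stop("'pre' must match the stack's image dimensions", call. = FALSE)
  out <- sweep(stack, 1:2, pre, "-")
  if (clamp) out[out < 0] <- 0
  out
}

#' Early-time-point pixel-by-pixel channel normalization
#'
#' Rescales the control channel pixelwise so that the two channels agree
#' exactly at an early post-injection frame, correcting for per-pixel
#' differences in signal intensity between the two fluorophores (detection
#' efficiency, dose). The scale map is `targeted/control` at the early
#' frame; pixels with nonpositive control signal there are masked out.
#'
#' @param stackT,stackC background-subtracted stacks `c(rows, cols,
#'   frames)`.
#' @param frameTimes frame times (min).
#' @param earlyTime normalization time (min); default: first frame at
#'   `>= 1` min.
#' @return A list with `control` (normalized control stack), `scaleMap`,
#'   `excluded` (logical matrix of masked pixels) and `earlyIndex`.
#' @export
earlyNormalize <- function(stackT, stackC, frameTimes, earlyTime = NULL) {
  d <- dim(stackT)
  if (!identical(dim(stackC), d))
    stop("stacks must have identical dimensions", call. = FALSE)
  if (length(frameTimes) != d[3])
    stop("'frameTimes' must match the number of frames", call. = FALSE)
  if (is.null(earlyTime)) {
    idx <- which(frameTimes >= 1)[1]
    if (is.na(idx)) idx <- length(frameTimes)
  } else {
    if (earlyTime > max(frameTimes))
      stop("'earlyTime' lies outside the acquisition", call. = FALSE)
    idx <- which.min(abs(frameTimes - earlyTime))
  }
  eT <- stackT[, , idx]; eC <- stackC[, , idx]
  excluded <- !(eC > 0)
  scaleMap <- matrix(NA_real_, d[1], d[2])
  scaleMap[!excluded] <- eT[!excluded] / eC[!excluded]
  norm <- stackC * array(scaleMap, dim = d)
  list(control = norm, scaleMap = scaleMap, excluded = excluded,
       earlyIndex = idx)
}

#' Correct a control-agent curve for plasma-kinetics differences
#'
#' Model-based equivalent of deconvolution correction: the measured control
#' tissue curve is the convolution of the control plasma input with the
#' tissue impulse response. The impulse response is recovered by causal
#' deconvolution against `plasmaC` (midpoint-quadrature lower-triangular
#' system, exactly invertible for noise-free curves) and re-convolved with
#' `plasmaT`, i.e. the curve is re-expressed as if the control agent had
#' shared the targeted agent's plasma kinetics. Identity when the two
#' plasma inputs coincide.
#'
#' For noisy curves the inversion is Tikhonov-regularized
#' (`(L'L + lambda I) h = L'y`). When `noiseSd > 0` the weight is chosen
#' by the discrepancy principle: the smallest `lambda` on a log grid whose
#' residual norm reaches `sqrt(n) * noiseSd`; otherwise `lambda =
#' lambdaRel * ||L||^2` (default 0: exact triangular solve).
#'
#' @param x measured control tissue curve on a uniform time grid (numeric
#'   vector), or a matrix with one curve per row.
#' @param time uniform time grid (min).
#' @param plasmaT,plasmaC [PlasmaInput-class] objects for the targeted and
#'   control agents.
#' @param lambdaRel relative Tikhonov weight (default 0: unregularized,
#'   suited to noise-free curves).
#' @param noiseSd optional noise SD for the discrepancy principle.
#' @return Corrected curve(s), same shape as `x`, with attribute
#'   `"lambda"` (the weight used) and `"condition"` (an estimate of the
#'   condition number of the convolution operator).
#' @export
plasmaCorrect <- function(x, time, plasmaT, plasmaC, lambdaRel = 0,
                          noiseSd = 0) {
  stopifnot(is(plasmaT, "PlasmaInput"), is(plasmaC, "PlasmaInput"))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else x
  n <- ncol(xm)
  if (length(time) != n)
    stop("'time' must match the curve length", call. = FALSE)
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-8 * dt[1]))
    stop("plasma correction requires a uniform time grid", call. = FALSE)
  dt <- dt[1]
  if (all(xm == 0)) {
    out <- xm
    attr(out, "lambda") <- 0; attr(out, "condition") <- 1
    return(if (vec) drop(out) else out)
  }
  # midpoint quadrature: y[i] = dt * sum_{m < i} cp(t_i - t_{m+1/2}) h[m];
  # the impulse response is estimated at the n-1 midpoints.
  mids <- (time[-n] + time[-1]) / 2
  convOp <- function(p) {
    M <- outer(time[-1], mids, "-")
    L <- matrix(0, n - 1L, n - 1L)
    keep <- M > 0
    L[keep] <- plasmaConcentration(p, M[keep]) * dt
    L
  }
  L <- convOp(plasmaC)
  LT <- convOp(plasmaT)
  y <- xm[, -1, drop = FALSE]
  condition <- kappa(L, exact = FALSE)
  if (noiseSd > 0) {
    G <- crossprod(L)
    nrm <- max(diag(G))
    grid <- nrm * 10^seq(-12, 0, length.out = 25)
    target <- sqrt(n - 1) * noiseSd
    pick <- NA_real_
    for (lam in grid) {
      h <- solve(G + diag(lam, n - 1L), crossprod(L, t(y)))
      if (sqrt(mean(colSums((L %*% h - t(y))^2))) >= target) { pick <- lam; break }
    }
    lambda <- if (is.na(pick)) grid[length(grid)] else pick
    h <- solve(crossprod(L) + diag(lambda, n - 1L), crossprod(L, t(y)))
  } else if (lambdaRel > 0) {
    lambda <- lambdaRel * max(diag(crossprod(L)))
    h <- solve(crossprod(L) + diag(lambda, n - 1L), crossprod(L, t(y)))
  } else {
    lambda <- 0
    h <- forwardsolve(L, t(y))
  }
  out <- cbind(xm[, 1, drop = FALSE] * 0, t(LT %*% h))
  attr(out, "lambda") <- lambda
  attr(out, "condition") <- condition
  if (vec) {
    o <- drop(out)
    attributes(o) <- attributes(out)[c("lambda", "condition")]
    o
  } else out
}

#' Fit a biexponential plasma model to a blood curve
#'
#' Nonlinear least squares for `A exp(-alpha t) + B exp(-beta t)` with
#' multi-start initialization; the identifiability convention
#' `alpha > beta` is enforced by post-sorting.
#'
#' @param time times (min), at least 8 points.
#' @param y measured blood concentrations, positive.
#' @return A [FitResult-class] with estimates `A`, `alpha`, `B`, `beta`.
#' @export
fitBiexponential <- function(time, y) {
  if (length(time) < 8L) stop("need at least 8 time points", call. = FALSE)
  if (any(y <= 0)) stop("blood curve must be positive", call. = FALSE)
  span <- max(time) - min(time)
  rate0 <- max(log(max(y) / max(min(y), 1e-12)), 0.1) / max(span, 1e-6)
  y0 <- y[which.min(time)]
  starts <- list(
    c(A = y0 / 2, alpha = 4 * rate0, B = y0 / 2, beta = rate0 / 4),
    c(A = y0 * 0.8, alpha = 10 * rate0, B = y0 * 0.2, beta = rate0),
    c(A = y0 * 0.2, alpha = rate0, B = y0 * 0.8, beta = rate0 / 10))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-alpha * time) + B * exp(-beta * time),
                        start = as.list(s),
                        lower = c(0, 1e-9, 0, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(new("FitResult", estimates = c(A = NA_real_, alpha = NA_real_,
                                          B = NA_real_, beta = NA_real_),
               residualNorm = NA_real_, converged = FALSE,
               message = "all starts failed"))
  est <- stats::coef(best$fit)
  if (est[["alpha"]] < est[["beta"]])
    est <- c(A = est[["B"]], alpha = est[["beta"]],
             B = est[["A"]], beta = est[["alpha"]])
  new("FitResult", estimates = est[c("A", "alpha", "B", "beta")],
      residualNorm = best$rss, converged = TRUE, message = "ok")
}

#' Fit the Kety model to a control-agent tissue curve
#'
#' Least squares over `(K1, k2)` with [ketyClosedForm()] as the forward
#' model, bounded to `fitBounds` and multi-started (3 starts) to avoid
#' local minima.
#'
#' @param time times (min).
#' @param y measured tissue curve (same length).
#' @param plasma the known [PlasmaInput-class].
#' @param bounds lower/upper bounds on both rates (default `c(1e-6, 10)`).
#' @return A [FitResult-class] with estimates `K1`, `k2`.
#' @export
fitKety <- function(time, y, plasma, bounds = c(1e-6, 10)) {
  if (length(y) != length(time)) stop("lengths differ", call. = FALSE)
  if (all(y <= 0)) {
    # no uptake: K1 pinned at the lower bound, zero residual
    return(new("FitResult", estimates = c(K1 = bounds[1], k2 = bounds[1]),
               residualNorm = 0, converged = TRUE, message = "zero curve"))
  }
  starts <- list(c(K1 = 0.01, k2 = 0.01), c(K1 = 0.1, k2 = 0.05),
                 c(K1 = 1, k2 = 0.5))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ ketyClosedForm(K1, k2, plasma, time),
                        start = as.list(s),
                        lower = rep(bounds[1], 2), upper = rep(bounds[2], 2),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(new("FitResult", estimates = c(K1 = NA_real_, k2 = NA_real_),
               residualNorm = NA_real_, converged = FALSE,
               message = "all starts failed"))
  new("FitResult", estimates = stats::coef(best$fit)[c("K1", "k2")],
      residualNorm = best$rss, converged = TRUE, message = "ok")
}

#' Run the full dual-channel analysis chain
#'
#' Applies, in order: pre-injection subtraction (both channels), early
#' time-point normalization of the control channel, optional
#' plasma-kinetics correction of the control channel, and per-frame
#' discrimination metrics for the single-agent (targeted channel) and
#' paired-agent (pixelwise BPratio) protocols. Also returns a BPratio map
#' (averaged over `config$bpFrames`), ROI-averaged BPratio per region, and,
#' when a plasma model is supplied, a Kety fit to the ROI-mean control
#' curve.
#'
#' @param scene a [RenderedScene-class]; or supply raw arrays via
#'   `stackT`/`stackC`/`preT`/`preC`/`frameTimes`/`tumorMask`/`bgMask`.
#' @param stackT,stackC,preT,preC,frameTimes,tumorMask,bgMask raw inputs,
#'   ignored when `scene` is given.
#' @param plasmaT,plasmaC plasma models of the two agents; the correction
#'   step runs only when both are given and differ.
#' @param plasma plasma model for the Kety fit (defaults to `plasmaT`).
#' @param config an [analysisConfig()].
#' @return A list with elements `sa`, `pa` ([MetricTimeSeries-class]),
#'   `bpMap`, `bpTumor`, `bpBackground`, `ketyFit` (or `NULL`), `scaleMap`
#'   and `excluded`.
#' @export
analyzeExperiment <- function(scene = NULL, stackT = NULL, stackC = NULL,
                              preT = NULL, preC = NULL, frameTimes = NULL,
                              tumorMask = NULL, bgMask = NULL,
                              plasmaT = NULL, plasmaC = NULL, plasma = NULL,
                              config = analysisConfig()) {
  if (!is.null(scene)) {
    stopifnot(is(scene, "RenderedScene"))
    stackT <- scene@targeted; stackC <- scene@control
    preT <- scene@preT; preC <- scene@preC
    frameTimes <- scene@frameTimes
    tumorMask <- scene@tumorMask; bgMask <- scene@bgMask
  }
  if (is.null(stackT) || is.null(stackC))
    stop("both channel stacks are required", call. = FALSE)
  if (is.null(preT)) preT <- array(0, dim(stackT)[1:2])
  if (is.null(preC)) preC <- array(0, dim(stackC)[1:2])

  stackT <- subtractPreinjection(stackT, preT, clamp = config$clampNegative)
  stackC <- subtractPreinjection(stackC, preC, clamp = config$clampNegative)
  norm <- earlyNormalize(stackT, stackC, frameTimes,
                         earlyTime = config$earlyTime)
  stackC <- norm$control
  analyzable <- !norm$excluded
  if (!is.null(plasmaT) && !is.null(plasmaC) &&
      !isTRUE(all.equal(c(plasmaT@A, plasmaT@alpha, plasmaT@B, plasmaT@beta,
                          plasmaT@scale),
                        c(plasmaC@A, plasmaC@alpha, plasmaC@B, plasmaC@beta,
                          plasmaC@scale)))) {
    d <- dim(stackC)
    flat <- matrix(stackC, d[1] * d[2], d[3])
    keep <- which(as.vector(analyzable))
    flat[keep, ] <- plasmaCorrect(flat[keep, , drop = FALSE], frameTimes,
                                  plasmaT, plasmaC)
    stackC <- array(flat, d)
  }
  tumorOK <- tumorMask & analyzable
  bgOK <- bgMask & analyzable
  sa <- metricTimeSeries(stackT, NULL, tumorOK, bgOK, frameTimes, "SA")
  pa <- metricTimeSeries(stackT, stackC, tumorOK, bgOK, frameTimes, "PA")

  frames <- if (identical(config$bpFrames, "last")) dim(stackT)[3]
            else config$bpFrames
  bpMap <- matrix(0, dim(stackT)[1], dim(stackT)[2])
  for (f in frames) {
    frT <- stackT[, , f]; frC <- stackC[, , f]
    r <- matrix(NA_real_, nrow(bpMap), ncol(bpMap))
    ok <- frC > 0
    r[ok] <- (frT[ok] - frC[ok]) / frC[ok]
    bpMap <- bpMap + r / length(frames)
  }
  roiBP <- function(mask) {
    if (config$bpMode == "pixelwise") mean(bpMap[mask], na.rm = TRUE)
    else {
      f <- frames[length(frames)]
      mT <- mean(stackT[, , f][mask]); mC <- mean(stackC[, , f][mask])
      if (mC > 0) (mT - mC) / mC else NA_real_
    }
  }
  ketyFit <- NULL
  pl <- if (!is.null(plasma)) plasma else plasmaT
  if (!is.null(pl)) {
    ctlCurve <- apply(stackC, 3, function(fr) mean(fr[tumorOK]))
    ketyFit <- fitKety(frameTimes, ctlCurve, pl, bounds = config$fitBounds)
  }
  list(sa = sa, pa = pa, bpMap = bpMap,
       bpTumor = roiBP(tumorOK), bpBackground = roiBP(bgOK),
       ketyFit = ketyFit, scaleMap = norm$scaleMap, excluded = norm$excluded)
}
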