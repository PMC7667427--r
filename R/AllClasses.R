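#' @import methods
NULL

## Central S4 data containers. Units are fixed package-wide: time in minutes,
## rate constants in 1/min, concentrations in nM, fractional blood volume
## unitless.


# -- PlasmaInput ---------------------------------------------------------

#' Biexponential plasma input function
#'
#' Represents the blood-plasma concentration of an imaging agent over time as
#' \eqn{C_p(t) = s\,[A e^{-\alpha t} + B e^{-\beta t}]}, the standard
#' biexponential pharmacokinetic form with a fast distribution phase
#' (\eqn{A}, \eqn{\alpha}) and a slow elimination phase (\eqn{B},
#' \eqn{\beta}). The `scale` slot \eqn{s} (nM) maps the unitless
#' biexponential to a reference concentration.
#'
#' @slot A distribution fraction (unitless), `A >= 0`
#' @slot alpha distribution phase rate constant (1/min), `alpha > 0`
#' @slot B elimination fraction (unitless), `B >= 0`
#' @slot beta elimination phase rate constant (1/min), `beta > 0`
#' @slot scale reference plasma concentration (nM), `scale >= 0`
#'
#' @seealso [plasmaInput()], [plasmaConcentration()], [fitBiexponential()]
#' @export
setClass("PlasmaInput",
  representation(A = "numeric", alpha = "numeric", B = "numeric",
                 beta = "numeric", scale = "numeric"),
  prototype(A = 1, alpha = 0.1, B = 0, beta = 1e-3, scale = 1))

setValidity("PlasmaInput", function(object) {
  msg <- character()
  for (s in c("A", "alpha", "B", "beta", "scale")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) msg <- c(msg, paste0("'", s, "' must be a finite scalar"))
  }
  if (length(msg)) return(msg)
  if (object@A < 0) msg <- c(msg, "'A' must be >= 0")
  if (object@B < 0) msg <- c(msg, "'B' must be >= 0")
  if (object@A + object@B <= 0) msg <- c(msg, "'A' + 'B' must be > 0")
  if (object@alpha <= 0) msg <- c(msg, "'alpha' must be > 0")
  if (object@beta <= 0) msg <- c(msg, "'beta' must be > 0")
  if (object@scale < 0) msg <- c(msg, "'scale' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a plasma input function
#'
#' @param A,alpha,B,beta biexponential parameters (see [PlasmaInput-class]).
#' @param scale reference plasma concentration in nM (default 1).
#' @return A [PlasmaInput-class] object.
#' @examples
#' p <- plasmaInput(A = 0.6, alpha = 0.2, B = 0.4, beta = 5e-3)
#' plasmaConcentration(p, c(0, 10, 60))
#' @export
plasmaInput <- function(A, alpha, B, beta, scale = 1) {
  new("PlasmaInput", A = as.numeric(A), alpha = as.numeric(alpha),
      B = as.numeric(B), beta = as.numeric(beta), scale = as.numeric(scale))
}

setMethod("show", "PlasmaInput", function(object) {
  cat("PlasmaInput: Cp(t) = scale * [A exp(-alpha t) + B exp(-beta t)]\n")
  cat(sprintf("  A = %g, alpha = %g /min; B = %g, beta = %g /min; scale = %g nM\n",
              object@A, object@alpha, object@B, object@beta, object@scale))
})

# -- AgentKinetics -------------------------------------------------------

#' Tissue-level kinetic parameters of an imaging agent
#'
#' First-order rate constants of the two-compartment (free + specifically
#' bound) tissue model for a targeted agent, or of the one-compartment Kety
#' model when binding is absent. The binding rate constant
#' \eqn{k_3 = k_{on} B_{avail}} and the dissociation rate constant
#' \eqn{k_4 = k_{off}} are derived, as are the equilibrium dissociation
#' constant \eqn{K_D = k_{off}/k_{on}} and the binding potential
#' \eqn{BP = B_{avail}/K_D}.
#'
#' @slot K1 extravasation rate constant, plasma to tissue (1/min)
#' @slot k2 efflux rate constant, tissue to plasma (1/min)
#' @slot kon association rate constant (1/nM/min)
#' @slot koff dissociation rate constant (1/min)
#' @slot Bavail available receptor concentration (nM)
#' @slot vp fractional blood volume (unitless, in `[0, 1)`; default 0)
#'
#' @seealso [agentKinetics()], [bindingPotential()], [solveTargeted()]
#' @export
setClass("AgentKinetics",
  representation(K1 = "numeric", k2 = "numeric", kon = "numeric",
                 koff = "numeric", Bavail = "numeric", vp = "numeric"),
  prototype(K1 = 0, k2 = 0, kon = 0, koff = 0, Bavail = 0, vp = 0))

setValidity("AgentKinetics", function(object) {
  msg <- character()
  for (s in c("K1", "k2", "kon", "koff", "Bavail", "vp")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) msg <- c(msg, paste0("'", s, "' must be a finite scalar"))
    else if (v < 0) msg <- c(msg, paste0("'", s, "' must be >= 0"))
  }
  if (length(msg)) return(msg)
  if (object@vp >= 1) msg <- c(msg, "'vp' must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct an agent kinetics parameter set
#'
#' @param K1 extravasation rate (1/min).
#' @param k2 efflux rate (1/min).
#' @param kon association rate (1/nM/min); 0 for a non-binding (control) agent.
#' @param koff dissociation rate (1/min).
#' @param Bavail available receptor concentration (nM).
#' @param vp fractional blood volume (default 0).
#' @return An [AgentKinetics-class] object.
#' @examples
#' k <- agentKinetics(K1 = 0.4, k2 = 0.2, kon = 0.1, koff = 0.1, Bavail = 10)
#' bindingPotential(k)
#' @export
agentKinetics <- function(K1, k2, kon = 0, koff = 0, Bavail = 0, vp = 0) {
  new("AgentKinetics", K1 = as.numeric(K1), k2 = as.numeric(k2),
      kon = as.numeric(kon), koff = as.numeric(koff),
      Bavail = as.numeric(Bavail), vp = as.numeric(vp))
}

setMethod("show", "AgentKinetics", function(object) {
  cat(sprintf("AgentKinetics: K1 = %g, k2 = %g /min; kon = %g /nM/min, koff = %g /min\n",
              object@K1, object@k2, object@kon, object@koff))
  cat(sprintf("  Bavail = %g nM, vp = %g; k3 = %g, k4 = %g /min; BP = %s\n",
              object@Bavail, object@vp, rateK3(object), rateK4(object),
              format(bindingPotential(object))))
})

# -- UptakeCurves --------------------------------------------------------

#' Simulated tissue uptake curves and measurable ROI signals
#'
#' Holds the free targeted (`cfT`), bound targeted (`cbT`) and free control
#' (`cfC`) tissue concentration curves on a common time grid, plus the
#' assembled region-of-interest signals `roiT` and `roiC` once
#' [roiSignal()] has been applied. Unpopulated channels have length 0.
#'
#' @slot time time grid in minutes, strictly increasing, starting at 0
#' @slot cfT free targeted-agent concentration (nM per tissue volume)
#' @slot cbT bound targeted-agent concentration (nM)
#' @slot cfC free control-agent concentration (nM)
#' @slot roiT,roiC measurable ROI signals (arbitrary units)
#' @slot etaT,etaC signal scale factors applied when assembling ROI signals
#' @slot bavail available receptor concentration used in the solve (nM; `NA`
#'   when not applicable)
#' @slot traceExceeded `TRUE` when the bound concentration exceeded 5% of
#'   `bavail` somewhere on the grid (trace-condition violation)
#' @export
setClass("UptakeCurves",
  representation(time = "numeric", cfT = "numeric", cbT = "numeric",
                 cfC = "numeric", roiT = "numeric", roiC = "numeric",
                 etaT = "numeric", etaC = "numeric", bavail = "numeric",
                 traceExceeded = "logical"),
  prototype(time = 0, cfT = numeric(), cbT = numeric(), cfC = numeric(),
            roiT = numeric(), roiC = numeric(), etaT = 1, etaC = 1,
            bavail = NA_real_, traceExceeded = FALSE))

setValidity("UptakeCurves", function(object) {
  msg <- character()
  t <- object@time
  if (length(t) < 1L || any(!is.finite(t))) msg <- c(msg, "'time' must be finite")
  else {
    if (t[1] != 0) msg <- c(msg, "'time' must start at 0")
    if (length(t) > 1L && any(diff(t) <= 0)) msg <- c(msg, "'time' must be strictly increasing")
  }
  for (s in c("cfT", "cbT", "cfC", "roiT", "roiC")) {
    v <- slot(object, s)
    if (length(v) && length(v) != length(t))
      msg <- c(msg, paste0("'", s, "' must be empty or match length(time)"))
    if (length(v) && any(v < -1e-9, na.rm = TRUE))
      msg <- c(msg, paste0("'", s, "' must be nonnegative"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "UptakeCurves", function(object) {
  pop <- c(cfT = length(object@cfT), cbT = length(object@cbT),
           cfC = length(object@cfC), roiT = length(object@roiT),
           roiC = length(object@roiC)) > 0
  cat(sprintf("UptakeCurves: %d time points over [0, %g] min\n",
              length(object@time), max(object@time)))
  cat("  populated:", paste(names(pop)[pop], collapse = ", "), "\n")
  if (isTRUE(object@traceExceeded))
    cat("  note: trace condition violated (max Cb >= 5% of Bavail)\n")
})

#' @describeIn UptakeCurves-class curves as a data frame with columns
#'   `t_min`, `Cf_T`, `Cb_T`, `Cf_C`, `roi_T`, `roi_C` (`NA` for
#'   unpopulated channels).
#' @param x an `UptakeCurves` object
#' @param row.names,optional,... ignored (S3 compatibility)
#' @export
setMethod("as.data.frame", "UptakeCurves",
  function(x, row.names = NULL, optional = FALSE, ...) {
    n <- length(x@time)
    pad <- function(v) if (length(v)) v else rep(NA_real_, n)
    data.frame(t_min = x@time, Cf_T = pad(x@cfT), Cb_T = pad(x@cbT),
               Cf_C = pad(x@cfC), roi_T = pad(x@roiT), roi_C = pad(x@roiC))
  })

# -- RegionSamples -------------------------------------------------------

#' Pixel samples from tumor and background regions
#'
#' @slot tumor numeric vector of pixel signal values in the tumor region
#' @slot background numeric vector of pixel signal values in the background
#'   (normal tissue) region
#' @seealso [cvr()], [auroc()]
#' @export
setClass("RegionSamples",
  representation(tumor = "numeric", background = "numeric"))

setValidity("RegionSamples", function(object) {
  msg <- character()
  if (!length(object@tumor)) msg <- c(msg, "'tumor' must be nonempty")
  if (!length(object@background)) msg <- c(msg, "'background' must be nonempty")
  if (any(!is.finite(object@tumor)) || any(!is.finite(object@background)))
    msg <- c(msg, "sample values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct region samples
#' @param tumor,background numeric vectors of pixel values.
#' @return A [RegionSamples-class] object.
#' @export
regionSamples <- function(tumor, background) {
  new("RegionSamples", tumor = as.numeric(tumor),
      background = as.numeric(background))
}

setMethod("show", "RegionSamples", function(object) {
  cat(sprintf("RegionSamples: %d tumor, %d background pixels\n",
              length(object@tumor), length(object@background)))
})

# -- MetricTimeSeries ----------------------------------------------------

#' Time-resolved tumor-discrimination metrics
#'
#' Per-frame contrast-to-variability ratio (CVR) and AUROC for a
#' single-agent (`"SA"`) or paired-agent (`"PA"`) protocol.
#'
#' @slot time frame times (min)
#' @slot cvr CVR per frame (`>= 0`, `NA` where undefined)
#' @slot auroc AUROC per frame (in `[0, 1]`, `NA` where undefined)
#' @slot protocol `"SA"` or `"PA"`
#' @seealso [metricTimeSeries()], [findTmax()]
#' @export
setClass("MetricTimeSeries",
  representation(time = "numeric", cvr = "numeric", auroc = "numeric",
                 protocol = "character"))

setValidity("MetricTimeSeries", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@cvr) != n || length(object@auroc) != n)
    msg <- c(msg, "'cvr' and 'auroc' must match length(time)")
  if (any(object@cvr < 0, na.rm = TRUE)) msg <- c(msg, "'cvr' must be >= 0")
  if (any(object@auroc < 0 | object@auroc > 1, na.rm = TRUE))
    msg <- c(msg, "'auroc' must lie in [0, 1]")
  if (length(object@protocol) != 1L || !object@protocol %in% c("SA", "PA"))
    msg <- c(msg, "'protocol' must be \"SA\" or \"PA\"")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MetricTimeSeries", function(object) {
  cat(sprintf("MetricTimeSeries (%s): %d frames over [%g, %g] min\n",
              object@protocol, length(object@time),
              min(object@time), max(object@time)))
  i <- which.max(object@cvr)
  if (length(i))
    cat(sprintf("  max CVR %.3g at t = %g min; max AUROC %.3g\n",
                object@cvr[i], object@time[i], suppressWarnings(max(object@auroc, na.rm = TRUE))))
})

#' @describeIn MetricTimeSeries-class metrics as a data frame with columns
#'   `t_min`, `cvr`, `auroc`, `protocol`.
#' @param x a `MetricTimeSeries` object
#' @param row.names,optional,... ignored (S3 compatibility)
#' @export
setMethod("as.data.frame", "MetricTimeSeries",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(t_min = x@time, cvr = x@cvr, auroc = x@auroc,
               protocol = x@protocol)
  })

# -- ContrastWindow ------------------------------------------------------

#' Time of maximum CVR and the 98%-of-maximum window
#'
#' @slot tMax time of maximum CVR (min)
#' @slot cvrMax maximum CVR
#' @slot tStart98 first time at which CVR reaches 98% of its maximum (min)
#' @slot tEnd98 last time at which CVR is still at 98% of its maximum (min)
#' @slot atBoundary `TRUE` when the maximum sits on the first or last frame,
#'   i.e. the peak may not be resolved by the grid
#' @seealso [findTmax()]
#' @export
setClass("ContrastWindow",
  representation(tMax = "numeric", cvrMax = "numeric", tStart98 = "numeric",
                 tEnd98 = "numeric", atBoundary = "logical"))

setValidity("ContrastWindow", function(object) {
  msg <- character()
  if (!(object@tStart98 <= object@tMax && object@tMax <= object@tEnd98))
    msg <- c(msg, "window must contain tMax (tStart98 <= tMax <= tEnd98)")
  if (object@cvrMax < 0) msg <- c(msg, "'cvrMax' must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ContrastWindow", function(object) {
  cat(sprintf("ContrastWindow: Tmax = %g min (CVRmax = %.4g)\n",
              object@tMax, object@cvrMax))
  cat(sprintf("  98%% window: [%g, %g] min (length %g)%s\n",
              object@tStart98, object@tEnd98, object@tEnd98 - object@tStart98,
              if (object@atBoundary) " [peak at grid boundary]" else ""))
})

# -- DetectorSpec --------------------------------------------------------

#' Shot-noise-limited detector model
#'
#' @slot bits bit depth (8, 12 or 16)
#' @slot fraction fraction of the full dynamic range occupied by the peak
#'   expected signal (in `(0, 1]`; default 0.2)
#' @slot noise `"poisson"` or `"none"`
#' @seealso [detectorSpec()], [renderImageStack()]
#' @export
setClass("DetectorSpec",
  representation(bits = "integer", fraction = "numeric", noise = "character"),
  prototype(bits = 16L, fraction = 0.2, noise = "poisson"))

setValidity("DetectorSpec", function(object) {
  msg <- character()
  if (!object@bits %in% c(8L, 12L, 16L)) msg <- c(msg, "'bits' must be 8, 12 or 16")
  if (object@fraction <= 0 || object@fraction > 1)
    msg <- c(msg, "'fraction' must be in (0, 1]")
  if (!object@noise %in% c("poisson", "none"))
    msg <- c(msg, "'noise' must be \"poisson\" or \"none\"")
  if (length(msg)) msg else TRUE
})

#' Construct a detector specification
#' @param bits bit depth (default 16).
#' @param fraction peak-signal fraction of full scale (default 0.2).
#' @param noise noise model, `"poisson"` (default) or `"none"`.
#' @return A [DetectorSpec-class] object.
#' @export
detectorSpec <- function(bits = 16L, fraction = 0.2, noise = "poisson") {
  new("DetectorSpec", bits = as.integer(bits), fraction = as.numeric(fraction),
      noise = match.arg(noise, c("poisson", "none")))
}

setMethod("show", "DetectorSpec", function(object) {
  cat(sprintf("DetectorSpec: %d-bit, peak at %g%% of full scale (%g counts), %s noise\n",
              object@bits, 100 * object@fraction,
              object@fraction * (2^object@bits - 1), object@noise))
})

# -- SceneSpec -----------------------------------------------------------

#' Specification of a synthetic dual-channel imaging scene
#'
#' Describes a tumor disc embedded in normal tissue imaged in two
#' fluorescence channels (targeted and control agent). Kinetic parameters
#' vary pixel-to-pixel: `K1` and `k2` are drawn from truncated-at-zero
#' normal distributions with region-specific mean and SD; the binding
#' potential is constant within each region.
#'
#' `tumorParams` and `backgroundParams` are lists with elements `K1` and
#' `k2`, each `c(mean, sd)` in 1/min, and a scalar `BP` (unitless).
#'
#' @slot dim image dimensions `c(rows, cols)` in pixels
#' @slot tumorCenter,tumorRadius tumor disc geometry (pixels)
#' @slot bgInner,bgOuter background annulus radii (pixels)
#' @slot tumorParams,backgroundParams per-region kinetic parameter
#'   distributions (see Details)
#' @slot kon,koff binding/dissociation rate constants (shared by regions)
#' @slot plasma a [PlasmaInput-class]
#' @slot frameTimes acquisition times (min), increasing, first frame at 0
#' @slot detector a [DetectorSpec-class]
#' @slot seed random seed for maps and noise
#' @slot autofluorescence constant autofluorescence offset (expected counts)
#' @slot etaT,etaC channel signal scale factors
#' @slot vp fractional blood volume used in ROI assembly
#' @seealso [sceneSpec()], [sceneFromPreset()], [generateParameterMaps()],
#'   [renderImageStack()]
#' @export
setClass("SceneSpec",
  representation(dim = "integer", tumorCenter = "numeric", tumorRadius = "numeric",
                 bgInner = "numeric", bgOuter = "numeric",
                 tumorParams = "list", backgroundParams = "list",
                 kon = "numeric", koff = "numeric", plasma = "PlasmaInput",
                 frameTimes = "numeric", detector = "DetectorSpec",
                 seed = "integer", autofluorescence = "numeric",
                 etaT = "numeric", etaC = "numeric", vp = "numeric"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 2L || any(object@dim < 4L))
    msg <- c(msg, "'dim' must be two pixel counts >= 4")
  for (p in c("tumorParams", "backgroundParams")) {
    pp <- slot(object, p)
    if (!all(c("K1", "k2", "BP") %in% names(pp)))
      msg <- c(msg, paste0("'", p, "' needs elements K1, k2, BP"))
    else {
      if (length(pp$K1) != 2L || length(pp$k2) != 2L)
        msg <- c(msg, paste0("'", p, "' K1/k2 must be c(mean, sd)"))
      else if (pp$K1[2] < 0 || pp$k2[2] < 0)
        msg <- c(msg, paste0("'", p, "' SDs must be >= 0"))
      if (length(pp$BP) != 1L || pp$BP < 0)
        msg <- c(msg, paste0("'", p, "' BP must be a scalar >= 0"))
    }
  }
  if (object@bgInner < object@tumorRadius)
    msg <- c(msg, "'bgInner' must be >= 'tumorRadius' (disjoint regions)")
  if (object@bgOuter <= object@bgInner)
    msg <- c(msg, "'bgOuter' must be > 'bgInner'")
  ft <- object@frameTimes
  if (length(ft) < 2L || any(diff(ft) <= 0) || ft[1] < 0)
    msg <- c(msg, "'frameTimes' must be increasing and nonnegative")
  if (object@vp < 0 || object@vp >= 1) msg <- c(msg, "'vp' must be in [0, 1)")
  if (object@autofluorescence < 0) msg <- c(msg, "'autofluorescence' must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %dx%d px, tumor disc r=%g at (%g, %g), background annulus [%g, %g]\n",
              object@dim[1], object@dim[2], object@tumorRadius,
              object@tumorCenter[1], object@tumorCenter[2],
              object@bgInner, object@bgOuter))
  cat(sprintf("  tumor: K1 %g+-%g, k2 %g+-%g, BP %g | background: K1 %g+-%g, k2 %g+-%g, BP %g\n",
              object@tumorParams$K1[1], object@tumorParams$K1[2],
              object@tumorParams$k2[1], object@tumorParams$k2[2], object@tumorParams$BP,
              object@backgroundParams$K1[1], object@backgroundParams$K1[2],
              object@backgroundParams$k2[1], object@backgroundParams$k2[2],
              object@backgroundParams$BP))
  cat(sprintf("  %d frames over [%g, %g] min; seed %d\n",
              length(object@frameTimes), min(object@frameTimes),
              max(object@frameTimes), object@seed))
})

# -- RenderedScene -------------------------------------------------------

#' A rendered synthetic dual-channel image time series
#'
#' Output of [renderImageStack()]: integer count stacks for the targeted and
#' control channels, the underlying noise-free expected-count stacks, the
#' pre-injection frames, region masks, and the joint channel scale factor.
#' Stacks are arrays of dimension `c(rows, cols, frames)`.
#'
#' @slot targeted,control integer count stacks
#' @slot targetedExpected,controlExpected noise-free expected-count stacks
#' @slot preT,preC pre-injection frames (counts)
#' @slot tumorMask,bgMask logical region masks
#' @slot scale joint counts-per-nM scale factor applied to both channels
#' @slot frameTimes acquisition times (min)
#' @slot spec the generating [SceneSpec-class]
#' @export
setClass("RenderedScene",
  representation(targeted = "array", control = "array",
                 targetedExpected = "array", controlExpected = "array",
                 preT = "matrix", preC = "matrix",
                 tumorMask = "matrix", bgMask = "matrix",
                 scale = "numeric", frameTimes = "numeric", spec = "SceneSpec"))

setMethod("show", "RenderedScene", function(object) {
  d <- dim(object@targeted)
  cat(sprintf("RenderedScene: %dx%d px, %d frames, %d tumor / %d background pixels\n",
              d[1], d[2], d[3], sum(object@tumorMask), sum(object@bgMask)))
  cat(sprintf("  peak expected count %g; joint scale %.4g counts/nM; noise: %s\n",
              max(object@targetedExpected, object@controlExpected),
              object@scale, object@spec@detector@noise))
})

# -- FitResult -----------------------------------------------------------

#' Nonlinear least-squares fit result
#'
#' @slot estimates named numeric vector of parameter estimates
#' @slot residualNorm residual sum of squares
#' @slot converged logical convergence flag
#' @slot message solver diagnostic message
#' @seealso [fitKety()], [fitBiexponential()]
#' @export
setClass("FitResult",
  representation(estimates = "numeric", residualNorm = "numeric",
                 converged = "logical", message = "character"))

setValidity("FitResult", function(object) {
  if (length(object@residualNorm) == 1L && is.finite(object@residualNorm) &&
      object@residualNorm < 0) "'residualNorm' must be >= 0" else TRUE
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", if (object@converged) "converged" else "NOT converged", "\n")
  est <- object@estimates
  cat("  ", paste(sprintf("%s = %.6g", names(est), est), collapse = ", "), "\n")
  cat(sprintf("  residual norm = %.4g\n", object@residualNorm))
})

#' Extract fit estimates
#' @param fit a [FitResult-class]
#' @return Named numeric vector of estimates.
#' @export
fitEstimates <- function(fit) fit@estimates

# -- ClassRanges ---------------------------------------------------------

#' Kinetic parameter ranges for a class of imaging agents
#'
#' Minimum/maximum sampling ranges for tumor and normal-tissue `K1` and
#' `k2` and for the binding potential, together with the class plasma input
#' and the time grid on which contrast curves for this class are evaluated.
#'
#' @slot name class name
#' @slot ranges 5 x 2 matrix (`min`, `max` columns) with rows `K1_tumor`,
#'   `k2_tumor`, `K1_normal`, `k2_normal`, `BP`
#' @slot plasma class [PlasmaInput-class] used for contrast simulation
#' @slot timeGrid evaluation grid (min)
#' @seealso [classRanges()], [runStudy()]
#' @export
setClass("ClassRanges",
  representation(name = "character", ranges = "matrix",
                 plasma = "PlasmaInput", timeGrid = "numeric"))

setValidity("ClassRanges", function(object) {
  msg <- character()
  r <- object@ranges
  need <- c("K1_tumor", "k2_tumor", "K1_normal", "k2_normal", "BP")
  if (!is.numeric(r) || nrow(r) != 5L || ncol(r) != 2L ||
      !identical(rownames(r), need))
    msg <- c(msg, "'ranges' must be a 5x2 numeric matrix with rows K1_tumor, k2_tumor, K1_normal, k2_normal, BP")
  else {
    if (any(r <= 0)) msg <- c(msg, "all range bounds must be positive")
    if (any(r[, 1] > r[, 2])) msg <- c(msg, "range minima must be <= maxima")
  }
  if (length(object@timeGrid) < 2L || object@timeGrid[1] != 0 ||
      any(diff(object@timeGrid) <= 0))
    msg <- c(msg, "'timeGrid' must start at 0 and increase")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClassRanges", function(object) {
  cat(sprintf("ClassRanges '%s' (grid [0, %g] min, %d points)\n",
              object@name, max(object@timeGrid), length(object@timeGrid)))
  r <- object@ranges
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-10s [%g, %g]\n", rownames(r)[i], r[i, 1], r[i, 2]))
})

# -- StudyResult ---------------------------------------------------------

#' Result of a Monte-Carlo contrast-timing study
#'
#' Per-iteration records (sampled parameters, numeric and analytical times
#' of maximum CVR for the single-agent and paired-agent protocols, 98%
#' windows, flags) plus pooled and per-class summaries.
#'
#' @slot records one row per iteration; see [runStudy()] for columns
#' @slot summary list of pooled/per-class summary statistics
#' @slot seed study seed
#' @slot nIterations iterations per class
#' @slot plasmaMode `"mono"` or `"biexp"` plasma-input mode used
#' @seealso [runStudy()], [summarizeTmaxByClass()], [studyRecords()],
#'   [studySummary()]
#' @export
setClass("StudyResult",
  representation(records = "data.frame", summary = "list", seed = "integer",
                 nIterations = "integer", plasmaMode = "character"))

setMethod("show", "StudyResult", function(object) {
  cat(sprintf("StudyResult: %d iterations x %d classes (seed %d, %s plasma)\n",
              object@nIterations,
              length(unique(object@records$class)), object@seed,
              object@plasmaMode))
  s <- object@summary
  if (!is.null(s$pearson_r_pa))
    cat(sprintf("  analytical vs numeric Tmax: r = %.3f (SA %.3f); PA mean rel. error %.1f%%\n",
                s$pearson_r_pa, s$pearson_r_sa, 100 * s$mre_pa))
})

#' Per-iteration records of a study
#' @param result a [StudyResult-class]
#' @return The records data frame.
#' @export
studyRecords <- function(result) result@records

#' Summary statistics of a study
#' @param result a [StudyResult-class]
#' @return The summary list.
#' @export
studySummary <- function(result) result@summary
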