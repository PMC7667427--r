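# Generics for the kinetic and metric accessors.

#' Binding rate constant k3 = kon * Bavail
#' @param object an [AgentKinetics-class]
#' @return k3 in 1/min.
#' @export
setGeneric("rateK3", function(object) standardGeneric("rateK3"))

#' Dissociation rate constant k4 = koff
#' @param object an [AgentKinetics-class]
#' @return k4 in 1/min.
#' @export
setGeneric("rateK4", function(object) standardGeneric("rateK4"))

#' Equilibrium dissociation constant KD = koff / kon
#' @param object an [AgentKinetics-class]
#' @return KD in nM (`NA` when `kon == 0`).
#' @export
setGeneric("dissociationConstant",
           function(object) standardGeneric("dissociationConstant"))

#' Binding potential BP = Bavail / KD = kon * Bavail / koff
#' @param object an [AgentKinetics-class]
#' @return BP (unitless; `NA` when `koff == 0`).
#' @export
setGeneric("bindingPotential",
           function(object) standardGeneric("bindingPotential"))

#' Contrast-to-variability ratio
#'
#' CVR = |mean(tumor) - mean(background)| / sqrt(var(tumor) + var(background)),
#' with sample (n-1) variances. A surrogate for ideal-observer
#' discriminability between the two pixel populations.
#'
#' @param x a [RegionSamples-class], or a numeric vector of tumor pixel
#'   values
#' @param ... for the numeric method, `background`: the background pixel
#'   values
#' @return CVR (unitless scalar).
#' @examples
#' cvr(c(2, 4), c(0, 2))            # 1
#' cvr(regionSamples(c(2, 4), c(0, 2)))
#' @export
setGeneric("cvr", function(x, ...) standardGeneric("cvr"))

#' Area under the ROC curve (ideal observer)
#'
#' Rank-based (Mann-Whitney) estimate: the fraction of (tumor, background)
#' pixel pairs in which the tumor pixel is brighter, ties counted 1/2.
#'
#' @param x a [RegionSamples-class], or a numeric vector of tumor pixel
#'   values
#' @param ... for the numeric method, `background`: the background pixel
#'   values
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(2, 3, 4), c(1, 2, 3))    # 7/9
#' @export
setGeneric("auroc", function(x, ...) standardGeneric("auroc"))

#' Locate the time of maximum CVR and its 98% window
#'
#' Finds the maximum of the CVR curve (first index on exact ties) and the
#' times before and after it at which the curve crosses 98% of the maximum,
#' located by linear interpolation between frames.
#'
#' @param x a [MetricTimeSeries-class], or a numeric vector of metric values
#' @param ... further arguments; for the numeric method `time` (the time
#'   grid) is required. `smooth`: optional odd moving-average window length
#'   (default 0, off) applied before locating the peak.
#' @return A [ContrastWindow-class].
#' @export
setGeneric("findTmax", function(x, ...) standardGeneric("findTmax"))

#' Ratiometric binding potential from paired-agent signals
#'
#' BPratio(t) = (ROI_T(t) - ROI_C(t)) / ROI_C(t), the normalized difference
#' of the targeted and control channel signals; at equilibrium it
#' approximates the binding potential. Times where the control signal is
#' zero are returned as `NA` (undefined), not infinity.
#'
#' @param x an [UptakeCurves-class] with both ROI signals populated, or a
#'   numeric vector of targeted-channel values
#' @param ... for the numeric method, `roiC`: control-channel values
#' @return Numeric vector of BPratio values.
#' @export
setGeneric("bpRatio", function(x, ...) standardGeneric("bpRatio"))
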