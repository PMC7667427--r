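# Closed-form predictions of the time of maximum CVR for single-agent and
# paired-agent protocols, and lookup-grid generation.

#' Apparent tumor efflux rate
#'
#' `k2a = k2 / (1 + BP)`: the effective washout rate of a reversibly bound
#' agent from tissue; binding (large BP) slows apparent efflux.
#'
#' @param k2 efflux rate (1/min), `>= 0`.
#' @param BP binding potential (unitless), `>= 0`.
#' @return Apparent efflux rate (1/min).
#' @examples
#' k2Apparent(0.66, 40)   # 0.0161
#' @export
k2Apparent <- function(k2, BP) {
  if (any(k2 < 0) || any(BP < 0))
    stop("'k2' and 'BP' must be nonnegative", call. = FALSE)
  k2 / (1 + BP)
}

#' Predicted time of maximum single-agent contrast
#'
#' Closed-form estimate
#' \deqn{T_{max,SA} \approx \frac{\ln(K_1'/K_1)}{k_2' - k_{2a}},}
#' where primed constants refer to normal tissue and
#' \eqn{k_{2a} = k_2/(1+BP)} is the apparent tumor efflux rate. Negative
#' values of the expression — parameter combinations for which tumor
#' contrast is maximal essentially immediately — are clamped to 0 and
#' flagged via the `"contrastImmediate"` attribute.
#'
#' @param K1_tumor,K1_normal extravasation rates (1/min), `> 0`.
#' @param k2_tumor,k2_normal efflux rates (1/min), `> 0`.
#' @param BP tumor binding potential (unitless), `>= 0`.
#' @return Predicted time (min) with logical attribute
#'   `"contrastImmediate"`.
#' @examples
#' tmaxSA(K1_tumor = 0.2, K1_normal = 0.4, k2_tumor = 0.66,
#'        k2_normal = 0.5, BP = 40)   # ~1.43 min
#' @export
tmaxSA <- function(K1_tumor, K1_normal, k2_tumor, k2_normal, BP) {
  if (K1_tumor <= 0 || K1_normal <= 0)
    stop("extravasation rates must be > 0", call. = FALSE)
  if (k2_tumor < 0 || k2_normal < 0 || BP < 0)
    stop("rates and BP must be nonnegative", call. = FALSE)
  k2a <- k2Apparent(k2_tumor, BP)
  denom <- k2_normal - k2a
  if (denom == 0)
    stop("singular input: k2_normal equals the apparent tumor efflux rate",
         call. = FALSE)
  raw <- log(K1_normal / K1_tumor) / denom
  out <- max(raw, 0)
  attr(out, "contrastImmediate") <- raw < 0
  out
}

#' Predicted time of maximum paired-agent contrast
#'
#' Closed-form estimate
#' \deqn{T_{max,PA} \approx \frac{10}{k_2 - k_{2a}}
#'   \left[\ln\!\left(\frac{1}{k_2^2} - \frac{1}{k_{2a}^2}\right)
#'   - \ln\!\left(\frac{2}{k_2^2} - \frac{2}{k_2 k_{2a}}\right)\right],}
#' depending only on the tumor efflux rate and the binding potential. Both
#' log arguments are negative whenever `k2a < k2`; the difference of logs is
#' evaluated as the log of the (positive) ratio, which is algebraically
#' identical wherever both logs exist and defined everywhere the ratio is
#' positive. The leading factor 10 is an empirical proportionality
#' correction and is kept verbatim.
#'
#' @param k2_tumor tumor efflux rate (1/min), `> 0`.
#' @param BP tumor binding potential (unitless), `> 0` (at `BP = 0` the
#'   expression is singular: `k2a = k2`).
#' @return Predicted time (min), `> 0`.
#' @examples
#' tmaxPA(k2_tumor = 0.66, BP = 40)   # ~47.3 min
#' @export
tmaxPA <- function(k2_tumor, BP) {
  if (k2_tumor <= 0) stop("'k2_tumor' must be > 0", call. = FALSE)
  if (BP < 0) stop("'BP' must be nonnegative", call. = FALSE)
  if (BP == 0)
    stop("singular input: BP = 0 makes k2a equal to k2", call. = FALSE)
  k2a <- k2Apparent(k2_tumor, BP)
  ratio <- (1 / k2_tumor^2 - 1 / k2a^2) /
    (2 / k2_tumor^2 - 2 / (k2_tumor * k2a))
  if (!is.finite(ratio) || ratio <= 0)
    stop("singular input: log argument not positive", call. = FALSE)
  10 / (k2_tumor - k2a) * log(ratio)
}

#' Lookup grid of predicted times of maximum contrast
#'
#' Evaluates the closed-form predictions on a dense parameter grid, as an
#' order-of-magnitude lookup table. For the SA protocol the axes are the
#' extravasation ratio `K1_normal / K1_tumor` and the apparent tumor efflux
#' rate `k2a`, at a fixed normal-tissue efflux rate `k2_normal` (which must
#' be supplied explicitly). For the PA protocol the axes are `BP` and
#' `k2_tumor`. Singular cells are `NA`.
#'
#' @param axis1 for SA: `K1_normal/K1_tumor` values; for PA: `BP` values.
#' @param axis2 for SA: `k2a` values (1/min); for PA: `k2_tumor` values
#'   (1/min).
#' @param protocol `"SA"` or `"PA"`.
#' @param k2_normal fixed normal-tissue efflux rate (1/min), required for
#'   SA.
#' @return A matrix of predicted times (min) with `axis1` on rows and
#'   `axis2` on columns; axis values in `dimnames` and axis labels in the
#'   `"axes"` attribute.
#' @examples
#' g <- tmaxLookupGrid(axis1 = c(20, 40), axis2 = c(0.33, 0.66),
#'                     protocol = "PA")
#' @export
tmaxLookupGrid <- function(axis1, axis2, protocol = c("SA", "PA"),
                           k2_normal = NULL) {
  protocol <- match.arg(protocol)
  if (!length(axis1) || !length(axis2) || any(axis1 <= 0) || any(axis2 <= 0))
    stop("axis values must be positive", call. = FALSE)
  out <- matrix(NA_real_, length(axis1), length(axis2),
                dimnames = list(format(axis1, trim = TRUE),
                                format(axis2, trim = TRUE)))
  if (protocol == "SA") {
    if (is.null(k2_normal))
      stop("SA grid requires an explicit 'k2_normal'", call. = FALSE)
    for (i in seq_along(axis1)) for (j in seq_along(axis2)) {
      denom <- k2_normal - axis2[j]
      if (denom != 0) out[i, j] <- max(log(axis1[i]) / denom, 0)
    }
    attr(out, "axes") <- c("K1_normal/K1_tumor", "k2a_per_min")
    attr(out, "k2_normal") <- k2_normal
  } else {
    for (i in seq_along(axis1)) for (j in seq_along(axis2)) {
      val <- tryCatch(tmaxPA(axis2[j], axis1[i]), error = function(e) NA_real_)
      out[i, j] <- val
    }
    attr(out, "axes") <- c("BP", "k2_tumor_per_min")
  }
  attr(out, "protocol") <- protocol
  out
}
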