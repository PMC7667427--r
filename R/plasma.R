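# Plasma input function evaluation.

#' Evaluate a plasma input function
#'
#' Computes \eqn{C_p(t) = s\,[A e^{-\alpha t} + B e^{-\beta t}]} on a time
#' grid.
#'
#' @param p a [PlasmaInput-class].
#' @param t times in minutes (scalar or vector, `t >= 0`).
#' @return Plasma concentration in nM, same length as `t`.
#' @examples
#' p <- plasmaInput(A = 0.02, alpha = 0.3, B = 2e-3, beta = 6e-4)
#' plasmaConcentration(p, 10)
#' @export
plasmaConcentration <- function(p, t) {
  stopifnot(is(p, "PlasmaInput"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("negative times are outside the model domain", call. = FALSE)
  p@scale * (p@A * exp(-p@alpha * t) + p@B * exp(-p@beta * t))
}
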