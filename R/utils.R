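# Internal helpers.

.assertScalarNonneg <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    stop("'", name, "' must be a finite nonnegative scalar", call. = FALSE)
  invisible(x)
}

.assertTimeGrid <- function(t, requireZero = TRUE) {
  if (!length(t) || any(!is.finite(t)))
    stop("time grid must be finite and nonempty", call. = FALSE)
  if (any(t < 0)) stop("negative times are outside the model domain", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  if (requireZero && t[1] != 0)
    stop("time grid must start at 0", call. = FALSE)
  invisible(t)
}

#' Derive a reproducible child seed from a global seed
#'
#' A single global seed fans out to per-stage child seeds so that adding a
#' pipeline stage never perturbs the random draws of another stage. The
#' mapping hashes the stage tag into a 31-bit integer offset.
#'
#' @param seed integer global seed.
#' @param tag character stage tag, e.g. `"maps"` or `"noise"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @examples
#' childSeed(1L, "maps")
#' @export
childSeed <- function(seed, tag) {
  .assertScalarNonneg(seed, "seed")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Truncated-at-zero normal draws via inverse-CDF so that draws are a pure
# function of the RNG stream (one uniform per value).
.rtruncnorm0 <- function(n, mean, sd) {
  if (all(sd == 0)) return(rep_len(mean, n) + 0 * stats::runif(n))
  lo <- stats::pnorm(0, mean = mean, sd = sd)
  u <- stats::runif(n, min = lo, max = 1)
  stats::qnorm(u, mean = mean, sd = sd)
}

# Realized mean and SD of a normal(mu, sigma) truncated at zero.
.truncnorm0Moments <- function(mu, sigma) {
  a <- -mu / sigma
  h <- stats::dnorm(a) / (1 - stats::pnorm(a))
  m <- mu + sigma * h
  v <- sigma^2 * (1 + a * h - h^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Underlying (mu, sigma) such that the zero-truncated normal has the target
# mean and SD. The truncated family cannot reach coefficients of variation
# much above ~0.75 (half-normal limit); when matching fails the nominal
# parameters are returned with attainable = FALSE and the draws carry the
# truncation bias.
.truncnorm0Match <- function(mean, sd) {
  if (sd <= 0) return(list(mu = mean, sigma = sd, attainable = TRUE))
  obj <- function(p) {
    mo <- .truncnorm0Moments(p[1], exp(p[2]))
    (mo[1] / mean - 1)^2 + (mo[2] / sd - 1)^2
  }
  fit <- tryCatch(
    stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(fit) && fit$value < 1e-6)
    list(mu = fit$par[1], sigma = exp(fit$par[2]), attainable = TRUE)
  else list(mu = mean, sigma = sd, attainable = FALSE)
}

# Moving-average smoother with edge shrinkage; w must be odd, w <= 1 is a
# no-op.
.movingAverage <- function(x, w) {
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) stop("smoothing window must be odd", call. = FALSE)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    out[i] <- mean(x[j])
  }
  out
}

.packageVersionString <- function() {
  as.character(utils::packageVersion("fgskinetics"))
}
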