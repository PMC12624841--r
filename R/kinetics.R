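#' @include AllClasses.R
NULL

.checkTrace <- function(times, fractions) {
  if (is.data.frame(times)) {
    df <- times
    need <- c("time_s", "fraction")
    if (!all(need %in% names(df)))
      stop("a kinetics trace data.frame needs columns 'time_s' and 'fraction'")
    times <- df$time_s; fractions <- df$fraction
  }
  stopifnot(is.numeric(times), is.numeric(fractions))
  if (length(times) != length(fractions))
    stop("'times' and 'fractions' must have equal length")
  if (length(times) < 3L) stop("a kinetics trace needs at least 3 points")
  if (any(times < 0)) stop("times must be non-negative (seconds)")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(fractions < -1e-9 | fractions > 1 + 1e-9))
    stop("fractions must lie in [0, 1]")
  list(t = times, f = pmin(1, pmax(0, fractions)))
}

#' Fit first-order approach-to-equilibrium kinetics
#'
#' Least-squares fit of the pseudo-first-order model
#' \deqn{f(t) = f_{eq}\,(1 - e^{-kt})}
#' to a product-fraction time series (e.g. glycosylamine formation
#' followed by NMR integration).  The nonlinear solve is initialized
#' from the log-linearized trace; back-reaction and hydrolysis are
#' lumped into the plateau \eqn{f_{eq}}.
#'
#' @param times numeric seconds (strictly increasing, >= 3 points), or
#'   a data.frame with columns \code{time_s} and \code{fraction}.
#' @param fractions product fractions in \eqn{[0, 1]} (ignored when a
#'   data.frame is given).
#' @return a [KineticsFit-class].
#' @examples
#' tr <- simulateKinetics(k = 2.5e-4, fEq = 0.96,
#'                        times = seq(0, 2e4, length.out = 12))
#' fitFirstOrder(tr)
#' @export
fitFirstOrder <- function(times, fractions = NULL) {
  tr <- .checkTrace(times, fractions)
  t <- tr$t; f <- tr$f
  if (diff(range(f)) < 1e-9)
    stop("trace is flat (already equilibrated?); ",
         "the rate constant is not identifiable")
  if (stats::cor(t, f) < 0)
    warning("trace decreases with time; the growth model will fit poorly")

  ## log-linearized initial estimate
  fEq0 <- min(1, max(f) / 0.999)
  ok <- f / fEq0 < 1 & f / fEq0 > 0 & t > 0
  k0 <- if (sum(ok) >= 2L) {
    z <- log(1 - f[ok] / fEq0)
    max(1e-12, -sum(z * t[ok]) / sum(t[ok]^2))
  } else 1 / stats::median(t[t > 0])

  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ fEq * (1 - exp(-k * t)),
                      start = list(fEq = fEq0, k = k0),
                      lower = c(fEq = 1e-9, k = 1e-12),
                      upper = c(fEq = 1, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("kinetics fit did not converge (", conditionMessage(e),
           "); starting values were fEq=", signif(fEq0, 4),
           ", k=", signif(k0, 4), call. = FALSE))
  co <- stats::coef(fit)
  res <- f - co[["fEq"]] * (1 - exp(-co[["k"]] * t))
  new("KineticsFit",
      k = co[["k"]], fEq = co[["fEq"]],
      rmse = sqrt(mean(res^2)),
      t99 = log(100) / co[["k"]],
      residuals = res,
      details = list(n = length(t), start = c(fEq = fEq0, k = k0),
                     convInfo = fit$convInfo))
}

#' Time to reach a fraction of the equilibrium plateau
#'
#' \eqn{t = -\ln(1 - \mathrm{threshold})/k}; with the default
#' threshold 0.99 this is \eqn{\ln(100)/k}, the operational "time to
#' equilibrium".
#'
#' @param fit a [KineticsFit-class].
#' @param threshold fraction of \eqn{f_{eq}} to reach, in (0, 1).
#' @return time in seconds.
#' @export
timeToEquilibrium <- function(fit, threshold = 0.99) {
  stopifnot(is(fit, "KineticsFit"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie strictly between 0 and 1")
  -log(1 - threshold) / rateConstant(fit)
}
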