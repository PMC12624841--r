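#' @include coupling_io.R
NULL

.usableVector <- function(experimental) {
  if (is.data.frame(experimental)) {
    sel <- experimental$status == "ok" & !is.na(experimental$value)
    stats::setNames(experimental$value[sel], experimental$id[sel])
  } else {
    stopifnot(is.numeric(experimental), !is.null(names(experimental)))
    experimental[!is.na(experimental)]
  }
}

#' Two-state pyranose ring-conformer fit
#'
#' Estimates the \eqn{^4C_1} fraction \eqn{x} of a two-state
#' \eqn{^4C_1 \rightleftharpoons {}^1C_4} chair equilibrium by fitting
#' the linear combination of the conformer-pure theoretical ring
#' couplings to the experimental values:
#' \deqn{r_i = J_i^{exp} - [\,x\,J_i(^4C_1) + (1-x)\,J_i(^1C_4)\,]}
#' minimizing either the mean absolute error (default, consistent with
#' the multi-conformer aglycone fit) or the sum of squared residuals
#' over \eqn{x \in [0,1]}.  The SSE problem is solved in closed form
#' (clipped to the unit interval); the MAE problem by a dense grid
#' (step 0.001) refined by golden-section search (the 1-D MAE
#' objective is convex piecewise-linear).
#'
#' @param experimental usable experimental couplings: either a named
#'   numeric vector (Hz) or a coupling record data.frame (only status
#'   \code{ok} rows are used).
#' @param j4C1,j1C4 named numeric vectors of conformer-pure couplings
#'   (Hz) for the two chairs, e.g. from [pyranoseEndpoints()].
#' @param objective \code{"mae"} or \code{"sse"}.
#' @return a [TwoStateFit-class].
#' @examples
#' ep <- pyranoseEndpoints("7b")
#' fitTwoState(ep$j4C1, ep$j4C1, ep$j1C4)  # pure endpoint: x = 1
#' @export
fitTwoState <- function(experimental, j4C1, j1C4,
                        objective = c("mae", "sse")) {
  objective <- match.arg(objective)
  jexp <- .usableVector(experimental)
  ids <- Reduce(intersect, list(names(jexp), names(j4C1), names(j1C4)))
  excluded <- setdiff(names(jexp), ids)
  if (!length(ids))
    stop("no usable coupling shared by the experimental and both endpoint sets")
  je <- jexp[ids]; j4 <- j4C1[ids]; j1 <- j1C4[ids]
  d <- j4 - j1
  if (max(abs(d)) < 1e-8)
    stop("endpoint coupling vectors are identical; the chair fraction ",
         "is not identifiable")

  obj <- function(x) {
    r <- je - (x * j4 + (1 - x) * j1)
    if (objective == "mae") mean(abs(r)) else sum(r^2)
  }
  if (objective == "sse") {
    x <- sum((je - j1) * d) / sum(d^2)
    x <- min(1, max(0, x))
  } else {
    grid <- seq(0, 1, by = 0.001)
    vals <- vapply(grid, obj, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1L, i - 2L)]; hi <- grid[min(length(grid), i + 2L)]
    x <- stats::optimize(obj, c(lo, hi), tol = 1e-9)$minimum
    if (obj(grid[i]) < obj(x)) x <- grid[i]
  }
  r <- je - (x * j4 + (1 - x) * j1)
  new("TwoStateFit",
      populations = c("4C1" = x, "1C4" = 1 - x),
      mae = mean(abs(r)),
      residuals = r,
      degenerate = FALSE,
      couplingsUsed = ids,
      couplingsExcluded = excluded,
      objective = objective,
      details = list(objectiveValue = obj(x)))
}

#' Two-state ring fit of a template compound from a coupling table
#'
#' Convenience wrapper: selects the ring \eqn{^3J(H,H)} couplings of
#' one compound from an experimental table, predicts the chair
#' endpoint couplings from the built-in idealized template, and runs
#' [fitTwoState()].
#'
#' @param records coupling record data.frame (see
#'   [readCouplingTable()]).
#' @param compound template identifier (see [pyranoseCompounds()]).
#' @param objective passed to [fitTwoState()].
#' @param registry Karplus registry (see [karplusRegistry()]).
#' @return a [TwoStateFit-class].
#' @export
ringFitCompound <- function(records, compound, objective = c("mae", "sse"),
                            registry = karplusRegistry()) {
  ep <- pyranoseEndpoints(compound, registry)
  jexp <- couplingVector(records, compound)
  fitTwoState(jexp[names(jexp) %in% names(ep$j4C1)],
              ep$j4C1, ep$j1C4, objective = match.arg(objective))
}
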