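#' @include coupling_io.R
NULL

#' Filter a conformer library by relative energy
#'
#' Keeps conformers whose relative energy does not exceed the cutoff
#' (inclusive), preserving order.  Energies are expected to be
#' normalized (library construction guarantees a minimum of 0).
#'
#' @param lib a [ConformerLibrary-class].
#' @param cutoff relative-energy cutoff, kcal/mol; default 5.
#' @return the filtered [ConformerLibrary-class].
#' @export
filterConformers <- function(lib, cutoff = 5.0) {
  stopifnot(is(lib, "ConformerLibrary"))
  keep <- relativeEnergies(lib) <= cutoff
  if (!any(keep))
    stop("no conformer within ", cutoff,
         " kcal/mol of the minimum; increase the cutoff")
  new("ConformerLibrary", compound = compoundName(lib),
      couplings = couplingMatrix(lib)[, keep, drop = FALSE],
      energies = relativeEnergies(lib)[keep])
}

## Enumerate the probability simplex on a regular grid (stars and bars).
## Returns a matrix with one row per grid point, k columns, rows sum to 1.
## Cached per (k, step): the same grid is reused across fits.
.gridCache <- new.env(parent = emptyenv())

.simplexGrid <- function(k, step) {
  key <- paste(k, step)
  if (!is.null(g <- .gridCache[[key]])) return(g)
  g <- .simplexGridBuild(k, step)
  .gridCache[[key]] <- g
  g
}

.simplexGridBuild <- function(k, step) {
  n <- round(1 / step)
  if (abs(n * step - 1) > 1e-9) stop("1/step must be an integer")
  if (k == 1L) return(matrix(1, 1, 1))
  bars <- utils::combn(n + k - 1L, k - 1L)
  counts <- rbind(bars[1L, ] - 1L,
                  if (k > 2L) bars[-1L, , drop = FALSE] -
                    bars[-(k - 1L), , drop = FALSE] - 1L,
                  n + k - 1L - bars[k - 1L, ])
  t(counts) / n
}

.maeObjective <- function(P, jmat, jexp, weights) {
  ## P: npts x k; jmat: m x k; jexp: length m
  model <- abs(P %*% t(jmat))               # npts x m
  dev <- abs(sweep(model, 2L, jexp))
  as.numeric(dev %*% weights) / sum(weights)
}

#' Deconvolve ensemble couplings into conformer populations
#'
#' Estimates conformer populations \eqn{p} on the probability simplex
#' by minimizing the mean absolute error between each experimental
#' coupling magnitude and the absolute value of the
#' population-weighted sum of the signed calculated couplings:
#' \deqn{\mathrm{MAE}(p) = \frac{1}{m}\sum_i \big|\,J_i^{exp} -
#'   |\textstyle\sum_c p_c J_{i,c}|\,\big|.}
#'
#' The solver enumerates an exhaustive simplex grid (step 0.01 for up
#' to 4 conformers, 0.05 beyond) and, when \code{refine = TRUE},
#' polishes the best distinct grid points with Nelder--Mead on a
#' softmax parametrization (deterministic multistart).  When several
#' population vectors differing by more than 0.05 in any component lie
#' within 0.01 Hz of the optimum, the fit is flagged degenerate and
#' the maximum-entropy member of the near-optimal set is reported.
#'
#' @param experimental named numeric vector of experimental coupling
#'   magnitudes (Hz), or a coupling record data.frame (status
#'   \code{ok} rows are used).
#' @param lib a [ConformerLibrary-class] (energy-filter it first with
#'   [filterConformers()] if desired).
#' @param couplings optional identifiers restricting the fit to a
#'   coupling subset.
#' @param weights optional per-coupling weights (default equal).
#' @param gridStep simplex grid resolution; default 0.01 (0.05 for
#'   more than 4 conformers).
#' @param refine polish grid solutions by local search.
#' @param degenTolHz,degenTolP thresholds of the degeneracy flag: MAE
#'   band around the optimum (Hz) and minimum component difference.
#' @return a [PopulationFit-class].
#' @export
fitPopulations <- function(experimental, lib, couplings = NULL,
                           weights = NULL, gridStep = NULL, refine = TRUE,
                           degenTolHz = 0.01, degenTolP = 0.05) {
  stopifnot(is(lib, "ConformerLibrary"))
  jexp <- .usableVector(experimental)
  if (!is.null(couplings)) {
    couplings <- .canonicalIds(couplings)
    jexp <- jexp[names(jexp) %in% couplings]
  }
  jm <- couplingMatrix(lib)
  k <- ncol(jm)
  if (k < 2L)
    stop("population fitting needs at least 2 conformers (after filtering)")
  ids <- intersect(names(jexp), rownames(jm))
  ids <- ids[!apply(is.na(jm[ids, , drop = FALSE]), 1L, any)]
  excluded <- setdiff(names(jexp), ids)
  m <- length(ids)
  if (!m) stop("all couplings excluded; nothing to fit")
  if (m < k - 1L)
    warning("only ", m, " usable coupling(s) for ", k,
            " conformers; populations may be poorly determined")
  jmat <- jm[ids, , drop = FALSE]
  je <- jexp[ids]
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m, all(weights >= 0), sum(weights) > 0)

  ## rank deficiency: two conformers with identical coupling columns
  dup <- FALSE
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
    if (max(abs(jmat[, a] - jmat[, b])) < 1e-8) dup <- TRUE
  if (dup)
    warning("library contains conformers with identical coupling vectors; ",
            "their populations are not individually identifiable")

  if (is.null(gridStep)) gridStep <- if (k <= 4L) 0.01 else 0.05
  P <- .simplexGrid(k, gridStep)
  vals <- .maeObjective(P, jmat, je, weights)
  iopt <- which.min(vals)
  gridOpt <- P[iopt, ]
  gridMae <- vals[iopt]

  ## near-optimal set and degeneracy
  near <- which(vals <= gridMae + degenTolHz)
  nearP <- P[near, , drop = FALSE]
  spread <- apply(nearP, 2L, function(col) diff(range(col)))
  degenerate <- any(spread > degenTolP) || dup

  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  maxentIdx <- near[which.max(apply(nearP, 1L, entropy))]

  objFun <- function(p) .maeObjective(matrix(p, 1L), jmat, je, weights)
  refined <- gridOpt
  refinedMae <- gridMae
  if (refine) {
    ## deterministic multistart from distinct top grid points
    ord <- order(vals)[seq_len(min(200L, length(vals)))]
    starts <- list(P[ord[1L], ])
    for (i in ord[-1L]) {
      if (length(starts) >= 5L) break
      if (all(vapply(starts, function(s) max(abs(s - P[i, ])) > 0.1,
                     logical(1))))
        starts <- c(starts, list(P[i, ]))
    }
    softmaxObj <- function(theta) {
      e <- exp(theta - max(theta)); objFun(e / sum(e))
    }
    for (s in starts) {
      th0 <- log(pmax(s, 1e-6))
      opt <- stats::optim(th0, softmaxObj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10))
      e <- exp(opt$par - max(opt$par)); pcand <- e / sum(e)
      if (opt$value < refinedMae - 1e-12) {
        refined <- pcand; refinedMae <- opt$value
      }
    }
  }

  reported <- if (degenerate) P[maxentIdx, ] else refined
  reported <- reported / sum(reported)
  names(reported) <- colnames(jmat)
  model <- abs(as.numeric(jmat %*% reported))
  res <- je - model
  new("PopulationFit",
      populations = reported,
      mae = .maeObjective(matrix(reported, 1L), jmat, je, weights),
      residuals = res,
      degenerate = degenerate,
      couplingsUsed = ids,
      couplingsExcluded = excluded,
      objective = "mae",
      details = list(gridStep = gridStep, gridMae = gridMae,
                     optMae = min(refinedMae, gridMae),
                     gridOptimum = stats::setNames(gridOpt, colnames(jmat)),
                     refinedOptimum = stats::setNames(refined, colnames(jmat)),
                     nNearOptimal = length(near)))
}

#' Dihedral-scan sensitivity summary
#'
#' Per-coupling range (maximum minus minimum) over a dihedral scan;
#' the quantity used to decide which couplings are conformationally
#' informative.
#'
#' @param scanTable data.frame with a \code{phi} column and one
#'   numeric column per coupling (see [readPhiScan()],
#'   [simulatePhiScan()]).
#' @return named numeric vector of ranges, Hz.
#' @export
scanSensitivity <- function(scanTable) {
  stopifnot(is.data.frame(scanTable), "phi" %in% names(scanTable))
  if (nrow(scanTable) < 2L) stop("scan needs at least 2 points")
  cols <- setdiff(names(scanTable), "phi")
  vapply(scanTable[cols], function(v) max(v) - min(v), numeric(1))
}

#' Rank couplings by across-conformer spread
#'
#' Orders the couplings of a library by how strongly they separate
#' the conformers (max minus min of the calculated values across
#' conformers); ties and zero-spread couplings rank last.
#'
#' @param lib a [ConformerLibrary-class].
#' @return data.frame with columns \code{id} and \code{spread} (Hz),
#'   ordered by decreasing spread.
#' @export
rankCouplingInformativeness <- function(lib) {
  stopifnot(is(lib, "ConformerLibrary"))
  if (ncol(couplingMatrix(lib)) < 2L)
    stop("ranking needs at least 2 conformers")
  m <- couplingMatrix(lib)
  spread <- apply(m, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) max(v) - min(v) else 0
  })
  o <- order(spread, decreasing = TRUE)
  data.frame(id = rownames(m)[o], spread = unname(spread[o]),
             stringsAsFactors = FALSE)
}
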