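#' @import methods
NULL

#' Karplus-type parameter set
#'
#' Coefficients of a Karplus-type equation relating a vicinal coupling
#' constant to the intervening dihedral angle.  Two forms are supported:
#' the \code{basic} three-coefficient equation
#' \deqn{J(\theta) = A\cos^2\theta + B\cos\theta + C}
#' and the \code{extended} generalized (Haasnoot--Altona-type) equation
#' \deqn{J(\theta) = P_1\cos^2\theta + P_2\cos\theta + P_3 +
#'   \sum_i \lambda_i\,[P_4 + P_5\cos^2(\xi_i\theta + P_6|\lambda_i|)]}
#' in which each non-hydrogen substituent on the coupled H--C--C--H
#' fragment contributes a correction governed by its group
#' electronegativity difference \eqn{\lambda_i} (relative to hydrogen)
#' and an orientation sign \eqn{\xi_i \in \{+1,-1\}}.
#'
#' @slot form either \code{"basic"} or \code{"extended"}.
#' @slot coefficients named numeric; \code{A,B,C} (basic) or
#'   \code{P1..P6} (extended), all in Hz (the cosine arguments are in
#'   degrees).
#' @slot substituents data.frame with columns \code{lambda}
#'   (dimensionless electronegativity difference) and \code{xi}
#'   (orientation sign, +1 or -1); 0 to 4 rows, used only by the
#'   extended form.
#'
#' @seealso [karplusJ()], [basicKarplus()], [extendedKarplus()]
#' @export
setClass("KarplusParameterSet",
  representation(form = "character",
                 coefficients = "numeric",
                 substituents = "data.frame"),
  prototype(form = "basic",
            coefficients = c(A = 7, B = -1, C = 1),
            substituents = data.frame(lambda = numeric(0), xi = numeric(0))))

setValidity("KarplusParameterSet", function(object) {
  msg <- character(0)
  if (length(object@form) != 1L || !object@form %in% c("basic", "extended"))
    msg <- c(msg, "'form' must be \"basic\" or \"extended\"")
  need <- if (identical(object@form, "extended")) paste0("P", 1:6) else c("A", "B", "C")
  missing <- setdiff(need, names(object@coefficients))
  if (length(missing))
    msg <- c(msg, paste0("missing coefficient(s): ", paste(missing, collapse = ", ")))
  if (anyNA(object@coefficients[need]))
    msg <- c(msg, "coefficients must be finite")
  if (identical(object@form, "extended")) {
    s <- object@substituents
    if (!all(c("lambda", "xi") %in% names(s)))
      msg <- c(msg, "substituents must have columns 'lambda' and 'xi'")
    else {
      if (nrow(s) > 4L)
        msg <- c(msg, "at most 4 substituent entries are allowed")
      if (nrow(s) && !all(s$xi %in% c(-1, 1)))
        msg <- c(msg, "substituent 'xi' must be +1 or -1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Conformer geometry
#'
#' A labelled conformer together with the dihedral angle governing each
#' of its couplings.  Angles follow the IUPAC sign convention and are
#' normalized to the half-open interval (-180, 180] degrees.
#'
#' @slot label conformer label, e.g. \code{"4C1"}, \code{"1C4"},
#'   \code{"(R)-(-gauche)"}.
#' @slot dihedrals named numeric vector, degrees; names are canonical
#'   coupling identifiers (see [parseCouplingId()]).
#'
#' @export
setClass("ConformerGeometry",
  representation(label = "character", dihedrals = "numeric"),
  prototype(label = "conformer", dihedrals = numeric(0)))

setValidity("ConformerGeometry", function(object) {
  msg <- character(0)
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "'label' must be a single non-empty string")
  d <- object@dihedrals
  if (length(d)) {
    if (is.null(names(d)) || any(!nzchar(names(d))) || anyDuplicated(names(d)))
      msg <- c(msg, "dihedrals must carry unique coupling-identifier names")
    if (any(d <= -180 | d > 180, na.rm = TRUE))
      msg <- c(msg, "dihedrals must lie in (-180, 180] degrees")
  }
  if (length(msg)) msg else TRUE
})

#' Per-conformer coupling library
#'
#' Calculated (signed) coupling constants for each conformer of a
#' compound, together with conformer relative energies.  This is the
#' container the population fits consume; it emulates the per-conformer
#' coupling tables that quantum-chemical calculations produce.
#'
#' Relative energies are normalized on construction so that the most
#' stable conformer sits at 0 kcal/mol.  Couplings missing for a subset
#' of conformers are stored as \code{NA} and flagged.
#'
#' @slot compound compound identifier.
#' @slot couplings numeric matrix, rows = canonical coupling
#'   identifiers, columns = conformer labels; signed values in Hz.
#' @slot energies named numeric, relative energies in kcal/mol
#'   (minimum 0), one per conformer.
#'
#' @seealso [conformerLibrary()], [readConformerLibrary()],
#'   [fitPopulations()], [filterConformers()]
#' @export
setClass("ConformerLibrary",
  representation(compound = "character",
                 couplings = "matrix",
                 energies = "numeric"))

setValidity("ConformerLibrary", function(object) {
  msg <- character(0)
  if (length(object@compound) != 1L)
    msg <- c(msg, "'compound' must be a single string")
  m <- object@couplings
  if (!is.numeric(m)) msg <- c(msg, "'couplings' must be a numeric matrix")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "conformer labels (colnames) must be present and unique")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "coupling identifiers (rownames) must be present and unique")
  e <- object@energies
  if (length(e) != ncol(m) || !identical(names(e), colnames(m)))
    msg <- c(msg, "'energies' must be named identically to the conformer columns")
  else {
    if (anyNA(e) || any(!is.finite(e)))
      msg <- c(msg, "energies must be finite")
    else if (length(e) && abs(min(e)) > 1e-9)
      msg <- c(msg, "energies must be normalized (minimum 0 kcal/mol)")
  }
  if (length(msg)) msg else TRUE
})

#' Population fit result
#'
#' Conformer populations estimated from ensemble-averaged couplings,
#' with fit diagnostics.  Populations live on the probability simplex;
#' the objective is the mean absolute error (MAE, Hz) between each
#' experimental coupling magnitude and the absolute value of the
#' population-weighted sum of the calculated (signed) couplings.
#'
#' @slot populations named numeric fractions, sum 1.
#' @slot mae mean absolute error of the reported solution, Hz.
#' @slot residuals named numeric, per-coupling residuals (experimental
#'   minus model), Hz.
#' @slot degenerate TRUE when materially different population vectors
#'   fit the data essentially equally well; the reported vector is then
#'   the maximum-entropy member of the near-optimal set.
#' @slot couplingsUsed,couplingsExcluded canonical coupling identifiers.
#' @slot objective objective that was minimized ("mae" or "sse").
#' @slot details list of solver diagnostics (grid optimum, near-optimal
#'   set size, solver path, ...).
#'
#' @export
setClass("PopulationFit",
  representation(populations = "numeric",
                 mae = "numeric",
                 residuals = "numeric",
                 degenerate = "logical",
                 couplingsUsed = "character",
                 couplingsExcluded = "character",
                 objective = "character",
                 details = "list"),
  prototype(degenerate = FALSE, objective = "mae",
            couplingsExcluded = character(0), details = list()))

setValidity("PopulationFit", function(object) {
  msg <- character(0)
  p <- object@populations
  if (is.null(names(p)) || anyDuplicated(names(p)))
    msg <- c(msg, "populations must carry unique conformer names")
  if (any(p < -1e-9) || any(p > 1 + 1e-9))
    msg <- c(msg, "populations must lie in [0, 1]")
  if (length(p) && abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "populations must sum to 1 (within 1e-9)")
  if (length(object@mae) != 1L || object@mae < 0)
    msg <- c(msg, "'mae' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Two-state ring-conformer fit
#'
#' A [PopulationFit-class] restricted to the two pyranose chair states
#' \code{4C1} and \code{1C4}.  See [fitTwoState()].
#'
#' @export
setClass("TwoStateFit", contains = "PopulationFit")

setValidity("TwoStateFit", function(object) {
  if (!identical(sort(names(object@populations)), c("1C4", "4C1")))
    "populations must be named '4C1' and '1C4'" else TRUE
})

#' First-order kinetics fit
#'
#' Result of fitting the pseudo-first-order approach-to-equilibrium
#' model \eqn{f(t) = f_{eq}(1 - e^{-kt})} to a trace of product
#' fraction versus time.
#'
#' @slot k rate constant, 1/s.
#' @slot fEq equilibrium (plateau) fraction, in (0, 1].
#' @slot rmse root-mean-square residual of the fit.
#' @slot t99 time to reach 99 percent of \code{fEq}, seconds
#'   (\code{log(100)/k}).
#' @slot residuals per-point residuals.
#' @slot details solver diagnostics.
#'
#' @seealso [fitFirstOrder()], [timeToEquilibrium()]
#' @export
setClass("KineticsFit",
  representation(k = "numeric", fEq = "numeric", rmse = "numeric",
                 t99 = "numeric", residuals = "numeric", details = "list"),
  prototype(details = list()))

setValidity("KineticsFit", function(object) {
  msg <- character(0)
  if (length(object@k) != 1L || !is.finite(object@k) || object@k <= 0)
    msg <- c(msg, "'k' must be a single positive number")
  if (length(object@fEq) != 1L || object@fEq <= 0 || object@fEq > 1 + 1e-6)
    msg <- c(msg, "'fEq' must lie in (0, 1]")
  if (length(object@k) == 1L && is.finite(object@k) && object@k > 0 &&
      abs(object@t99 - log(100) / object@k) > 1e-6 * object@t99)
    msg <- c(msg, "'t99' must equal log(100)/k")
  if (length(msg)) msg else TRUE
})
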