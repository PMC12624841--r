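#' @include karplus.R
NULL

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Aglycone rotamer torsions (phi = O5-C1-N-Ci) and the six
## rotamer x nitrogen-configuration labels used for synthetic conformers.
.ROTAMER_ANGLES <- c("-gauche" = -60, "+gauche" = 60, "trans" = 180)

.conformerLabelSet <- function(n) {
  rot <- rep(names(.ROTAMER_ANGLES), each = 2L)
  cfg <- rep(c("R", "S"), 3L)
  labs <- sprintf("(%s)-(%s)", cfg, rot)
  if (n > length(labs))
    labs <- c(labs, sprintf("conf%d", seq_len(n - length(labs))))
  labs[seq_len(n)]
}

#' Default synthetic coupling model
#'
#' A per-coupling Karplus model for the redundant nitrogen-mediated
#' coupling set used by the synthetic generator.  Each entry carries a
#' basic Karplus parameter set and a phase offset (degrees) relative
#' to the aglycone torsion \eqn{\phi} = O5-C1-N-Ci, so that different
#' couplings peak at different rotamers -- the redundancy that makes
#' the ensemble deconvolution identifiable.  Curve amplitudes are
#' chosen to emulate the reported conformational sensitivities of the
#' real couplings (about 13 Hz for \eqn{^3J(NH,H1)} down to
#' near-constant phenyl-ring couplings); see the methods vignette.
#'
#' @return named list; each element has components \code{params}
#'   ([KarplusParameterSet-class]) and \code{phase} (degrees).
#' @export
defaultCouplingModel <- function() {
  mk <- function(A, B, C, phase)
    list(params = basicKarplus(A, B, C), phase = phase)
  list(
    "3J(NH,H1)" = mk(10.8, -2.2,  2.3, -120),
    "2J(N,H1)"  = mk( 5.6,  1.8, -3.0,    0),
    "3J(N,H2)"  = mk( 1.6, -0.4,  0.6,  -60),
    "1J(N,C1)"  = mk( 5.0, -1.0,  9.5,   60),
    "2J(N,C2)"  = mk( 3.4,  1.2,  1.5,  180),
    "3J(N,C3)"  = mk( 1.8,  0.5,  0.4,  120),
    "3J(N,C5)"  = mk( 1.2, -0.3,  0.7, -120),
    "1J(N,Ci)"  = mk( 0.6,  0.2, 13.5,    0)
  )
}

#' Simulate an ensemble-averaged coupling experiment
#'
#' Generates a synthetic conformer library together with a noisy
#' ensemble-averaged "experimental" coupling vector of known
#' ground-truth populations, emulating the statistical structure of a
#' redundant-coupling measurement: per-conformer couplings are Karplus
#' curves evaluated at the rotamer torsions (-60/+60/180, perturbed by
#' a small nitrogen-configuration shift and a seeded jitter), the
#' experimental value of coupling \eqn{i} is
#' \eqn{|\sum_c p_c J_{i,c} + \epsilon_i|} with
#' \eqn{\epsilon \sim N(0, \sigma)}, reported as a magnitude.
#'
#' @param nConformers number of conformers (2--6).
#' @param populations ground-truth simplex vector (length
#'   \code{nConformers}) or \code{"random"}.
#' @param couplingModel per-coupling model as from
#'   [defaultCouplingModel()] (its first \code{nCouplings} entries are
#'   used) or an explicit signed coupling matrix (rows = couplings,
#'   columns = conformers).
#' @param nCouplings number of couplings drawn from the model.
#' @param noiseSigma Gaussian noise s.d. on the signed ensemble
#'   average, Hz; default 0.3 (mid-range of typical fit residuals).
#' @param jitterSd s.d. (degrees) of the per-conformer torsion jitter.
#' @param configShift torsion offset (degrees) distinguishing the R
#'   and S nitrogen configurations.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param labels optional conformer labels of the form
#'   \code{"(R)-(-gauche)"} / \code{"(S)-(trans)"} etc.; the rotamer
#'   part sets each conformer's torsion.  Defaults to the standard
#'   rotamer-times-configuration label cycle.
#' @param compound compound tag for the library.
#' @param energyMax relative energies are drawn uniformly on
#'   \code{[0, energyMax]} kcal/mol (then min-shifted to 0).
#' @return list with elements \code{library}
#'   ([ConformerLibrary-class]), \code{experimental} (coupling record
#'   data.frame) and \code{truth} (list: populations, torsions, seed,
#'   noiseSigma).
#' @examples
#' sim <- simulateEnsemble(nConformers = 2, populations = c(0.81, 0.19),
#'                         noiseSigma = 0, seed = 1)
#' fitPopulations(sim$experimental, sim$library)
#' @export
simulateEnsemble <- function(nConformers = 4, populations = "random",
                             couplingModel = defaultCouplingModel(),
                             nCouplings = NULL, noiseSigma = 0.3,
                             jitterSd = 10, configShift = 12,
                             seed = NULL, labels = NULL,
                             compound = "synthetic", energyMax = 3) {
  stopifnot(nConformers >= 1L, nConformers <= 6L, noiseSigma >= 0)
  .withSeed(seed, {
    labs <- if (is.null(labels)) .conformerLabelSet(nConformers)
            else as.character(labels)
    if (length(labs) != nConformers || anyDuplicated(labs))
      stop("'labels' must be ", nConformers, " unique conformer labels")
    if (identical(populations, "random")) {
      p <- stats::rexp(nConformers)
      p <- p / sum(p)
    } else {
      p <- as.numeric(populations)
      if (length(p) != nConformers)
        stop("'populations' must have length ", nConformers)
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
        stop("'populations' must be a probability vector on the simplex")
    }

    if (is.matrix(couplingModel)) {
      jmat <- couplingModel
      if (ncol(jmat) != nConformers)
        stop("explicit coupling matrix must have one column per conformer")
      colnames(jmat) <- labs
      torsions <- rep(NA_real_, nConformers)
    } else {
      if (is.null(nCouplings)) nCouplings <- length(couplingModel)
      model <- couplingModel[seq_len(min(nCouplings, length(couplingModel)))]
      rot <- .ROTAMER_ANGLES[sub("^\\([RS]\\)-\\((.*)\\)$", "\\1", labs)]
      rot[is.na(rot)] <- stats::runif(sum(is.na(rot)), -180, 180)
      cfg <- ifelse(grepl("^\\(R\\)", labs), 1, -1)
      torsions <- normalizeAngle(rot + cfg * configShift +
                                 stats::rnorm(nConformers, 0, jitterSd))
      jmat <- sapply(seq_len(nConformers), function(c.)
        vapply(model, function(mdl)
          karplusJ(torsions[c.] + mdl$phase, mdl$params), numeric(1)))
      jmat <- matrix(jmat, nrow = length(model),
                     dimnames = list(names(model), labs))
    }

    energies <- stats::runif(nConformers, 0, energyMax)
    lib <- conformerLibrary(compound, jmat,
                            stats::setNames(energies, labs))

    signedAvg <- as.numeric(jmat %*% p)
    eps <- if (noiseSigma > 0) stats::rnorm(nrow(jmat), 0, noiseSigma) else 0
    jexp <- abs(signedAvg + eps)
    experimental <- data.frame(compound = compound,
                               id = rownames(couplingMatrix(lib)),
                               value = jexp, status = "ok",
                               stringsAsFactors = FALSE)
    list(library = lib, experimental = experimental,
         truth = list(populations = stats::setNames(p, labs),
                      torsions = stats::setNames(torsions, labs),
                      seed = seed, noiseSigma = noiseSigma))
  })
}

#' Simulate a dihedral scan of predicted couplings
#'
#' Evaluates each coupling model on a regular grid of the aglycone
#' torsion, emulating a theoretical dihedral scan with Karplus curves.
#'
#' @param couplingModel as in [simulateEnsemble()].
#' @param step grid step in degrees; must divide 360.  The scan runs
#'   over \eqn{\phi \in \{-180, -180+step, \ldots, 180-step\}}.
#' @return data.frame: \code{phi} plus one column per coupling.
#' @export
simulatePhiScan <- function(couplingModel = defaultCouplingModel(),
                            step = 20) {
  stopifnot(step > 0)
  if (360 %% step != 0) stop("'step' must divide 360")
  phi <- seq(-180, 180 - step, by = step)
  out <- data.frame(phi = phi)
  for (id in names(couplingModel)) {
    mdl <- couplingModel[[id]]
    out[[id]] <- karplusJ(phi + mdl$phase, mdl$params)
  }
  out
}

#' Simulate an approach-to-equilibrium kinetics trace
#'
#' \eqn{f(t) = f_{eq}(1 - e^{-kt}) + \epsilon}, clipped to
#' \eqn{[0, 1]}; deterministic at fixed seed.
#'
#' @param k rate constant, 1/s (> 0).
#' @param fEq equilibrium fraction, in (0, 1].
#' @param times sample times, seconds.
#' @param noiseSigma Gaussian noise s.d. on the fractions.
#' @param seed integer seed.
#' @return data.frame with columns \code{time_s}, \code{fraction}.
#' @export
simulateKinetics <- function(k, fEq, times, noiseSigma = 0, seed = NULL) {
  stopifnot(is.numeric(k), length(k) == 1L, k > 0,
            fEq > 0, fEq <= 1, noiseSigma >= 0)
  .withSeed(seed, {
    f <- fEq * (1 - exp(-k * times))
    if (noiseSigma > 0) f <- f + stats::rnorm(length(times), 0, noiseSigma)
    data.frame(time_s = times, fraction = pmin(1, pmax(0, f)))
  })
}
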