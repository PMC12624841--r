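#' @include AllClasses.R
NULL

#' Normalize a dihedral angle
#'
#' Maps angles onto the IUPAC half-open interval (-180, 180] degrees;
#' -180 maps to +180.  Idempotent and vectorized.
#'
#' @param theta numeric, degrees.
#' @return numeric of the same length, in (-180, 180].
#' @examples
#' normalizeAngle(c(-180, 270, 360, 65))
#' @export
normalizeAngle <- function(theta) {
  stopifnot(is.numeric(theta))
  w <- theta %% 360
  ifelse(w > 180, w - 360, ifelse(w == -180 | w == 180, 180, w))
}

#' Construct a basic Karplus parameter set
#'
#' @param A,B,C coefficients in Hz of \eqn{J = A\cos^2\theta +
#'   B\cos\theta + C}.  The defaults are a generic vicinal H,H set.
#' @return a [KarplusParameterSet-class].
#' @examples
#' karplusJ(180, basicKarplus(7, -1, 1))
#' @export
basicKarplus <- function(A = 7.76, B = -1.10, C = 1.40) {
  new("KarplusParameterSet", form = "basic",
      coefficients = c(A = A, B = B, C = C))
}

#' Construct an extended (Haasnoot--Altona-type) Karplus parameter set
#'
#' The generalized vicinal-coupling equation with substituent
#' electronegativity corrections,
#' \eqn{J = P_1\cos^2\theta + P_2\cos\theta + P_3 + \sum_i
#' \lambda_i [P_4 + P_5 \cos^2(\xi_i\theta + P_6 |\lambda_i|)]}.
#' The default coefficients are the classic generalized H-C-C-H set;
#' they can be overridden per coupling through the registry file (see
#' [karplusRegistry()]).
#'
#' @param substituents data.frame with columns \code{lambda}
#'   (electronegativity difference vs. H, dimensionless) and \code{xi}
#'   (+1 or -1, substituent orientation); 0--4 rows.
#' @param P1,P2,P3,P4,P5,P6 equation coefficients.
#' @return a [KarplusParameterSet-class].
#' @export
extendedKarplus <- function(substituents = data.frame(lambda = numeric(0),
                                                      xi = numeric(0)),
                            P1 = 13.70, P2 = -0.73, P3 = 0,
                            P4 = 0.56, P5 = -2.47, P6 = 16.9) {
  new("KarplusParameterSet", form = "extended",
      coefficients = c(P1 = P1, P2 = P2, P3 = P3, P4 = P4, P5 = P5, P6 = P6),
      substituents = as.data.frame(substituents))
}

#' Evaluate a Karplus-type equation
#'
#' Predicts a conformer-pure three-bond coupling from the dihedral
#' angle.  Vectorized over \code{theta}.
#'
#' @param theta dihedral angle(s), degrees (any range; normalized
#'   internally).
#' @param params a [KarplusParameterSet-class].
#' @return predicted coupling(s), Hz.
#' @examples
#' p <- basicKarplus(7, -1, 1)
#' karplusJ(c(60, 180), p)
#' @export
karplusJ <- function(theta, params) {
  stopifnot(is(params, "KarplusParameterSet"))
  validObject(params)
  th <- normalizeAngle(theta) * pi / 180
  co <- params@coefficients
  if (identical(params@form, "basic"))
    return(unname(co["A"] * cos(th)^2 + co["B"] * cos(th) + co["C"]))
  j <- co["P1"] * cos(th)^2 + co["P2"] * cos(th) + co["P3"]
  s <- params@substituents
  if (nrow(s)) {
    p6 <- co["P6"] * pi / 180
    for (i in seq_len(nrow(s))) {
      lam <- s$lambda[i]
      j <- j + lam * (co["P4"] +
        co["P5"] * cos(s$xi[i] * th + p6 * abs(lam))^2)
    }
  }
  unname(j)
}

#' Load the Karplus parameter registry
#'
#' The registry is a JSON file holding (i) a generic basic parameter
#' set, (ii) the generalized extended set, and (iii) the group
#' electronegativity differences (Huggins scale, corrected for beta
#' substituents) used when building substituted H-C-C-H fragments.  A
#' versioned default ships with the package; pass \code{file} to
#' override any entry.
#'
#' @param file path to a registry JSON file, or \code{NULL} for the
#'   packaged default.
#' @return a list with elements \code{basic} and \code{extended}
#'   ([KarplusParameterSet-class] objects) and \code{lambda} (named
#'   numeric electronegativity table).
#' @export
karplusRegistry <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "karplus_params.json", package = "Jdeconv",
                        mustWork = TRUE)
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  bs <- raw$basic_default
  ex <- raw$extended_default
  if (is.null(bs) || is.null(ex) || is.null(raw$lambda))
    stop("registry file must define 'basic_default', 'extended_default' and 'lambda'")
  list(
    basic = basicKarplus(A = bs$A, B = bs$B, C = bs$C),
    extended = extendedKarplus(P1 = ex$P1, P2 = ex$P2, P3 = ex$P3,
                               P4 = ex$P4, P5 = ex$P5, P6 = ex$P6),
    lambda = unlist(raw$lambda)
  )
}

#' Predict the couplings of one conformer
#'
#' Applies [karplusJ()] to every dihedral of a conformer geometry,
#' looking the parameter set for each coupling up in a registry.
#'
#' @param geometry a [ConformerGeometry-class].
#' @param paramRegistry named list of [KarplusParameterSet-class]
#'   objects keyed by canonical coupling identifier.
#' @return data.frame with columns \code{id}, \code{value} (Hz) and
#'   \code{status} (\code{"ok"}), one row per mapped coupling.
#' @export
predictConformerCouplings <- function(geometry, paramRegistry) {
  stopifnot(is(geometry, "ConformerGeometry"))
  validObject(geometry)
  ids <- names(geometry@dihedrals)
  if (!length(ids))
    return(data.frame(id = character(0), value = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  missing <- setdiff(ids, names(paramRegistry))
  if (length(missing))
    stop("no Karplus parameter set for coupling(s): ",
         paste(missing, collapse = ", "))
  vals <- vapply(ids, function(id)
    karplusJ(geometry@dihedrals[[id]], paramRegistry[[id]]), numeric(1))
  data.frame(id = ids, value = unname(vals), status = "ok",
             stringsAsFactors = FALSE)
}
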