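#' @include karplus.R
NULL

## ---- idealized chair geometry -------------------------------------------
##
## Six ring atoms on a circle of unit radius, alternating z = +/- sqrt(2)/8.
## This is the exact ideal chair: all bond angles tetrahedral, all ring
## torsions +/-60 degrees.  Exocyclic (axial/equatorial) directions are the
## tetrahedral completion of the two ring bonds at each atom, so H-C-C-H
## and substituent torsions come out exactly staggered (+/-60, 180).

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

.torsionDeg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## ring atom order: O5, C1, C2, C3, C4, C5 (indices 1..6)
.chairRing <- function(invert = FALSE) {
  b <- sqrt(2) / 8
  z <- rep(c(1, -1), 3) * b
  if (invert) z <- -z
  cbind(cos((0:5) * pi / 3), sin((0:5) * pi / 3), z)
}

## axial and equatorial unit directions at ring atom i
.exoDirections <- function(P, i) {
  u <- P[(i - 2) %% 6 + 1, ] - P[i, ]
  v <- P[i %% 6 + 1, ] - P[i, ]
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  s <- u + v; s <- s / sqrt(sum(s^2))
  p <- (1 / 3) / sqrt((1 + sum(u * v)) / 2)  # gives d.u = d.v = cos 109.47
  q <- sqrt(max(0, 1 - p^2))
  n <- .cross3(u, v); n <- n / sqrt(sum(n^2))
  d1 <- -p * s + q * n
  d2 <- -p * s - q * n
  if (abs(d1[3]) >= abs(d2[3])) list(ax = d1, eq = d2) else list(ax = d2, eq = d1)
}

## ---- pyranose templates --------------------------------------------------
##
## Each template records, for the 4C1 chair, whether the heteroatom
## substituent at each ring carbon is axial or equatorial; the 1C4 chair
## swaps every assignment (chair inversion), which preserves all relative
## configurations.  Pentoses carry two C5 protons: H5' is the proton that
## is axial in 4C1 (the convention matching the larger 3J(H4,H5') observed
## for 4C1 beta-xylopyranosylamine), H5 the equatorial one.

.PYRANOSE_TEMPLATES <- list(
  "5a" = list(sugar = "alpha-D-glucopyranosylamine", type = "hexose",
              cls = c(C1 = "ax", C2 = "eq", C3 = "eq", C4 = "eq")),
  "5b" = list(sugar = "beta-D-glucopyranosylamine", type = "hexose",
              cls = c(C1 = "eq", C2 = "eq", C3 = "eq", C4 = "eq")),
  "6a" = list(sugar = "alpha-D-mannopyranosylamine", type = "hexose",
              cls = c(C1 = "ax", C2 = "ax", C3 = "eq", C4 = "eq")),
  "6b" = list(sugar = "beta-D-mannopyranosylamine", type = "hexose",
              cls = c(C1 = "eq", C2 = "ax", C3 = "eq", C4 = "eq")),
  "7a" = list(sugar = "alpha-D-xylopyranosylamine", type = "pentose",
              cls = c(C1 = "ax", C2 = "eq", C3 = "eq", C4 = "eq")),
  "7b" = list(sugar = "beta-D-xylopyranosylamine", type = "pentose",
              cls = c(C1 = "eq", C2 = "eq", C3 = "eq", C4 = "eq")),
  "8a" = list(sugar = "alpha-D-lyxopyranosylamine", type = "pentose",
              cls = c(C1 = "ax", C2 = "ax", C3 = "eq", C4 = "eq")),
  "8b" = list(sugar = "beta-D-lyxopyranosylamine", type = "pentose",
              cls = c(C1 = "eq", C2 = "ax", C3 = "eq", C4 = "eq"))
)

#' Compounds with built-in pyranose chair templates
#'
#' @return character vector of template identifiers.
#' @export
pyranoseCompounds <- function() names(.PYRANOSE_TEMPLATES)

## orientation sign xi of a substituent: the substituent sits staggered at
## psi = phi(H,H) +/- 120; xi follows the offset sign.  The overall sign
## convention is anchored on reproducing the experimental pattern of
## ax/eq couplings in pyranoses (see the methods vignette).
.xiFromOffset <- function(psi, phi) {
  delta <- normalizeAngle(psi - phi)
  if (abs(abs(delta) - 120) > 25)
    stop("substituent not staggered (offset ", round(delta, 1), " deg)")
  if (delta > 0) -1 else 1
}

## Build one chair of a template compound: dihedral map plus per-coupling
## substituent descriptions for the extended Karplus equation.
.buildChair <- function(compound, chair = c("4C1", "1C4"),
                        registry = karplusRegistry()) {
  chair <- match.arg(chair)
  tpl <- .PYRANOSE_TEMPLATES[[compound]]
  if (is.null(tpl))
    stop("unknown compound '", compound, "'; see pyranoseCompounds()")
  lam <- registry$lambda
  P <- .chairRing(invert = identical(chair, "1C4"))
  slots <- lapply(1:6, function(i) if (i == 1) NULL else .exoDirections(P, i))
  flip <- function(cl) if (identical(chair, "1C4")) c(ax = "eq", eq = "ax")[[cl]] else cl

  ## exocyclic atom positions per carbon: list(H = ..., S = ..., lambdaKey)
  carbons <- vector("list", 6)
  for (i in 2:5) {  # C1..C4 carry one heteroatom + one H
    cname <- paste0("C", i - 1)
    scls <- flip(tpl$cls[[cname]])
    hcls <- if (scls == "ax") "eq" else "ax"
    carbons[[i]] <- list(
      H = P[i, ] + slots[[i]][[hcls]],
      S = P[i, ] + slots[[i]][[scls]],
      lambdaKey = if (i == 2) "N_anilino" else "OH")
  }
  if (identical(tpl$type, "pentose")) {
    hax <- flip("ax"); heq <- if (hax == "ax") "eq" else "ax"
    carbons[[6]] <- list(H = P[6, ] + slots[[6]][[heq]],      # H5
                         Hp = P[6, ] + slots[[6]][[hax]],     # H5'
                         S = NULL, lambdaKey = NULL)
  } else {
    scls <- flip("eq"); hcls <- if (scls == "ax") "eq" else "ax"
    carbons[[6]] <- list(H = P[6, ] + slots[[6]][[hcls]],
                         S = P[6, ] + slots[[6]][[scls]],
                         lambdaKey = "C_exo")
  }

  ## ring 3J(H,H) fragments: consecutive carbon pairs
  pairs <- list(
    list(id = "3J(H1,H2)", a = 2L, b = 3L),
    list(id = "3J(H2,H3)", a = 3L, b = 4L),
    list(id = "3J(H3,H4)", a = 4L, b = 5L),
    list(id = "3J(H4,H5)", a = 5L, b = 6L, proton = "H"))
  if (identical(tpl$type, "pentose"))
    pairs <- c(pairs, list(list(id = "3J(H4,H5')", a = 5L, b = 6L,
                                proton = "Hp")))

  dihedrals <- numeric(0)
  paramSets <- list()
  for (pr in pairs) {
    a <- pr$a; b <- pr$b
    Ha <- carbons[[a]]$H
    Hb <- if (is.null(pr$proton)) carbons[[b]]$H else carbons[[b]][[pr$proton]]
    phi <- .torsionDeg(Ha, P[a, ], P[b, ], Hb)

    subst <- list()
    addSub <- function(pos, key, onA) {
      psi <- if (onA) .torsionDeg(pos, P[a, ], P[b, ], Hb)
             else     .torsionDeg(Ha, P[a, ], P[b, ], pos)
      subst[[length(subst) + 1L]] <<- c(lambda = unname(lam[[key]]),
                                        xi = .xiFromOffset(psi, phi))
    }
    ## substituents on the front carbon: other ring neighbour + heteroatom
    prevIdx <- (a - 2) %% 6 + 1
    addSub(P[prevIdx, ], if (prevIdx == 1) "O_ring" else "C_ring", onA = TRUE)
    if (!is.null(carbons[[a]]$S))
      addSub(carbons[[a]]$S, carbons[[a]]$lambdaKey, onA = TRUE)
    ## substituents on the back carbon
    nextIdx <- b %% 6 + 1
    addSub(P[nextIdx, ], if (nextIdx == 1) "O_ring" else "C_ring", onA = FALSE)
    if (!is.null(carbons[[b]]$S))
      addSub(carbons[[b]]$S, carbons[[b]]$lambdaKey, onA = FALSE)
    if (identical(tpl$type, "pentose") && b == 6L) {
      other <- if (is.null(pr$proton) || pr$proton == "H") "Hp" else "H"
      addSub(carbons[[6]][[other]], "H", onA = FALSE)  # lambda 0, inert
    }

    sdf <- as.data.frame(do.call(rbind, subst))
    sdf <- sdf[sdf$lambda != 0, , drop = FALSE]
    ex <- registry$extended@coefficients
    dihedrals[[pr$id]] <- normalizeAngle(phi)
    paramSets[[pr$id]] <- extendedKarplus(substituents = sdf,
      P1 = ex[["P1"]], P2 = ex[["P2"]], P3 = ex[["P3"]],
      P4 = ex[["P4"]], P5 = ex[["P5"]], P6 = ex[["P6"]])
  }

  list(geometry = new("ConformerGeometry", label = chair, dihedrals = dihedrals),
       paramSets = paramSets, template = tpl)
}

#' Idealized chair geometry of a template compound
#'
#' Builds the ring-proton dihedral map of one chair state of a built-in
#' pyranosylamine template from an exact ideal chair (tetrahedral
#' angles, ring torsions of 60 degrees).
#'
#' @param compound template identifier (see [pyranoseCompounds()]).
#' @param chair \code{"4C1"} or \code{"1C4"}.
#' @param registry parameter registry, see [karplusRegistry()].
#' @return a [ConformerGeometry-class]; the matching per-coupling
#'   extended Karplus parameter sets (substituent electronegativities
#'   and orientation signs read off the same geometry) are attached as
#'   attribute \code{"paramSets"}.
#' @export
pyranoseChairGeometry <- function(compound, chair = c("4C1", "1C4"),
                                  registry = karplusRegistry()) {
  built <- .buildChair(compound, chair, registry)
  g <- built$geometry
  attr(g, "paramSets") <- built$paramSets
  g
}

#' Karplus-predicted chair endpoint couplings
#'
#' Predicts the conformer-pure ring \eqn{^3J(H,H)} couplings of both
#' chair states of a template compound with the extended Karplus
#' equation evaluated on the idealized chair geometries.  These are the
#' endpoint vectors the two-state ring fit consumes.
#'
#' @inheritParams pyranoseChairGeometry
#' @return list with named numeric vectors \code{j4C1} and \code{j1C4}
#'   (Hz, keyed by canonical coupling identifier).
#' @examples
#' pyranoseEndpoints("7b")
#' @export
pyranoseEndpoints <- function(compound, registry = karplusRegistry()) {
  out <- lapply(c("4C1", "1C4"), function(ch) {
    built <- .buildChair(compound, ch, registry)
    pred <- predictConformerCouplings(built$geometry, built$paramSets)
    stats::setNames(pred$value, pred$id)
  })
  list(j4C1 = out[[1]], j1C4 = out[[2]])
}

#' Canonical dihedral of an idealized chair proton pair
#'
#' Returns the idealized H-C-C-H dihedral for a ring proton pair:
#' 180 degrees for an axial-axial pair, 60 degrees otherwise.  The
#' \code{relation} argument states the pair's relation in the 4C1
#' reference chair; chair inversion (\code{ringState = "1C4"}) swaps
#' axial and equatorial.  When a template \code{compound} is given, the
#' refined value from the exact ideal-chair geometry is returned
#' instead.
#'
#' @param ringState \code{"4C1"} or \code{"1C4"}.
#' @param protonPair canonical coupling identifier, e.g.
#'   \code{"3J(H3,H4)"}.
#' @param relation \code{"ax-ax"}, \code{"ax-eq"} or \code{"eq-eq"},
#'   stated for the 4C1 chair; may be omitted when \code{compound} is
#'   given.
#' @param compound optional template identifier.
#' @return dihedral angle, degrees, in (-180, 180].
#' @examples
#' canonicalDihedral("4C1", "3J(H3,H4)", "ax-ax")   # 180
#' canonicalDihedral("1C4", "3J(H3,H4)", "ax-ax")   # chair flip -> 60
#' @export
canonicalDihedral <- function(ringState = c("4C1", "1C4"), protonPair,
                              relation = NULL, compound = NULL) {
  ringState <- match.arg(ringState)
  if (!is.null(compound)) {
    g <- pyranoseChairGeometry(compound, ringState)
    d <- dihedrals(g)
    id <- formatCouplingId(parseCouplingId(protonPair))
    if (!id %in% names(d))
      stop("pair '", id, "' not in the ", compound, " template")
    return(unname(d[[id]]))
  }
  if (is.null(relation))
    stop("either 'relation' or 'compound' must be supplied")
  relation <- match.arg(relation, c("ax-ax", "ax-eq", "eq-eq"))
  if (identical(ringState, "1C4")) {
    relation <- chartr("axeq", "eqax", relation)  # ax<->eq swap
    relation <- c("ax-ax" = "ax-ax", "eq-ax" = "ax-eq", "ax-eq" = "ax-eq",
                  "eq-eq" = "eq-eq")[[relation]]
  }
  if (identical(relation, "ax-ax")) 180 else 60
}
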