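#' @include AllClasses.R
NULL

## gas constant in kcal/(mol K)
.R_KCAL <- 1.987204e-3

.checkEnergyRecords <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("label", "group", "gibbs")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("energy records must have column(s): ", paste(miss, collapse = ", "))
  if (!nrow(records)) stop("no energy records")
  if (anyDuplicated(records$label)) stop("duplicate conformer labels")
  if (anyNA(records$gibbs) || any(!is.finite(records$gibbs)))
    stop("Gibbs energies must be finite")
  records
}

#' Boltzmann populations from free energies
#'
#' \eqn{p_i \propto \exp(-(G_i - G_{min})/(RT))} with
#' \eqn{R = 1.987204\times 10^{-3}} kcal/(mol K).
#'
#' @param gibbs named numeric vector of Gibbs energies, kcal/mol (any
#'   common offset; only differences matter).
#' @param temperature absolute temperature, K; default 298.15 (ambient
#'   solution NMR).
#' @return named numeric fractions summing to 1.
#' @examples
#' boltzmannPopulations(c(a = 0, b = 0.1))   # ~0.542 / 0.458
#' @export
boltzmannPopulations <- function(gibbs, temperature = 298.15) {
  stopifnot(is.numeric(gibbs), length(gibbs) >= 1L,
            all(is.finite(gibbs)))
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("'temperature' must be a single positive number (K)")
  w <- exp(-(gibbs - min(gibbs)) / (.R_KCAL * temperature))
  w / sum(w)
}

#' Per-group Boltzmann populations
#'
#' Two grouping conventions for conformers that fall into groups (for
#' instance the two anomers of a sugar):
#' \describe{
#'   \item{\code{scope = "global"}}{all conformers enter one Boltzmann
#'     distribution and the per-conformer populations are then summed
#'     by group -- the procedure for total anomer ratios.}
#'   \item{\code{scope = "within_group"}}{each group is normalized
#'     separately -- the weighting used for per-group property
#'     averaging.}
#' }
#'
#' @param records data.frame with columns \code{label}, \code{group},
#'   \code{gibbs} (kcal/mol) and optionally property columns.
#' @param temperature K.
#' @param scope \code{"global"} or \code{"within_group"}.
#' @return data.frame \code{label}, \code{group}, \code{fraction};
#'   under \code{"global"} scope the per-group totals are attached as
#'   attribute \code{"groupTotals"} (named numeric).
#' @export
groupPopulations <- function(records, temperature = 298.15,
                             scope = c("global", "within_group")) {
  scope <- match.arg(scope)
  records <- .checkEnergyRecords(records)
  out <- data.frame(label = records$label, group = records$group,
                    fraction = NA_real_, stringsAsFactors = FALSE)
  if (scope == "global") {
    out$fraction <- as.numeric(boltzmannPopulations(records$gibbs, temperature))
    totals <- tapply(out$fraction, out$group, sum)
    attr(out, "groupTotals") <- stats::setNames(as.numeric(totals),
                                                names(totals))
  } else {
    for (g in unique(records$group)) {
      sel <- records$group == g
      out$fraction[sel] <- as.numeric(
        boltzmannPopulations(records$gibbs[sel], temperature))
    }
  }
  out
}

#' Boltzmann-averaged property per group
#'
#' Weighted average \eqn{\sum_i p_i v_i} of a property over the
#' conformers of each group, with within-group Boltzmann weights by
#' default (the convention for per-anomer property averages).
#'
#' @param records energy record data.frame carrying the property as a
#'   numeric column.
#' @param property property column name (e.g. \code{"dipole"}).
#' @param temperature K.
#' @param scope weighting scope, normally \code{"within_group"}.
#' @return named numeric, one averaged value per group.
#' @export
averageProperty <- function(records, property, temperature = 298.15,
                            scope = c("within_group", "global")) {
  scope <- match.arg(scope)
  records <- .checkEnergyRecords(records)
  if (!property %in% names(records))
    stop("no property column '", property, "'")
  v <- records[[property]]
  if (anyNA(v))
    stop("property '", property, "' missing for record(s): ",
         paste(records$label[is.na(v)], collapse = ", "))
  pops <- groupPopulations(records, temperature, scope)
  groups <- unique(records$group)
  vapply(stats::setNames(groups, groups), function(g) {
    sel <- pops$group == g
    p <- pops$fraction[sel]
    sum(p * v[sel]) / sum(p)   # sum(p) = 1 within-group; renormalizes global
  }, numeric(1))
}
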