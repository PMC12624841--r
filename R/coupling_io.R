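#' @include AllClasses.R
NULL

## Nucleus ordering used when canonicalizing a coupling identifier:
## the amide proton NH first, then nitrogen, then other protons, then
## carbons (the order coupling tables conventionally print).
.nucleusRank <- function(label) {
  el <- substr(label, 1L, 1L)
  ifelse(label == "NH", 0L,
    ifelse(el == "N", 1L, ifelse(el == "H", 2L, ifelse(el == "C", 3L, 4L))))
}

#' Parse a coupling identifier
#'
#' The identifier grammar is \code{"nJ(a,b)"}: \code{n} the number of
#' intervening bonds (>= 1), \code{a} and \code{b} atom labels such as
#' \code{H1}, \code{H5'}, \code{NH}, \code{N}, \code{C1}, \code{Ci}.
#' Isotope prefixes (\code{15N}, \code{13C1}) are stripped to
#' element+position; a Unicode prime is normalized to an ASCII
#' apostrophe.  The canonical form orders the pair NH, then N, then H,
#' then C (within a class by position), and round-trips through
#' [formatCouplingId()].
#'
#' @param text identifier string(s).
#' @return for a single string, a list with elements \code{nBonds},
#'   \code{nucleusA}, \code{nucleusB}; for several, a list of such
#'   lists.
#' @examples
#' parseCouplingId("3J(H1,H2)")
#' parseCouplingId("1J(15N,C1)")  # isotope prefix stripped
#' @export
parseCouplingId <- function(text) {
  if (length(text) != 1L) return(lapply(text, parseCouplingId))
  stopifnot(is.character(text))
  s <- gsub("′", "'", trimws(text))
  m <- regexec("^([0-9]+)J\\(([^,()]+),([^,()]+)\\)$", s)[[1]]
  if (m[1] == -1) {
    ## locate the first offending position for the error message
    pos <- regexpr("[^0-9A-Za-z'(),J]", s)
    stop("malformed coupling identifier '", text, "'",
         if (pos > 0) paste0(" (unexpected character at position ", pos, ")")
         else " (expected \"nJ(a,b)\" with two nuclei)")
  }
  parts <- regmatches(s, regexec("^([0-9]+)J\\(([^,()]+),([^,()]+)\\)$", s))[[1]]
  n <- as.integer(parts[2])
  if (n < 1L) stop("bond count must be >= 1 in '", text, "'")
  nuc <- vapply(parts[3:4], function(a) {
    a <- trimws(a)
    a <- sub("^[0-9]+(?=[A-Za-z])", "", a, perl = TRUE)  # isotope prefix
    if (!grepl("^[A-Za-z]+[0-9]*'?$", a))
      stop("malformed nucleus label '", a, "' in '", text, "'")
    a
  }, character(1), USE.NAMES = FALSE)
  r <- .nucleusRank(nuc)
  o <- order(r, nuc)
  list(nBonds = n, nucleusA = nuc[o[1]], nucleusB = nuc[o[2]])
}

#' Format a coupling identifier canonically
#'
#' @param id a parsed identifier (list from [parseCouplingId()]) or a
#'   string to be re-canonicalized.
#' @return canonical identifier string.
#' @export
formatCouplingId <- function(id) {
  if (is.character(id)) id <- parseCouplingId(id)
  if (!is.null(id$nBonds))
    return(sprintf("%dJ(%s,%s)", id$nBonds, id$nucleusA, id$nucleusB))
  vapply(id, formatCouplingId, character(1))
}

.canonicalIds <- function(x) vapply(x, function(s) formatCouplingId(s), character(1), USE.NAMES = FALSE)

#' Read an experimental coupling table
#'
#' Reads a comma-separated table with columns \code{compound},
#' \code{coupling} and \code{value} (one row per compound/coupling).
#' Cells \code{"nd"} (not determined) and \code{"b"} (broad signal)
#' become records with the matching status and no numeric value; a
#' printed \code{0} is kept as a measured 0 Hz.  Experimental values
#' are magnitudes and must be non-negative.  Malformed numeric cells
#' and duplicate (compound, coupling) rows are rejected.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{compound}, \code{id}
#'   (canonical identifier), \code{value} (Hz, \code{NA} when flagged)
#'   and \code{status} (\code{ok}/\code{nd}/\code{broad}).
#' @export
readCouplingTable <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  if (!nrow(raw))
    return(data.frame(compound = character(0), id = character(0),
                      value = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  need <- c("compound", "coupling", "value")
  if (!all(need %in% names(raw)))
    stop("coupling table must have columns: ", paste(need, collapse = ", "))
  status <- rep("ok", nrow(raw))
  v <- trimws(raw$value)
  status[v == "nd"] <- "nd"
  status[v == "b"] <- "broad"
  value <- rep(NA_real_, nrow(raw))
  numRows <- status == "ok"
  parsed <- suppressWarnings(as.numeric(v[numRows]))
  if (anyNA(parsed)) {
    bad <- v[numRows][is.na(parsed)]
    stop("non-numeric value cell(s) (not 'nd'/'b'): ",
         paste(unique(bad), collapse = ", "))
  }
  if (any(parsed < 0))
    stop("experimental couplings are magnitudes; negative value found")
  value[numRows] <- parsed
  id <- .canonicalIds(raw$coupling)
  key <- paste(raw$compound, id)
  if (anyDuplicated(key))
    stop("duplicate (compound, coupling) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  data.frame(compound = raw$compound, id = id, value = value,
             status = status, stringsAsFactors = FALSE)
}

#' Write an experimental coupling table
#'
#' Inverse of [readCouplingTable()]; status flags are written back as
#' their cell codes so that write/read round-trips.
#'
#' @param records data.frame as returned by [readCouplingTable()].
#' @param path output CSV path.
#' @export
writeCouplingTable <- function(records, path) {
  v <- ifelse(records$status == "nd", "nd",
        ifelse(records$status == "broad", "b",
               vapply(records$value, function(x) format(x, digits = 15),
                      character(1))))
  utils::write.csv(data.frame(compound = records$compound,
                              coupling = records$id, value = v),
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract the usable couplings of one compound as a named vector
#'
#' Keeps records with status \code{ok} (measured values, including
#' measured zeros); \code{nd}/\code{broad} records are dropped.
#'
#' @param records coupling record data.frame.
#' @param compound compound identifier to select.
#' @return named numeric vector (Hz, magnitudes).
#' @export
couplingVector <- function(records, compound) {
  sel <- records$compound == compound & records$status == "ok"
  stats::setNames(records$value[sel], records$id[sel])
}

#' Construct a conformer library
#'
#' @param compound compound identifier.
#' @param couplings numeric matrix (rows = coupling identifiers,
#'   columns = conformer labels) of signed calculated couplings, Hz.
#' @param energies numeric relative energies (kcal/mol), one per
#'   conformer; normalized so the minimum is 0.
#' @return a [ConformerLibrary-class].
#' @export
conformerLibrary <- function(compound, couplings, energies) {
  couplings <- as.matrix(couplings)
  rownames(couplings) <- .canonicalIds(rownames(couplings))
  if (is.null(names(energies))) names(energies) <- colnames(couplings)
  energies <- energies[colnames(couplings)]
  energies <- energies - min(energies)
  if (anyNA(couplings))
    warning("conformer library has missing couplings for some conformers")
  new("ConformerLibrary", compound = compound, couplings = couplings,
      energies = energies)
}

#' Read / write a conformer library
#'
#' Libraries are stored as structured JSON:
#' \preformatted{
#' {"compound": "6b",
#'  "conformers": [
#'    {"label": "(R)-(-gauche)", "relative_energy": 0.0,
#'     "couplings": {"3J(NH,H1)": 10.9, "1J(N,C1)": -12.4}}, ...]}
#' }
#' Energies are re-normalized to minimum 0 on read; conformers with
#' mismatched coupling sets are merged over the union of identifiers
#' with a warning, missing entries flagged as \code{NA}.
#'
#' @param path JSON file path.
#' @return [readConformerLibrary()] returns a
#'   [ConformerLibrary-class]; [writeConformerLibrary()] returns the
#'   path, invisibly.
#' @export
readConformerLibrary <- function(path) {
  raw <- jsonlite::read_json(path)
  if (is.null(raw$compound) || is.null(raw$conformers))
    stop("library file must have 'compound' and 'conformers'")
  labs <- vapply(raw$conformers, function(cf) cf$label, character(1))
  if (anyDuplicated(labs))
    stop("duplicate conformer label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  ids <- lapply(raw$conformers, function(cf) .canonicalIds(names(cf$couplings)))
  all_ids <- Reduce(union, ids)
  if (!all(vapply(ids, function(i) setequal(i, all_ids), logical(1))))
    warning("conformers do not share a common coupling set; ",
            "taking the union and flagging missing entries")
  m <- matrix(NA_real_, length(all_ids), length(labs),
              dimnames = list(all_ids, labs))
  for (j in seq_along(raw$conformers)) {
    cj <- raw$conformers[[j]]$couplings
    m[.canonicalIds(names(cj)), j] <- unlist(cj)
  }
  en <- vapply(raw$conformers, function(cf) as.numeric(cf$relative_energy),
               numeric(1))
  conformerLibrary(raw$compound, m, stats::setNames(en, labs))
}

#' @rdname readConformerLibrary
#' @param lib a [ConformerLibrary-class].
#' @export
writeConformerLibrary <- function(lib, path) {
  stopifnot(is(lib, "ConformerLibrary"))
  m <- couplingMatrix(lib)
  conf <- lapply(colnames(m), function(lab) {
    cpl <- m[, lab]
    cpl <- cpl[!is.na(cpl)]
    list(label = lab,
         relative_energy = unname(relativeEnergies(lib)[lab]),
         couplings = as.list(cpl))
  })
  jsonlite::write_json(list(compound = compoundName(lib), conformers = conf),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a dihedral-scan table
#'
#' CSV with a \code{phi} column (degrees) followed by one numeric
#' column per coupling.
#'
#' @param path CSV file path.
#' @return data.frame with \code{phi} plus coupling columns (canonical
#'   identifiers).
#' @export
readPhiScan <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"phi" %in% names(d)) stop("scan table must have a 'phi' column")
  if (!all(vapply(d, is.numeric, logical(1))))
    stop("scan table cells must all be numeric")
  names(d)[-1] <- .canonicalIds(names(d)[-1])
  d
}

#' Write / read a fit report
#'
#' Serializes a [PopulationFit-class] (or [TwoStateFit-class]) as
#' structured JSON.
#'
#' @param fit a [PopulationFit-class].
#' @param path JSON path.
#' @export
writeFitReport <- function(fit, path) {
  stopifnot(is(fit, "PopulationFit"))
  jsonlite::write_json(list(
    class = class(fit)[1],
    populations = as.list(populations(fit)),
    mae = maeHz(fit),
    residuals = as.list(residuals(fit)),
    degenerate = isDegenerate(fit),
    couplings_used = couplingsUsed(fit),
    couplings_excluded = couplingsExcluded(fit),
    objective = fit@objective), path,
    auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname writeFitReport
#' @export
readFitReport <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- if (identical(raw$class, "TwoStateFit")) "TwoStateFit" else "PopulationFit"
  new(cls,
      populations = unlist(raw$populations),
      mae = raw$mae,
      residuals = if (length(raw$residuals)) unlist(raw$residuals) else numeric(0),
      degenerate = isTRUE(raw$degenerate),
      couplingsUsed = as.character(raw$couplings_used),
      couplingsExcluded = as.character(raw$couplings_excluded),
      objective = raw$objective %||% "mae")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
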