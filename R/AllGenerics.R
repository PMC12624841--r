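#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the fit and library classes; use these
#' rather than reaching into slots.
#'
#' @param object an object of the appropriate class.
#' @param ... passed to methods.
#' @return the corresponding component (see the method signatures).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("populations", function(object, ...) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("maeHz", function(object, ...) standardGeneric("maeHz"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(object, ...) standardGeneric("isDegenerate"))

#' @rdname accessors
#' @export
setGeneric("couplingsUsed", function(object, ...) standardGeneric("couplingsUsed"))

#' @rdname accessors
#' @export
setGeneric("couplingsExcluded", function(object, ...) standardGeneric("couplingsExcluded"))

#' @rdname accessors
#' @export
setGeneric("compoundName", function(object, ...) standardGeneric("compoundName"))

#' @rdname accessors
#' @export
setGeneric("conformerLabels", function(object, ...) standardGeneric("conformerLabels"))

#' @rdname accessors
#' @export
setGeneric("relativeEnergies", function(object, ...) standardGeneric("relativeEnergies"))

#' @rdname accessors
#' @export
setGeneric("couplingMatrix", function(object, ...) standardGeneric("couplingMatrix"))

#' @rdname accessors
#' @export
setGeneric("couplingIds", function(object, ...) standardGeneric("couplingIds"))

#' @rdname accessors
#' @export
setGeneric("fraction4C1", function(object, ...) standardGeneric("fraction4C1"))

#' @rdname accessors
#' @export
setGeneric("fraction1C4", function(object, ...) standardGeneric("fraction1C4"))

#' @rdname accessors
#' @export
setGeneric("rateConstant", function(object, ...) standardGeneric("rateConstant"))

#' @rdname accessors
#' @export
setGeneric("plateauFraction", function(object, ...) standardGeneric("plateauFraction"))

#' @rdname accessors
#' @export
setGeneric("dihedrals", function(object, ...) standardGeneric("dihedrals"))
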