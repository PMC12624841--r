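#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @aliases populations,PopulationFit-method
setMethod("populations", "PopulationFit", function(object, ...) object@populations)

#' @rdname accessors
setMethod("maeHz", "PopulationFit", function(object, ...) object@mae)

#' @rdname accessors
setMethod("isDegenerate", "PopulationFit", function(object, ...) object@degenerate)

#' @rdname accessors
setMethod("couplingsUsed", "PopulationFit", function(object, ...) object@couplingsUsed)

#' @rdname accessors
setMethod("couplingsExcluded", "PopulationFit", function(object, ...) object@couplingsExcluded)

#' @importFrom stats residuals
#' @rdname accessors
#' @param object a fitted object.
#' @exportMethod residuals
setMethod("residuals", "PopulationFit",
          function(object, ...) object@residuals)

#' @rdname accessors
setMethod("fraction4C1", "TwoStateFit", function(object, ...)
  unname(object@populations["4C1"]))

#' @rdname accessors
setMethod("fraction1C4", "TwoStateFit", function(object, ...)
  unname(object@populations["1C4"]))

#' @rdname accessors
setMethod("compoundName", "ConformerLibrary", function(object, ...) object@compound)

#' @rdname accessors
setMethod("conformerLabels", "ConformerLibrary", function(object, ...)
  colnames(object@couplings))

#' @rdname accessors
setMethod("relativeEnergies", "ConformerLibrary", function(object, ...) object@energies)

#' @rdname accessors
setMethod("couplingMatrix", "ConformerLibrary", function(object, ...) object@couplings)

#' @rdname accessors
setMethod("couplingIds", "ConformerLibrary", function(object, ...)
  rownames(object@couplings))

#' @rdname accessors
setMethod("rateConstant", "KineticsFit", function(object, ...) object@k)

#' @rdname accessors
setMethod("plateauFraction", "KineticsFit", function(object, ...) object@fEq)

#' @rdname accessors
#' @exportMethod residuals
setMethod("residuals", "KineticsFit", function(object, ...) object@residuals)

#' @rdname accessors
setMethod("dihedrals", "ConformerGeometry", function(object, ...) object@dihedrals)

setMethod("show", "KarplusParameterSet", function(object) {
  cat("KarplusParameterSet (", object@form, " form)\n", sep = "")
  co <- object@coefficients
  cat("  ", paste(names(co), format(co, digits = 4), sep = "=", collapse = "  "),
      "\n", sep = "")
  if (identical(object@form, "extended") && nrow(object@substituents))
    cat("  substituents: ",
        paste(sprintf("(lambda=%.3g, xi=%+d)", object@substituents$lambda,
                      as.integer(object@substituents$xi)), collapse = " "),
        "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "ConformerGeometry", function(object) {
  cat("ConformerGeometry \"", object@label, "\" with ",
      length(object@dihedrals), " dihedral(s)\n", sep = "")
  if (length(object@dihedrals)) {
    d <- object@dihedrals
    cat(paste0("  ", names(d), ": ", sprintf("%.1f", d), " deg",
               collapse = "\n"), "\n")
  }
  invisible(NULL)
})

setMethod("show", "ConformerLibrary", function(object) {
  cat("ConformerLibrary for ", object@compound, ": ",
      ncol(object@couplings), " conformer(s) x ",
      nrow(object@couplings), " coupling(s)\n", sep = "")
  e <- object@energies
  cat("  conformers: ",
      paste(sprintf("%s (%.2f kcal/mol)", names(e), e), collapse = ", "),
      "\n", sep = "")
  if (anyNA(object@couplings))
    cat("  note: ", sum(is.na(object@couplings)),
        " missing coupling value(s)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "PopulationFit", function(object) {
  cat(class(object), " (objective: ", object@objective, ")\n", sep = "")
  p <- object@populations
  cat("  populations: ",
      paste(sprintf("%s = %.1f%%", names(p), 100 * p), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  MAE = %.3f Hz over %d coupling(s)%s\n", object@mae,
              length(object@couplingsUsed),
              if (isTRUE(object@degenerate)) "  [degenerate]" else ""))
  invisible(NULL)
})

setMethod("show", "KineticsFit", function(object) {
  cat("KineticsFit: k = ", format(object@k, digits = 4), " 1/s, f_eq = ",
      sprintf("%.3f", object@fEq), "\n", sep = "")
  cat(sprintf("  rmse = %.4g; t99 = %.4g s (%.2f h)\n", object@rmse,
              object@t99, object@t99 / 3600))
  invisible(NULL)
})
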