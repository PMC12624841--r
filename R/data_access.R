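#' @include coupling_io.R
NULL

#' Bundled experimental coupling table
#'
#' The experimental ring, nitrogen-proton and nitrogen-carbon
#' couplings of the eight N-phenyl glycosylamines (compounds 5a--8b;
#' methanol-d4 solution), re-typed from the published table.  Cells
#' flagged \code{nd} (signal overlap) or \code{b} (broad signal) carry
#' the matching status and no numeric value.
#'
#' @return coupling record data.frame (see [readCouplingTable()]).
#' @examples
#' head(glycosylamineCouplings())
#' @export
glycosylamineCouplings <- function() {
  readCouplingTable(system.file("extdata", "glycosylamine_couplings.csv",
                                package = "Jdeconv", mustWork = TRUE))
}
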