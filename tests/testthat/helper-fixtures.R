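# Shared fixture builders; everything is generated in code.

# tiny two-conformer library with well separated coupling profiles
tinyLibrary <- function(compound = "toy") {
  m <- cbind("A" = c(10.5, -3.2, 1.0, 5.8),
             "B" = c(2.1, 4.4, -0.5, 1.2))
  rownames(m) <- c("3J(NH,H1)", "2J(N,H1)", "3J(N,H2)", "1J(N,C1)")
  conformerLibrary(compound, m, c(A = 0.4, B = 0))
}

# exact ensemble-average magnitudes for a library and populations
ensembleAverage <- function(lib, p) {
  abs(as.numeric(couplingMatrix(lib) %*% p))
}

asRecords <- function(values, compound = "toy") {
  data.frame(compound = compound, id = names(values),
             value = unname(values), status = "ok",
             stringsAsFactors = FALSE)
}

writeTempCsv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# brute-force MAE minimizer on a fine two-conformer grid (independent
# of the package solver; used as an oracle)
bruteTwoConformerMae <- function(jexp, jmat, step = 1e-3) {
  xs <- seq(0, 1, by = step)
  vals <- vapply(xs, function(x) {
    mean(abs(jexp - abs(jmat %*% c(x, 1 - x))))
  }, numeric(1))
  xs[which.min(vals)]
}
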