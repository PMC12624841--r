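test_that("coupling identifier grammar parses, strips isotopes, canonicalizes", {
  p <- parseCouplingId("3J(H1,H2)")
  expect_equal(p$nBonds, 3L)
  expect_equal(p$nucleusA, "H1")
  expect_equal(p$nucleusB, "H2")

  p2 <- parseCouplingId("1J(15N,C1)")
  expect_equal(p2$nucleusA, "N")      # isotope prefix stripped
  expect_equal(p2$nucleusB, "C1")
  expect_equal(formatCouplingId(p2), "1J(N,C1)")

  # NH sorts first; N before H before C; unicode prime normalized
  expect_equal(formatCouplingId("3J(H1,NH)"), "3J(NH,H1)")
  expect_equal(formatCouplingId("3J(H2,15N)"), "3J(N,H2)")
  expect_equal(formatCouplingId("3J(H5′,H4)"), "3J(H4,H5')")

  # round trip is stable
  ids <- c("3J(NH,H1)", "1J(N,C1)", "3J(H4,H5')", "2J(N,Co)")
  expect_equal(vapply(ids, formatCouplingId, character(1), USE.NAMES = FALSE),
               ids)

  expect_error(parseCouplingId("J(H1)"), "malformed")
  expect_error(parseCouplingId("3J(H1)"), "malformed")
  expect_error(parseCouplingId("0J(H1,H2)"), ">= 1")
})

test_that("coupling tables read flags, zeros and reject bad cells", {
  f <- writeTempCsv(c(
    'compound,coupling,value',
    '5b,"3J(H1,H2)",8.7',
    '8b,"3J(NH,H1)",nd',
    '7a,"3J(15N,C3)",b',
    '5a,"3J(15N,C3)",0'))
  tab <- readCouplingTable(f)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$value[tab$compound == "5b"], 8.7)
  expect_equal(tab$status[tab$compound == "8b"], "nd")
  expect_true(is.na(tab$value[tab$compound == "8b"]))
  expect_equal(tab$status[tab$compound == "7a"], "broad")
  # a printed 0 is a measured zero, not a flag
  expect_equal(tab$value[tab$compound == "5a"], 0)
  expect_equal(tab$status[tab$compound == "5a"], "ok")
  # measured zero is kept by couplingVector, nd is not
  expect_equal(unname(couplingVector(tab, "5a")), 0)
  expect_length(couplingVector(tab, "8b"), 0L)

  bad <- writeTempCsv(c('compound,coupling,value', '5b,"3J(H1,H2)",oops'))
  expect_error(readCouplingTable(bad), "non-numeric")
  dup <- writeTempCsv(c('compound,coupling,value',
                        '5b,"3J(H1,H2)",8.7', '5b,"3J(H1,H2)",8.6'))
  expect_error(readCouplingTable(dup), "duplicate")
  neg <- writeTempCsv(c('compound,coupling,value', '5b,"3J(H1,H2)",-2'))
  expect_error(readCouplingTable(neg), "magnitude")

  empty <- writeTempCsv('compound,coupling,value')
  expect_equal(nrow(readCouplingTable(empty)), 0L)
})

test_that("coupling table write/read round-trips including flags", {
  tab <- glycosylamineCouplings()
  f <- tempfile(fileext = ".csv")
  writeCouplingTable(tab, f)
  back <- readCouplingTable(f)
  expect_equal(back, tab)
})

test_that("the bundled experimental table matches spot checks", {
  tab <- glycosylamineCouplings()
  expect_equal(unname(couplingVector(tab, "5b")["3J(H1,H2)"]), 8.7)
  expect_equal(tab$status[tab$compound == "8b" & tab$id == "3J(NH,H1)"], "nd")
  expect_equal(unname(couplingVector(tab, "5a")["3J(N,C3)"]), 0)
  expect_equal(unname(couplingVector(tab, "8a")["3J(H4,H5')"]), 3.3)
})

test_that("conformer libraries normalize energies and round-trip exactly", {
  m <- cbind(X = c(1.25, -0.5), Y = c(3.7, 2.2))
  rownames(m) <- c("3J(NH,H1)", "1J(15N,C1)")
  lib <- conformerLibrary("demo", m, c(X = 3.2, Y = 4.0))
  expect_equal(unname(relativeEnergies(lib)), c(0, 0.8))   # min-shifted
  expect_equal(couplingIds(lib), c("3J(NH,H1)", "1J(N,C1)"))  # canonicalized

  f <- tempfile(fileext = ".json")
  writeConformerLibrary(lib, f)
  back <- readConformerLibrary(f)
  expect_identical(couplingMatrix(back), couplingMatrix(lib))
  expect_identical(relativeEnergies(back), relativeEnergies(lib))
  expect_identical(compoundName(back), "demo")
})

test_that("mismatched conformer coupling sets warn and take the union", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    compound = "demo",
    conformers = list(
      list(label = "A", relative_energy = 0,
           couplings = list("3J(NH,H1)" = 10, "1J(N,C1)" = 12)),
      list(label = "B", relative_energy = 1,
           couplings = list("3J(NH,H1)" = 2)))),
    f, auto_unbox = TRUE)
  ws <- capture_warnings(lib <- readConformerLibrary(f))
  expect_true(any(grepl("union", ws)))          # mismatch -> union warning
  expect_true(any(grepl("missing couplings", ws)))
  expect_true(is.na(couplingMatrix(lib)["1J(N,C1)", "B"]))

  jsonlite::write_json(list(
    compound = "demo",
    conformers = list(
      list(label = "A", relative_energy = 0, couplings = list(x = 1)),
      list(label = "A", relative_energy = 1, couplings = list(x = 2)))),
    f, auto_unbox = TRUE)
  expect_error(suppressWarnings(readConformerLibrary(f)), "duplicate")
})

test_that("fit reports serialize and deserialize", {
  fit <- fitTwoState(c("3J(H1,H2)" = 5), c("3J(H1,H2)" = 8),
                     c("3J(H1,H2)" = 2))
  f <- tempfile(fileext = ".json")
  writeFitReport(fit, f)
  back <- readFitReport(f)
  expect_s4_class(back, "TwoStateFit")
  expect_equal(populations(back), populations(fit))
  expect_equal(maeHz(back), maeHz(fit))
})
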