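test_that("angle normalization maps onto (-180, 180] and is idempotent", {
  expect_equal(normalizeAngle(-180), 180)
  expect_equal(normalizeAngle(180), 180)
  expect_equal(normalizeAngle(270), -90)
  expect_equal(normalizeAngle(360), 0)
  th <- seq(-720, 720, by = 7.3)
  w <- normalizeAngle(th)
  expect_true(all(w > -180 & w <= 180))
  expect_equal(normalizeAngle(w), w)
  # same angle modulo 360 after normalization
  expect_equal((w - th) %% 360, rep(0, length(th)))
})

test_that("basic Karplus equation reproduces direct substitution", {
  p <- basicKarplus(7, -1, 1)
  expect_equal(karplusJ(90, p), 1.0)            # cos 90 = 0 forces J = C
  expect_equal(karplusJ(180, p), 7 + 1 + 1)     # cos^2 = 1, cos = -1
  expect_equal(karplusJ(60, p), 7 * 0.25 - 0.5 + 1)
  expect_equal(karplusJ(60, p), karplusJ(-60, p))  # cos is even
})

test_that("extended form with no substituent weight equals the basic form", {
  subs <- data.frame(lambda = c(0, 0), xi = c(1, -1))
  ext <- extendedKarplus(substituents = subs, P1 = 7, P2 = -1, P3 = 1)
  bas <- basicKarplus(7, -1, 1)
  th <- seq(-180, 180, by = 15)
  expect_equal(karplusJ(th, ext), karplusJ(th, bas))
})

test_that("extended substituent term matches a hand-written evaluation", {
  subs <- data.frame(lambda = c(1.3, 0.4), xi = c(1, -1))
  ext <- extendedKarplus(substituents = subs)
  manual <- function(th) {
    t <- th * pi / 180
    13.70 * cos(t)^2 - 0.73 * cos(t) +
      1.3 * (0.56 - 2.47 * cos( t + 16.9 * 1.3 * pi / 180)^2) +
      0.4 * (0.56 - 2.47 * cos(-t + 16.9 * 0.4 * pi / 180)^2)
  }
  for (th in c(-170, -60, 0, 55, 180))
    expect_equal(karplusJ(th, ext), manual(th), tolerance = 1e-12)
})

test_that("basic-form output respects the |A|+|B|+|C| bound and evenness", {
  set.seed(11)
  for (rep in 1:20) {
    co <- stats::runif(3, -10, 10)
    p <- basicKarplus(co[1], co[2], co[3])
    th <- stats::runif(50, -180, 180)
    expect_true(all(abs(karplusJ(th, p)) <= sum(abs(co)) + 1e-12))
    expect_equal(karplusJ(th, p), karplusJ(-th, p))
  }
})

test_that("extended-form bound includes the substituent contribution", {
  set.seed(12)
  subs <- data.frame(lambda = c(1.3, 0.79), xi = c(1, -1))
  p <- extendedKarplus(substituents = subs)
  th <- stats::runif(200, -180, 180)
  bound <- 13.70 + 0.73 + 0 + sum(abs(subs$lambda)) * (0.56 + 2.47)
  expect_true(all(abs(karplusJ(th, p)) <= bound + 1e-12))
  # mirror symmetry: negating the angle and all orientation signs
  # leaves the coupling unchanged
  p2 <- extendedKarplus(substituents = data.frame(lambda = c(1.3, 0.4),
                                                  xi = c(1, -1)))
  p2m <- extendedKarplus(substituents = data.frame(lambda = c(1.3, 0.4),
                                                   xi = c(-1, 1)))
  expect_equal(karplusJ(th, p2), karplusJ(-th, p2m))
  # with the phase term switched off (P6 = 0) the xi = +1 form is even
  p3 <- extendedKarplus(substituents = data.frame(lambda = c(1.3, 0.4),
                                                  xi = c(1, 1)), P6 = 0)
  expect_equal(karplusJ(th, p3), karplusJ(-th, p3))
})

test_that("incomplete parameter sets are rejected", {
  expect_error(new("KarplusParameterSet", form = "basic",
                   coefficients = c(A = 1, B = 2)), "missing coefficient")
  expect_error(new("KarplusParameterSet", form = "extended",
                   coefficients = c(P1 = 1)), "missing coefficient")
  expect_error(extendedKarplus(substituents = data.frame(lambda = 1, xi = 2)),
               "xi")
})

test_that("predictConformerCouplings composes elementwise karplusJ calls", {
  reg <- list("3J(H1,H2)" = basicKarplus(7, -1, 1),
              "3J(H2,H3)" = basicKarplus(9, -0.5, 0.3))
  g <- new("ConformerGeometry", label = "test",
           dihedrals = c("3J(H1,H2)" = 180, "3J(H2,H3)" = 60))
  pred <- predictConformerCouplings(g, reg)
  expect_equal(nrow(pred), 2L)
  expect_equal(pred$value[1], karplusJ(180, reg[["3J(H1,H2)"]]))
  expect_equal(pred$value[2], karplusJ(60, reg[["3J(H2,H3)"]]))

  empty <- new("ConformerGeometry", label = "none")
  expect_equal(nrow(predictConformerCouplings(empty, reg)), 0L)

  g2 <- new("ConformerGeometry", label = "bad",
            dihedrals = c("3J(H3,H4)" = 60))
  expect_error(predictConformerCouplings(g2, reg), "3J\\(H3,H4\\)")
})

test_that("beta-xylose template couplings equal manual closed-form values", {
  # independent oracle: hand substitution of the extended equation at the
  # idealized diaxial torsion, with the template's substituent lambdas
  reg <- karplusRegistry()
  ep <- pyranoseEndpoints("7b", reg)
  lam <- reg$lambda
  corr180 <- function(l) l * (0.56 - 2.47 * cos((180 + 16.9 * l) * pi / 180)^2)
  # H2-C2-C3-H3 diaxial: substituents C1, O2 (on C2) and C4, O3 (on C3)
  jManual <- 13.70 - 0.73 * cos(pi) * -1 + 0 +  # cos(180) = -1 -> +0.73
    corr180(lam[["C_ring"]]) + corr180(lam[["OH"]]) +
    corr180(lam[["C_ring"]]) + corr180(lam[["OH"]])
  # note: P2*cos(180) = (-0.73)(-1) = +0.73
  jManual <- 13.70 + 0.73 +
    2 * corr180(lam[["C_ring"]]) + 2 * corr180(lam[["OH"]])
  expect_equal(unname(ep$j4C1[["3J(H2,H3)"]]), unname(jManual),
               tolerance = 1e-10)
})
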