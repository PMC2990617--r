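# Forward-model correctness: closed-form evolution against numerical ODE
# oracles, conservation, linearity, and the discrete-RF acquisition train.

test_that("closed-form evolution reproduces the decoupled and identity limits", {
  p <- ExchangeParameters(kFwd = 0, kRev = 0, r1Sub = 0.05, r1Prod = 0.1,
                          m0Sub = 2, m0Prod = 0)
  out <- evolveClosedForm(p, c(0, 5, 30))
  expect_equal(out$mzSub, 2 * exp(-0.05 * c(0, 5, 30)))
  expect_equal(out$mzProd, rep(0, 3))

  pid <- ExchangeParameters(kFwd = 0, kRev = 0, r1Sub = 0, r1Prod = 0,
                            m0Sub = 1.5, m0Prod = 0.5)
  out <- evolveClosedForm(pid, c(0, 1, 100))
  expect_equal(out$mzSub, rep(1.5, 3))
  expect_equal(out$mzProd, rep(0.5, 3))

  expect_error(evolveClosedForm(p, -1), "t must be")
})

test_that("closed-form evolution matches fixed-step RK4 integration", {
  set.seed(42)
  for (i in 1:4) {
    kf <- runif(1, 0.001, 0.3); kr <- runif(1, 0, 0.1)
    r1s <- runif(1, 0.01, 0.1); r1p <- runif(1, 0.01, 0.1)
    m0 <- c(runif(1, 0.5, 5), runif(1, 0, 1))
    p <- ExchangeParameters(kf, kr, r1s, r1p, m0[1], m0[2])
    got <- evolveClosedForm(p, 10)
    want <- rk4Evolve(kf, kr, r1s, r1p, m0, 10, h = 2e-4)
    expect_equal(c(got$mzSub, got$mzProd), want, tolerance = 1e-6)
  }
})

test_that("degenerate (repeated-eigenvalue) systems use the limiting form", {
  # equal eigenvalues via kRev = 0 and r1Prod = kFwd + r1Sub:
  # M_p(t) = e^(lambda t) (m0p + kFwd t m0s)
  kf <- 0.05; r1s <- 0.02
  p <- ExchangeParameters(kFwd = kf, kRev = 0, r1Sub = r1s,
                          r1Prod = kf + r1s, m0Sub = 3, m0Prod = 0.2)
  tt <- c(0, 1, 10, 60)
  out <- evolveClosedForm(p, tt)
  lam <- -(kf + r1s)
  expect_equal(out$mzSub, 3 * exp(lam * tt), tolerance = 1e-10)
  expect_equal(out$mzProd, exp(lam * tt) * (0.2 + kf * tt * 3),
               tolerance = 1e-10)
})

test_that("unidirectional exchange matches the textbook A->B closed form", {
  kf <- 0.075; r1s <- 1 / 30; r1p <- 1 / 25
  p <- ExchangeParameters(kFwd = kf, r1Sub = r1s, r1Prod = r1p, m0Sub = 1)
  tt <- seq(0, 120, by = 7)
  out <- evolveClosedForm(p, tt)
  a <- kf + r1s
  expect_equal(out$mzSub, exp(-a * tt), tolerance = 1e-12)
  expect_equal(out$mzProd, kf / (a - r1p) * (exp(-r1p * tt) - exp(-a * tt)),
               tolerance = 1e-10)
})

test_that("total magnetisation is conserved without relaxation or RF", {
  set.seed(7)
  for (i in 1:10) {
    p <- ExchangeParameters(kFwd = runif(1, 0, 0.5), kRev = runif(1, 0, 0.5),
                            r1Sub = 0, r1Prod = 0,
                            m0Sub = runif(1, 0.1, 10), m0Prod = runif(1, 0, 5))
    tt <- runif(5, 0, 300)
    out <- evolveClosedForm(p, tt)
    expect_equal(out$mzSub + out$mzProd, rep(p@m0Sub + p@m0Prod, 5),
                 tolerance = 1e-10)
  }
})

test_that("acquisition train matches a brute-force small-step simulation", {
  p <- ExchangeParameters(kFwd = 0.075, kRev = 0.02, r1Sub = 1 / 30,
                          r1Prod = 1 / 28, m0Sub = 75, m0Prod = 0)
  sch <- AcquisitionScheme(6, 1, 40L)
  got <- simulateAcquisition(p, sch)
  want <- eulerAcquire(0.075, 0.02, 1 / 30, 1 / 28, c(75, 0), 6, 1, 40L,
                       h = 5e-5)
  expect_equal(got@times, want$times)
  expect_equal(got@signalSub, want$signalSub, tolerance = 1e-4)
  expect_equal(got@signalProd, want$signalProd, tolerance = 1e-4)
})

test_that("acquisition output is linear in the initial magnetisations", {
  sch <- tumourScheme()
  p1 <- ExchangeParameters(kFwd = 0.075, m0Sub = 1, m0Prod = 0.1)
  p2 <- ExchangeParameters(kFwd = 0.075, m0Sub = 7, m0Prod = 0.7)
  t1 <- simulateAcquisition(p1, sch)
  t2 <- simulateAcquisition(p2, sch)
  expect_equal(t2@signalSub, 7 * t1@signalSub, tolerance = 1e-12)
  expect_equal(t2@signalProd, 7 * t1@signalProd, tolerance = 1e-12)
})

test_that("no exchange and no initial product gives zero product signal", {
  tr <- simulateAcquisition(ExchangeParameters(kFwd = 0, m0Sub = 1),
                            cellScheme())
  expect_equal(tr@signalProd, rep(0, 240))
})

test_that("product signal rises to a single interior maximum then falls", {
  tr <- simulateAcquisition(ExchangeParameters(kFwd = 0.075),
                            AcquisitionScheme(5, 1, 128L))
  d <- diff(tr@signalProd)
  expect_equal(sum(diff(sign(d)) != 0), 1)  # one sign change: rise then fall
  imax <- which.max(tr@signalProd)
  expect_gt(imax, 1)
  expect_lt(imax, 128)
})

test_that("effective-decay RF mode tracks the discrete-pulse simulation", {
  p <- ExchangeParameters(kFwd = 0.075)
  sch <- tumourScheme()
  disc <- simulateAcquisition(p, sch)
  eff <- simulateAcquisition(p, sch, rfMode = "effective")
  # same decay budget per TR, but sampling before vs after the cosine loss
  # differs by at most one pulse's cos factor
  ratio <- eff@signalSub / disc@signalSub
  expect_true(all(ratio > cos(5 * pi / 180)^2 & ratio < 1 / cos(5 * pi / 180)^2))
})

test_that("scheme invariants reject unusable acquisitions", {
  expect_error(AcquisitionScheme(90, 1, 128), "flipAngle")
  expect_error(AcquisitionScheme(5, 0, 128), "repetitionTime")
  expect_error(AcquisitionScheme(5, 1, 1), "nTransients")
  expect_error(AcquisitionScheme(5, 1, 10, excludedIndices = 11),
               "excludedIndices")
})
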