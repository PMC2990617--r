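# Synthetic-cohort generator: reproducibility, cytometry mixture and
# gating semantics, NADH scaling, null calibration of the group test, and
# the necrosis -> k_F linearity the fumarate readout rests on.

test_that("a cohort is a pure function of its seed", {
  c1 <- generateCohort(cellSchedule(), nPerGroup = 2, seed = 7,
                       nCytometryEvents = 200)
  c2 <- generateCohort(cellSchedule(), nPerGroup = 2, seed = 7,
                       nCytometryEvents = 200)
  expect_identical(lapply(c1, function(s) s@pyruvate@signalSub),
                   lapply(c2, function(s) s@pyruvate@signalSub))
  expect_identical(lapply(c1, function(s) s@cytometry),
                   lapply(c2, function(s) s@cytometry))
  c3 <- generateCohort(cellSchedule(), nPerGroup = 2, seed = 8,
                       nCytometryEvents = 200)
  expect_false(identical(c1[[1]]@pyruvate@signalSub,
                         c3[[1]]@pyruvate@signalSub))
})

test_that("per-sample true rates follow the schedule scaling", {
  coh <- generateCohort(cellSchedule(), nPerGroup = 4, seed = 3,
                        nCytometryEvents = 0)
  kp <- vapply(coh, function(s) s@trueKp, numeric(1))
  tp <- vapply(coh, function(s) s@timepoint, numeric(1))
  # 10% CV: group means land near kpBase * kpScale
  expect_equal(mean(kp[tp == 0]), 0.075, tolerance = 0.15)
  expect_equal(mean(kp[tp == 96]), 0.075 * 0.28, tolerance = 0.2)
  expect_true(all(vapply(coh, function(s) s@trueKf[1], numeric(1))[tp == 0] == 0))
})

test_that("an all-viable population gates entirely double-negative", {
  sched <- TreatmentSchedule(0, 1, 0, 1, 0, 0)  # weights (1, 0, 0)
  ev <- generateCytometry(sched, 0, nEvents = 5000, seed = 2)
  g <- gateEvents(ev)
  expect_equal(unname(g["viable"]), 1)
  expect_equal(unname(g["necrotic"]), 0)
})

test_that("gated fractions recover the mixture weights within sampling error", {
  sched <- TreatmentSchedule(c(0, 72), c(1, 1), c(0, 0), c(1, 1),
                             c(0.05, 0.25), c(0.02, 0.15))
  ev <- generateCytometry(sched, 72, nEvents = 20000, seed = 5)
  g <- gateEvents(ev)
  # binomial sd at n = 20000 is ~0.3 points; 1.5 points is ~5 sd
  expect_lt(abs(g[["viable"]] - 0.60), 0.015)
  expect_lt(abs(g[["apoptotic"]] - 0.25), 0.015)
  expect_lt(abs(g[["necrotic"]] - 0.15), 0.015)
})

test_that("quadrant gating matches a hand-built one-event-per-quadrant set", {
  thr <- defaultGateThresholds()
  lo <- thr[["annexin"]] / 10; hi <- thr[["annexin"]] * 10
  ev <- data.frame(annexin = c(lo, hi, hi, lo),
                   sytox = c(lo, lo, hi, hi),
                   nadh = rep(1, 4))
  g <- gateEvents(ev, thr)
  expect_equal(unname(g), c(0.25, 0.25, 0.25, 0.25))
  expect_error(gateEvents(ev[0, ], thr), "empty")
  expect_error(gateEvents(ev, c(annexin = -1, sytox = 1)), "positive")
})

test_that("NADH autofluorescence scales exactly with the schedule", {
  ev0 <- generateCytometry(cellSchedule(), 0, nEvents = 20000, seed = 21)
  ev72 <- generateCytometry(cellSchedule(), 72, nEvents = 20000, seed = 22)
  drop <- percentChange(mean(ev0$nadh), mean(ev72$nadh))
  expect_equal(drop, 77, tolerance = 2 / 77)
})

test_that("a null treatment effect keeps the group test calibrated", {
  nullSched <- TreatmentSchedule(c(0, 72), c(1, 1), c(0, 0), c(1, 1),
                                 c(0.05, 0.05), c(0.02, 0.02))
  nSig <- 0
  nRep <- 50
  for (r in seq_len(nRep)) {
    coh <- generateCohort(nullSched, nPerGroup = 4, seed = 1000 + r,
                          nCytometryEvents = 0)
    fits <- fitCohort(coh, cellScheme(), which = "pyruvate")
    p <- rankSumTest(fits$khatP[fits$timepoint == 0],
                     fits$khatP[fits$timepoint == 72])$p.value
    nSig <- nSig + (p < 0.05)
  }
  # exact 4v4 Mann-Whitney rejects at most 2/70 of null cohorts; >= 90%
  # of replicates must be non-significant
  expect_gte(nRep - nSig, 0.9 * nRep)
})

test_that("fitted k_F tracks the necrotic fraction linearly", {
  necFrac <- seq(0.05, 0.5, length.out = 6)
  alpha <- 1.2e-3  # s^-1 per unit necrotic fraction
  sched <- TreatmentSchedule(c(0, seq_along(necFrac) * 24),
                             rep(1, 7), c(0, alpha * necFrac),
                             rep(1, 7), rep(0, 7), c(0, necFrac))
  meanKf <- vapply(necFrac, function(nf) {
    tp <- sched@timepoints[match(nf, sched@necroticFrac)]
    coh <- generateCohort(sched, nPerGroup = 3, seed = round(1e4 * nf),
                          nCytometryEvents = 0, timepoints = tp)
    fits <- fitCohort(coh, cellScheme(), which = "fumarate")
    mean(fits$khatF)
  }, numeric(1))
  expect_gt(linearR2(necFrac, meanKf), 0.9)
})
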