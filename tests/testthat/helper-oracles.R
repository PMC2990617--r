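# Independent numerical oracles, deliberately naive: fixed-step ODE
# integration of the two-pool system and a brute-force pairwise-count
# Mann-Whitney U. These never call the package's closed-form/enumeration
# code paths.

oracleRateMatrix <- function(kFwd, kRev, r1Sub, r1Prod) {
  matrix(c(-(kFwd + r1Sub), kFwd, kRev, -(kRev + r1Prod)), 2, 2)
}

# Classic fixed-step RK4 on dM/dt = A M from M0 to time tEnd.
rk4Evolve <- function(kFwd, kRev, r1Sub, r1Prod, m0, tEnd, h = 1e-3) {
  A <- oracleRateMatrix(kFwd, kRev, r1Sub, r1Prod)
  n <- ceiling(tEnd / h)
  h <- tEnd / n
  M <- m0
  for (i in seq_len(n)) {
    k1 <- A %*% M
    k2 <- A %*% (M + h / 2 * k1)
    k3 <- A %*% (M + h / 2 * k2)
    k4 <- A %*% (M + h * k3)
    M <- M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.numeric(M)
}

# Brute-force acquisition: small-step Euler integration of the continuous
# dynamics with discrete sin/cos readout events at the pulse times.
eulerAcquire <- function(kFwd, kRev, r1Sub, r1Prod, m0, flipDeg, tr, n,
                         tFirst = tr, h = 1e-4) {
  A <- oracleRateMatrix(kFwd, kRev, r1Sub, r1Prod)
  theta <- flipDeg * pi / 180
  stepTo <- function(M, dt) {
    steps <- max(1L, ceiling(dt / h))
    hh <- dt / steps
    for (i in seq_len(steps)) M <- M + hh * (A %*% M)
    M
  }
  M <- stepTo(m0, tFirst)
  sigS <- sigP <- numeric(n)
  for (i in seq_len(n)) {
    sigS[i] <- sin(theta) * M[1]
    sigP[i] <- sin(theta) * M[2]
    M <- cos(theta) * M
    if (i < n) M <- stepTo(M, tr)
  }
  list(times = tFirst + (seq_len(n) - 1) * tr, signalSub = sigS,
       signalProd = sigP)
}

# Pairwise-count definition of the Mann-Whitney U statistic (ties 1/2).
bruteU <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Dense log-spaced grid search for the best-fitting unidirectional rate.
# The model is linear in m0, so m0 is profiled out exactly at each grid
# point (least-squares projection onto the unit-m0 model curve).
gridSearchK <- function(series, scheme, kGrid,
                        fixed = c(r1Sub = 1 / 30, r1Prod = 1 / 30)) {
  usable <- setdiff(seq_len(scheme@nTransients), scheme@excludedIndices)
  obs <- c(series@substrate[usable], series@product[usable])
  rss <- vapply(kGrid, function(k) {
    tr <- simulateAcquisition(
      ExchangeParameters(kFwd = k, r1Sub = fixed[["r1Sub"]],
                         r1Prod = fixed[["r1Prod"]], m0Sub = 1), scheme)
    mod <- c(tr@signalSub[usable], tr@signalProd[usable])
    m0 <- sum(mod * obs) / sum(mod * mod)
    sum((m0 * mod - obs)^2)
  }, numeric(1))
  kGrid[which.min(rss)]
}
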