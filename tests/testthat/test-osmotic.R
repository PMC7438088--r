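test_that("surface area follows the sphere identity and scaling law", {
  V1 <- 4 / 3 * pi * (1e-6)^3
  expect_equal(surfaceArea(V1), 4 * pi * 1e-12, tolerance = 1e-12)
  V2 <- 4 / 3 * pi * (9.1e-6)^3
  expect_equal(surfaceArea(V2), 4 * pi * (9.1e-6)^2, tolerance = 1e-12)
  expect_equal(surfaceArea(8 * V1), 4 * surfaceArea(V1), tolerance = 1e-12)
  expect_error(surfaceArea(-1), "positive")
  expect_error(surfaceArea(0), "positive")
})

test_that("intracellular osmolarity obeys mass conservation", {
  Vr <- 4 / 3 * pi * (9.1e-6)^3
  # reference state returns the reference osmolarity
  ni <- 333 * 0.6 * Vr
  expect_equal(intracellularOsmolarity(Vr, ni, 0.6, Vr), 333,
               tolerance = 1e-10)
  # all water active: c_i = ni / V at any volume
  ni1 <- 333 * 1.0 * Vr
  expect_equal(intracellularOsmolarity(1.37 * Vr, ni1, 1, Vr),
               ni1 / (1.37 * Vr), tolerance = 1e-10)
  # hand evaluation: phir = 0.5, V = 1.2 Vr -> phi_i = 1 - 0.5/1.2,
  # c_i = (333 * 0.5) / (phi_i * 1.2)
  ni2 <- 333 * 0.5 * Vr
  expect_equal(intracellularOsmolarity(1.2 * Vr, ni2, 0.5, Vr),
               166.5 / ((1 - 0.5 / 1.2) * 1.2), tolerance = 1e-10)
  # cell at or below its solid fraction is degenerate
  expect_error(intracellularOsmolarity(0.4 * Vr, ni2, 0.5, Vr),
               "degenerate")
})

test_that("equilibrium volume ratio matches the closed form", {
  expect_equal(equilibriumVolumeRatio(1, 333, 466), 333 / 466,
               tolerance = 1e-12)
  expect_equal(equilibriumVolumeRatio(0, 333, 466), 1)
  expect_equal(equilibriumVolumeRatio(0.5, 466, 333),
               0.5 + 0.5 * 466 / 333, tolerance = 1e-12)
  expect_error(equilibriumVolumeRatio(0.5, 333, -1), "positive")
  expect_error(equilibriumVolumeRatio(1.2, 333, 466), "phir")
})

test_that("no osmotic gradient leaves the volume untouched", {
  pr <- OsmoticProtocol(osmolarity = c(333, 333), duration = c(120, 120),
                        equilibration = 333)
  tr <- simulateVolumeResponse(untreatedParams(), pr)
  Vr <- 4 / 3 * pi * (9.1e-6)^3
  expect_lt(max(abs(traceVolume(tr) / Vr - 1)), 1e-6)
})

test_that("volume is monotone within steps: shrink on hyper, swell on hypo", {
  tr <- simulateVolumeResponse(untreatedParams(), defaultProtocol())
  hyper <- traceVolume(tr)[traceStepLabel(tr) == "hyper"]
  hypo <- traceVolume(tr)[traceStepLabel(tr) == "hypo"]
  expect_true(all(diff(hyper) < 0))
  expect_true(all(diff(hypo) > 0))
})

test_that("simulated plateau matches the equilibrium closed form on a grid", {
  # long single steps so the plateau is fully reached
  for (phir in c(0, 0.25, 0.5, 0.75, 1)) {
    for (step in list(c(333, 466), c(466, 333))) {
      pr <- OsmoticProtocol(osmolarity = step[2], duration = 3600,
                            equilibration = step[1])
      tr <- simulateVolumeResponse(
        cellParams(Lp = 7.2e-14, phir = phir, refRadius = 9.1e-6), pr,
        samplingInterval = 10)
      ratio <- tail(traceVolume(tr), 1) / traceVolume(tr)[1]
      expect_equal(ratio, equilibriumVolumeRatio(phir, step[1], step[2]),
                   tolerance = 1e-3)
    }
  }
})

test_that("trajectories are invariant under (Lp, t) -> (k Lp, t / k)", {
  p1 <- untreatedParams(Lp = 7.2e-14)
  p2 <- untreatedParams(Lp = 1.44e-13)
  pr1 <- OsmoticProtocol(466, 300, 333)
  pr2 <- OsmoticProtocol(466, 150, 333)
  tr1 <- simulateVolumeResponse(p1, pr1, samplingInterval = 2)
  tr2 <- simulateVolumeResponse(p2, pr2, samplingInterval = 1)
  expect_equal(traceVolume(tr2), traceVolume(tr1), tolerance = 1e-6)
})

test_that("the simulator conserves intracellular solute within a step", {
  # reconstruct c_i from the ODE (dV/dt = A Lp RT (c_i - c_e)) by finite
  # differences, then check n_i = c_i phi_i V stays constant
  phir <- 0.6
  Lp <- 7.2e-14
  pr <- OsmoticProtocol(466, 300, 333)
  tr <- simulateVolumeResponse(untreatedParams(Lp, phir), pr,
                               samplingInterval = 0.5)
  V <- traceVolume(tr); tt <- traceTime(tr)
  Vr <- V[1]
  RT <- 8.314 * 295.15
  i <- 2:(length(V) - 1)
  dVdt <- (V[i + 1] - V[i - 1]) / (tt[i + 1] - tt[i - 1])
  ci <- dVdt / (surfaceArea(V[i]) * Lp * RT) + 466
  phii <- 1 - (1 - phir) * Vr / V[i]
  ni <- ci * phii * V[i]
  expect_lt(max(abs(ni / ni[1] - 1)), 0.01)
})

test_that("phir is recovered from an equilibrium plateau", {
  # exact inverse pairs of the closed form
  tr1 <- plateauTrace(333 / 466)
  est1 <- estimatePhirFromEquilibrium(tr1, "hyper", cer = 333, ce = 466)
  expect_equal(est1$phir, 1, tolerance = 1e-3)
  tr2 <- plateauTrace(1)
  expect_equal(
    estimatePhirFromEquilibrium(tr2, "hyper", 333, 466)$phir, 0,
    tolerance = 1e-3)
  tr3 <- plateauTrace(0.88)
  expect_equal(
    estimatePhirFromEquilibrium(tr3, "hyper", 333, 466)$phir,
    (0.88 - 1) / (333 / 466 - 1), tolerance = 1e-3)
  # unidentifiable and no-plateau errors
  expect_error(estimatePhirFromEquilibrium(tr1, "hyper", 466, 466),
               "unidentifiable")
  # steady drift (e.g. a bursting or unattached cell) never plateaus
  tt <- seq(0, 300, 2)
  ramp <- cellVolumeTrace("drift", tt, 3e-15 * (1 - 0.0015 * tt),
                          rep("hyper", length(tt)))
  expect_error(estimatePhirFromEquilibrium(ramp, "hyper", 333, 466),
               "plateau")
})

test_that("noiseless fits recover Lp and phir across the parameter grid", {
  pr <- OsmoticProtocol(466, 300, 333)
  grid <- expand.grid(Lp = c(2e-14, 7.2e-14, 2e-13),
                      phir = c(0.3, 0.6, 0.9))
  for (i in seq_len(nrow(grid))) {
    tr <- simulateVolumeResponse(
      cellParams(Lp = grid$Lp[i], phir = grid$phir[i],
                 refRadius = 9.1e-6), pr)
    fit <- fitMixtureModel(tr, "hyper", cer = 333, ce = 466)
    expect_true(isConverged(fit))
    expect_lt(abs(hydraulicPermeability(fit) / grid$Lp[i] - 1), 0.01)
    expect_lt(abs(activeWaterFraction(fit) - grid$phir[i]), 0.01)
  }
})

test_that("a zero osmotic step is flagged unidentifiable", {
  pr <- OsmoticProtocol(333, 300, 333)
  tr <- simulateVolumeResponse(untreatedParams(), pr)
  fit <- fitMixtureModel(tr, "iso", cer = 333, ce = 333)
  expect_false(isConverged(fit))
  expect_true("unidentifiable" %in% qcFlags(fit))
  expect_true(is.na(hydraulicPermeability(fit)))
})

test_that("mean fitted Lp under sub-pixel radius noise is unbiased", {
  # 0.5% radius noise ~ 0.25 px jitter on a 45 px cell, the accuracy the
  # segmentation stage actually delivers
  pr <- OsmoticProtocol(466, 300, 333)
  tr0 <- simulateVolumeResponse(untreatedParams(Lp = 1e-13), pr)
  set.seed(42)
  est <- replicate(60, {
    eps <- rnorm(length(traceVolume(tr0)), 0, 0.005)
    tr <- cellVolumeTrace("c", traceTime(tr0),
                          traceVolume(tr0) * (1 + eps)^3,
                          traceStepLabel(tr0))
    hydraulicPermeability(fitMixtureModel(tr, "hyper", 333, 466))
  })
  expect_lt(abs(mean(est) / 1e-13 - 1), 0.05)
})

test_that("heavily noisy traces are flagged by the fit QC, not trusted", {
  # at 5% per-frame radius noise (15% volume noise) the transient carries
  # almost no information; the R^2 QC rule must flag such fits
  pr <- OsmoticProtocol(466, 300, 333)
  tr0 <- simulateVolumeResponse(untreatedParams(Lp = 1e-13), pr)
  set.seed(43)
  flagged <- replicate(10, {
    eps <- rnorm(length(traceVolume(tr0)), 0, 0.05)
    tr <- cellVolumeTrace("c", traceTime(tr0),
                          traceVolume(tr0) * (1 + eps)^3,
                          traceStepLabel(tr0))
    "low_r2" %in% qcFlags(fitMixtureModel(tr, "hyper", 333, 466))
  })
  expect_true(all(flagged))
})

test_that("two-step fitting resets the reference state per step", {
  pr <- defaultProtocol()
  tr <- simulateVolumeResponse(
    cellParams(Lp = c(7.2e-14, 8.8e-14), phir = 0.6,
               refRadius = 9.1e-6), pr)
  fits <- fitTwoStepSequence(tr, pr)
  expect_named(fits, c("hyper", "hypo"))
  expect_lt(abs(hydraulicPermeability(fits$hyper) / 7.2e-14 - 1), 0.01)
  expect_lt(abs(hydraulicPermeability(fits$hypo) / 8.8e-14 - 1), 0.01)
  expect_lt(abs(activeWaterFraction(fits$hyper) - 0.6), 0.01)
  # step-2 reference is reset, so its active water fraction is the
  # re-referenced value 1 - (1 - phir) Vr / V1
  V1overVr <- equilibriumVolumeRatio(0.6, 333, 466)
  expect_lt(abs(activeWaterFraction(fits$hypo) -
                (1 - (1 - 0.6) / V1overVr)), 0.01)
})

test_that("symmetric protocols with equal Lp give equal estimates", {
  pr <- OsmoticProtocol(osmolarity = c(466, 333),
                        duration = c(600, 600), equilibration = 333)
  tr <- simulateVolumeResponse(untreatedParams(Lp = 8e-14), pr)
  fits <- fitTwoStepSequence(tr, pr)
  expect_equal(hydraulicPermeability(fits$hyper),
               hydraulicPermeability(fits$hypo), tolerance = 0.01)
})

test_that("a trace truncated before step 2 raises a protocol mismatch", {
  pr <- defaultProtocol()
  tr <- simulateVolumeResponse(untreatedParams(), pr)
  keep <- traceStepLabel(tr) == "hyper"
  short <- cellVolumeTrace(cellId(tr), traceTime(tr)[keep],
                           traceVolume(tr)[keep],
                           traceStepLabel(tr)[keep])
  expect_error(fitTwoStepSequence(short, pr), "protocol mismatch")
})

test_that("volume traces survive a CSV round trip, radius or volume", {
  pr <- defaultProtocol()
  trs <- list(a = simulateVolumeResponse(untreatedParams(), pr,
                                         cellId = "a"))
  f <- tempfile(fileext = ".csv")
  writeVolumeTraces(trs, f)
  back <- readVolumeTraces(f)
  expect_equal(traceVolume(back$a), traceVolume(trs$a), tolerance = 1e-9)
  # radius-typed CSV converts through the sphere relation
  df <- data.frame(cell_id = "b", t_s = 0:4,
                   radius_um = c(9.1, 9.0, 8.9, 8.85, 8.84),
                   step_label = "hyper")
  f2 <- tempfile(fileext = ".csv")
  write.csv(df, f2, row.names = FALSE)
  back2 <- readVolumeTraces(f2)
  expect_equal(traceVolume(back2$b),
               4 / 3 * pi * (df$radius_um * 1e-6)^3, tolerance = 1e-12)
})

test_that("trace and protocol validity rules reject malformed objects", {
  expect_error(cellVolumeTrace("c", c(0, 2, 2), c(1, 1, 1) * 1e-15,
                               rep("hyper", 3)), "increasing")
  expect_error(cellVolumeTrace("c", c(0, 2), c(1e-15, -1e-15),
                               rep("hyper", 2)), "positive")
  expect_error(OsmoticProtocol(c(466, -333), c(300, 300)), "positive")
  expect_error(OsmoticProtocol(466, -300), "positive")
  expect_error(cellParams(Lp = -1e-14, phir = 0.6, refRadius = 9e-6),
               "Lp")
})
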