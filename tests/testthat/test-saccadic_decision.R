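# Drift-diffusion scanpath engine: maps, drift rates, accumulator
# dynamics, saccade metrics, gaze update, and the simulation loop.

test_that("feature scaling is the stated linear map", {
  expect_equal(scaleFeature(matrix(0), 0.3)[1], 0.3)
  expect_equal(scaleFeature(matrix(1), 0.3)[1], 1)
  expect_equal(scaleFeature(matrix(0.5), 0.2)[1], 0.6)
})

test_that("sensitivity is a peak-normalized Gaussian with object spread", {
  par <- modelParams(sigmaS = 7)
  ppd <- 2
  fov <- matrix(FALSE, 64, 64); fov[50:60, 50:60] <- TRUE
  S <- sensitivityMap(c(20, 20), fov, ppd, par)
  expect_equal(S[20, 20], 1)
  expect_equal(S[55, 55], 1)          # on the foveated object, far away
  sig <- 7 * ppd
  expect_equal(S[20, 20 + sig], exp(-1 / 2), tolerance = 1e-6)
})

test_that("momentum biases sensitivity toward the previous direction", {
  par <- modelParams(momentum = list(enabled = TRUE, maxValue = 1,
                                     minValue = 0.5, angleRange = 180))
  none <- matrix(FALSE, 64, 64)
  S <- sensitivityMap(c(32, 32), none, 2, par, prevAngle = 0)
  expect_gt(S[32, 60], S[32, 4])      # forward beats backward
  # linear decay: at 90 degrees the preference is midway
  Sup <- sensitivityMap(c(32, 32), none, 2, par, prevAngle = 90)
  expect_equal(Sup[60, 32] / S[32, 60], 1, tolerance = 1e-6)
  # undefined previous angle: no bias
  S0 <- sensitivityMap(c(32, 32), none, 2, par, prevAngle = NA)
  expect_equal(S0[32, 60], S0[32, 4])
})

test_that("presaccadic attention spreads to likely targets", {
  par <- modelParams(presaccadic = list(enabled = TRUE,
                                        triggerFraction = 0.3))
  seg <- matrix(1L, 64, 64); seg[10:20, 40:50] <- 5L
  none <- matrix(FALSE, 64, 64)
  V <- c("1" = 0.1, "5" = 0.3 * 4 + 0.1)  # object 5 above trigger
  S <- sensitivityMap(c(32, 10), none, 2, par, seg = seg, V = V)
  expect_true(all(S[seg == 5L] == 1))
  Vlow <- c("1" = 0.1, "5" = 0.2)
  S2 <- sensitivityMap(c(32, 10), none, 2, par, seg = seg, V = Vlow)
  expect_lt(max(S2[seg == 5L]), 1)
})

test_that("evidence map is the elementwise product", {
  a <- matrix(0.5, 4, 4); b <- matrix(0.4, 4, 4); c0 <- matrix(0.8, 4, 4)
  expect_equal(evidenceMap(a, b, c0)[1, 1], 0.16)
  expect_true(all(evidenceMap(a, b, matrix(0, 4, 4)) == 0))
  expect_true(all(evidenceMap(matrix(1, 4, 4), matrix(1, 4, 4),
                              matrix(1, 4, 4)) == 1))
})

test_that("drift rates follow mask-mean evidence and log2 area", {
  ppd <- 4  # 1 dva^2 == 16 px
  seg <- matrix(0L, 32, 32)
  seg[1:4, 1:4] <- 1L     # exactly 1 dva^2
  seg[9:16, 9:16] <- 2L   # 64 px = 4 dva^2
  E <- matrix(0, 32, 32)
  E[seg == 1L] <- 1
  E[seg == 2L] <- 0.5
  mu <- driftRates(E, seg, ppd)
  expect_equal(unname(mu["1"]), 1)            # 1 * max(1, log2 1) = 1
  expect_equal(unname(mu["2"]), 1)            # 0.5 * max(1, 2) = 1
  E0 <- matrix(0, 32, 32)
  expect_equal(unname(driftRates(E0, seg, ppd)["1"]), 0)
})

test_that("noise-free crossing times are exact", {
  par <- modelParams(theta = 4, noise = 0)
  V <- c("7" = 0)
  # mu = 1, nu = 1: crossing at exactly 4 frames
  t <- 0
  for (k in 1:10) {
    st <- ddmStep(V, c("7" = 1), par, nu = 1)
    V <- st$V
    if (!is.null(st$crossing)) { t <- k - 1 + st$crossing$frac; break }
  }
  expect_identical(t, 4)
  # two options: larger drift wins at theta / mu
  V <- c("1" = 0, "2" = 0)
  for (k in 1:10) {
    st <- ddmStep(V, c("1" = 2, "2" = 1), par, nu = 1)
    V <- st$V
    if (!is.null(st$crossing)) {
      expect_identical(st$crossing$id, 1L)
      expect_identical(k - 1 + st$crossing$frac, 2)
      break
    }
  }
  # zero drift, zero noise: no crossing
  V <- c("7" = 0)
  for (k in 1:100) {
    st <- ddmStep(V, c("7" = 0), par, nu = 1)
    expect_null(st$crossing)
    V <- st$V
  }
  expect_identical(unname(V), 0)
})

test_that("no evidence accumulates during saccades (nu = 0)", {
  par <- modelParams(theta = 4, noise = 0.5)
  set.seed(1)
  V <- c("1" = 1.5, "2" = 0.3)
  st <- ddmStep(V, c("1" = 2, "2" = 1), par, nu = 0)
  expect_identical(st$V[c("1", "2")], V)
  expect_null(st$crossing)
})

test_that("accumulators survive transient option dropout", {
  par <- modelParams(theta = 4, noise = 0)
  V <- c("1" = 0, "2" = 0)
  V <- ddmStep(V, c("1" = 1, "2" = 0.5), par, 1)$V
  # option 2 vanishes for one step, then returns
  V <- ddmStep(V, c("1" = 1), par, 1)$V
  expect_identical(unname(V["2"]), 0.5)
  V <- ddmStep(V, c("1" = 1, "2" = 0.5), par, 1)$V
  expect_identical(unname(V["2"]), 1)
})

test_that("saccade duration is linear in amplitude", {
  expect_identical(saccadeDuration(0), 23)
  expect_identical(saccadeDuration(10), 50)
  expect_identical(saccadeDuration(1), 25.7)
})

test_that("landing positions follow the masked product density", {
  set.seed(5)
  mask <- matrix(FALSE, 8, 8); mask[3, 4] <- TRUE
  Fp <- matrix(1, 8, 8); S <- matrix(1, 8, 8)
  land <- sampleLanding(mask, Fp, S)
  expect_equal(unname(land), c(4, 3))
  # two-pixel mask with 0.8 / 0.2 weights: frequencies about 4:1
  mask2 <- matrix(FALSE, 8, 8); mask2[2, 2] <- TRUE; mask2[6, 6] <- TRUE
  Fp2 <- matrix(0, 8, 8); Fp2[2, 2] <- 0.8; Fp2[6, 6] <- 0.2
  draws <- replicate(4000, sampleLanding(mask2, Fp2, S)[1])
  phat <- mean(draws == 2)
  expect_lt(abs(phat - 0.8), 3 * sqrt(0.8 * 0.2 / 4000) + 0.005)
  # uniform product: uniform landing (chi-squared)
  mask3 <- matrix(FALSE, 8, 8); mask3[1:4, 1:4] <- TRUE
  d3 <- replicate(4000, {
    l <- sampleLanding(mask3, S, S); (l[2] - 1) * 4 + l[1]
  })
  expect_gt(stats::chisq.test(table(factor(d3, levels = 1:16)))$p.value,
            1e-4)
  # degenerate product: uniform fallback with warning
  expect_warning(sampleLanding(mask3, matrix(0, 8, 8), S), "uniform")
})

test_that("pursuit advects the gaze with interpolated flow", {
  fl <- array(0, c(16, 16, 2))
  expect_identical(pursueGaze(c(8, 8), fl), c(8, 8))
  fl[, , 1] <- 2
  expect_identical(pursueGaze(c(8, 8), fl), c(10, 8))
  # outward flow at the border clamps to the frame
  fl[, , 1] <- 10
  expect_identical(pursueGaze(c(15, 8), fl), c(16, 8))
})

test_that("simulation is reproducible and well-formed", {
  sc <- exampleScene("three-object", nFrames = 24L)
  prov <- syntheticCueProvider(exampleNoise())
  par <- modelParams()
  sp1 <- simulateScanpath(sc, prov, par, seed = 4)
  sp2 <- simulateScanpath(sc, prov, par, seed = 4)
  expect_identical(scanpathEvents(sp1), scanpathEvents(sp2))
  sp3 <- simulateScanpath(sc, prov, par, seed = 5)
  expect_false(identical(scanpathEvents(sp1), scanpathEvents(sp3)))

  ev <- scanpathEvents(sp1)
  expect_true(all(ev$t_end_ms > ev$t_start_ms))
  expect_true(all(ev$t_end_ms <= 24 * 1000 / 30 + 1e-9))
  # events alternate foveation / saccade
  expect_true(all(ev$event_type[c(TRUE, FALSE)] == "foveation"))
  expect_true(all(ev$event_type[c(FALSE, TRUE)] == "saccade"))
  # contiguous timeline
  expect_equal(ev$t_start_ms[-1], ev$t_end_ms[-nrow(ev)])
  expect_true(all(saccades(sp1)$amplitude_dva >= 0))
})

test_that("a noise-free run saccades to the predicted object at the
           predicted time", {
  # u_min = f_min = 1 removes feature and uncertainty contributions;
  # gt perceptual units and zero DDM noise make the race deterministic,
  # so the winner and its crossing time theta / mu follow from
  # analytically constructed maps
  sc <- exampleScene("single-object", nFrames = 20L)
  prov <- syntheticCueProvider(cueNoise())
  par <- modelParams(uMin = 1, fMin = 1, noise = 0, theta = 4)
  start <- c(56, 56)  # ~2.8 dva from the object center (64, 64)
  sp <- simulateScanpath(sc, prov, par, seed = 2, initGaze = start,
                         gtObjects = TRUE)
  sac <- saccades(sp)
  expect_gt(nrow(sac), 0)

  # oracle: drift rates from analytically constructed maps
  ppd <- pxPerDva(sc)
  gt <- gtLabels(sc, 0)
  seg <- gt + 1L
  S <- sensitivityMap(start, matrix(FALSE, 128, 128), ppd, par)
  mu <- driftRates(evidenceMap(S, scaleFeature(featureMap(sc, 0), 1),
                               matrix(1, 128, 128)), seg, ppd)
  target <- as.integer(names(which.max(mu)))
  expect_identical(target, 2L)             # the object, not background
  expect_identical(sac$object_id[1], target)
  land <- round(c(sac$x_px[1], sac$y_px[1]))
  expect_identical(gt[land[2], land[1]], 1L)
  tCross <- par@theta / max(mu) * 1000 / fps(sc)
  fov <- foveations(sp)
  expect_equal(fov$duration_ms[1], tCross, tolerance = 1e-9)
})

test_that("gt-objects mode consumes ground-truth perceptual units", {
  sc <- exampleScene("three-object", nFrames = 20L)
  prov <- syntheticCueProvider(exampleNoise())
  sp <- simulateScanpath(sc, prov, modelParams(), seed = 3,
                         gtObjects = TRUE)
  ev <- scanpathEvents(sp)
  sac <- ev[ev$event_type == "saccade", ]
  # in gt mode, unit ids are gt + 1, so a saccade's landing gt follows
  # its target id directly
  for (i in seq_len(nrow(sac))) {
    land <- pmin(pmax(round(c(sac$x_px[i], sac$y_px[i])), 1), 128)
    tFrame <- min(floor(sac$t_end_ms[i] / (1000 / 30)), 19)
    expect_identical(gtLabels(sc, tFrame)[land[2], land[1]] + 1L,
                     sac$object_id[i])
  }
})

test_that("dead time prolongs foveations without accumulating evidence", {
  sc <- exampleScene("single-object", nFrames = 20L)
  prov <- syntheticCueProvider(cueNoise())
  base <- modelParams(uMin = 1, fMin = 1, noise = 0, theta = 3.5)
  dead <- modelParams(uMin = 1, fMin = 1, noise = 0, theta = 3.5,
                      deadTimeMs = 50)
  start <- c(44, 44)
  f0 <- foveations(simulateScanpath(sc, prov, base, 2, start))
  f1 <- foveations(simulateScanpath(sc, prov, dead, 2, start))
  expect_equal(f1$duration_ms[1], f0$duration_ms[1] + 50,
               tolerance = 1e-6)
})
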