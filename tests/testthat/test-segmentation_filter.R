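# Particle filter over segmentations: predict / weight / resample /
# incorporate and the marginal maps.

test_that("predict is the identity under zero flow and a shift under
           uniform flow", {
  set.seed(1)
  p <- splitRaster(10)
  b <- new("SegmentationBelief", particles = list(p, splitRaster(20)),
           weights = c(0.5, 0.5))
  zero <- array(0, c(32, 32, 2))
  expect_identical(predictBelief(b, zero)@particles, b@particles)

  fl <- array(0, c(32, 32, 2)); fl[, , 1] <- 3
  shifted <- predictBelief(b, fl)
  manual <- splitRaster(13)
  expect_identical(shifted@particles[[1]][, 4:32], manual[, 4:32])
  expect_error(predictBelief(b, array(NaN, c(32, 32, 2))), "NaN")
})

test_that("predict with ground-truth flow reproduces the next frame", {
  sc <- movingDiscScene()
  b <- new("SegmentationBelief", particles = list(gtLabels(sc, 0)),
           weights = 1)
  b2 <- predictBelief(b, sceneFlow(sc, 0))
  nxt <- gtLabels(sc, 1)
  # exact on the object; the uncovered trailing strip is filled by vote
  expect_identical(b2@particles[[1]][nxt == 1], nxt[nxt == 1])
  expect_gt(mean(b2@particles[[1]] == nxt), 0.99)
})

test_that("boundaryDistance matches the brute-force oracle", {
  # parallel straight splits: the two-sided convention gives d - 0.5
  expect_equal(boundaryDistance(splitRaster(10), splitRaster(14)), 3.5)
  expect_equal(bruteBoundaryDistance(splitRaster(10), splitRaster(14)), 3.5)
  expect_identical(boundaryDistance(splitRaster(10), splitRaster(10)), 0)

  set.seed(42)
  for (i in 1:6) {
    a <- matrix(0L, 24, 24)
    a[sample(5:18, 1):sample(19:24, 1), sample(5:18, 1):sample(19:24, 1)] <- 1L
    b <- matrix(0L, 24, 24)
    b[sample(2:12, 1):sample(13:22, 1), sample(2:12, 1):sample(13:22, 1)] <- 1L
    expect_equal(boundaryDistance(a, b), bruteBoundaryDistance(a, b),
                 tolerance = 1e-12)
  }
})

test_that("boundaryDistance handles boundary-free rasters one-sidedly", {
  flat <- matrix(1L, 16, 16)
  expect_identical(boundaryDistance(flat, flat), 0)
  d <- boundaryDistance(flat, splitRaster(8, 16))
  expect_true(is.finite(d) && d > 0)
})

test_that("weights follow the exponential distance likelihood", {
  m <- cueMeasurement("semantic", splitRaster(10), confidence = 2)
  b <- new("SegmentationBelief",
           particles = list(splitRaster(10), splitRaster(14)),
           weights = c(0.5, 0.5))
  bw <- weightBelief(b, list(m), lambdaD = 8)
  w <- particleWeights(bw)
  expect_equal(sum(w), 1)
  expect_gt(w[1], w[2])  # exact match dominates
  d <- bruteBoundaryDistance(splitRaster(10), splitRaster(14))
  expect_equal(w[1] / w[2], exp(2 * d / 8), tolerance = 1e-10)

  # equal distances give equal weights
  b2 <- new("SegmentationBelief",
            particles = list(splitRaster(8), splitRaster(12)),
            weights = c(0.5, 0.5))
  w2 <- particleWeights(weightBelief(b2, list(m), lambdaD = 8))
  expect_equal(w2, c(0.5, 0.5))
})

test_that("extreme likelihood sharpness stays numerically stable", {
  # log-domain weighting keeps the best particle representable even
  # when raw likelihoods would underflow to zero
  m <- cueMeasurement("semantic", splitRaster(10), confidence = 1e6)
  b <- new("SegmentationBelief",
           particles = list(splitRaster(10), splitRaster(30)),
           weights = c(0.5, 0.5))
  w <- particleWeights(weightBelief(b, list(m), lambdaD = 1e-12))
  expect_equal(sum(w), 1)
  expect_equal(w[1], 1)
})

test_that("systematic resampling: degenerate and uniform cases", {
  set.seed(7)
  parts <- lapply(c(5, 10, 15, 20), splitRaster)
  b <- new("SegmentationBelief", particles = parts,
           weights = c(1, 0, 0, 0))
  r <- resampleBelief(b)
  for (p in r@particles) expect_identical(p, parts[[1]])
  expect_equal(particleWeights(r), rep(0.25, 4))

  # uniform weights preserve the multiset (property of systematic
  # resampling, checked over repeated draws)
  bu <- new("SegmentationBelief", particles = parts,
            weights = rep(0.25, 4))
  for (i in 1:20) {
    ru <- resampleBelief(bu)
    key <- function(ps) sort(vapply(ps, function(p) sum(p == 2L), 0L))
    expect_identical(key(ru@particles), key(parts))
  }
})

test_that("resampling copy counts are proportional to weights", {
  set.seed(11)
  parts <- lapply(c(5, 10, 15, 20), splitRaster)
  w <- c(0.4, 0.3, 0.2, 0.1)
  b <- new("SegmentationBelief", particles = parts, weights = w)
  counts <- numeric(4)
  reps <- 2000
  for (i in seq_len(reps)) {
    r <- resampleBelief(b)
    for (k in 1:4)
      counts[k] <- counts[k] +
        sum(vapply(r@particles, identical, TRUE, parts[[k]]))
  }
  expected <- 4 * w
  se <- sqrt(expected * (1 - w) / reps)
  expect_true(all(abs(counts / reps - expected) < 3 * pmax(se, 0.02)))
})

test_that("incorporation anchors particles near measurements", {
  set.seed(3)
  parts <- lapply(c(5, 10, 15, 20), splitRaster)
  b <- new("SegmentationBelief", particles = parts,
           weights = rep(0.25, 4))
  # fraction 0 is the identity
  m <- cueMeasurement("semantic", splitRaster(25), confidence = 1)
  expect_identical(incorporateMeasurements(b, list(m), 0)@particles,
                   b@particles)
  # a prompted mask ends up as a segment of every particle
  mask <- matrix(0L, 32, 32); mask[10:20, 10:20] <- 1L
  pm <- cueMeasurement("prompted", mask, confidence = 3,
                       promptPoint = c(15, 15), maskOnly = TRUE)
  bi <- incorporateMeasurements(b, list(pm), 1)
  for (p in bi@particles) {
    seg <- p[15, 15]
    expect_identical(unname(p == seg), unname(mask == 1L))
  }
  # boundary likelihood along the mask boundary strictly increases
  pbBefore <- boundaryLikelihood(b)
  pbAfter <- boundaryLikelihood(bi)
  bm <- gazefilter:::cpp_boundary_mask(mask + 1L)
  expect_gt(mean(pbAfter[bm]), mean(pbBefore[bm]))
})

test_that("incorporation leaves unmeasured pixels untouched", {
  set.seed(5)
  p0 <- splitRaster(16)
  b <- new("SegmentationBelief", particles = list(p0), weights = 1)
  # a motion-style cue that only asserts a small moving segment
  seg <- matrix(0L, 32, 32); seg[4:8, 4:8] <- 1L
  m <- cueMeasurement("motion", seg, confidence = 1)
  bi <- incorporateMeasurements(b, list(m), 1)
  p1 <- bi@particles[[1]]
  # the split boundary survives away from the painted segment
  expect_true(all(p1[20:32, 10] != p1[20:32, 25]))
  # the painted segment is present
  expect_identical(unname(p1 == p1[5, 5]), unname(seg == 1L))
})

test_that("boundary likelihood marginalizes particle weights", {
  p1 <- splitRaster(10); p2 <- splitRaster(20)
  # unanimous belief: pb is 0/1
  bu <- new("SegmentationBelief", particles = list(p1, p1),
            weights = c(0.5, 0.5))
  pb <- boundaryLikelihood(bu)
  expect_true(all(pb %in% c(0, 1)))
  # equal weights, boundary in exactly one particle
  be <- new("SegmentationBelief", particles = list(p1, p2),
            weights = c(0.5, 0.5))
  pbE <- boundaryLikelihood(be)
  expect_equal(pbE[16, 9], 0.5)
  # weights 0.7 / 0.3
  bw <- new("SegmentationBelief", particles = list(p1, p2),
            weights = c(0.7, 0.3))
  expect_equal(boundaryLikelihood(bw)[16, 9], 0.7)
})

test_that("entropy map implements binary entropy in nats", {
  expect_equal(entropyMap(matrix(c(0, 1))), matrix(c(0, 0)))
  expect_equal(entropyMap(matrix(0.5))[1], log(2))
  expect_equal(entropyMap(matrix(0.25))[1],
               -0.25 * log(0.25) - 0.75 * log(0.75))
  expect_equal(entropyMap(matrix(0.25))[1], 0.5623, tolerance = 1e-4)
})

test_that("map segmentation recovers the majority structure", {
  # no boundary evidence: one region
  expect_true(all(mapSegmentation(matrix(0, 16, 16)) == 1L))
  # 0.7 vs 0.3 disagreement about a split: majority wins at 0.5
  p1 <- splitRaster(8, 16); p2 <- splitRaster(12, 16)
  b <- new("SegmentationBelief", particles = list(p1, p2),
           weights = c(0.7, 0.3))
  seg <- mapSegmentation(boundaryLikelihood(b), 0.5)
  expect_label_equivalent(seg[, c(1:6, 9:16)], p1[, c(1:6, 9:16)])
  # unanimous belief: exact round trip away from the boundary wall
  sc <- movingDiscScene()
  gt <- gtLabels(sc, 0)
  pb <- boundaryLikelihood(new("SegmentationBelief",
                               particles = list(gt), weights = 1))
  segd <- mapSegmentation(pb)
  wall <- gazefilter:::cpp_boundary_mask(gt)
  inner <- segd[24, 15]
  expect_identical((segd == inner)[!wall], (gt == 1)[!wall])
  expect_gt(mean((segd == inner) == (gt == 1)), 0.995)
  # bijective region correspondence
  expect_identical(length(unique(as.vector(segd))),
                   length(unique(as.vector(gt))))
})

test_that("uncertainty map rescales blurred entropy into [uMin, 1]", {
  H0 <- matrix(0, 32, 32)
  u <- uncertaintyMap(H0, 4, 1 / 3)
  expect_true(all(abs(u$Uprime - 1 / 3) < 1e-12))
  u1 <- uncertaintyMap(matrix(log(2) / 2, 32, 32), 0, 1)
  expect_true(all(u1$Uprime == 1))
  # U = 0.5 with uMin = 1/3 maps to 2/3
  u2 <- uncertaintyMap(matrix(log(2) / 2, 32, 32), 0, 1 / 3)
  expect_equal(u2$U[1, 1], 0.5)
  expect_equal(u2$Uprime[1, 1], 2 / 3)
})

test_that("weights stay normalized and particle count constant", {
  set.seed(9)
  sc <- twoObjectScene()
  cues <- syntheticCues(sc, 0, cueNoise(jitterPx = 1), seed = 2)
  b <- initialBelief(cues, 12)
  expect_identical(nParticles(b), 12L)
  for (step in 1:3) {
    b <- predictBelief(b, sceneFlow(sc, 0))
    b <- weightBelief(b, cues, 16)
    expect_equal(sum(particleWeights(b)), 1)
    b <- incorporateMeasurements(b, cues, 0.2)
    b <- resampleBelief(b)
    expect_identical(nParticles(b), 12L)
    expect_equal(sum(particleWeights(b)), 1)
  }
})

test_that("repeated noise-free measurements drive convergence", {
  set.seed(21)
  # full-frame three-segment measurement with straight boundaries
  target <- matrix(1L, 64, 64)
  target[, 22:43] <- 2L; target[, 44:64] <- 3L
  meas <- cueMeasurement("semantic", target, confidence = 1)
  init <- list(cueMeasurement("appearance", splitRaster(12, 64)),
               cueMeasurement("motion", matrix(1L, 64, 64)),
               cueMeasurement("semantic", splitRaster(50, 64)))
  b <- initialBelief(init, 50)
  for (k in 1:10) {
    b <- weightBelief(b, list(meas), 16)
    b <- incorporateMeasurements(b, list(meas), 0.2)
    b <- resampleBelief(b)
  }
  pb <- boundaryLikelihood(b)
  bm <- gazefilter:::cpp_boundary_mask(target)
  expect_lt(mean(entropyMap(pb)[bm]), 0.05)
  expect_label_equivalent(mapSegmentation(pb), target)
})

test_that("a prompted measurement reduces uncertainty inside its mask", {
  set.seed(31)
  sc <- twoObjectScene()
  noise <- cueNoise(jitterPx = 2, dropProb = 0.4)
  b <- initialBelief(syntheticCues(sc, 0, noise, 1), 30)
  for (t in 1:5) {
    cues <- syntheticCues(sc, 0, noise, t)
    b <- weightBelief(b, cues, 16)
    b <- incorporateMeasurements(b, cues, 0.1)
    b <- resampleBelief(b)
  }
  up <- function(bel) uncertaintyMap(
    entropyMap(boundaryLikelihood(bel)), 8, 1 / 3)$Uprime
  pr <- promptedCue(sc, 0, c(20, 40), cueNoise(), 1)
  before <- up(b)
  b <- weightBelief(b, list(pr), 16)
  b <- incorporateMeasurements(b, list(pr), 0.1)
  b <- resampleBelief(b)
  after <- up(b)
  mask <- pr@labels > 0
  expect_lt(mean(after[mask]), mean(before[mask]))
})
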