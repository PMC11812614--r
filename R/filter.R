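# Recursive Bayesian particle filter over scene segmentations.
#
# The belief over the segmentation is a weighted set of label-raster
# hypotheses. Each frame it is advected by optical flow (predict), weighted
# by boundary distance to the cue measurements, partially overwritten by
# direct measurement incorporation, and resampled. Marginalizing the set
# yields a per-pixel boundary likelihood, a most-likely segmentation, and a
# boundary-entropy uncertainty map.

# Index particles by identity: returns list(uniq = indices of first
# occurrences, map = for each particle the index into uniq). Resampling
# and incorporation duplicate many particles, so per-particle raster work
# (warping, boundary masks, distance transforms) is done once per
# distinct hypothesis.
.dedupIndex <- function(particles) cpp_dedup_index(particles)

#' Initialize a segmentation belief from global cue measurements
#'
#' Particles are drawn round-robin from the full-frame measurements
#' (mask-only measurements are skipped), with uniform weights. The initial
#' diversity of the belief therefore reflects the disagreement between the
#' cues.
#'
#' @param measurements list of \linkS4class{CueMeasurement}
#' @param nParticles particle count (default 50)
#' @return a \linkS4class{SegmentationBelief}
#' @export
initialBelief <- function(measurements, nParticles = 50L) {
  full <- Filter(function(m) !m@maskOnly, measurements)
  if (!length(full)) stop("need at least one full-frame measurement")
  particles <- lapply(seq_len(nParticles), function(i)
    full[[(i - 1L) %% length(full) + 1L]]@labels)
  new("SegmentationBelief", particles = particles,
      weights = rep(1 / nParticles, nParticles))
}

#' Advect the belief by optical flow (predict step)
#'
#' Each particle's label raster is forward-warped by the flow field; holes
#' are filled with the nearest surviving label and destination collisions
#' keep the larger label. Weights are unchanged.
#'
#' @param belief a \linkS4class{SegmentationBelief}
#' @param flow H x W x 2 flow array (x then y displacement, px/frame)
#' @return the advected belief
#' @export
predictBelief <- function(belief, flow) {
  if (any(!is.finite(flow))) stop("NaN flow")
  d <- dim(belief@particles[[1]])
  if (!identical(dim(flow)[1:2], d)) stop("flow shape mismatch")
  if (all(flow == 0)) return(belief)
  fx <- flow[, , 1]; fy <- flow[, , 2]
  ix <- .dedupIndex(belief@particles)
  warped <- lapply(belief@particles[ix$uniq], cpp_warp_labels, fx = fx,
                   fy = fy)
  belief@particles <- warped[ix$map]
  belief
}

# Distance-to-nearest-boundary raster (exact Euclidean, via the
# compiled two-pass transform; tests pin its equality to
# EBImage::distmap). Rasters with no boundary at all get a constant at
# the frame diagonal, an upper bound on any within-frame distance.
.boundaryDistmap <- function(bm) {
  if (!any(bm)) {
    d <- dim(bm)
    return(matrix(sqrt(sum(d^2)), d[1], d[2]))
  }
  cpp_edt(bm)
}

.batchBoundaryDistmap <- function(bms) lapply(bms, .boundaryDistmap)

# Dilated window around the nonzero support of a mask-only measurement.
.maskWindow <- function(labels, windowPx) {
  m <- labels > 0
  if (!any(m) || !is.finite(windowPx))
    return(matrix(TRUE, nrow(labels), ncol(labels)))
  cpp_edt(m) <= windowPx
}

.chamfer <- function(bmA, distA, bmB, distB, window = NULL)
  cpp_chamfer(bmA, distA, bmB, distB, window)

#' Symmetric mean boundary distance between two segmentations
#'
#' Average chamfer distance between the boundary-pixel sets of two label
#' rasters: the mean over a's boundary pixels of the Euclidean distance to
#' b's nearest boundary pixel, averaged with the reverse direction. Zero
#' iff the boundary sets coincide. If one raster has no boundary, the
#' one-sided term is used; if neither has, the distance is 0.
#'
#' For mask-only measurements the comparison is restricted to a window
#' around the measured mask (its support dilated by \code{windowPx}), so a
#' local measurement does not penalize remote scene structure.
#'
#' @param a,b integer label rasters of equal size (b may be a single-mask
#'   measurement raster)
#' @param maskOnly restrict the comparison to a window around b's support
#' @param windowPx window dilation radius in px (used when maskOnly)
#' @return nonnegative scalar distance in px
#' @export
boundaryDistance <- function(a, b, maskOnly = FALSE, windowPx = Inf) {
  stopifnot(identical(dim(a), dim(b)))
  bmA <- cpp_boundary_mask(a)
  bmB <- cpp_boundary_mask(b)
  win <- if (maskOnly) .maskWindow(b, windowPx) else NULL
  .chamfer(bmA, .boundaryDistmap(bmA), bmB, .boundaryDistmap(bmB), win)
}

#' Weight the belief by cue measurements
#'
#' Per-measurement likelihood \code{exp(-confidence * d / lambdaD)} with d
#' the symmetric mean boundary distance between particle and measurement;
#' particle weights are proportional to the product over measurements and
#' renormalized. If all likelihoods underflow to zero the weights fall
#' back to uniform with a warning.
#'
#' @param belief a \linkS4class{SegmentationBelief}
#' @param measurements list of \linkS4class{CueMeasurement}
#' @param lambdaD likelihood length scale in px (> 0)
#' @param windowPx window radius (px) for mask-only measurements
#' @return the reweighted belief (weights sum to 1)
#' @export
weightBelief <- function(belief, measurements, lambdaD, windowPx = Inf) {
  stopifnot(lambdaD > 0)
  P <- nParticles(belief)
  # per-measurement precomputation: boundary mask, distmap, window
  mbms <- lapply(measurements, function(m) cpp_boundary_mask(m@labels))
  mdms <- .batchBoundaryDistmap(mbms)
  meas <- lapply(seq_along(measurements), function(k) {
    m <- measurements[[k]]
    list(bm = mbms[[k]], dist = mdms[[k]], conf = m@confidence,
         win = if (m@maskOnly) .maskWindow(m@labels, windowPx) else NULL)
  })
  ix <- .dedupIndex(belief@particles)
  bms <- lapply(belief@particles[ix$uniq], cpp_boundary_mask)
  dms <- .batchBoundaryDistmap(bms)
  logwU <- vapply(seq_along(ix$uniq), function(j) {
    lw <- 0
    for (m in meas)
      lw <- lw - m$conf *
        .chamfer(bms[[j]], dms[[j]], m$bm, m$dist, m$win) / lambdaD
    lw
  }, 0)
  logw <- logwU[ix$map]
  w <- exp(logw - max(logw)) * belief@weights
  if (!any(is.finite(w)) || sum(w) == 0) {
    warning("all measurement likelihoods vanished; uniform fallback")
    w <- rep(1, P)
  }
  belief@weights <- w / sum(w)
  belief
}

#' Systematic resampling of the belief
#'
#' P draws with replacement proportional to the weights using systematic
#' resampling (a single uniform offset, stratified positions); weights are
#' reset to 1/P. Uses the current RNG stream.
#'
#' @param belief a \linkS4class{SegmentationBelief}
#' @return the resampled belief
#' @export
resampleBelief <- function(belief) {
  P <- nParticles(belief)
  u <- (stats::runif(1) + seq_len(P) - 1) / P
  idx <- findInterval(u, cumsum(belief@weights), left.open = TRUE) + 1L
  idx[idx > P] <- P
  belief@particles <- belief@particles[idx]
  belief@weights <- rep(1 / P, P)
  belief
}

# Paint every measured segment (given as a list of pixel-index vectors)
# into particle p with fresh labels, then clean up: any pre-existing
# label reduced to less than half of its former extent (the ring
# slivers a jittered overwrite leaves behind, or a region the
# measurement repartitioned) is dissolved into the nearest surviving
# label. Canonical renumbering keeps identically adjusted particles
# bit-identical.
.paintSegments <- function(p, segIdx) {
  if (!length(segIdx)) return(p)
  cpp_paint_segments(p, segIdx)
}

#' Incorporate measured segments into part of the particle set
#'
#' Adjusts a random subset of particles to match each eligible
#' measurement directly, by overwriting the pixels of every measured
#' segment with a fresh label (pixels the measurement does not label are
#' left untouched — a cue that cannot see part of the scene asserts
#' nothing there). Leftover slivers of repartitioned labels are
#' dissolved into their surroundings.
#'
#' The subset size per measurement is
#' \code{ceiling(fraction * confidence * P)} for full-frame cues, so
#' higher-confidence measurements anchor a larger share of the belief;
#' mask-only (prompted) measurements are local patches and are
#' incorporated into every particle, which is what collapses uncertainty
#' at the gaze position while leaving multimodality elsewhere untouched.
#'
#' All cue kinds are eligible by default: restricting incorporation to a
#' single cue makes that cue an absorbing state, collapsing the belief's
#' multimodality and with it the uncertainty map.
#'
#' @param belief a \linkS4class{SegmentationBelief}
#' @param measurements list of \linkS4class{CueMeasurement}
#' @param fraction base fraction of particles to adjust, in [0, 1]
#' @param kinds cue kinds eligible for incorporation
#' @return the adjusted belief
#' @export
incorporateMeasurements <- function(belief, measurements, fraction = 0.05,
                                    kinds = c("appearance", "motion",
                                              "semantic", "prompted")) {
  stopifnot(fraction >= 0, fraction <= 1)
  elig <- Filter(function(m) m@kind %in% kinds, measurements)
  if (fraction == 0 || !length(elig)) return(belief)
  P <- nParticles(belief)
  # painting is deterministic in (particle content, measurement): do it
  # once per group of identical particles, tracking each particle's
  # paint history as its cache key
  ix <- .dedupIndex(belief@particles)
  key <- as.character(ix$map)
  cache <- new.env(parent = emptyenv())
  for (q in seq_along(elig)) {
    m <- elig[[q]]
    segIdx <- lapply(which(tabulate(m@labels) > 0),
                     function(s) which(m@labels == s))
    n <- if (m@maskOnly) P else min(P, ceiling(fraction * m@confidence * P))
    idx <- sample.int(P, n)
    for (i in idx) {
      k2 <- paste0(key[i], "+", q)
      got <- cache[[k2]]
      if (is.null(got)) {
        got <- .paintSegments(belief@particles[[i]], segIdx)
        cache[[k2]] <- got
      }
      belief@particles[[i]] <- got
      key[i] <- k2
    }
  }
  belief
}

#' Marginal boundary likelihood of the belief
#'
#' Per pixel, the summed weight of particles that have a boundary there
#' (a 4-neighbor with a different label), i.e. the posterior probability
#' of an object boundary at that pixel.
#'
#' @param belief a \linkS4class{SegmentationBelief} with normalized weights
#' @return numeric matrix p_b in [0, 1]
#' @export
boundaryLikelihood <- function(belief) {
  d <- dim(belief@particles[[1]])
  pb <- matrix(0, d[1], d[2])
  ix <- .dedupIndex(belief@particles)
  for (j in seq_along(ix$uniq)) {
    w <- sum(belief@weights[ix$map == j])
    pb <- pb + w * cpp_boundary_mask(belief@particles[[ix$uniq[j]]])
  }
  pmin(pmax(pb, 0), 1)  # guard rounding of the weight sum
}

#' Binary boundary entropy map
#'
#' Per-pixel binary entropy of the boundary likelihood, in nats, with the
#' convention 0 * log(0) = 0. Maximal (log 2) where the belief is evenly
#' split on the presence of a boundary.
#'
#' @param pb boundary-likelihood matrix in [0, 1]
#' @return numeric matrix H in [0, log 2]
#' @export
entropyMap <- function(pb) {
  rng <- range(pb)
  if (rng[1] < 0 || rng[2] > 1) stop("pb must lie in [0, 1]")
  h <- -pb * log(pb) - (1 - pb) * log(1 - pb)
  h[pb == 0 | pb == 1] <- 0
  h
}

#' Most likely segmentation from the boundary likelihood
#'
#' Thresholds p_b into a boundary mask, morphologically closes it (3 x 3
#' box), labels the 4-connected non-boundary regions, and assigns boundary
#' pixels to the nearest region so that every pixel is labeled.
#'
#' @param pb boundary-likelihood matrix
#' @param threshold boundary threshold in (0, 1), default 0.5
#' @return integer label matrix (labels 1..K, every pixel labeled)
#' @export
mapSegmentation <- function(pb, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  bnd <- pb >= threshold
  if (any(bnd)) {
    closed <- EBImage::closing(matrix(as.numeric(bnd), nrow(pb), ncol(pb)),
                               EBImage::makeBrush(3L, "box"))
    bnd <- matrix(closed > 0.5, nrow(pb), ncol(pb))
  }
  if (all(bnd)) {
    warning("boundary mask covers the whole frame; single-region fallback")
    return(matrix(1L, nrow(pb), ncol(pb)))
  }
  lab <- matrix(as.integer(EBImage::bwlabel(
    matrix(as.numeric(!bnd), nrow(pb), ncol(pb)))), nrow(pb), ncol(pb))
  cpp_fill_nearest(lab, 0L)
}

#' Uncertainty map from the entropy raster
#'
#' The entropy map is blurred with a Gaussian (so boundary uncertainty is
#' attributed to both adjacent objects), rescaled from its value range
#' [0, log 2] to [0, 1], and linearly mapped to [uMin, 1]. \code{uMin = 1}
#' removes uncertainty from the evidence product entirely.
#'
#' @param H entropy matrix in nats
#' @param blurSigmaPx Gaussian blur sigma in px
#' @param uMin floor of the rescaled map, in [0, 1]
#' @return list with components H, U (blurred, rescaled to [0, 1]) and
#'   Uprime (in [uMin, 1])
#' @export
uncertaintyMap <- function(H, blurSigmaPx, uMin) {
  stopifnot(uMin >= 0, uMin <= 1)
  U <- if (blurSigmaPx > 0) {
    r <- min(2L * ceiling(3 * blurSigmaPx) + 1L, min(dim(H)) - 1L)
    if (r %% 2L == 0L) r <- r - 1L
    matrix(EBImage::gblur(H, sigma = blurSigmaPx, radius = r),
           nrow(H), ncol(H))
  } else H
  U <- pmin(pmax(U / log(2), 0), 1)
  list(H = H, U = U, Uprime = uMin + (1 - uMin) * U)
}
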