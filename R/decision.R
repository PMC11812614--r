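# Multi-option drift-diffusion scanpath engine.
#
# Per frame, sensitivity (S), rescaled saliency (F') and rescaled
# segmentation uncertainty (U') multiply into an evidence map E = S*F'*U'.
# Each segmented object accumulates the mask-mean of E (scaled by log2 of
# its area in dva^2) in a drift-diffusion race toward a shared threshold;
# the first crossing triggers a saccade whose duration grows linearly with
# amplitude and whose landing point is sampled within the target object.
# Between saccades the gaze is advected by optical flow (fixation or
# smooth pursuit).

#' Construct the model parameter set
#'
#' Defaults correspond to the base model: threshold theta = 4, uncertainty
#' floor uMin = 1/3, sensitivity spread sigmaS = 7 dva, update step of one
#' frame, 50 particles. The dead-time extension uses
#' \code{deadTimeMs = 50} with a lowered threshold \code{theta = 3.5}.
#'
#' @param fMin feature-map floor in [0, 1]
#' @param uMin uncertainty-map floor in [0, 1]
#' @param theta decision threshold (> 0)
#' @param noise diffusion noise level s (>= 0)
#' @param sigmaS sensitivity spread in dva
#' @param dt accumulator step in frames
#' @param lambdaD measurement-likelihood length scale in dva
#' @param blurSigma entropy blur in dva
#' @param nParticles particle count
#' @param incorporateFraction fraction of particles receiving direct
#'   measurement incorporation per frame
#' @param mapThreshold boundary-likelihood threshold
#' @param momentum list(enabled, maxValue, minValue, angleRange) saccadic
#'   momentum extension
#' @param presaccadic list(enabled, triggerFraction) presaccadic attention
#'   extension
#' @param deadTimeMs saccadic dead time in ms
#' @return a \linkS4class{ModelParams}
#' @export
modelParams <- function(fMin = 0.15, uMin = 1 / 3, theta = 4, noise = 0.35,
                        sigmaS = 7, dt = 1, lambdaD = 2, blurSigma = 1,
                        nParticles = 50L, incorporateFraction = 0.05,
                        mapThreshold = 0.5,
                        momentum = list(enabled = FALSE, maxValue = 1,
                                        minValue = 0.5, angleRange = 180),
                        presaccadic = list(enabled = FALSE,
                                           triggerFraction = 0.3),
                        deadTimeMs = 0) {
  new("ModelParams", fMin = fMin, uMin = uMin, theta = theta, noise = noise,
      sigmaS = sigmaS, dt = dt, lambdaD = lambdaD, blurSigma = blurSigma,
      nParticles = as.integer(nParticles),
      incorporateFraction = incorporateFraction,
      mapThreshold = mapThreshold, momentum = momentum,
      presaccadic = presaccadic, deadTimeMs = deadTimeMs)
}

#' Rescale the feature map to [fMin, 1]
#'
#' @param F feature raster in [0, 1]
#' @param fMin floor in [0, 1]
#' @return F' = fMin + (1 - fMin) * F
#' @export
scaleFeature <- function(F, fMin) {
  stopifnot(fMin >= 0, fMin <= 1)
  fMin + (1 - fMin) * F
}

.wrapAngle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180  # half-open (-180, 180]
  a
}

#' Gaze-dependent visual sensitivity map
#'
#' An isotropic, peak-normalized Gaussian around the gaze position
#' (spread sigmaS), overwritten with 1 across the currently foveated
#' object (uniform object-based attentional spread). With the momentum
#' extension, multiplied by an angle-preference raster that is maximal in
#' the previous saccade's direction and decays linearly with angular
#' deviation; with the presaccadic extension, objects whose accumulated
#' evidence exceeds the trigger fraction of the threshold are also set
#' to 1.
#'
#' Angles are measured in screen coordinates (x right, y down), in
#' degrees from the positive x axis.
#'
#' @param gaze position c(x, y) in px
#' @param foveatedMask logical raster of the currently foveated object
#'   (may be empty for background foveation)
#' @param pxPerDvaVal pixels per dva
#' @param params a \linkS4class{ModelParams}
#' @param prevAngle previous saccade direction in degrees, or NA before
#'   the first saccade (momentum raster is then 1 everywhere)
#' @param seg label raster (needed for the presaccadic extension)
#' @param V named accumulator vector (needed for the presaccadic extension)
#' @return sensitivity matrix S in (0, 1]
#' @export
sensitivityMap <- function(gaze, foveatedMask, pxPerDvaVal, params,
                           prevAngle = NA, seg = NULL, V = NULL) {
  h <- nrow(foveatedMask); w <- ncol(foveatedMask)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  sig <- params@sigmaS * pxPerDvaVal
  S <- exp(-((xs - gaze[1])^2 + (ys - gaze[2])^2) / (2 * sig^2))
  S[foveatedMask] <- 1
  if (isTRUE(params@momentum$enabled) && !is.na(prevAngle)) {
    ang <- atan2(ys - gaze[2], xs - gaze[1]) * 180 / pi
    dev <- abs(.wrapAngle(ang - prevAngle))
    mo <- params@momentum
    pref <- mo$maxValue - (mo$maxValue - mo$minValue) *
      pmin(dev, mo$angleRange) / mo$angleRange
    S <- S * pref
  }
  if (isTRUE(params@presaccadic$enabled) && length(V)) {
    hot <- names(V)[V > params@presaccadic$triggerFraction * params@theta]
    if (length(hot) && !is.null(seg))
      S[seg %in% as.integer(hot)] <- 1
  }
  S
}

#' Evidence map
#'
#' Elementwise product E = S * F' * U'.
#'
#' @param S,Fprime,Uprime rasters of equal size
#' @return evidence matrix
#' @export
evidenceMap <- function(S, Fprime, Uprime) {
  stopifnot(identical(dim(S), dim(Fprime)), identical(dim(S), dim(Uprime)))
  S * Fprime * Uprime
}

#' Per-object drift rates
#'
#' For each segment i, mu_i = mean(E over the mask) * max(1,
#' log2(area_i / pxPerDva^2)): the mask-mean evidence scaled
#' logarithmically by the object's area in dva^2.
#'
#' @param E evidence raster
#' @param seg label raster (every id > 0 is a potential target, including
#'   background segments)
#' @param pxPerDvaVal pixels per dva
#' @return named numeric vector of drift rates (names = segment ids)
#' @export
driftRates <- function(E, seg, pxPerDvaVal) {
  keep <- seg > 0L
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  v <- seg[keep]
  sums <- rowsum(E[keep], v)  # one row per id, sorted numerically
  cnt <- rowsum(rep(1, length(v)), v)[, 1]
  ids <- as.integer(rownames(sums))
  # order ids lexicographically so option order (and hence the RNG
  # pairing in the diffusion step) is stable across segmentations
  ord <- order(as.character(ids))
  mu <- (sums[ord, 1] / cnt[ord]) *
    pmax(1, log2(cnt[ord] / pxPerDvaVal^2))
  stats::setNames(as.numeric(mu), as.character(ids[ord]))
}

#' One drift-diffusion update step
#'
#' Each accumulator is incremented by nu * (mu_i * dt + s * eps_i *
#' sqrt(dt)) with independent standard-normal eps_i. If any accumulator
#' reaches the threshold, the earliest linearly-interpolated crossing
#' within the step wins (ties broken by larger drift, then lower id) and
#' all accumulators are reset to zero.
#'
#' @param V named accumulator vector (aligned to mu)
#' @param mu named drift-rate vector
#' @param params a \linkS4class{ModelParams}
#' @param nu fraction of the step spent foveating (0 during saccades)
#' @return list(V = updated accumulators, crossing = NULL or
#'   list(id, frac) with frac the fraction of the accumulating time at
#'   which the threshold was crossed)
#' @export
ddmStep <- function(V, mu, params, nu = 1) {
  stopifnot(nu >= 0, nu <= 1)
  # align accumulators to the current option set; new options start at
  # 0. Accumulators whose object is momentarily absent from the
  # segmentation are retained unchanged (identities are never reused),
  # so a one-frame segmentation flicker does not erase evidence.
  V0 <- stats::setNames(numeric(length(mu)), names(mu))
  keep <- intersect(names(V), names(mu))
  V0[keep] <- V[keep]
  dormant <- V[setdiff(names(V), names(mu))]
  if (nu == 0) return(list(V = c(V0, dormant), crossing = NULL))
  dt <- params@dt
  eps <- stats::rnorm(length(mu))
  inc <- nu * (mu * dt + params@noise * eps * sqrt(dt))
  V1 <- V0 + inc
  crossed <- which(V1 >= params@theta & inc > 0)
  if (!length(crossed)) return(list(V = c(V1, dormant), crossing = NULL))
  frac <- (params@theta - V0[crossed]) / inc[crossed]
  ord <- order(frac, -mu[crossed], as.integer(names(mu)[crossed]))
  win <- crossed[ord[1]]
  list(V = stats::setNames(numeric(length(mu) + length(dormant)),
                           c(names(mu), names(dormant))),
       crossing = list(id = as.integer(names(mu)[win]),
                       frac = as.numeric(frac[names(mu)[win]])))
}

#' Saccade duration from amplitude
#'
#' Linear amplitude-duration law: tau_s = 2.7 ms/dva * a_s + 23 ms.
#'
#' @param amplitudeDva saccade amplitude in dva (>= 0)
#' @return duration in ms
#' @export
saccadeDuration <- function(amplitudeDva) {
  stopifnot(all(amplitudeDva >= 0))
  2.7 * amplitudeDva + 23
}

#' Sample a saccade landing position within the target object
#'
#' One pixel is drawn with probability proportional to
#' O_i * F' * S inside the target mask; if the product vanishes
#' everywhere, the landing is uniform over the mask (with a warning).
#'
#' @param targetMask logical raster of the target object (nonempty)
#' @param Fprime rescaled feature raster
#' @param S sensitivity raster
#' @return landing position c(x, y) in px
#' @export
sampleLanding <- function(targetMask, Fprime, S) {
  idx <- which(targetMask)
  if (!length(idx)) stop("target mask is empty")
  w <- (Fprime * S)[idx]
  if (sum(w) == 0) {
    warning("degenerate landing weights; uniform over mask")
    w <- rep(1, length(idx))
  }
  pick <- idx[sample.int(length(idx), 1L, prob = w)]
  h <- nrow(targetMask)
  c(x = ((pick - 1L) %/% h) + 1L, y = ((pick - 1L) %% h) + 1L)
}

#' Advect the gaze with the optical flow (fixation / smooth pursuit)
#'
#' The gaze position moves with the bilinearly interpolated flow at its
#' current position and is clamped to the frame.
#'
#' @param gaze position c(x, y) in px
#' @param flow H x W x 2 flow array
#' @return updated position c(x, y)
#' @export
pursueGaze <- function(gaze, flow) {
  h <- dim(flow)[1]; w <- dim(flow)[2]
  x <- min(max(gaze[1], 1), w); y <- min(max(gaze[2], 1), h)
  x0 <- floor(x); x1 <- min(x0 + 1, w); y0 <- floor(y); y1 <- min(y0 + 1, h)
  ax <- x - x0; ay <- y - y0
  bi <- function(f)
    (1 - ax) * ((1 - ay) * f[y0, x0] + ay * f[y1, x0]) +
    ax * ((1 - ay) * f[y0, x1] + ay * f[y1, x1])
  out <- c(gaze[1] + bi(flow[, , 1]), gaze[2] + bi(flow[, , 2]))
  c(min(max(out[1], 1), w), min(max(out[2], 1), h))
}

.majority <- function(x) {
  if (!length(x)) return(0L)
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Simulate a scanpath on a scene
#'
#' Runs the full interconnected loop: per frame, cue measurements
#' (including the gaze-prompted object) update the segmentation belief
#' (predict, weight, incorporate, resample), the marginal segmentation is
#' identity-matched, the evidence map S * F' * U' drives the per-object
#' drift-diffusion race, and a threshold crossing triggers a saccade
#' (duration linear in amplitude, landing sampled within the target);
#' otherwise the gaze pursues the optical flow. No evidence is
#' accumulated during saccades or during the optional saccadic dead time,
#' which prolongs each foveation before the saccade is executed.
#'
#' @param scene a \linkS4class{Scene} with >= 2 frames
#' @param provider a \linkS4class{CueProvider}
#' @param params a \linkS4class{ModelParams}
#' @param seed RNG seed; the full run is reproducible from it
#' @param initGaze initial gaze c(x, y) in px, or NULL for uniform random
#' @param gtObjects if TRUE, the decision process consumes the
#'   ground-truth objects as perceptual units (background as one unit)
#'   while the uncertainty map is still computed by the filter
#' @param sceneId identifier recorded in the scanpath
#' @return a \linkS4class{Scanpath}
#' @export
simulateScanpath <- function(scene, provider, params = modelParams(),
                             seed = 1L, initGaze = NULL, gtObjects = FALSE,
                             sceneId = "scene") {
  T <- nFrames(scene)
  stopifnot(T >= 2)
  sz <- frameSize(scene)
  ppd <- pxPerDva(scene)
  fd <- 1000 / fps(scene)
  lambdaPx <- params@lambdaD * ppd
  windowPx <- 2 * ppd
  set.seed(as.integer(seed))
  gaze <- if (is.null(initGaze))
    c(stats::runif(1, 1, sz[2]), stats::runif(1, 1, sz[1]))
  else as.numeric(initGaze)

  belief <- NULL
  track <- trackState()
  V <- stats::setNames(numeric(0), character(0))
  prevAngle <- NA_real_
  accumFrom <- 0        # absolute ms before which no evidence accrues
  pending <- NULL       # in-progress saccade: land, landTime, sacStart
  fovStart <- 0
  fovId <- NA_integer_
  trace <- list()       # per-frame c(x, y, gt) while foveating
  rows <- list()

  emit <- function(...) rows[[length(rows) + 1L]] <<- list(...)

  for (t in 0:(T - 1L)) {
    t0 <- t * fd; t1 <- t0 + fd
    # saccade landing within this frame: jump at frame granularity
    if (!is.null(pending) && pending$landTime <= t1) {
      gaze <- pending$land
      fovStart <- pending$landTime
      fovId <- NA_integer_  # resolved from this frame's segmentation
      trace <- list()
      pending <- NULL
    }
    gz <- pmin(pmax(round(gaze), 1L), c(sz[2], sz[1]))

    glob <- provider@globalCues(scene, t, seed)
    pr <- provider@promptedCue(scene, t, gaze, seed)
    meas <- c(glob, if (!is.null(pr)) list(pr))

    belief <- if (is.null(belief))
      initialBelief(glob, params@nParticles)
    else predictBelief(belief, sceneFlow(scene, t - 1L))
    belief <- weightBelief(belief, meas, lambdaPx, windowPx)
    belief <- incorporateMeasurements(belief, meas,
                                      params@incorporateFraction)
    belief <- resampleBelief(belief)

    pb <- boundaryLikelihood(belief)
    H <- entropyMap(pb)
    if (gtObjects) {
      seg <- gtLabels(scene, t) + 1L
    } else {
      mi <- matchIds(mapSegmentation(pb, params@mapThreshold), track, t)
      seg <- mi$labels
      track <- mi$state
    }
    # the foveated perceptual unit is whatever segment currently
    # contains the gaze point (re-evaluated every frame, so identity
    # churn in the segmentation cannot detach the attentional spread)
    fovId <- seg[gz[2], gz[1]]

    # object-based attentional spread applies only to object-like
    # segments: those mostly supported by the global cues' measured
    # object segments (measured background regions do not count).
    # Foveating a background region leaves S a pure Gaussian.
    support <- Reduce(`|`, lapply(glob, function(m)
      m@labels > 0 & !(m@labels %in% m@background)))
    fovMask <- seg == fovId
    if (!any(fovMask) || mean(support[fovMask]) <= 0.5)
      fovMask <- matrix(FALSE, sz[1], sz[2])

    Fp <- scaleFeature(featureMap(scene, t), params@fMin)
    Up <- uncertaintyMap(H, params@blurSigma * ppd, params@uMin)$Uprime
    S <- sensitivityMap(gaze, fovMask, ppd, params, prevAngle, seg, V)
    E <- evidenceMap(S, Fp, Up)
    mu <- driftRates(E, seg, ppd)

    consumed <- min(max(accumFrom - t0, 0), fd)
    nu <- (fd - consumed) / fd
    if (nu > 0)
      trace[[length(trace) + 1L]] <-
        c(gaze, gtLabels(scene, t)[gz[2], gz[1]])

    step <- ddmStep(V, mu, params, nu)
    V <- step$V

    if (!is.null(step$crossing)) {
      crossMs <- t0 + consumed + step$crossing$frac * (fd - consumed)
      fovEnd <- crossMs + params@deadTimeMs
      tid <- step$crossing$id
      mask <- seg == tid
      land <- sampleLanding(mask, Fp, S)
      amp <- sqrt(sum((land - gaze)^2)) / ppd
      tau <- saccadeDuration(amp)
      ang <- atan2(land[2] - gaze[2], land[1] - gaze[1]) * 180 / pi
      gts <- vapply(trace, `[`, 0, 3)
      emit(event_type = "foveation", t_start_ms = fovStart,
           t_end_ms = fovEnd, x_px = gaze[1], y_px = gaze[2],
           object_id = fovId, gt_object_id = .majority(gts),
           angle_deg = NA_real_)
      emit(event_type = "saccade", t_start_ms = fovEnd,
           t_end_ms = fovEnd + tau, x_px = land[1], y_px = land[2],
           object_id = tid, gt_object_id = NA_integer_,
           angle_deg = ang, amplitude = amp)
      pending <- list(land = as.numeric(land), landTime = fovEnd + tau,
                      sacStart = fovEnd)
      accumFrom <- fovEnd + tau
      prevAngle <- ang
      V[] <- 0
      trace <- list()
    } else if ((is.null(pending) || t1 <= pending$sacStart) &&
               t < T - 1L) {
      gaze <- pursueGaze(gaze, sceneFlow(scene, t))
    }
  }

  tEnd <- T * fd
  if (is.null(pending)) {
    gts <- vapply(trace, `[`, 0, 3)
    emit(event_type = "foveation", t_start_ms = fovStart, t_end_ms = tEnd,
         x_px = gaze[1], y_px = gaze[2], object_id = fovId,
         gt_object_id = .majority(gts), angle_deg = NA_real_)
  }

  ev <- do.call(rbind, lapply(rows, function(r)
    data.frame(event_type = r$event_type, t_start_ms = r$t_start_ms,
               t_end_ms = r$t_end_ms, x_px = r$x_px, y_px = r$y_px,
               object_id = r$object_id, gt_object_id = r$gt_object_id,
               category = NA_character_,
               amplitude_dva = if (is.null(r$amplitude)) NA_real_
                               else r$amplitude,
               duration_ms = NA_real_, angle_deg = r$angle_deg,
               rel_angle_deg = NA_real_, seed = as.integer(seed))))
  # truncate events at clip end (a saccade in flight is cut short)
  ev <- ev[ev$t_start_ms < tEnd, , drop = FALSE]
  ev$t_end_ms <- pmin(ev$t_end_ms, tEnd)
  ev$duration_ms <- ev$t_end_ms - ev$t_start_ms
  sac <- which(ev$event_type == "saccade")
  if (length(sac) > 1)
    ev$rel_angle_deg[sac[-1]] <-
      .wrapAngle(ev$angle_deg[sac[-1]] - ev$angle_deg[sac[-length(sac)]])
  rownames(ev) <- NULL
  new("Scanpath", events = ev, sceneId = sceneId, seed = as.integer(seed),
      fps = fps(scene), pxPerDva = ppd)
}
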