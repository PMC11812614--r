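# Synthetic-scene generation and cue measurements.
#
# The generator emulates the statistical structure the segmentation filter
# sees on real video: several objects (possibly multi-part, possibly
# camouflaged) move on parametric trajectories in front of a static or
# translating camera; ground-truth labels, exact flow, and a saliency
# raster of peak-normalized Gaussian bumps are derived analytically.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps cue generation deterministic in
# (scene, t, gaze, seed) without disturbing the simulation RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Describe one synthetic object
#'
#' @param shape "disc" or "rect".
#' @param size disc radius in px, or c(halfwidth, halfheight) for rect.
#' @param center initial center c(x, y) in px at frame 0.
#' @param velocity translation in px/frame c(vx, vy); c(0, 0) for a static
#'   object.
#' @param parts number of vertical appearance sub-parts (>= 1) with
#'   distinct appearance identities; multi-part objects make the appearance
#'   cue over-segment relative to the semantic cue.
#' @param camouflage if TRUE the object is invisible to the appearance cue
#'   (merged into background), emulating an object of background-like color.
#' @param amplitude peak saliency of the object's feature bump in [0, 1].
#' @param featureSigma spread (px) of the feature bump; defaults to half
#'   the object's nominal radius, emulating the strong localization of
#'   video-saliency maps around the salient object's center.
#' @return list of class "objectSpec"
#' @export
objectSpec <- function(shape = c("disc", "rect"), size = 8,
                       center = c(0, 0), velocity = c(0, 0), parts = 1L,
                       camouflage = FALSE, amplitude = 1,
                       featureSigma = NULL) {
  shape <- match.arg(shape)
  if (is.null(featureSigma)) featureSigma <- max(size) / 2
  structure(list(shape = shape, size = size, center = center,
                 velocity = velocity, parts = as.integer(parts),
                 camouflage = camouflage, amplitude = amplitude,
                 featureSigma = featureSigma),
            class = "objectSpec")
}

#' Describe a synthetic scene
#'
#' @param nFrames number of frames T.
#' @param height,width frame size in px.
#' @param fps frames per second (default 30, a typical video frame rate).
#' @param pxPerDva pixels per degree of visual angle; the default 40.2
#'   corresponds to a display where 1536 px span 38.2 dva.
#' @param camera global camera translation c(vx, vy) in px/frame, applied
#'   to background and objects alike.
#' @param objects list of \code{\link{objectSpec}} descriptors; later
#'   objects occlude earlier ones (painter's order).
#' @return list of class "sceneSpec"
#' @export
sceneSpec <- function(nFrames, height, width, fps = 30,
                      pxPerDva = 1536 / 38.2, camera = c(0, 0),
                      objects = list()) {
  structure(list(nFrames = as.integer(nFrames), height = as.integer(height),
                 width = as.integer(width), fps = fps, pxPerDva = pxPerDva,
                 camera = camera, objects = objects),
            class = "sceneSpec")
}

#' Cue noise specification
#'
#' @param jitterPx maximum morphological boundary jitter of the semantic
#'   (and prompted) cue, in px; each object is randomly dilated or eroded
#'   by up to this radius.
#' @param mergeProb probability per object and frame that the semantic cue
#'   merges the whole object into the background (a whole-object miss).
#' @param splitProb probability per multi-part object and frame that the
#'   semantic cue splits the object into its appearance parts.
#' @param dropProb probability per appearance part and frame that the
#'   part merges into background in the appearance cue (an object of
#'   background-like color transiently disappearing from the
#'   appearance segmentation).
#' @return list of class "cueNoise"
#' @export
cueNoise <- function(jitterPx = 0, mergeProb = 0, splitProb = 0,
                     dropProb = 0) {
  structure(list(jitterPx = as.integer(jitterPx), mergeProb = mergeProb,
                 splitProb = splitProb, dropProb = dropProb),
            class = "cueNoise")
}

.rasterizeObject <- function(obj, center, height, width) {
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  if (obj$shape == "disc") {
    (xs - center[1])^2 + (ys - center[2])^2 <= obj$size[1]^2
  } else {
    hw <- if (length(obj$size) > 1) obj$size else rep(obj$size, 2)
    abs(xs - center[1]) <= hw[1] & abs(ys - center[2]) <= hw[2]
  }
}

#' Generate a synthetic Scene
#'
#' Rasterizes the analytic trajectories of a \code{\link{sceneSpec}} into
#' ground-truth labels, appearance-part labels, exact optical flow and a
#' saliency feature raster. Flow at a pixel follows the object finally
#' visible there (occluders win); background flow equals the camera
#' translation. The feature raster is the sum of peak-normalized Gaussian
#' bumps centered on the objects, capped to [0, 1].
#'
#' @param spec a \code{\link{sceneSpec}}
#' @param seed RNG seed (reserved; generation itself is deterministic)
#' @return a \linkS4class{Scene}
#' @export
generateScene <- function(spec, seed = 1L) {
  H <- spec$height; W <- spec$width; T <- spec$nFrames
  nobj <- length(spec$objects)
  labels <- array(0L, c(H, W, T))
  parts <- array(0L, c(H, W, T))
  feature <- array(0, c(H, W, T))
  flow <- array(0, c(H, W, 2L, max(T - 1L, 1L)))
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  maxParts <- if (nobj) max(vapply(spec$objects, `[[`, 1L, "parts")) else 1L

  for (t in seq_len(T) - 1L) {
    lab <- matrix(0L, H, W)
    prt <- matrix(0L, H, W)
    feat <- matrix(0, H, W)
    vx <- matrix(spec$camera[1], H, W)
    vy <- matrix(spec$camera[2], H, W)
    for (k in seq_len(nobj)) {
      obj <- spec$objects[[k]]
      ctr <- obj$center + t * (obj$velocity + spec$camera)
      m <- .rasterizeObject(obj, ctr, H, W)
      if (!any(m))
        stop("object ", k, " leaves the frame entirely at frame ", t)
      lab[m] <- k
      # vertical appearance parts over the mask's x-extent
      if (obj$parts > 1L) {
        xr <- range(xs[m])
        band <- pmin(obj$parts, 1L + as.integer(floor((xs - xr[1]) /
                 ((diff(xr) + 1) / obj$parts))))
        prt[m] <- (k - 1L) * maxParts + band[m]
      } else {
        prt[m] <- (k - 1L) * maxParts + 1L
      }
      v <- obj$velocity + spec$camera
      vx[m] <- v[1]; vy[m] <- v[2]
      feat <- feat + obj$amplitude *
        exp(-((xs - ctr[1])^2 + (ys - ctr[2])^2) / (2 * obj$featureSigma^2))
    }
    labels[, , t + 1L] <- lab
    parts[, , t + 1L] <- prt
    if (max(feat) > 1) feat <- feat / max(feat)
    feature[, , t + 1L] <- feat
    if (t < T - 1L) {
      flow[, , 1L, t + 1L] <- vx
      flow[, , 2L, t + 1L] <- vy
    }
  }
  meta <- if (nobj) data.frame(
    id = seq_len(nobj),
    camouflage = vapply(spec$objects, `[[`, FALSE, "camouflage"),
    amplitude = vapply(spec$objects, `[[`, 0, "amplitude"),
    vx = vapply(spec$objects, function(o) o$velocity[1], 0),
    vy = vapply(spec$objects, function(o) o$velocity[2], 0)
  ) else data.frame(id = integer(), camouflage = logical(),
                    amplitude = numeric(), vx = numeric(), vy = numeric())
  new("Scene", labels = labels, parts = parts, flow = flow,
      feature = feature, fps = spec$fps, pxPerDva = spec$pxPerDva,
      camera = as.numeric(spec$camera), objectMeta = meta)
}

#' Construct a cue measurement
#'
#' @param kind cue kind
#' @param labels integer label matrix
#' @param confidence positive weight multiplier
#' @param promptPoint prompt position c(x, y) for prompted cues
#' @param maskOnly TRUE for single-mask measurements
#' @param background labels denoting measured background regions
#' @return a \linkS4class{CueMeasurement}
#' @export
cueMeasurement <- function(kind, labels, confidence = 1,
                           promptPoint = c(NA_real_, NA_real_),
                           maskOnly = FALSE, background = integer(0)) {
  new("CueMeasurement", kind = kind, labels = labels,
      confidence = confidence, promptPoint = as.numeric(promptPoint),
      maskOnly = maskOnly, background = as.integer(background))
}

# Morphological boundary jitter of one object's binary mask: randomly
# dilate or erode by a light-tailed radius up to `jitter` px (disc
# brush). The radius is binomial with mean 0.3 * jitter, so the exact
# boundary remains the modal outcome and the jitter perturbs rather than
# dissolves the segment. Draws from the current RNG stream.
.jitterMask <- function(mask, jitter) {
  if (jitter <= 0) return(mask)
  r <- stats::rbinom(1L, jitter, 0.3)
  if (r == 0) return(mask)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- if (stats::runif(1) < 0.5) EBImage::dilate(m, brush)
         else EBImage::erode(m, brush)
  matrix(out > 0.5, nrow(mask), ncol(mask))
}

#' Global segmentation cues for one frame of a synthetic scene
#'
#' Emulates the characteristic disagreements of appearance-, motion- and
#' semantics-based segmentation backends: the appearance cue splits
#' multi-part objects into their parts and misses camouflaged objects; the
#' motion cue only contains objects moving relative to the background; the
#' semantic cue reproduces whole objects up to morphological boundary
#' jitter and occasional whole-object merge errors.
#'
#' @param scene a \linkS4class{Scene}
#' @param t 0-based frame index
#' @param noise a \code{\link{cueNoise}} specification
#' @param seed RNG seed; cues are deterministic in (scene, t, noise, seed)
#' @param confidence confidence assigned to each global cue
#' @param cues subset of c("appearance", "motion", "semantic") to produce
#' @return list of \linkS4class{CueMeasurement}
#' @export
syntheticCues <- function(scene, t, noise = cueNoise(), seed = 1L,
                          confidence = 1,
                          cues = c("appearance", "motion", "semantic")) {
  .checkFrame(scene, t)
  gt <- gtLabels(scene, t)
  out <- list()
  withSeed(seed * 10007L + t, {
    if ("appearance" %in% cues) {
      # appearance segmentation covers the full frame: background
      # texture forms its own region, and camouflaged objects or
      # dropped parts merge into it (they look like background)
      bgId <- 10000L
      prt <- partLabels(scene, t)
      camo <- scene@objectMeta$id[scene@objectMeta$camouflage]
      if (length(camo)) prt[gt %in% camo] <- 0L
      app <- matrix(bgId, nrow(gt), ncol(gt))
      for (pid in which(tabulate(prt) > 0)) {
        if (noise$dropProb > 0 && stats::runif(1) < noise$dropProb) next
        m <- .jitterMask(prt == pid, noise$jitterPx)
        app[m] <- pid
      }
      out <- c(out, cueMeasurement("appearance", app, confidence,
                                   background = bgId))
    }
    if ("motion" %in% cues) {
      fl <- sceneFlow(scene, min(t, nFrames(scene) - 2L))
      rel <- sqrt((fl[, , 1] - scene@camera[1])^2 +
                  (fl[, , 2] - scene@camera[2])^2)
      moving <- rel > 0.25
      mot <- matrix(as.integer(EBImage::bwlabel(
        matrix(as.numeric(moving), nrow(gt), ncol(gt)))), nrow(gt), ncol(gt))
      out <- c(out, cueMeasurement("motion", mot, confidence))
    }
    if ("semantic" %in% cues) {
      sem <- matrix(0L, nrow(gt), ncol(gt))
      ids <- sort(unique(gt[gt > 0]))
      for (k in ids) {
        if (stats::runif(1) < noise$mergeProb) next  # whole-object miss
        m <- .jitterMask(gt == k, noise$jitterPx)
        if (noise$splitProb > 0 && stats::runif(1) < noise$splitProb) {
          prt <- partLabels(scene, t)
          sem[m & gt == k] <- prt[m & gt == k] + 1000L * k
        } else {
          sem[m] <- k
        }
      }
      out <- c(out, cueMeasurement("semantic", sem, confidence))
    }
  })
  out
}

#' Gaze-prompted object measurement
#'
#' Returns the high-confidence mask of the object containing the gaze
#' point. With \code{level = "semantic"} the whole (multi-part) object is
#' returned; with \code{level = "appearance"} only the touched appearance
#' part, emulating a low-level prompt. On background, a local disc patch
#' (default radius 1 dva) excluding all objects is returned, so foveating
#' background still resolves uncertainty locally.
#'
#' @param scene a \linkS4class{Scene}
#' @param t 0-based frame index
#' @param gaze pixel position c(x, y)
#' @param noise a \code{\link{cueNoise}}; jitter applies to object masks
#' @param seed RNG seed
#' @param level "semantic" (whole object) or "appearance" (single part)
#' @param radiusDva radius of the background patch, in dva
#' @param confidence confidence of the prompted measurement (must exceed
#'   the global-cue confidence)
#' @return a \linkS4class{CueMeasurement} with \code{maskOnly = TRUE}
#' @export
promptedCue <- function(scene, t, gaze, noise = cueNoise(), seed = 1L,
                        level = c("semantic", "appearance"),
                        radiusDva = 1, confidence = 3) {
  level <- match.arg(level)
  .checkFrame(scene, t)
  gz <- round(gaze)
  sz <- frameSize(scene)
  gz <- pmin(pmax(gz, 1), c(sz[2], sz[1]))
  gt <- gtLabels(scene, t)
  hit <- gt[gz[2], gz[1]]
  withSeed(seed * 20011L + t, {
    if (hit > 0) {
      mask <- if (level == "semantic") gt == hit else {
        prt <- partLabels(scene, t)
        prt == prt[gz[2], gz[1]]
      }
      mask <- .jitterMask(mask, noise$jitterPx)
      mask[gz[2], gz[1]] <- TRUE  # prompt point always inside
      # keep the connected component containing the prompt point
      cc <- EBImage::bwlabel(matrix(as.numeric(mask), sz[1], sz[2]))
      mask <- cc == cc[gz[2], gz[1]]
    } else {
      xs <- matrix(seq_len(sz[2]), sz[1], sz[2], byrow = TRUE)
      ys <- matrix(seq_len(sz[1]), sz[1], sz[2])
      mask <- (xs - gz[1])^2 + (ys - gz[2])^2 <=
        (radiusDva * pxPerDva(scene))^2 & gt == 0
    }
    cueMeasurement("prompted", matrix(as.integer(mask), sz[1], sz[2]),
                   confidence = confidence, promptPoint = gz,
                   maskOnly = TRUE)
  })
}

#' Synthetic cue provider
#'
#' Packages \code{\link{syntheticCues}} and \code{\link{promptedCue}} into
#' the provider contract consumed by \code{\link{simulateScanpath}}. Cue
#' subsets and prompt level select the ablation conditions: low-level
#' global cues only (appearance + motion), high-level only (semantic), a
#' low-level (appearance) prompt, or no prompt at all.
#'
#' @param noise a \code{\link{cueNoise}} shared by all cues
#' @param cues global cue subset
#' @param prompt "semantic", "appearance", or "none"
#' @param globalConfidence confidence of global cues
#' @param promptConfidence confidence of the prompted cue
#' @return a \linkS4class{CueProvider}
#' @export
syntheticCueProvider <- function(noise = cueNoise(),
                                 cues = c("appearance", "motion", "semantic"),
                                 prompt = c("semantic", "appearance", "none"),
                                 globalConfidence = 1,
                                 promptConfidence = 3) {
  prompt <- match.arg(prompt)
  force(noise); force(cues)
  gfun <- function(scene, t, seed)
    syntheticCues(scene, t, noise, seed, globalConfidence, cues)
  # the prompted measurement is markedly more accurate than the global
  # cues (high-resolution, gaze-centered): one jitter level less
  pnoise <- cueNoise(max(0L, noise$jitterPx - 1L), 0, 0)
  pfun <- if (prompt == "none") function(scene, t, gaze, seed) NULL
          else function(scene, t, gaze, seed)
            promptedCue(scene, t, gaze, pnoise, seed, level = prompt,
                        confidence = promptConfidence)
  new("CueProvider", globalCues = gfun, promptedCue = pfun,
      name = paste0("synthetic[", paste(substr(cues, 1, 3), collapse = "+"),
                    ";prompt=", prompt, "]"))
}
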