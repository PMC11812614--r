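# Accessors and show methods. Rasters are returned as plain matrices;
# frame indices are 0-based everywhere.

#' @describeIn Scene-accessors number of frames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @describeIn Scene-accessors frame size c(height, width) in px
#' @export
setGeneric("frameSize", function(x) standardGeneric("frameSize"))

#' @describeIn Scene-accessors pixels per degree of visual angle
#' @export
setGeneric("pxPerDva", function(x) standardGeneric("pxPerDva"))

#' @describeIn Scene-accessors frames per second
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @describeIn Scene-accessors ground-truth label raster of frame t
#' @export
setGeneric("gtLabels", function(x, t) standardGeneric("gtLabels"))

#' @describeIn Scene-accessors appearance-part label raster of frame t
#' @export
setGeneric("partLabels", function(x, t) standardGeneric("partLabels"))

#' @describeIn Scene-accessors optical flow of frame t (H x W x 2 array,
#'   mapping t to t+1)
#' @export
setGeneric("sceneFlow", function(x, t) standardGeneric("sceneFlow"))

#' @describeIn Scene-accessors feature (saliency) raster of frame t
#' @export
setGeneric("featureMap", function(x, t) standardGeneric("featureMap"))

#' Scene accessors
#'
#' Read-only access to the per-frame rasters and geometry of a
#' \linkS4class{Scene}. Frame index \code{t} is 0-based; flow is defined for
#' \code{t = 0..T-2}.
#'
#' @param x a \linkS4class{Scene}
#' @param t 0-based frame index
#' @name Scene-accessors
NULL

.checkFrame <- function(x, t, flow = FALSE) {
  tmax <- dim(x@labels)[3] - 1L - as.integer(flow)
  if (t < 0 || t > tmax) stop("frame index out of range: ", t)
}

#' @rdname Scene-accessors
#' @export
setMethod("nFrames", "Scene", function(x) dim(x@labels)[3])

#' @rdname Scene-accessors
#' @export
setMethod("frameSize", "Scene", function(x) dim(x@labels)[1:2])

#' @rdname Scene-accessors
#' @export
setMethod("pxPerDva", "Scene", function(x) x@pxPerDva)

#' @rdname Scene-accessors
#' @export
setMethod("fps", "Scene", function(x) x@fps)

#' @rdname Scene-accessors
#' @export
setMethod("gtLabels", "Scene", function(x, t) {
  .checkFrame(x, t)
  x@labels[, , t + 1L]
})

#' @rdname Scene-accessors
#' @export
setMethod("partLabels", "Scene", function(x, t) {
  .checkFrame(x, t)
  x@parts[, , t + 1L]
})

#' @rdname Scene-accessors
#' @export
setMethod("sceneFlow", "Scene", function(x, t) {
  .checkFrame(x, t, flow = TRUE)
  x@flow[, , , t + 1L]
})

#' @rdname Scene-accessors
#' @export
setMethod("featureMap", "Scene", function(x, t) {
  .checkFrame(x, t)
  x@feature[, , t + 1L]
})

setMethod("show", "Scene", function(object) {
  d <- dim(object@labels)
  cat("Scene:", d[1], "x", d[2], "px,", d[3], "frames @", object@fps, "fps\n")
  cat("  px/dva:", object@pxPerDva, " objects:", nrow(object@objectMeta), "\n")
})

#' @describeIn SegmentationBelief-accessors number of particles
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' @describeIn SegmentationBelief-accessors label raster of particle i
#' @export
setGeneric("particleLabels", function(x, i) standardGeneric("particleLabels"))

#' @describeIn SegmentationBelief-accessors normalized particle weights
#' @export
setGeneric("particleWeights", function(x) standardGeneric("particleWeights"))

#' SegmentationBelief accessors
#'
#' @param x a \linkS4class{SegmentationBelief}
#' @param i particle index (1-based)
#' @name SegmentationBelief-accessors
NULL

#' @rdname SegmentationBelief-accessors
#' @export
setMethod("nParticles", "SegmentationBelief", function(x) length(x@particles))

#' @rdname SegmentationBelief-accessors
#' @export
setMethod("particleLabels", "SegmentationBelief", function(x, i) x@particles[[i]])

#' @rdname SegmentationBelief-accessors
#' @export
setMethod("particleWeights", "SegmentationBelief", function(x) x@weights)

setMethod("show", "SegmentationBelief", function(object) {
  d <- dim(object@particles[[1]])
  cat("SegmentationBelief:", length(object@particles), "particles of",
      d[1], "x", d[2], "px\n")
  cat("  effective sample size:",
      round(1 / sum(object@weights^2), 2), "\n")
})

#' @describeIn Scanpath-accessors full event table
#' @export
setGeneric("scanpathEvents", function(x) standardGeneric("scanpathEvents"))

#' @describeIn Scanpath-accessors foveation events only
#' @export
setGeneric("foveations", function(x) standardGeneric("foveations"))

#' @describeIn Scanpath-accessors saccade events only
#' @export
setGeneric("saccades", function(x) standardGeneric("saccades"))

#' Scanpath accessors
#'
#' @param x a \linkS4class{Scanpath}
#' @name Scanpath-accessors
NULL

#' @rdname Scanpath-accessors
#' @export
setMethod("scanpathEvents", "Scanpath", function(x) x@events)

#' @rdname Scanpath-accessors
#' @export
setMethod("foveations", "Scanpath", function(x)
  x@events[x@events$event_type == "foveation", , drop = FALSE])

#' @rdname Scanpath-accessors
#' @export
setMethod("saccades", "Scanpath", function(x)
  x@events[x@events$event_type == "saccade", , drop = FALSE])

setMethod("show", "Scanpath", function(object) {
  fov <- foveations(object)
  sac <- saccades(object)
  cat("Scanpath on", object@sceneId, "(seed", object@seed, "):",
      nrow(fov), "foveations,", nrow(sac), "saccades\n")
  if (nrow(fov))
    cat("  median foveation:", round(stats::median(fov$duration_ms), 1), "ms\n")
  if (nrow(sac))
    cat("  median amplitude:", round(stats::median(sac$amplitude_dva), 2), "dva\n")
})

setMethod("show", "DistributionFit", function(object) {
  cat("DistributionFit [", object@family, "]: ",
      paste(names(object@pars), "=", signif(object@pars, 4), collapse = ", "),
      "; E[X] = ", signif(object@expectedValue, 5), "\n", sep = "")
})

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams: theta =", object@theta, " s =", object@noise,
      " fMin =", round(object@fMin, 3), " uMin =", round(object@uMin, 3), "\n")
  cat("  sigmaS =", object@sigmaS, "dva, particles =", object@nParticles,
      ", deadTime =", object@deadTimeMs, "ms\n")
  if (isTRUE(object@momentum$enabled)) cat("  + saccadic momentum\n")
  if (isTRUE(object@presaccadic$enabled)) cat("  + presaccadic attention\n")
})
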