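#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib gazefilter, .registration = TRUE
NULL

#' Scene: a dynamic scene as frame-indexed rasters
#'
#' A \code{Scene} bundles everything the segmentation filter and the saccadic
#' decision process consume for one clip: per-frame ground-truth object
#' labels, appearance-part labels, dense optical flow, and a saliency-like
#' feature raster, together with the pixel-to-degree conversion.
#'
#' Rasters are plain matrices indexed \code{[y, x]} (row = vertical pixel
#' coordinate); positions are length-2 vectors \code{c(x, y)} in pixels.
#' Frames are indexed \code{0..T-1} throughout the package, matching the
#' convention that \code{flow[,,,t+1]} maps frame \code{t} to \code{t+1}.
#'
#' @slot labels integer array \code{H x W x T}, ground-truth object identity
#'   per pixel (0 = background); identities are stable across frames.
#' @slot parts integer array \code{H x W x T}, appearance-part identity per
#'   pixel; distinct ids across objects (0 = background).
#' @slot flow numeric array \code{H x W x 2 x (T-1)}, optical flow in
#'   px/frame; slice 1 is the x (column) displacement, slice 2 the y (row)
#'   displacement, mapping frame t to t+1.
#' @slot feature numeric array \code{H x W x T}, saliency feature raster in
#'   \code{[0, 1]}.
#' @slot fps frames per second.
#' @slot pxPerDva pixels per degree of visual angle.
#' @slot camera length-2 camera translation (px/frame) used at generation.
#' @slot objectMeta data.frame with one row per synthetic object
#'   (id, camouflage, amplitude, vx, vy).
#' @exportClass Scene
setClass("Scene", representation(
  labels = "array", parts = "array", flow = "array", feature = "array",
  fps = "numeric", pxPerDva = "numeric", camera = "numeric",
  objectMeta = "data.frame"
))

setValidity("Scene", function(object) {
  d <- dim(object@labels)
  if (length(d) != 3) return("labels must be an H x W x T array")
  if (!identical(dim(object@feature), d)) return("feature dims must match labels")
  if (!identical(dim(object@parts), d)) return("parts dims must match labels")
  if (d[3] > 1) {
    fd <- dim(object@flow)
    if (!identical(fd, c(d[1], d[2], 2L, d[3] - 1L)))
      return("flow must be H x W x 2 x (T-1)")
  }
  rng <- range(object@feature)
  if (rng[1] < 0 || rng[2] > 1) return("feature raster must lie in [0, 1]")
  if (object@pxPerDva <= 0) return("pxPerDva must be positive")
  TRUE
})

#' CueMeasurement: one segmentation measurement for one frame
#'
#' Global cues (appearance, motion, semantic) carry a full-frame label
#' raster with 0 marking background/absent; the gaze-prompted cue carries a
#' single object mask (\code{maskOnly = TRUE}) at high confidence.
#'
#' @slot kind one of \code{"appearance"}, \code{"motion"}, \code{"semantic"},
#'   \code{"prompted"}.
#' @slot labels integer label matrix (segment ids local to the measurement).
#' @slot confidence positive scalar weight multiplier; the prompted cue must
#'   have higher confidence than the global cues.
#' @slot promptPoint pixel position \code{c(x, y)} (prompted cues only).
#' @slot maskOnly logical; TRUE if the measurement covers a single object
#'   mask rather than the full frame.
#' @slot background labels (if any) that denote measured background
#'   regions rather than objects: the appearance cue segments background
#'   texture into regions too, and those regions assert "no object
#'   here", unlike unlabeled (0) pixels which assert nothing.
#' @exportClass CueMeasurement
setClass("CueMeasurement", representation(
  kind = "character", labels = "matrix", confidence = "numeric",
  promptPoint = "numeric", maskOnly = "logical", background = "integer"
))

setValidity("CueMeasurement", function(object) {
  if (!object@kind %in% c("appearance", "motion", "semantic", "prompted"))
    return("unknown cue kind")
  if (object@confidence <= 0) return("confidence must be positive")
  if (object@kind == "prompted") {
    segs <- unique(object@labels[object@labels > 0])
    if (length(segs) != 1) return("prompted cue must contain exactly one segment")
    p <- round(object@promptPoint)
    if (object@labels[p[2], p[1]] == 0)
      return("prompted segment must contain the prompt point")
  }
  TRUE
})

#' CueProvider: pluggable source of segmentation measurements
#'
#' Behavioral contract abstracting over segmentation backends: given a scene
#' and frame index, return the global cue measurements; given additionally a
#' gaze point, return the prompted measurement (or NULL when prompting is
#' disabled). Providers must be deterministic given (scene, t, gaze, seed).
#'
#' @slot globalCues function(scene, t, seed) -> list of CueMeasurement.
#' @slot promptedCue function(scene, t, gaze, seed) -> CueMeasurement or NULL.
#' @slot name provider label used in logs.
#' @exportClass CueProvider
setClass("CueProvider", representation(
  globalCues = "function", promptedCue = "function", name = "character"
))

#' SegmentationBelief: weighted particle set over scene segmentations
#'
#' Each particle is one full-scene segmentation hypothesis (integer label
#' matrix); the weighted set represents the posterior over segmentations
#' given the measurement history.
#'
#' @slot particles list of integer label matrices, all of equal dimension.
#' @slot weights numeric particle weights, normalized to sum to 1.
#' @exportClass SegmentationBelief
setClass("SegmentationBelief", representation(
  particles = "list", weights = "numeric"
))

setValidity("SegmentationBelief", function(object) {
  if (length(object@particles) != length(object@weights))
    return("one weight per particle required")
  if (length(object@weights) == 0) return("belief must contain particles")
  if (any(!is.finite(object@weights)) || any(object@weights < 0))
    return("weights must be finite and nonnegative")
  if (abs(sum(object@weights) - 1) > 1e-8)
    return("weights must sum to 1")
  d <- dim(object@particles[[1]])
  for (p in object@particles)
    if (!identical(dim(p), d)) return("particles must share dimensions")
  TRUE
})

#' TrackState: identity bookkeeping for object tracking
#'
#' Holds the recent history of identity-resolved segmentations used by the
#' discounted-IoU bipartite matcher, plus the counter for fresh identities.
#'
#' @slot history list of identity-resolved integer label matrices (newest
#'   last), at most \code{horizon} entries.
#' @slot historyIds per-entry sorted identity vectors (cached).
#' @slot frames integer frame indices of the history entries.
#' @slot nextId next unused identity (identities are never reused).
#' @slot discount per-step decay factor gamma in (0, 1] applied to older
#'   history frames when scoring overlaps.
#' @slot floor minimum discounted-IoU weight for a match edge to be kept.
#' @slot horizon number of history frames retained.
#' @exportClass TrackState
setClass("TrackState", representation(
  history = "list", historyIds = "list", frames = "integer",
  nextId = "integer", discount = "numeric", floor = "numeric",
  horizon = "integer"
))

setValidity("TrackState", function(object) {
  if (object@discount <= 0 || object@discount > 1)
    return("discount must be in (0, 1]")
  if (length(object@history) > object@horizon)
    return("history exceeds horizon")
  TRUE
})

#' ModelParams: tunable parameters of the scanpath model
#'
#' @slot fMin floor of the rescaled feature map F' in [0, 1]; higher values
#'   weaken the influence of saliency.
#' @slot uMin floor of the rescaled uncertainty map U' in [0, 1]; higher
#'   values weaken the influence of segmentation uncertainty (uMin = 1
#'   removes it).
#' @slot theta decision threshold of the drift-diffusion process.
#' @slot noise diffusion noise level s (per sqrt(frame)).
#' @slot sigmaS spread of the visual-sensitivity Gaussian, in dva.
#' @slot dt accumulator update step in frames.
#' @slot lambdaD length scale (dva) of the exponential measurement
#'   likelihood in the particle filter.
#' @slot blurSigma Gaussian blur applied to the entropy map, in dva.
#' @slot nParticles particle count of the segmentation filter.
#' @slot incorporateFraction fraction of particles into which measurements
#'   are directly incorporated each frame.
#' @slot mapThreshold boundary-likelihood threshold for the most-likely
#'   segmentation.
#' @slot momentum list(enabled, maxValue, minValue, angleRange) for the
#'   saccadic-momentum sensitivity bias.
#' @slot presaccadic list(enabled, triggerFraction) for presaccadic
#'   attention spread.
#' @slot deadTimeMs saccadic dead time in ms appended to each foveation.
#' @exportClass ModelParams
setClass("ModelParams", representation(
  fMin = "numeric", uMin = "numeric", theta = "numeric", noise = "numeric",
  sigmaS = "numeric", dt = "numeric", lambdaD = "numeric",
  blurSigma = "numeric", nParticles = "integer",
  incorporateFraction = "numeric", mapThreshold = "numeric",
  momentum = "list", presaccadic = "list", deadTimeMs = "numeric"
))

setValidity("ModelParams", function(object) {
  if (object@theta <= 0) return("theta must be positive")
  if (object@noise < 0) return("noise must be nonnegative")
  if (object@sigmaS <= 0) return("sigmaS must be positive")
  if (object@fMin < 0 || object@fMin > 1) return("fMin must be in [0, 1]")
  if (object@uMin < 0 || object@uMin > 1) return("uMin must be in [0, 1]")
  tf <- object@presaccadic$triggerFraction
  if (!is.null(tf) && (tf <= 0 || tf >= 1))
    return("presaccadic trigger fraction must be in (0, 1)")
  TRUE
})

#' Scanpath: ordered foveation and saccade events of one simulation
#'
#' @slot events data.frame with columns event_type, t_start_ms, t_end_ms,
#'   x_px, y_px, object_id, gt_object_id, category, amplitude_dva,
#'   duration_ms, angle_deg, rel_angle_deg, seed. Events alternate
#'   foveation/saccade in time order.
#' @slot sceneId scene identifier.
#' @slot seed RNG seed of the simulation.
#' @slot fps frames per second of the scene.
#' @slot pxPerDva pixels per degree of visual angle.
#' @exportClass Scanpath
setClass("Scanpath", representation(
  events = "data.frame", sceneId = "character", seed = "integer",
  fps = "numeric", pxPerDva = "numeric"
))

setValidity("Scanpath", function(object) {
  ev <- object@events
  need <- c("event_type", "t_start_ms", "t_end_ms", "x_px", "y_px",
            "object_id", "gt_object_id", "category", "amplitude_dva",
            "duration_ms", "angle_deg", "rel_angle_deg", "seed")
  if (!all(need %in% names(ev))) return("events table is missing columns")
  if (nrow(ev) && any(ev$t_end_ms < ev$t_start_ms))
    return("events must have nonnegative duration")
  TRUE
})

#' DistributionFit: parametric fit of a scanpath statistic
#'
#' @slot family "lognormal" or "gamma".
#' @slot pars named parameters: meanlog/sdlog (lognormal) or shape/rate
#'   (gamma).
#' @slot expectedValue closed-form expected value: exp(mu + sigma^2/2) for
#'   the lognormal, shape/rate for the gamma.
#' @exportClass DistributionFit
setClass("DistributionFit", representation(
  family = "character", pars = "numeric", expectedValue = "numeric"
))
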