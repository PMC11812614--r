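# Canonical synthetic scenes used in examples, tests and the acceptance
# battery. The three-object scene is the package's standard desk-scale
# study condition: one moving two-part object (appearance and motion cues
# disagree with the semantic cue), one static salient object (absent from
# the motion cue), and one camouflaged static object (absent from the
# appearance cue), so the cue ensemble sustains segmentation uncertainty
# the way real video cues do.

#' Canonical synthetic example scenes
#'
#' \code{"three-object"} builds the standard evaluation scene: a moving
#' two-part disc, a static salient two-part disc, and a camouflaged
#' static rectangle on a static background. Multi-part objects keep the
#' appearance and semantic cues in structural disagreement over object
#' interiors (the parts-versus-whole ambiguity typical of real
#' segmentation backends), which the gaze-contingent prompt resolves. \code{"single-object"} holds one
#' salient static disc. Both default to 128 x 128 px at 4 px/dva: a
#' 32 dva wide field, proportioned like a wide free-viewing display, so
#' eccentricity genuinely attenuates sensitivity at the 7 dva spread of
#' the sensitivity Gaussian.
#'
#' @param kind scene variant
#' @param nFrames number of frames
#' @param size frame side length in px
#' @param pxPerDva pixels per dva
#' @return a \linkS4class{Scene}
#' @export
exampleScene <- function(kind = c("three-object", "single-object"),
                         nFrames = 90L, size = 128L, pxPerDva = 4) {
  kind <- match.arg(kind)
  s <- size / 128
  objects <- switch(kind,
    "three-object" = list(
      objectSpec("disc", round(10 * s), c(24, 40) * s,
                 velocity = c(1, 0), parts = 2L, amplitude = 0.8),
      objectSpec("disc", round(9 * s), c(90, 36) * s, parts = 2L,
                 amplitude = 1.0),
      objectSpec("rect", round(c(9, 12) * s), c(64, 95) * s,
                 camouflage = TRUE, amplitude = 0.6)),
    "single-object" = list(
      objectSpec("disc", round(10 * s), c(64, 64) * s, amplitude = 1.0)))
  generateScene(sceneSpec(nFrames, size, size, fps = 30,
                          pxPerDva = pxPerDva, objects = objects))
}

#' Default cue noise of the example scenes
#'
#' Light boundary jitter (1 px) and occasional whole-object semantic
#' misses. Structural cue disagreements (camouflage, multi-part objects,
#' static objects absent from the motion cue) carry most of the
#' segmentation uncertainty, as they do for real segmentation backends;
#' heavier jitter would smear the boundary likelihood below the map
#' threshold and dissolve objects entirely.
#'
#' @return a \code{\link{cueNoise}}
#' @export
exampleNoise <- function()
  cueNoise(jitterPx = 1, mergeProb = 0.05, dropProb = 0.15)

#' Calibrated parameter sets for the standard evaluation conditions
#'
#' Model parameters for the base model and its uncertainty/prompt
#' ablations on the three-object example scene. The decision threshold
#' and noise level were fit per condition by a grid search minimizing
#' the mean of the foveation-duration and saccade-amplitude
#' Kolmogorov-Smirnov distances against reference samples drawn from
#' the human summary distributions (log-normal durations, gamma
#' amplitudes); the base model keeps theta = 4. Candidates scoring
#' within 0.01 of the best are treated as tied and resolved toward the
#' parameters closest to the base model. Refitting per condition
#' mirrors how the threshold and noise are chosen anew whenever the
#' uncertainty weighting changes or the prompted cue is removed, so
#' that conditions are compared at matched summary statistics. The
#' methods vignette documents the calibration.
#'
#' @param condition evaluation condition: \code{"base"} (uMin = 1/3),
#'   \code{"high-uncertainty"} (uMin = 0), \code{"no-uncertainty"}
#'   (uMin = 1), or \code{"no-prompt"} (base uncertainty, prompted cue
#'   removed at the provider).
#' @return a \linkS4class{ModelParams}
#' @export
referenceParams <- function(condition = c("base", "high-uncertainty",
                                          "no-uncertainty",
                                          "no-prompt")) {
  condition <- match.arg(condition)
  switch(condition,
    "base" = modelParams(),
    "high-uncertainty" = modelParams(uMin = 0, theta = 2.75, noise = 0.35),
    "no-uncertainty" = modelParams(uMin = 1, theta = 5, noise = 0.2),
    "no-prompt" = modelParams(theta = 7, noise = 0.35))
}
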