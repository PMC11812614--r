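# Scanpath evaluation: foveation categories, their time course, empirical
# distribution statistics and parametric fits, the relative-saccade-angle
# profile of foveation durations (temporal inhibition of return), and the
# grid-search driver for parameter fitting.

#' Classify foveations into functional categories
#'
#' Each foveation is labeled by its role in exploration, based on the
#' ground-truth object under the gaze (majority over the foveation's
#' positional trace, recorded at simulation time):
#' \emph{Background} if on no object; \emph{Detection} if on an object
#' never foveated before within this scanpath; \emph{Inspection} if on
#' the same object as the immediately preceding foveation; \emph{Return}
#' if on a previously foveated object that is not the immediately
#' preceding one.
#'
#' @param scanpath a \linkS4class{Scanpath}
#' @return the scanpath with the category column filled in
#' @export
classifyFoveations <- function(scanpath) {
  ev <- scanpath@events
  fi <- which(ev$event_type == "foveation")
  seen <- integer(0)
  lastObj <- NA_integer_
  for (i in fi) {
    g <- ev$gt_object_id[i]
    ev$category[i] <- if (is.na(g) || g == 0) "Background"
      else if (!is.na(lastObj) && g == lastObj) "Inspection"
      else if (g %in% seen) "Return"
      else "Detection"
    if (!is.na(g) && g > 0) {
      seen <- union(seen, g)
      lastObj <- g
    } else lastObj <- NA_integer_
  }
  scanpath@events <- ev
  scanpath
}

#' Share of foveation time per category over time
#'
#' Splits the clip into windows and computes, per window, the share of
#' foveation time spent in each category (shares sum to 1 in every
#' window with any foveation time; empty windows are omitted).
#'
#' @param scanpaths list of classified \linkS4class{Scanpath} objects
#' @param windowMs window length in ms
#' @return data.frame(window_start_ms, category, share)
#' @export
categoryTimeCourse <- function(scanpaths, windowMs = 500) {
  if (is(scanpaths, "Scanpath")) scanpaths <- list(scanpaths)
  fov <- do.call(rbind, lapply(scanpaths, foveations))
  if (is.null(fov) || !nrow(fov)) stop("no foveations")
  if (anyNA(fov$category)) stop("run classifyFoveations first")
  tmax <- max(fov$t_end_ms)
  starts <- seq(0, tmax - 1e-9, by = windowMs)
  cats <- c("Background", "Detection", "Inspection", "Return")
  out <- list()
  for (ws in starts) {
    ov <- pmax(0, pmin(fov$t_end_ms, ws + windowMs) -
                  pmax(fov$t_start_ms, ws))
    tot <- sum(ov)
    if (tot <= 0) next
    sh <- vapply(cats, function(cc) sum(ov[fov$category == cc]) / tot, 0)
    out[[length(out) + 1L]] <- data.frame(window_start_ms = ws,
                                          category = cats, share = sh)
  }
  do.call(rbind, out)
}

#' Average share of foveation time per category
#'
#' @param scanpaths list of classified \linkS4class{Scanpath} objects
#' @return named numeric shares (sum to 1)
#' @export
categoryShares <- function(scanpaths) {
  if (is(scanpaths, "Scanpath")) scanpaths <- list(scanpaths)
  fov <- do.call(rbind, lapply(scanpaths, foveations))
  if (anyNA(fov$category)) stop("run classifyFoveations first")
  cats <- c("Background", "Detection", "Inspection", "Return")
  tot <- sum(fov$duration_ms)
  vapply(cats, function(cc)
    sum(fov$duration_ms[fov$category == cc]) / tot, 0)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum distance between the two empirical cumulative distribution
#' functions, D = sup_x |N(x) - M(x)|.
#'
#' @param a,b nonempty numeric samples
#' @return D in [0, 1]
#' @export
ksStatistic <- function(a, b) {
  if (!length(a) || !length(b)) stop("samples must be nonempty")
  x <- sort(unique(c(a, b)))
  Fa <- vapply(x, function(v) mean(a <= v), 0)
  Fb <- vapply(x, function(v) mean(b <= v), 0)
  max(abs(Fa - Fb))
}

#' Construct a distribution fit from known parameters
#'
#' @param family "lognormal" or "gamma"
#' @param pars named parameters: c(meanlog=, sdlog=) or c(shape=, rate=)
#' @return a \linkS4class{DistributionFit} with the closed-form expected
#'   value: exp(meanlog + sdlog^2 / 2) for the lognormal, shape / rate for
#'   the gamma
#' @export
distributionFit <- function(family = c("lognormal", "gamma"), pars) {
  family <- match.arg(family)
  ev <- if (family == "lognormal")
    exp(pars[["meanlog"]] + pars[["sdlog"]]^2 / 2)
  else pars[["shape"]] / pars[["rate"]]
  new("DistributionFit", family = family, pars = pars, expectedValue = ev)
}

#' Maximum-likelihood fit of a log-normal or gamma distribution
#'
#' @param sample positive-valued numeric sample
#' @param family "lognormal" or "gamma"
#' @return a \linkS4class{DistributionFit}
#' @export
fitDistribution <- function(sample, family = c("lognormal", "gamma")) {
  family <- match.arg(family)
  if (any(sample <= 0)) stop("sample must be positive-valued")
  fd <- fitdistrplus::fitdist(as.numeric(sample),
                              if (family == "lognormal") "lnorm" else "gamma")
  distributionFit(family, fd$estimate)
}

#' Relative-saccade-angle profile of foveation durations
#'
#' For every pair of consecutive saccades, the relative angle (signed
#' difference of their directions, wrapped to (-180, 180]) is binned into
#' 30 bins of 12 degrees, and the median duration of the foveation between
#' the two saccades is computed per bin. A centered circular moving
#' average across 5 bins (skipping empty bins, renormalized window)
#' smooths the medians. Longer pre-return (|angle| near 180) than
#' pre-forward (|angle| near 0) foveations indicate temporal inhibition
#' of return.
#'
#' @param scanpaths list of \linkS4class{Scanpath} objects
#' @param binWidth bin width in degrees (default 12)
#' @param smoothBins moving-average window in bins (default 5)
#' @return data.frame(bin_center, n, median_ms, smoothed_ms)
#' @export
angleProfile <- function(scanpaths, binWidth = 12, smoothBins = 5) {
  if (is(scanpaths, "Scanpath")) scanpaths <- list(scanpaths)
  pairs <- list()
  for (sp in scanpaths) {
    ev <- sp@events
    sac <- which(ev$event_type == "saccade")
    if (length(sac) < 2) next
    for (k in 2:length(sac)) {
      fovBetween <- which(ev$event_type == "foveation" &
                          seq_len(nrow(ev)) > sac[k - 1] &
                          seq_len(nrow(ev)) < sac[k])
      if (!length(fovBetween)) next
      rel <- .wrapAngle(ev$angle_deg[sac[k]] - ev$angle_deg[sac[k - 1]])
      pairs[[length(pairs) + 1L]] <-
        c(rel, ev$duration_ms[fovBetween[1]])
    }
  }
  breaks <- seq(-180, 180, by = binWidth)
  nb <- length(breaks) - 1L
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  med <- rep(NA_real_, nb)
  n <- integer(nb)
  if (length(pairs)) {
    m <- do.call(rbind, pairs)
    # half-open bins (lo, hi]; -180 is wrapped to +180 upstream
    bin <- findInterval(m[, 1], breaks, left.open = TRUE,
                        rightmost.closed = TRUE)
    bin[bin < 1] <- 1L
    for (b in seq_len(nb)) {
      sel <- bin == b
      n[b] <- sum(sel)
      if (n[b]) med[b] <- stats::median(m[sel, 2])
    }
  }
  half <- (smoothBins - 1L) %/% 2L
  sm <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    idx <- ((b - half - 1L):(b + half - 1L)) %% nb + 1L
    vals <- med[idx]
    if (any(!is.na(vals))) sm[b] <- mean(vals, na.rm = TRUE)
  }
  data.frame(bin_center = centers, n = n, median_ms = med,
             smoothed_ms = sm)
}

#' Grid search over the model's free parameters
#'
#' For every grid point (noise s, threshold theta, fMin, uMin), simulates
#' \code{nSeeds} scanpaths per scene, pools the foveation durations and
#' saccade amplitudes, and scores the point by the mean of the two
#' Kolmogorov-Smirnov statistics against the reference samples
#' (D_FD + D_SA) / 2. Optionally refines with one pass at factor-2 finer
#' spacing around the best point of each uMin value.
#'
#' @param scenes list of \linkS4class{Scene} objects
#' @param provider a \linkS4class{CueProvider}
#' @param grid data.frame with columns noise, theta, fMin, uMin
#' @param reference list(durations = ..., amplitudes = ...) reference
#'   samples (ms, dva)
#' @param nSeeds scanpaths per scene per grid point (default 5)
#' @param baseParams \linkS4class{ModelParams} supplying the non-searched
#'   parameters
#' @param refine run the per-uMin refinement pass
#' @return list(ranking = scored grid sorted by score, refined = best
#'   point per uMin after refinement)
#' @export
gridSearch <- function(scenes, provider, grid, reference, nSeeds = 5L,
                       baseParams = modelParams(), refine = FALSE) {
  stopifnot(all(c("noise", "theta", "fMin", "uMin") %in% names(grid)))
  score1 <- function(row) {
    p <- baseParams
    p@noise <- row$noise; p@theta <- row$theta
    p@fMin <- row$fMin; p@uMin <- row$uMin
    dur <- c(); amp <- c()
    ok <- TRUE
    for (sc in scenes) for (s in seq_len(nSeeds)) {
      sp <- tryCatch(simulateScanpath(sc, provider, p, seed = s),
                     error = function(e) NULL)
      if (is.null(sp)) { ok <- FALSE; next }
      dur <- c(dur, foveations(sp)$duration_ms)
      amp <- c(amp, saccades(sp)$amplitude_dva)
    }
    if (!ok || !length(dur) || !length(amp))
      return(c(NA_real_, NA_real_, NA_real_))
    dfd <- ksStatistic(dur, reference$durations)
    dsa <- ksStatistic(amp, reference$amplitudes)
    c(dfd, dsa, (dfd + dsa) / 2)
  }
  scoreGrid <- function(g) {
    sc <- t(vapply(seq_len(nrow(g)), function(i) score1(g[i, ]),
                   numeric(3)))
    g$D_FD <- sc[, 1]; g$D_SA <- sc[, 2]; g$score <- sc[, 3]
    g$valid <- !is.na(g$score)
    g
  }
  ranked <- scoreGrid(grid)
  ranked <- ranked[order(ranked$score), ]
  refined <- NULL
  if (refine) {
    refined <- list()
    for (u in unique(grid$uMin)) {
      sub <- ranked[ranked$uMin == u & ranked$valid, ]
      if (!nrow(sub)) next
      best <- sub[1, ]
      stepOf <- function(v) if (length(unique(v)) > 1)
        min(diff(sort(unique(v)))) / 2 else 0
      ds <- stepOf(grid$noise); dt <- stepOf(grid$theta)
      df <- stepOf(grid$fMin)
      cand <- expand.grid(
        noise = unique(pmax(best$noise + ds * (-1:1), 1e-6)),
        theta = unique(pmax(best$theta + dt * (-1:1), 1e-6)),
        fMin = unique(pmin(pmax(best$fMin + df * (-1:1), 0), 1)),
        uMin = u)
      cg <- scoreGrid(cand)
      cg <- cg[order(cg$score), ]
      refined[[as.character(u)]] <- cg[1, ]
    }
  }
  list(ranking = ranked, refined = refined)
}
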