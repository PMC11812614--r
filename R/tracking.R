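# Object identity tracking: keeps segment identities stable over time by
# discounted-IoU maximum-weight bipartite matching between the segments of
# the current most-likely segmentation and the identities present in the
# recent segmentation history.

#' Create an empty tracking state
#'
#' @param discount per-step decay gamma applied to older history frames
#'   (newest frame has weight 1, a frame k steps back gamma^(k-1))
#' @param floor minimum discounted-IoU weight for a match edge to be kept
#' @param horizon number of past identity-resolved frames retained
#' @return a \linkS4class{TrackState}
#' @export
trackState <- function(discount = 0.9, floor = 0.1, horizon = 10L) {
  new("TrackState", history = list(), historyIds = list(),
      frames = integer(), nextId = 1L, discount = discount,
      floor = floor, horizon = as.integer(horizon))
}

# Discounted-IoU weight matrix between old identities and new segments.
.matchWeights <- function(current, segs, state) {
  oldIds <- sort(unique(unlist(state@historyIds)))
  maxOld <- max(oldIds)
  maxSeg <- max(segs)
  W <- matrix(0, length(oldIds), length(segs),
              dimnames = list(oldIds, segs))
  nh <- length(state@history)
  for (k in seq_len(nh)) {
    h <- state@history[[k]]
    g <- state@discount^(nh - k)  # newest history frame discount 1
    oc <- cpp_overlap_counts(h, current, maxOld, maxSeg)
    inter <- oc$inter[oldIds, segs, drop = FALSE]
    un <- outer(oc$na[oldIds], oc$nb[segs], `+`) - inter
    iou <- ifelse(un > 0, inter / un, 0)
    iou[oc$na[oldIds] == 0, ] <- 0
    W <- W + g * iou
  }
  W
}

# Maximum-weight bipartite matching on a weight matrix (rows = old ids,
# cols = new segments); returns per-column matched row index or NA.
.maxWeightMatch <- function(W) {
  keep <- which(W > 0, arr.ind = TRUE)
  if (!nrow(keep)) return(rep(NA_integer_, ncol(W)))
  nr <- nrow(W); nc <- ncol(W)
  edges <- rbind(keep[, 1], nr + keep[, 2])
  g <- igraph::make_bipartite_graph(rep(c(TRUE, FALSE), c(nr, nc)),
                                    edges = as.vector(edges),
                                    directed = FALSE)
  m <- igraph::max_bipartite_match(
    g, types = rep(c(TRUE, FALSE), c(nr, nc)),
    weights = W[keep])
  match <- m$matching[nr + seq_len(nc)]
  ifelse(is.na(match), NA_integer_, as.integer(match))
}

#' Match segment identities against the tracking history
#'
#' Scores every (old identity, new segment) pair by the sum over history
#' frames of the discounted intersection-over-union of their masks, removes
#' edges below the weight floor, and solves the maximum-weight bipartite
#' matching (Hungarian-style): matched segments inherit the old identity,
#' unmatched segments receive fresh identities (never reused). The history
#' is updated with the relabeled raster.
#'
#' @param current integer label raster (every segment id > 0 participates;
#'   0 pixels, if present, are left untouched)
#' @param state a \linkS4class{TrackState}
#' @param frame frame index recorded with the history entry
#' @return list(labels = identity-resolved raster, state = updated state)
#' @export
matchIds <- function(current, state, frame = length(state@frames)) {
  segs <- which(tabulate(current) > 0)  # ascending ids > 0
  if (!length(segs)) stop("current segmentation has no segments")
  out <- matrix(0L, nrow(current), ncol(current))
  if (!length(state@history)) {
    assign <- state@nextId + seq_along(segs) - 1L
    state@nextId <- state@nextId + length(segs)
  } else {
    W <- .matchWeights(current, segs, state)
    W[W < state@floor] <- 0
    rowMatch <- .maxWeightMatch(W)
    oldIds <- as.integer(rownames(W))
    assign <- integer(length(segs))
    for (si in seq_along(segs)) {
      if (!is.na(rowMatch[si])) {
        assign[si] <- oldIds[rowMatch[si]]
      } else {
        assign[si] <- state@nextId
        state@nextId <- state@nextId + 1L
      }
    }
  }
  for (si in seq_along(segs)) out[current == segs[si]] <- assign[si]
  state@history <- c(state@history, list(out))
  state@historyIds <- c(state@historyIds, list(sort(assign)))
  state@frames <- c(state@frames, as.integer(frame))
  if (length(state@history) > state@horizon) {
    state@history <- state@history[-1]
    state@historyIds <- state@historyIds[-1]
    state@frames <- state@frames[-1]
  }
  list(labels = out, state = state)
}
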