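# Shared fixtures and independent oracles. Oracles are deliberately
# naive (brute force / enumeration) and never call the code paths they
# check.

# small moving-disc scene: one object translating (+2, 0) px/frame
movingDiscScene <- function(nFrames = 6L, size = 48L, ppd = 8) {
  generateScene(sceneSpec(nFrames, size, size, pxPerDva = ppd,
    objects = list(objectSpec("disc", 7, c(15, 24), velocity = c(2, 0)))))
}

# two-object scene: a static two-part rect and a moving disc
twoObjectScene <- function(nFrames = 8L, size = 64L, ppd = 8) {
  generateScene(sceneSpec(nFrames, size, size, pxPerDva = ppd,
    objects = list(
      objectSpec("rect", c(8, 6), c(20, 40), parts = 2L, amplitude = 0.7),
      objectSpec("disc", 6, c(44, 20), velocity = c(1, 0), amplitude = 1))))
}

# vertical-split raster: labels 1 | 2 with the first column of label 2
# at `col`
splitRaster <- function(col, n = 32L) {
  m <- matrix(1L, n, n)
  m[, col:n] <- 2L
  m
}

# canonical relabeling by first occurrence, for label-permutation
# equivalent comparison
canonicalize <- function(lab) {
  u <- unique(as.vector(lab))
  matrix(match(lab, u), nrow(lab), ncol(lab))
}

expect_label_equivalent <- function(a, b) {
  expect_identical(canonicalize(a), canonicalize(b))
}

# brute-force symmetric mean nearest-boundary distance: all-pairs over
# boundary pixels, with the same two-sided 4-neighbor boundary
# convention
bruteBoundaryPixels <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  out <- NULL
  for (r in seq_len(n)) for (c in seq_len(m)) {
    v <- lab[r, c]
    if ((r > 1 && lab[r - 1, c] != v) || (r < n && lab[r + 1, c] != v) ||
        (c > 1 && lab[r, c - 1] != v) || (c < m && lab[r, c + 1] != v))
      out <- rbind(out, c(r, c))
  }
  out
}

bruteBoundaryDistance <- function(a, b) {
  pa <- bruteBoundaryPixels(a)
  pb <- bruteBoundaryPixels(b)
  if (is.null(pa) && is.null(pb)) return(0)
  one <- function(from, to) {
    mean(apply(from, 1, function(p)
      min(sqrt((to[, 1] - p[1])^2 + (to[, 2] - p[2])^2))))
  }
  if (is.null(pa)) return(one(pb, pb) * NA) # caller avoids this case
  if (is.null(pb)) return(one(pa, pa) * NA)
  mean(c(one(pa, pb), one(pb, pa)))
}

# brute-force two-sample KS statistic by evaluating both ECDFs on the
# pooled grid
bruteKS <- function(a, b) {
  grid <- sort(c(a, b))
  max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# brute-force maximum-weight assignment over all injective column->row
# maps (including leaving columns unassigned)
bruteMaxAssignment <- function(W) {
  nc <- ncol(W); nr <- nrow(W)
  best <- 0
  rec <- function(col, used, total) {
    if (col > nc) { best <<- max(best, total); return(invisible()) }
    rec(col + 1, used, total) # leave unassigned
    for (r in seq_len(nr)) if (!used[r] && W[r, col] > 0) {
      used[r] <- TRUE
      rec(col + 1, used, total + W[r, col])
      used[r] <- FALSE
    }
  }
  rec(1L, rep(FALSE, nr), 0)
  best
}
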