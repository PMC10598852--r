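#' Binarize a grayscale image
#'
#' Foreground is the brighter class. With `method = "otsu"` the threshold is
#' computed by Otsu's method (via \pkg{EBImage}); with `method = "fixed"` a
#' gray-level threshold in `[0, 255]` must be supplied. A constant image
#' cannot be thresholded by Otsu and yields an all-background mask with a
#' warning.
#'
#' @param image Integer/numeric matrix of gray levels 0-255.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Gray level for `method = "fixed"`; pixels strictly above
#'   it become foreground.
#' @return Integer 0/1 matrix of the same shape (a binary mask).
#' @export
#' @examples
#' img <- matrix(c(0, 0, 255, 255), 2, 2)
#' binarize(img)
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  stopf(is.matrix(image) && length(image) > 0, "image must be a non-empty matrix")
  if (method == "fixed") {
    stopf(is.numeric(threshold) && length(threshold) == 1 &&
            threshold >= 0 && threshold <= 255,
          "fixed method requires a threshold in [0, 255]")
    thr <- threshold
  } else {
    if (diff(range(image)) == 0) {
      warning("constant image: Otsu threshold undefined, returning all-background mask")
      return(matrix(0L, nrow(image), ncol(image)))
    }
    thr <- EBImage::otsu(EBImage::Image(image / 255), range = c(0, 1)) * 255
  }
  mask <- matrix(as.integer(image > thr), nrow(image), ncol(image))
  mask
}

# pad a 0/1 matrix with a 1-pixel background ring
pad_mask <- function(mask) {
  p <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  p
}

# the eight neighbour planes of the interior of a padded mask, in the
# clockwise ring order P2..P9 starting north
neighbor_planes <- function(p) {
  nr <- nrow(p) - 2L; nc <- ncol(p) - 2L
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  list(
    P2 = p[ri - 1L, ci, drop = FALSE],      # N
    P3 = p[ri - 1L, ci + 1L, drop = FALSE], # NE
    P4 = p[ri, ci + 1L, drop = FALSE],      # E
    P5 = p[ri + 1L, ci + 1L, drop = FALSE], # SE
    P6 = p[ri + 1L, ci, drop = FALSE],      # S
    P7 = p[ri + 1L, ci - 1L, drop = FALSE], # SW
    P8 = p[ri, ci - 1L, drop = FALSE],      # W
    P9 = p[ri - 1L, ci - 1L, drop = FALSE]  # NW
  )
}

# deletion map for one subiteration, computed from the state at entry
# (parallel semantics). Returns a logical matrix over the unpadded shape.
zs_deletions <- function(mask, subiteration) {
  np <- neighbor_planes(pad_mask(mask))
  B <- Reduce(`+`, np)
  ring <- c(np, np[1])                      # P2..P9, P2
  A <- Reduce(`+`, lapply(seq_len(8), function(i) {
    (ring[[i]] == 0L) * (ring[[i + 1L]] == 1L)
  }))
  base <- mask == 1L & B >= 2L & B <= 6L & A == 1L
  if (subiteration == 1L) {
    base & (np$P2 * np$P4 * np$P6 == 0L) & (np$P4 * np$P6 * np$P8 == 0L)
  } else {
    base & (np$P2 * np$P4 * np$P8 == 0L) & (np$P2 * np$P6 * np$P8 == 0L)
  }
}

#' Neighbourhood statistics of one mask pixel
#'
#' Returns `B`, the number of foreground 8-neighbours, and `A`, the number of
#' 0-to-1 transitions in the clockwise neighbour ring starting north
#' (the ordered sequence N, NE, E, SE, S, SW, W, NW, N). The mask border is
#' treated as padded with background.
#'
#' @param mask Integer 0/1 matrix.
#' @param pixel `c(row, col)`, 0-based.
#' @return Named integer vector `c(B = ..., A = ...)`.
#' @export
neighbor_stats <- function(mask, pixel) {
  r <- pixel[1] + 1L; c <- pixel[2] + 1L
  stopf(r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask),
        "pixel outside the mask")
  p <- pad_mask(mask)
  r <- r + 1L; c <- c + 1L
  ring <- c(p[r - 1, c], p[r - 1, c + 1], p[r, c + 1], p[r + 1, c + 1],
            p[r + 1, c], p[r + 1, c - 1], p[r, c - 1], p[r - 1, c - 1])
  seq9 <- c(ring, ring[1])
  c(B = sum(ring), A = sum(seq9[-9] == 0L & seq9[-1] == 1L))
}

#' Thin a binary mask to a unit-width skeleton
#'
#' Two-subiteration fast parallel thinning. In each subiteration every
#' foreground pixel whose neighbourhood satisfies `2 <= B <= 6`, `A == 1` and
#' the subiteration's directional conditions (subiteration 1:
#' `P2*P4*P6 == 0` and `P4*P6*P8 == 0`; subiteration 2: `P2*P4*P8 == 0` and
#' `P2*P6*P8 == 0`) is deleted; deletion decisions are taken from the grid
#' state at the start of the subiteration. The pair of subiterations is
#' repeated until no pixel is deleted, so the result is a fixpoint of the
#' rules.
#'
#' @param mask Integer 0/1 matrix.
#' @return Integer 0/1 matrix of the same shape: the skeleton.
#' @export
#' @examples
#' m <- matrix(0L, 7, 7); m[2:6, 2:6] <- 1L
#' thin(m)
thin <- function(mask) {
  stopf(is.matrix(mask) && all(mask %in% c(0L, 1L)), "mask must be a 0/1 matrix")
  g <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- zs_deletions(g, sub)
      if (any(del)) {
        g[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g
}

# label 8-connected components of a 0/1 matrix; returns the component count.
# Two-pass is overkill here: simple BFS flood fill over foreground pixels.
count_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  fg <- which(mask == 1L)
  for (p0 in fg) {
    if (lab[p0] != 0L) next
    nxt <- nxt + 1L
    queue <- p0
    lab[p0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] == 1L && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- c(queue, (cc - 1L) * nr + rr)
        }
      }
    }
  }
  nxt
}
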