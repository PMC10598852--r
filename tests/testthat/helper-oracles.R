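# Independent, deliberately naive oracles used to cross-check the package's
# vectorized implementations on small inputs.

# Naive per-pixel two-subiteration thinning: explicit loops, explicit ring
# walk, no shared code with teapick::thin().
naive_thin <- function(mask) {
  g <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  get <- function(r, c) {
    if (r < 1 || r > nrow(g) || c < 1 || c > ncol(g)) 0L else g[r, c]
  }
  deletable <- function(r, c, phase) {
    # ring P2..P9 clockwise from north
    p <- c(get(r - 1, c), get(r - 1, c + 1), get(r, c + 1), get(r + 1, c + 1),
           get(r + 1, c), get(r + 1, c - 1), get(r, c - 1), get(r - 1, c - 1))
    B <- sum(p)
    if (B < 2 || B > 6) return(FALSE)
    s <- c(p, p[1])
    A <- 0L
    for (i in 1:8) if (s[i] == 0 && s[i + 1] == 1) A <- A + 1L
    if (A != 1) return(FALSE)
    if (phase == 1) {
      p[1] * p[3] * p[5] == 0 && p[3] * p[5] * p[7] == 0
    } else {
      p[1] * p[3] * p[7] == 0 && p[1] * p[5] * p[7] == 0
    }
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      dels <- NULL
      for (r in seq_len(nrow(g))) for (c in seq_len(ncol(g))) {
        if (g[r, c] == 1L && deletable(r, c, phase)) dels <- rbind(dels, c(r, c))
      }
      if (!is.null(dels)) {
        g[dels] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g
}

# Naive 8-connected component count by repeated seed fill.
naive_components <- function(mask) {
  g <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  n <- 0L
  while (any(g == 1L)) {
    n <- n + 1L
    seed <- which(g == 1L)[1]
    comp <- matrix(FALSE, nrow(g), ncol(g))
    comp[seed] <- TRUE
    repeat {
      grown <- comp
      idx <- which(comp, arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        for (dr in -1:1) for (dc in -1:1) {
          r <- idx[k, 1] + dr; c <- idx[k, 2] + dc
          if (r >= 1 && r <= nrow(g) && c >= 1 && c <= ncol(g) && g[r, c] == 1L) {
            grown[r, c] <- TRUE
          }
        }
      }
      if (identical(grown, comp)) break
      comp <- grown
    }
    g[comp] <- 0L
  }
  n
}

# Random organ-like binary mask: thick strokes of varying orientation and
# thickness with bud-like disks attached to them — the kind of foreground a
# binarized image of stems and leaves produces. Isolated round blobs are
# deliberately not generated: the parallel thinning rules erase small
# symmetric blobs entirely (see the dedicated unit test), which would make a
# component-count comparison meaningless rather than wrong.
random_blob_mask <- function(nr = 32, nc = 32, n_strokes = 2, n_disks = 2) {
  m <- matrix(0L, nr, nc)
  rows <- matrix(rep(seq_len(nr), nc), nr)
  cols <- matrix(rep(seq_len(nc), each = nr), nr)
  anchors <- NULL
  for (i in seq_len(n_strokes)) {
    # keep the whole stroke inside the frame: a stroke clipped at the border
    # leaves a compact stub, which the parallel rules can erase like any
    # small blob
    repeat {
      r0 <- runif(1, 4, nr - 3); c0 <- runif(1, 4, nc - 3)
      ang <- runif(1, 0, pi)
      len <- runif(1, 8, 20)
      hw <- runif(1, 1, 2.5)
      r1 <- r0 + len * sin(ang); c1 <- c0 + len * cos(ang)
      if (r1 > hw + 1 && r1 < nr - hw && c1 > hw + 1 && c1 < nc - hw &&
          r0 > hw + 1 && r0 < nr - hw && c0 > hw + 1 && c0 < nc - hw) break
    }
    t <- seq(0, 1, length.out = 40)
    pr <- r0 + t * (r1 - r0); pc <- c0 + t * (c1 - c0)
    for (k in seq_along(t)) {
      m[(rows - pr[k])^2 + (cols - pc[k])^2 <= hw^2] <- 1L
    }
  }
  # bud-like disks centred on foreground pixels, so they stay connected to a
  # stroke and cannot vanish as isolated blobs under the parallel rules
  anchors <- which(m == 1L, arr.ind = TRUE)
  for (i in seq_len(n_disks)) {
    a <- anchors[sample(nrow(anchors), 1), ]
    rad <- runif(1, 2, 4)
    m[(rows - a[1])^2 + (cols - a[2])^2 <= rad^2] <- 1L
  }
  m
}

# Build one rendered synthetic shoot with a perfectly straight, vertical stem
# (used wherever an exactly known geometry is needed).
vertical_shoot_scene <- function(seed = 5, n_shoots = 1) {
  cfg <- scene_config(ranges = utils::modifyList(shoot_param_ranges(),
                                                 list(curvature_amplitude = c(0, 0))))
  truth <- build_scene(n_shoots, cfg, seed = seed)
  scene <- render_scene(truth, seed = seed)
  list(truth = truth, scene = scene,
       calib = camera_calibration(Ht = scene$image_height_Ht))
}
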