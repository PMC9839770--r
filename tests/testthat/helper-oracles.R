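# Brute-force oracles, written independently of the implementation paths
# they check.

# Connected components by label propagation: start with unique labels and
# repeatedly relabel every foreground pixel to the minimum label among itself
# and its 8 neighbours until nothing changes.
oracle_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask == 1L] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (c in seq_len(W)) for (r in seq_len(H)) {
      if (mask[r, c] == 0L) next
      for (dc in -1:1) for (dr in -1:1) {
        nr <- r + dr; nc <- c + dc
        if (nr < 1 || nr > H || nc < 1 || nc > W) next
        if (mask[nr, nc] == 1L && lab[nr, nc] < lab[r, c]) {
          lab[r, c] <- lab[nr, nc]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sets <- split(which(lab > 0L), lab[lab > 0L])
  lapply(unname(sets), function(ix) {
    px <- cbind((ix - 1L) %% H + 1L, (ix - 1L) %/% H + 1L)
    px[order(px[, 2], px[, 1]), , drop = FALSE]
  })
}

# Set-based segmentation metrics from explicit foreground pixel index sets.
oracle_metrics <- function(pred, truth) {
  X <- which(pred == 1L); Y <- which(truth == 1L)
  n <- length(pred)
  inter <- length(intersect(X, Y)); uni <- length(union(X, Y))
  iou <- if (uni == 0) 1 else inter / uni
  dice <- if (length(X) + length(Y) == 0) 1 else 2 * inter / (length(X) + length(Y))
  bgX <- setdiff(seq_len(n), X); bgY <- setdiff(seq_len(n), Y)
  accs <- c()
  if (length(Y) > 0) accs <- c(accs, inter / length(Y))
  if (length(bgY) > 0) accs <- c(accs, length(intersect(bgX, bgY)) / length(bgY))
  list(iou = iou, dice = dice, mpa = mean(accs),
       iou_bg = if (length(union(bgX, bgY)) == 0) 1 else
         length(intersect(bgX, bgY)) / length(union(bgX, bgY)))
}

# Convex-polygon point containment by the half-plane test (all cross
# products the same sign, zero meaning on the boundary).
oracle_in_convex <- function(px, py, v) {
  n <- nrow(v)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (v[j, 1] - v[i, 1]) * (py - v[i, 2]) - (v[j, 2] - v[i, 2]) * (px - v[i, 1])
    if (abs(cr) < 1e-9) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

# Random convex polygon: points on a jittered circle, in angular order.
random_convex_polygon <- function(n, cx, cy, radius) {
  ang <- sort(runif(n, 0, 2 * pi))
  cbind(cx + radius * cos(ang), cy + radius * sin(ang))
}

random_mask <- function(H, W, p = 0.3) {
  matrix(as.integer(runif(H * W) < p), H, W)
}

# A quick easy-synthetic config for unit tests (small frames, fast).
tiny_synth_config <- function(seed = 1L, n = 64L) {
  synthetic_config(height = n, width = n, n_teeth = 3L,
                   lesion_side_mean = 7, lesion_side_sd = 1, seed = seed)
}
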