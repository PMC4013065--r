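# Brute-force geometric oracles, deliberately independent of the package
# implementation (no contour tracing, no chull, no calipers).

# Corner points (x, y) of all foreground pixels of a mask.
oracle_all_corners <- function(mask) {
  rc <- which(unclass(mask), arr.ind = TRUE)
  xy <- rbind(cbind(rc[, 2] - 0.5, rc[, 1] - 0.5),
              cbind(rc[, 2] + 0.5, rc[, 1] - 0.5),
              cbind(rc[, 2] - 0.5, rc[, 1] + 0.5),
              cbind(rc[, 2] + 0.5, rc[, 1] + 0.5))
  unique(xy)
}

# O(n^2) maximum pairwise distance.
oracle_max_diameter <- function(pts) {
  d2 <- 0
  for (i in seq_len(nrow(pts) - 1L)) {
    di <- (pts[-seq_len(i), 1] - pts[i, 1])^2 +
      (pts[-seq_len(i), 2] - pts[i, 2])^2
    d2 <- max(d2, max(di))
  }
  sqrt(d2)
}

# O(n^3) convex hull via the edge half-plane test: (i, j) is a hull edge
# iff every other point lies on or to the left of the directed line i->j.
# Returns hull area by the shoelace formula on the ordered edge cycle.
oracle_hull_area <- function(pts) {
  n <- nrow(pts)
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- pts[i, ]; b <- pts[j, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
      (b[2] - a[2]) * (pts[, 1] - a[1])
    if (all(cr >= -1e-9)) edges[[length(edges) + 1L]] <- c(i, j)
  }
  el <- do.call(rbind, edges)
  # order the cycle
  start <- el[1, 1]
  cyc <- start
  cur <- start
  repeat {
    nxt <- el[el[, 1] == cur, 2]
    # pick the farthest collinear continuation to skip interior edge points
    if (length(nxt) > 1L) {
      d <- (pts[nxt, 1] - pts[cur, 1])^2 + (pts[nxt, 2] - pts[cur, 2])^2
      nxt <- nxt[which.max(d)]
    }
    if (nxt == start) break
    cyc <- c(cyc, nxt)
    cur <- nxt
  }
  v <- pts[cyc, , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Exhaustive orientation sweep for the minimum-area enclosing rectangle.
oracle_min_rect_area <- function(pts, step_deg = 0.1) {
  best <- Inf
  for (th in seq(0, 90 - step_deg, by = step_deg) * pi / 180) {
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
    pu <- pts[, 1] * u[1] + pts[, 2] * u[2]
    pv <- pts[, 1] * v[1] + pts[, 2] * v[2]
    best <- min(best, diff(range(pu)) * diff(range(pv)))
  }
  best
}

# A small pseudo-random blob mask: a chain of overlapping discs, so the
# foreground is a single connected component by construction.
random_blob_mask <- function(seed, size = 60L, ndisc = 4L) {
  set.seed(seed)
  g <- matrix(FALSE, size, size)
  i <- seq_len(size)
  r0 <- size / 2; c0 <- size / 2
  rad <- runif(1, size * 0.1, size * 0.2)
  for (k in seq_len(ndisc)) {
    g <- g | outer(i, i, function(r, c) (r - r0)^2 + (c - c0)^2 <= rad^2)
    th <- runif(1, 0, 2 * pi)
    newrad <- runif(1, size * 0.08, size * 0.18)
    step <- 0.8 * rad  # next disc overlaps the current one
    r0 <- min(max(r0 + step * sin(th), newrad + 2), size - newrad - 2)
    c0 <- min(max(c0 + step * cos(th), newrad + 2), size - newrad - 2)
    rad <- newrad
  }
  binary_mask(g)
}

# Deterministic rosette parameter draw for property tests.
random_rosette_params <- function(seed) {
  set.seed(seed)
  rosette_params(n_leaves = sample(3:10, 1),
                 leaf_length = runif(1, 6, 14),
                 leaf_width = runif(1, 3, 7),
                 petiole_length = runif(1, 0, 6),
                 jitter_sd = runif(1, 0, 0.8),
                 image_size = 160L, px_per_mm = 3)
}
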