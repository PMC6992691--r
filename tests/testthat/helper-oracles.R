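# Independent oracles, deliberately implemented by different algorithms
# than the package code they check.

# Even-odd ray-casting point-in-polygon (package uses winding number).
# Boundary points are resolved to TRUE explicitly, matching the retention
# rule under test.
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- ring[i, 1]; ay <- ring[i, 2]
    bx <- ring[j, 1]; by <- ring[j, 2]
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    if (abs(cross) < 1e-12 &&
        px >= min(ax, bx) - 1e-12 && px <= max(ax, bx) + 1e-12 &&
        py >= min(ay, by) - 1e-12 && py <= max(ay, by) + 1e-12) {
      return(TRUE)
    }
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- ring[i, 1]; ay <- ring[i, 2]
    bx <- ring[j, 1]; by <- ring[j, 2]
    if ((ay > py) != (by > py)) {
      xint <- ax + (py - ay) / (by - ay) * (bx - ax)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# O(n^3) brute-force convex hull area: every ordered vertex pair defines a
# candidate hull edge iff all other points lie on one side; the hull area is
# the shoelace sum over the resulting edge cycle.
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3L) return(0)
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      others <- pts[-c(i, j), , drop = FALSE]
      cross <- (pts[j, 1] - pts[i, 1]) * (others[, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (others[, 1] - pts[i, 1])
      if (all(cross <= 1e-9)) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  if (length(edges) < 3L) return(0)
  # walk the edge cycle
  em <- do.call(rbind, edges)
  start <- em[1, 1]
  cyc <- c(start)
  cur <- em[1, 2]
  while (cur != start) {
    cyc <- c(cyc, cur)
    nxt <- em[em[, 1] == cur, 2]
    nxt <- nxt[!nxt %in% cyc | nxt == start]
    if (length(nxt) == 0L) break
    cur <- nxt[[1]]
  }
  hx <- pts[cyc, 1]; hy <- pts[cyc, 2]
  m <- length(hx)
  jx <- c(m, seq_len(m - 1L))
  abs(sum(hx[jx] * hy - hx * hy[jx])) / 2
}

# Brute-force occupancy-grid cell count on already-projected km coordinates,
# enumerating cell labels directly (origin-centred cells, matching the
# documented grid anchor).
oracle_cell_count <- function(x, y, cell_km) {
  labs <- character()
  for (i in seq_along(x)) {
    lab <- paste(floor(x[i] / cell_km + 0.5), floor(y[i] / cell_km + 0.5))
    if (!lab %in% labs) labs <- c(labs, lab)
  }
  length(labs)
}

# Naive per-record confusion-matrix loop for one threshold.
oracle_confusion <- function(metric, truth, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(metric)) {
    pred <- metric[i] >= threshold
    if (pred && truth[i]) tp <- tp + 1L
    else if (pred && !truth[i]) fp <- fp + 1L
    else if (!pred && !truth[i]) tn <- tn + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}
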