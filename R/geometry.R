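# Honeycomb lobule skeleton: nodes (portal triads), septa (paired boundary
# sub-segments with a prismatic joint), revolute joints at triads, and
# hexagon descriptors. Flat-top hexagons; continuous 2-D coordinates with the
# patch's lower-left corner at the origin, y up.

SQRT3 <- sqrt(3)

#' Build a honeycomb lattice of hexagonal lobules
#'
#' Constructs the structural skeleton of a rectangular patch of
#' `n_rows x n_cols` flat-top hexagonal lobules with side (circumradius)
#' `hex_side`: portal-triad nodes at every hexagon vertex, one septum per
#' edge (each septum is a side-by-side pair of boundary sub-segments joined
#' by a prismatic joint and attached to its end nodes by revolute joints).
#'
#' @param n_rows,n_cols number of lobule rows and columns (>= 1).
#' @param hex_side hexagon side length in simulation length units (> 0).
#' @return An object of class `lobule_lattice`: a list with `nodes`
#'   (data frame: `id`, `x`, `y`, `degree`, `is_outer`), `septa`
#'   (`id`, `node_a`, `node_b`, `length`), `joints` (prismatic: one row per
#'   septum with its unit `axis`; revolute: one row per septum end with its
#'   `anchor` node), `lobules` (`id`, `cx`, `cy`), `lobule_nodes` (list of
#'   the 6 node ids per lobule), `hex_side`, `centers` (lobule centre
#'   matrix) and `patch_extent` (xmin, xmax, ymin, ymax).
#' @examples
#' lat <- build_lattice(2, 2, 1)
#' nrow(lat$nodes); nrow(lat$septa)
#' @export
build_lattice <- function(n_rows, n_cols, hex_side) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("n_rows and n_cols must be positive integers", call. = FALSE)
  }
  if (!is.numeric(hex_side) || hex_side <= 0) {
    stop("hex_side must be a positive length", call. = FALSE)
  }
  centers <- hex_grid_centers(n_rows, n_cols, hex_side)
  build_lattice_from_centers(centers, hex_side)
}

# Centres of a rectangular flat-top honeycomb (odd columns shifted up).
hex_grid_centers <- function(n_rows, n_cols, s) {
  ij <- expand.grid(i = seq_len(n_cols) - 1L, j = seq_len(n_rows) - 1L)
  cbind(x = 1.5 * s * ij$i,
        y = SQRT3 * s * (ij$j + 0.5 * (ij$i %% 2L)))
}

# Core builder shared by the rectangular grid and ad-hoc arrangements such
# as the seven-lobule ring fixture. Vertices shared between hexagons are
# merged by a rounded-coordinate key.
build_lattice_from_centers <- function(centers, hex_side) {
  s <- hex_side
  ang <- (0:5) * pi / 3
  vx_off <- s * cos(ang)
  vy_off <- s * sin(ang)

  n_hex <- nrow(centers)
  key_of <- function(x, y) sprintf("%.6f_%.6f", x, y)

  node_x <- numeric(0); node_y <- numeric(0)
  node_key <- character(0)
  lobule_nodes <- vector("list", n_hex)
  edge_a <- integer(0); edge_b <- integer(0); edge_nhex <- integer(0)
  edge_key <- character(0)

  node_env <- new.env(hash = TRUE, parent = emptyenv())
  edge_env <- new.env(hash = TRUE, parent = emptyenv())

  for (h in seq_len(n_hex)) {
    vx <- centers[h, 1] + vx_off
    vy <- centers[h, 2] + vy_off
    ids <- integer(6)
    for (k in 1:6) {
      ky <- key_of(vx[k], vy[k])
      id <- node_env[[ky]]
      if (is.null(id)) {
        node_x <- c(node_x, vx[k]); node_y <- c(node_y, vy[k])
        id <- length(node_x)
        node_env[[ky]] <- id
      }
      ids[k] <- id
    }
    lobule_nodes[[h]] <- ids
    for (k in 1:6) {
      a <- ids[k]; b <- ids[if (k == 6) 1 else k + 1]
      ky <- paste(min(a, b), max(a, b), sep = "-")
      eid <- edge_env[[ky]]
      if (is.null(eid)) {
        edge_a <- c(edge_a, min(a, b)); edge_b <- c(edge_b, max(a, b))
        eid <- length(edge_a)
        edge_env[[ky]] <- eid
        edge_nhex <- c(edge_nhex, 1L)
      } else {
        edge_nhex[eid] <- edge_nhex[eid] + 1L
      }
    }
  }

  # shift so the patch's lower-left bounding corner is the origin
  x0 <- min(node_x); y0 <- min(node_y)
  node_x <- node_x - x0; node_y <- node_y - y0
  centers <- cbind(x = centers[, 1] - x0, y = centers[, 2] - y0)

  degree <- tabulate(c(edge_a, edge_b), nbins = length(node_x))
  boundary_edge <- edge_nhex == 1L
  is_outer <- seq_along(node_x) %in% c(edge_a[boundary_edge],
                                       edge_b[boundary_edge])

  nodes <- data.frame(id = seq_along(node_x), x = node_x, y = node_y,
                      degree = degree, is_outer = is_outer)
  dx <- node_x[edge_b] - node_x[edge_a]
  dy <- node_y[edge_b] - node_y[edge_a]
  len <- sqrt(dx^2 + dy^2)
  septa <- data.frame(id = seq_along(edge_a), node_a = edge_a,
                      node_b = edge_b, length = len)
  joints <- list(
    prismatic = data.frame(septum = septa$id,
                           axis_x = dx / len, axis_y = dy / len),
    revolute  = data.frame(septum = rep(septa$id, 2L),
                           node = c(edge_a, edge_b),
                           anchor_x = c(node_x[edge_a], node_x[edge_b]),
                           anchor_y = c(node_y[edge_a], node_y[edge_b]))
  )
  structure(list(
    nodes = nodes, septa = septa, joints = joints,
    lobules = data.frame(id = seq_len(n_hex),
                         cx = centers[, 1], cy = centers[, 2]),
    lobule_nodes = lobule_nodes,
    hex_side = s, centers = centers,
    patch_extent = c(xmin = min(node_x), xmax = max(node_x),
                     ymin = min(node_y), ymax = max(node_y))
  ), class = "lobule_lattice")
}

#' @export
print.lobule_lattice <- function(x, ...) {
  cat(sprintf(
    "<lobule_lattice> %d lobules (side %.3g), %d nodes, %d septa\n",
    nrow(x$lobules), x$hex_side, nrow(x$nodes), nrow(x$septa)))
  invisible(x)
}

#' Classify lattice nodes for elastography
#'
#' Partitions the portal-triad nodes into *internal* nodes (three adjoining
#' septa and not on the outer border of the tissue patch; these receive the
#' elastography impulse) and *outer* nodes (on the outer border; held
#' immobile during measurement).
#'
#' @param lattice a [build_lattice()] result.
#' @return list with integer vectors `internal` and `outer` (node ids).
#' @export
classify_nodes <- function(lattice) {
  stopifnot(inherits(lattice, "lobule_lattice"))
  n <- lattice$nodes
  list(internal = n$id[n$degree == 3L & !n$is_outer],
       outer = n$id[n$is_outer])
}

#' Seed hepatocytes by spiral filling of every lobule
#'
#' Fills each lobule centre-outward along an Archimedean spiral sampled at
#' one cell diameter per arc step, then densifies by the contact-replication
#' rule (each placed cell spawns neighbours at exactly one diameter until no
#' empty space remains). Cell centres keep a `margin` clearance from the
#' septal boundary so cells do not intersect the boundary sub-segments.
#' Uses the current R random number generator state; the emergent count is
#' reproducible for a fixed seed.
#'
#' @param lattice a [build_lattice()] result.
#' @param cell_diameter hepatocyte diameter (< `hex_side`).
#' @param margin clearance of cell centres from the septal edge lines;
#'   default `0.8 * cell_diameter` (septum structural half-width plus cell
#'   radius).
#' @param n_angles candidate directions tried per replication attempt.
#' @return data frame with columns `x`, `y`, `lobule`.
#' @export
spiral_fill <- function(lattice, cell_diameter,
                        margin = 0.8 * cell_diameter, n_angles = 12L) {
  stopifnot(inherits(lattice, "lobule_lattice"))
  if (!is.numeric(cell_diameter) || cell_diameter <= 0 ||
      cell_diameter >= lattice$hex_side) {
    stop("infeasible packing: cell_diameter must be in (0, hex_side)",
         call. = FALSE)
  }
  s <- lattice$hex_side
  d <- cell_diameter
  out <- vector("list", nrow(lattice$lobules))
  for (h in seq_len(nrow(lattice$lobules))) {
    cx <- lattice$lobules$cx[h]; cy <- lattice$lobules$cy[h]
    seeds <- spiral_points(cx, cy, s, d, margin)
    if (nrow(seeds) == 0L) {
      # degenerate lobule: at most the centre point fits
      if (SQRT3 / 2 * s - margin >= 0) seeds <- cbind(cx, cy) else {
        out[[h]] <- NULL; next
      }
    }
    u <- runif(4L * ceiling(3 * s^2 / d^2) + 64L)
    pts <- cpp_pack_hex(seeds, cx, cy, s, d, margin, as.integer(n_angles), u)
    # replication loop until no cell finds empty neighbouring space: repeat
    # full passes so pores opened behind the growth frontier are refilled
    centers1 <- matrix(c(cx, cy), 1, 2)
    repeat {
      n0 <- nrow(pts)
      ord <- sample.int(n0)
      res <- cpp_find_sites(pts, ord, pts, rep(d / 2, n0), centers1, s,
                            margin, d, d / 2, as.integer(n_angles),
                            runif(n0))
      if (length(res$x) == 0L) break
      pts <- rbind(pts, cbind(res$x, res$y))
    }
    out[[h]] <- data.frame(x = pts[, 1], y = pts[, 2], lobule = h)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(x = numeric(0), y = numeric(0),
                                      lobule = integer(0))
  rownames(res) <- NULL
  res
}

# Archimedean spiral r = d * theta / (2*pi), sampled at arc steps of one
# cell diameter, clipped to the hexagon interior and thinned to pairwise
# distance >= d (greedy).
spiral_points <- function(cx, cy, s, d, margin) {
  apo <- SQRT3 / 2 * s - margin
  if (apo < 0) return(cbind(numeric(0), numeric(0)))
  px <- cx; py <- cy
  theta <- 2 * pi            # first turn starts one pitch out
  repeat {
    r <- d * theta / (2 * pi)
    if (r > s) break
    x <- cx + r * cos(theta); y <- cy + r * sin(theta)
    if (in_hex_r(x - cx, y - cy, s, margin)) { px <- c(px, x); py <- c(py, y) }
    theta <- theta + d / max(r, d / 2)
  }
  keep_x <- px[1]; keep_y <- py[1]
  for (i in seq_along(px)[-1]) {
    if (all((px[i] - keep_x)^2 + (py[i] - keep_y)^2 >= d^2 * (1 - 1e-12))) {
      keep_x <- c(keep_x, px[i]); keep_y <- c(keep_y, py[i])
    }
  }
  cbind(keep_x, keep_y)
}

# point-in-flat-top-hexagon with margin, vectorised (R mirror of the C++
# test; used where a C++ round-trip is not worth the call)
in_hex_r <- function(dx, dy, s, margin = 0) {
  a <- SQRT3 / 2 * s - margin
  qx <- abs(dx); qy <- abs(dy)
  qy <= a & (SQRT3 / 2 * qx + 0.5 * qy) <= a
}

# membership of points in the lobule patch (1-based lobule id, NA outside)
patch_member <- function(x, y, lattice, margin = 0) {
  cpp_hex_member(cbind(x, y), lattice$centers, lattice$hex_side, margin)
}
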