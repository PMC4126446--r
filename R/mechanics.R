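# Tissue mechanics: collision among structural agents (hepatocytes, dead
# hepatocytes, collagen, septal sub-segments, portal triads), joint-
# constrained motion of the septal skeleton, and the non-perturbing virtual
# elastography statistic.
#
# The skeleton uses reduced coordinates: each septum's two boundary
# sub-segments (rods) are anchored one at each end node (revolute joints:
# rod endpoint coincides with its node) and always lie along the node-node
# axis at a small fixed lateral offset (side-by-side pair). Relative sliding
# of the pair along that shared axis is the prismatic degree of freedom; it
# appears as a free telescoping of the septum within the node-distance
# window [Lmin, Lmax]. The joint constraints are therefore satisfied exactly
# by construction after every projection.

#' Extract the mechanical state from a simulation state
#'
#' Collects everything that contributes to tissue mechanics: positions and
#' radii of all colliding agents (hepatocytes, dead hepatocytes, collagen),
#' triad node positions, septa, joint parameters and mobility flags.
#' Non-colliding agents (Kupffer, fibrogenic cells) are excluded entirely.
#'
#' @param state a [sim_init()] / [sim_step()] simulation state.
#' @return object of class `mechanical_state`.
#' @export
mechanical_state <- function(state) {
  cfg <- state$config
  d <- cfg$geometry$cell_diameter
  lat <- state$lattice
  disks <- rbind(cbind(state$hep$x, state$hep$y),
                 cbind(state$dead$x, state$dead$y),
                 cbind(state$col$x, state$col$y))
  if (is.null(disks)) disks <- matrix(0, 0, 2)
  n_hep <- pop_n(state$hep); n_dead <- pop_n(state$dead)
  n_col <- pop_n(state$col)
  kind <- rep(c("hepatocyte", "dead", "collagen"),
              c(n_hep, n_dead, n_col))
  s <- lat$hex_side
  structure(list(
    nodes = cbind(lat$nodes$x, lat$nodes$y),
    pinned = rep(FALSE, nrow(lat$nodes)),
    node_r = cfg$geometry$triad_radius * d,
    septa = cbind(lat$septa$node_a, lat$septa$node_b),
    Lmin = cfg$mechanics$septum_min_frac * s,
    Lmax = cfg$mechanics$septum_max_frac * s,
    rod_len = cfg$mechanics$rod_length_frac * s,
    rod_halfw = cfg$geometry$septum_halfwidth * d,
    rod_off = cfg$geometry$rod_offset * d,
    disks = disks,
    disk_r = rep(d / 2, nrow(disks)),
    disk_kind = kind,
    disk_mobile = rep(TRUE, nrow(disks)),
    disk_weight = ifelse(kind == "collagen",
                         cfg$mechanics$collagen_weight, 1),
    tol = cfg$mechanics$tol * d
  ), class = "mechanical_state")
}

#' Resolve overlaps among colliding disks
#'
#' Iteratively separates overlapping disk pairs along their contact normals
#' (position-based relaxation, deterministic sorted-id sweep) until the
#' maximum residual overlap is below `tol` or `max_iter` sweeps have run.
#' Non-colliding agent types are never part of the state. On
#' non-convergence a warning is issued and the partially relaxed state
#' returned.
#'
#' @param mstate a [mechanical_state()].
#' @param tol maximum tolerated residual overlap (default: the state's).
#' @param max_iter relaxation sweeps.
#' @return the updated `mechanical_state`.
#' @export
resolve_collisions <- function(mstate, tol = mstate$tol, max_iter = 10L) {
  stopifnot(inherits(mstate, "mechanical_state"))
  if (nrow(mstate$disks) < 2L) return(mstate)
  w <- mstate$disk_weight * as.numeric(mstate$disk_mobile)
  res <- cpp_resolve_disks(mstate$disks, mstate$disk_r, w,
                           as.integer(max_iter), tol)
  if (res$max_overlap >= tol) {
    warning(sprintf(
      "collision relaxation did not converge (residual overlap %.3g)",
      res$max_overlap), call. = FALSE)
  }
  mstate$disks <- res$xy
  mstate
}

# Rod (boundary sub-segment) geometry derived from node positions:
# two rods per septum, along the node-node axis, laterally offset.
rod_geometry <- function(mstate) {
  nodes <- mstate$nodes; septa <- mstate$septa
  a <- septa[, 1]; b <- septa[, 2]
  dx <- nodes[b, 1] - nodes[a, 1]; dy <- nodes[b, 2] - nodes[a, 2]
  len <- sqrt(dx^2 + dy^2)
  ux <- dx / len; uy <- dy / len
  nx <- -uy; ny <- ux
  L <- pmin(mstate$rod_len, len)
  off <- mstate$rod_off
  data.frame(
    septum = rep(seq_len(nrow(septa)), 2L),
    side = rep(1:2, each = nrow(septa)),
    x1 = c(nodes[a, 1] + nx * off, nodes[b, 1] - nx * off),
    y1 = c(nodes[a, 2] + ny * off, nodes[b, 2] - ny * off),
    x2 = c(nodes[a, 1] + nx * off + ux * L, nodes[b, 1] - nx * off - ux * L),
    y2 = c(nodes[a, 2] + ny * off + uy * L, nodes[b, 2] - ny * off - uy * L),
    axis_x = c(ux, ux), axis_y = c(uy, uy)
  )
}

#' Project the joint constraints of the septal skeleton
#'
#' Clamps every septum's node-node distance into the telescoping window
#' `[Lmin, Lmax]` (the prismatic slide limits; pinned nodes never move) and
#' regenerates the boundary sub-segments from the node positions. After
#' projection the two sub-segments of each septum are exactly parallel to
#' the prismatic axis and each sub-segment endpoint coincides with its
#' revolute anchor node.
#'
#' @param mstate a [mechanical_state()].
#' @return the updated `mechanical_state` with a `rods` element (one row
#'   per sub-segment: endpoints and unit `axis`).
#' @export
apply_joints <- function(mstate) {
  stopifnot(inherits(mstate, "mechanical_state"))
  nodes <- mstate$nodes
  for (k in seq_len(nrow(mstate$septa))) {
    a <- mstate$septa[k, 1]; b <- mstate$septa[k, 2]
    v <- nodes[b, ] - nodes[a, ]
    len <- sqrt(sum(v^2))
    if (len < 1e-12) next
    target <- min(max(len, mstate$Lmin), mstate$Lmax)
    if (target == len) next
    wa <- as.numeric(!mstate$pinned[a]); wb <- as.numeric(!mstate$pinned[b])
    if (wa + wb == 0) next
    corr <- v * (len - target) / len / (wa + wb)
    nodes[a, ] <- nodes[a, ] + corr * wa
    nodes[b, ] <- nodes[b, ] - corr * wb
  }
  mstate$nodes <- nodes
  mstate$rods <- rod_geometry(mstate)
  mstate
}

#' Virtual elastography: mean internal-node displacement after an impulse
#'
#' Operates on a deep copy of the mechanical state only -- the passed
#' simulation state (and the R random number generator) are untouched, so
#' the measurement never perturbs the simulation. On the copy: (1) the
#' diameter of every hepatocyte and dead agent is reduced by
#' `shrink_fraction` (standing in for cellular compressibility so a fully
#' packed patch can compress at all); (2) all outer nodes are pinned; (3) a
#' centrally (inward) directed impulse displaces every internal node --
#' each node with three adjoining septa -- toward the patch centroid by
#' `impulse * mobility` (one overdamped step); (4) one mechanical step
#' (joint projection + collision relaxation) runs; (5) the mean
#' displacement magnitude of the internal nodes is returned and the copy
#' discarded. Higher displacement indicates more pliable tissue.
#'
#' @param state a simulation state.
#' @param impulse impulse magnitude (force x step); `impulse * mobility` is
#'   the free-motion displacement in simulation length units.
#' @param shrink_fraction fractional diameter reduction of
#'   hepatocytes/dead agents, in (0, 1).
#' @param iterations relaxation sweeps of the mechanical step.
#' @param mobility overdamped node mobility (displacement per unit
#'   impulse).
#' @param direction `"patch"`: impulse toward the patch centroid;
#'   `"lobule"`: toward the nearest lobule centre.
#' @return object of class `elastography_result`: list with `displacement`
#'   (mean over internal nodes), `per_node`, `step_index`.
#' @export
measure_elasticity <- function(state,
                               impulse = state$config$elastography$impulse,
                               shrink_fraction = state$config$elastography$shrink,
                               iterations = state$config$elastography$iterations,
                               mobility = state$config$elastography$mobility,
                               direction = state$config$elastography$direction) {
  if (!is.numeric(impulse) || impulse <= 0) {
    stop("impulse must be > 0", call. = FALSE)
  }
  if (shrink_fraction <= 0 || shrink_fraction >= 1) {
    stop("shrink_fraction must be in (0, 1)", call. = FALSE)
  }
  cls <- classify_nodes(state$lattice)
  if (length(cls$internal) == 0L) {
    stop("unmeasurable lattice: no internal (degree-3, non-border) nodes",
         call. = FALSE)
  }
  ms <- mechanical_state(state)
  orig <- ms$nodes
  shrinkable <- ms$disk_kind %in% c("hepatocyte", "dead")
  ms$disk_r[shrinkable] <- ms$disk_r[shrinkable] * (1 - shrink_fraction)
  ms$pinned[cls$outer] <- TRUE

  u0 <- impulse * mobility
  idx <- cls$internal
  if (identical(direction, "lobule")) {
    cen <- state$lattice$centers
    tx <- ty <- numeric(length(idx))
    for (q in seq_along(idx)) {
      dd <- (cen[, 1] - orig[idx[q], 1])^2 + (cen[, 2] - orig[idx[q], 2])^2
      w <- which.min(dd)
      tx[q] <- cen[w, 1]; ty[q] <- cen[w, 2]
    }
  } else {
    tx <- rep(mean(orig[, 1]), length(idx))
    ty <- rep(mean(orig[, 2]), length(idx))
  }
  vx <- tx - orig[idx, 1]; vy <- ty - orig[idx, 2]
  nv <- sqrt(vx^2 + vy^2)
  nz <- nv > 1e-12
  ux <- ifelse(nz, vx / nv, 0); uy <- ifelse(nz, vy / nv, 0)

  # the impulse is applied in substeps so the swept septa push tissue
  # continuously (a single jump would tunnel through thin contacts)
  substeps <- max(1L, as.integer(state$config$elastography$substeps %||% 10L))
  it_per <- max(2L, as.integer(ceiling(iterations / substeps)))
  w <- ms$disk_weight * as.numeric(ms$disk_mobile)
  nodes <- ms$nodes
  for (ss in seq_len(substeps)) {
    nodes[idx, 1] <- nodes[idx, 1] + u0 / substeps * ux
    nodes[idx, 2] <- nodes[idx, 2] + u0 / substeps * uy
    res <- cpp_mech_step(nodes, ms$pinned, ms$node_r, ms$septa,
                         ms$Lmin, ms$Lmax, ms$rod_len, ms$rod_halfw,
                         ms$rod_off, ms$disks, ms$disk_r, w,
                         it_per)
    nodes <- res$nodes
    ms$disks <- res$disks
  }
  disp <- sqrt((nodes[idx, 1] - orig[idx, 1])^2 +
               (nodes[idx, 2] - orig[idx, 2])^2)
  structure(list(displacement = mean(disp), per_node = disp,
                 step_index = state$step),
            class = "elastography_result")
}

#' @export
print.elastography_result <- function(x, ...) {
  cat(sprintf(
    "<elastography> step %d: mean internal-node displacement %.4f (%d nodes)\n",
    x$step_index, x$displacement, length(x$per_node)))
  invisible(x)
}

#' Fingerprint of a full simulation state
#'
#' A cheap order-sensitive checksum over the serialized state, used to
#' verify that measurements and renderers do not perturb the simulation.
#'
#' @param state any R object (normally a simulation state).
#' @return named numeric vector (byte count plus two weighted sums).
#' @export
state_fingerprint <- function(state) {
  raw <- serialize(state, NULL, version = 2)
  v <- as.integer(raw)
  w <- (seq_along(v) - 1) %% 97 + 1
  c(n = length(v), s1 = sum(v), s2 = sum(v * w))
}
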