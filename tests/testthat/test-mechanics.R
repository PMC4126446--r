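test_that("resolve_collisions separates overlapping disks", {
  st <- quick_state(seed = 3, steps = 0, fixture = "single_lobule")
  ms <- mechanical_state(st)

  # already relaxed packing: unchanged
  ms0 <- resolve_collisions(ms)
  expect_equal(ms0$disks, ms$disks, tolerance = 1e-12)

  # two equal disks overlapping by 0.4: displaced 0.2 each along the axis
  ms2 <- ms
  ms2$disks <- rbind(c(0, 0), c(0.6, 0))
  ms2$disk_r <- c(0.5, 0.5)
  ms2$disk_kind <- c("hepatocyte", "hepatocyte")
  ms2$disk_mobile <- c(TRUE, TRUE)
  ms2$disk_weight <- c(1, 1)
  out <- resolve_collisions(ms2, tol = 1e-9, max_iter = 5)
  expect_equal(out$disks[, 1], c(-0.2, 0.8), tolerance = 1e-9)
  expect_equal(out$disks[, 2], c(0, 0), tolerance = 1e-12)

  # random packing of 50 disks: exhaustive O(n^2) overlap audit
  set.seed(8)
  ms3 <- ms2
  ms3$disks <- cbind(runif(50, 0, 7), runif(50, 0, 7))
  ms3$disk_r <- rep(0.5, 50)
  ms3$disk_kind <- rep("hepatocyte", 50)
  ms3$disk_mobile <- rep(TRUE, 50)
  ms3$disk_weight <- rep(1, 50)
  out3 <- resolve_collisions(ms3, tol = 1e-3, max_iter = 400)
  expect_lt(oracle_max_overlap(out3$disks, out3$disk_r), 1e-3)

  # immobile disks never move
  ms4 <- ms2
  ms4$disk_mobile <- c(FALSE, TRUE)
  out4 <- resolve_collisions(ms4, tol = 1e-9, max_iter = 5)
  expect_equal(out4$disks[1, ], c(0, 0), tolerance = 1e-12)
  expect_gte(out4$disks[2, 1], 0.999)
})

test_that("apply_joints keeps the prismatic/revolute constraints exact", {
  st <- quick_state(seed = 4, steps = 0)
  ms <- mechanical_state(st)

  # no external force: node positions unchanged
  ms1 <- apply_joints(ms)
  expect_equal(ms1$nodes, ms$nodes, tolerance = 1e-12)

  # lateral push on one sub-segment (transmitted to its anchor node):
  # after projection both sub-segments lie exactly along the node-node
  # axis, so their relative displacement has no normal component
  ms2 <- ms
  ms2$nodes[1, ] <- ms2$nodes[1, ] + c(0.4, -0.3)
  ms2 <- apply_joints(ms2)
  rods <- ms2$rods
  for (k in seq_len(nrow(ms2$septa))) {
    pair <- rods[rods$septum == k, ]
    a <- ms2$septa[k, 1]; b <- ms2$septa[k, 2]
    ax <- ms2$nodes[b, 1] - ms2$nodes[a, 1]
    ay <- ms2$nodes[b, 2] - ms2$nodes[a, 2]
    nrm <- c(-ay, ax) / sqrt(ax^2 + ay^2)
    for (r in 1:2) {
      vx <- pair$x2[r] - pair$x1[r]; vy <- pair$y2[r] - pair$y1[r]
      expect_lt(abs(vx * nrm[1] + vy * nrm[2]), 1e-9)   # parallel to axis
    }
  }

  # each sub-segment start stays at fixed offset from its revolute anchor
  a_ids <- ms2$septa[rods$septum[rods$side == 1], 1]
  d1 <- sqrt((rods$x1[rods$side == 1] - ms2$nodes[a_ids, 1])^2 +
             (rods$y1[rods$side == 1] - ms2$nodes[a_ids, 2])^2)
  expect_equal(d1, rep(ms$rod_off, length(d1)), tolerance = 1e-9)

  # node pairs projected into the telescoping window
  for (k in seq_len(nrow(ms2$septa))) {
    a <- ms2$septa[k, 1]; b <- ms2$septa[k, 2]
    len <- sqrt(sum((ms2$nodes[a, ] - ms2$nodes[b, ])^2))
    expect_gte(len, ms$Lmin - 1e-9)
    expect_lte(len, ms$Lmax + 1e-9)
  }
})

test_that("measure_elasticity matches the free-motion closed form", {
  st <- quick_state(seed = 1, steps = 0)
  # empty the patch of all colliding agents
  st$hep <- lapply(st$hep, function(v) v[0])
  st$dead <- lapply(st$dead, function(v) v[0])
  st$col <- lapply(st$col, function(v) v[0])
  r <- measure_elasticity(st, impulse = 0.5, mobility = 1)
  expect_equal(r$displacement, 0.5, tolerance = 1e-9)
  expect_equal(r$per_node, rep(0.5, 6), tolerance = 1e-9)
  # zero mobility: fully pinned response
  r0 <- measure_elasticity(st, impulse = 0.5, mobility = 0)
  expect_equal(r0$displacement, 0)
  # invalid probe parameters
  expect_error(measure_elasticity(st, impulse = 0), "impulse")
  expect_error(measure_elasticity(st, shrink_fraction = 1.5), "shrink")
})

test_that("elastography errors on a lattice without internal nodes", {
  st <- quick_state(seed = 1, steps = 0, fixture = "single_lobule")
  expect_error(measure_elasticity(st), "unmeasurable")
})

test_that("collagen bridging septa never increases the displacement", {
  worse <- 0L
  for (seed in 1:10) {
    st <- quick_state(seed = seed, steps = 5)
    base <- measure_elasticity(st)$displacement
    # add collagen cords along every septum where space allows
    lat <- st$lattice
    xs <- ys <- numeric(0)
    for (k in seq_len(nrow(lat$septa))) {
      a <- lat$septa$node_a[k]; b <- lat$septa$node_b[k]
      ts <- seq(0.1, 0.9, by = 0.55 / lat$septa$length[k])
      px <- lat$nodes$x[a] + (lat$nodes$x[b] - lat$nodes$x[a]) * ts
      py <- lat$nodes$y[a] + (lat$nodes$y[b] - lat$nodes$y[a]) * ts
      vx <- lat$nodes$x[b] - lat$nodes$x[a]
      vy <- lat$nodes$y[b] - lat$nodes$y[a]
      L <- sqrt(vx^2 + vy^2)
      for (sgn in c(-1, 1)) {
        xs <- c(xs, px + sgn * 0.95 * (-vy / L))
        ys <- c(ys, py + sgn * 0.95 * (vx / L))
      }
    }
    inside <- !is.na(lobulesim:::patch_member(xs, ys, lat, 0.3))
    xs <- xs[inside]; ys <- ys[inside]
    # only positions that do not intrude into existing colliders
    ms <- mechanical_state(st)
    free <- vapply(seq_along(xs), function(i) {
      all((ms$disks[, 1] - xs[i])^2 + (ms$disks[, 2] - ys[i])^2 >= 0.999^2)
    }, TRUE)
    st2 <- st
    st2$col <- lobulesim:::new_collagen(xs[free], ys[free], 2L, 1L,
                                        rep(0.95, sum(free)))
    withcol <- measure_elasticity(st2)$displacement
    if (withcol > base + 1e-9) worse <- worse + 1L
  }
  expect_lte(worse, 1L)   # monotone within noise across the 10 seeds
})

test_that("measurement does not perturb the simulation state", {
  st <- quick_state(seed = 6, steps = 8)
  before_fp <- state_fingerprint(st)
  before_raw <- serialize(st, NULL)
  rng_before <- .Random.seed
  invisible(measure_elasticity(st))
  expect_identical(state_fingerprint(st), before_fp)
  expect_identical(serialize(st, NULL), before_raw)
  expect_identical(.Random.seed, rng_before)
})
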