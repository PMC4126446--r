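new_hep <- lobulesim:::new_hepatocytes
new_dead <- lobulesim:::new_dead
new_kc <- lobulesim:::new_kupffer
new_fib <- lobulesim:::new_fibrogenic

test_that("initialize_populations reproduces the 60/15/5 census arithmetic", {
  expect_equal(initialize_populations(3857),
               list(n_kupffer = 964, n_hsc = 321))
  expect_equal(initialize_populations(0), list(n_kupffer = 0, n_hsc = 0))
  expect_equal(initialize_populations(120), list(n_kupffer = 30, n_hsc = 10))
  expect_error(initialize_populations(-1))
})

test_that("hepatocyte rule: survival, senescence cap and bystander death", {
  one <- new_hep(0, 0, 1L, lifespan = 100)
  # quiet cell: nothing to do
  expect_identical(
    hepatocyte_step(one, FALSE, FALSE, FALSE, death_prob = 0.5), "none")
  # empty space + collagen + exhausted replication budget: senescence cap
  capped <- new_hep(0, 0, 1L, lifespan = 100, rep_count = 2L)
  expect_identical(
    hepatocyte_step(capped, FALSE, TRUE, TRUE, death_prob = 0,
                    replication_prob = 1), "none")
  # below the cap it may replicate even beside collagen
  ok <- new_hep(0, 0, 1L, lifespan = 100, rep_count = 1L)
  expect_identical(
    hepatocyte_step(ok, FALSE, TRUE, TRUE, death_prob = 0,
                    replication_prob = 1), "replicate")
  # over-age cells die regardless
  old <- new_hep(0, 0, 1L, lifespan = 5, age = 6L)
  expect_identical(hepatocyte_step(old, FALSE, FALSE, FALSE, 0), "die")

  # binomial oracle on the lumped TNF bystander death
  set.seed(11)
  n <- 10000
  p <- 0.3
  pop <- new_hep(runif(n), runif(n), 1L, lifespan = 1000)
  ev <- hepatocyte_step(pop, rep(TRUE, n), rep(FALSE, n), rep(FALSE, n),
                        death_prob = p)
  frac <- mean(ev == "die")
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("polarization and secretion follow the M1/M2 mixing rule", {
  # endpoints of the mixing rule
  s0 <- kupffer_secretion(0, TRUE, 2, 3)
  expect_equal(s0$tnf, 2); expect_equal(s0$tgf, 0)
  s1 <- kupffer_secretion(1, TRUE, 2, 3)
  expect_equal(s1$tnf, 0); expect_equal(s1$tgf, 3)
  # quiescent cells secrete nothing
  sq <- kupffer_secretion(0.4, FALSE, 2, 3)
  expect_equal(sq$tnf, 0); expect_equal(sq$tgf, 0)

  # k-fold composition equals a hand-rolled sequential oracle
  inc <- 0.23
  m <- 0
  for (k in 1:8) m <- min(1, m + inc)
  expect_equal(polarization_update(0, 8, inc), m)
  expect_equal(polarization_update(0.9, 3, inc), 1)  # cap at pure M2
  # m is non-decreasing in phagocytosis count
  expect_true(all(diff(polarization_update(0.2, 0:12, 0.1)) >= 0))
})

test_that("kupffer_step phagocytizes each dead agent at most once", {
  set.seed(5)
  kcs <- new_kc(c(0, 0.4, 5), c(0, 0, 5))
  dead <- new_dead(0.2, 0, 1L)
  res <- kupffer_step(kcs, dead, radius = 1.5, increment = 0.1,
                      tnf_range = c(1, 1), tgf_range = c(1, 1),
                      active_lifespan = c(50, 60), phago_prob = 1)
  expect_identical(res$phagocytized, 1L)       # one dead, eaten once
  expect_equal(sum(res$kcs$activated), 1L)     # exactly one eater activated
  expect_equal(sum(res$kcs$phago), 1L)
  # the far cell stays quiescent and silent
  expect_false(res$kcs$activated[3])
  expect_equal(res$tnf[3], 0)

  # no dead neighbours: nothing happens
  res2 <- kupffer_step(new_kc(0, 0), new_dead(numeric(0), numeric(0),
                                              integer(0)),
                       1.5, 0.1, c(1, 1), c(1, 1), c(50, 60))
  expect_length(res2$phagocytized, 0)
  expect_equal(res2$tnf, 0)
  expect_equal(res2$tgf, 0)
})

test_that("monocyte recruitment spawns at HMGB1 hot spots", {
  lat <- build_lattice(2, 2, 6)
  f <- cytokine_field("HMGB1", lat, h = 1, threshold = 0.5)
  # zero field: no recruits
  expect_equal(lobulesim:::pop_n(
    recruit_monocytes(f, lat, 1, c(50, 60))), 0L)
  # one hot cell at a lobule centre, probability 1: exactly one recruit
  f1 <- deposit(f, c(lat$lobules$cx[1], lat$lobules$cy[1]), 10)
  set.seed(2)
  rec <- recruit_monocytes(f1, lat, 1, c(50, 60))
  expect_equal(lobulesim:::pop_n(rec), 1L)
  expect_true(all(rec$activated))
  expect_equal(rec$m, 0)                        # recruits enter as M1

  # binomial oracle: N hot sites, probability p, many steps
  fN <- f
  ij <- rbind(c(8, 8), c(9, 8), c(10, 9), c(8, 10), c(11, 11))
  for (k in seq_len(nrow(ij))) fN$grid[ij[k, 1], ij[k, 2]] <- 1
  N <- sum(!is.na(lobulesim:::patch_member(
    lobulesim:::cells_above_threshold(fN)[, 1],
    lobulesim:::cells_above_threshold(fN)[, 2], lat, 0)))
  p <- 0.2; steps <- 1000
  set.seed(3)
  tot <- 0
  for (k in seq_len(steps)) {
    tot <- tot + lobulesim:::pop_n(recruit_monocytes(fN, lat, p, c(50, 60)))
  }
  mu <- N * steps * p
  expect_lt(abs(tot - mu), 3 * sqrt(N * steps * p * (1 - p)))
})

test_that("fibrogenic rule: irreversible transformation and gating", {
  # all fields below threshold: nothing
  hsc <- new_fib(0, 0, lobulesim:::FIB_HSC)
  ev <- fibrogenic_step(hsc, FALSE, FALSE, FALSE, 1, 1, 1)
  expect_false(any(ev$transform | ev$deposit | ev$proliferate))
  # TNF above threshold transforms an HSC (probability 1)
  ev2 <- fibrogenic_step(hsc, TRUE, FALSE, FALSE, 1, 1, 1)
  expect_true(ev2$transform)
  # HMGB1 stimulates only when the flag allows it
  ev3 <- fibrogenic_step(hsc, FALSE, TRUE, FALSE, 1, 1, 1,
                         hmgb1_activates = FALSE)
  expect_false(ev3$transform)
  ev4 <- fibrogenic_step(hsc, FALSE, TRUE, FALSE, 1, 1, 1,
                         hmgb1_activates = TRUE)
  expect_true(ev4$transform)
  # myofibroblasts never transform again; they respond to TGF
  mf <- new_fib(0, 0, lobulesim:::FIB_MF)
  ev5 <- fibrogenic_step(mf, TRUE, TRUE, TRUE, 1, 1, 1)
  expect_false(ev5$transform)
  expect_true(ev5$deposit)
  expect_true(ev5$proliferate)
})

test_that("a stimulated myofibroblast beside a septum deposits one anchored unit", {
  cfg <- make_fixture("single_lobule")
  cfg$fibro$deposit_prob <- 1
  cfg$fibro$tgf_halfsat <- 1e-9       # fully dose-saturated
  cfg$fibro$proliferate_prob <- 0
  cfg$injury$enabled <- FALSE
  st <- sim_init(cfg)
  # clear the parenchyma so the site search is unobstructed, then place
  # one myofibroblast near the middle of a septum with TGF flooded
  st$hep <- lapply(st$hep, `[`, 0)
  lat <- st$lattice
  sep <- lat$septa[1, ]
  mx <- (lat$nodes$x[sep$node_a] + lat$nodes$x[sep$node_b]) / 2
  my <- (lat$nodes$y[sep$node_a] + lat$nodes$y[sep$node_b]) / 2
  ctr <- c(lat$lobules$cx[1], lat$lobules$cy[1])
  inward <- c(ctr[1] - mx, ctr[2] - my)
  inward <- inward / sqrt(sum(inward^2))
  st$fib <- lobulesim:::new_fibrogenic(mx + 1.5 * inward[1],
                                       my + 1.5 * inward[2],
                                       lobulesim:::FIB_MF)
  st$fields$tgf$grid[] <- 10 * st$fields$tgf$threshold
  st2 <- lobulesim:::fibrogenic_phase(st)
  expect_equal(lobulesim:::pop_n(st2$col), 1L)
  expect_equal(st2$col$anchor_type, 2L)         # anchored to a septum
  # deposit touches the septal band: distance to the septum centre line
  a <- c(lat$nodes$x[sep$node_a], lat$nodes$y[sep$node_a])
  b <- c(lat$nodes$x[sep$node_b], lat$nodes$y[sep$node_b])
  v <- b - a; v <- v / sqrt(sum(v^2))
  w <- c(st2$col$x - a[1], st2$col$y - a[2])
  perp <- abs(w[1] * v[2] - w[2] * v[1])
  expect_equal(perp, 0.9, tolerance = 0.07)
})
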