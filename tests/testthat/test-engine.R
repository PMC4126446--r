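test_that("configuration validation aggregates and names offenders", {
  expect_error(sim_config(bogus = list(a = 1)), "bogus")
  expect_error(sim_config(injury = list(kill_prob = 1.5)),
               "injury.kill_prob")
  # several violations reported together
  err <- tryCatch(
    sim_config(injury = list(kill_prob = 2),
               hepatocyte = list(tnf_death_prob = -0.1)),
    error = conditionMessage)
  expect_match(err, "injury.kill_prob")
  expect_match(err, "hepatocyte.tnf_death_prob")
  expect_error(sim_config(fields = list(tnf = list(diffusion = 0.4))),
               "stability")
  expect_error(sim_config(injury = list(radius = 50)), "inradius")
})

test_that("apply_therapy mutates exactly the stated parameter", {
  cfg <- sim_config()
  expect_identical(apply_therapy(cfg), cfg)   # none: unchanged

  anti <- sim_config(therapy = list(name = "anti_tnf", anti_tnf_factor = 2))
  anti2 <- apply_therapy(anti)
  expect_equal(anti2$fields$tnf$degradation, 2 * cfg$fields$tnf$degradation)
  expect_identical(anti2$fields$tgf, cfg$fields$tgf)
  expect_identical(anti2$kupffer$tgf_production, cfg$kupffer$tgf_production)
  expect_identical(apply_therapy(anti2), anti2)   # idempotent

  m2 <- apply_therapy(sim_config(therapy = list(name = "m2_enhance",
                                                m2_factor = 2)))
  expect_equal(m2$kupffer$tgf_production, 2 * cfg$kupffer$tgf_production)
  expect_identical(m2$fields$tnf, cfg$fields$tnf)

  expect_error(apply_therapy(sim_config(
    therapy = list(name = "anti_tnf", anti_tnf_factor = 1))), "> 1")
  expect_error(apply_therapy(sim_config(
    therapy = list(name = "m2_enhance", m2_factor = 0.5))), "> 1")
})

test_that("initialization seeds populations in the 60:15:5 pattern", {
  cfg <- make_fixture("seven_lobule")
  st <- sim_init(cfg)
  n <- lobulesim:::pop_n(st$hep)
  expect_equal(lobulesim:::pop_n(st$kc), round(n * 15 / 60))
  expect_equal(sum(st$fib$kind == lobulesim:::FIB_HSC), round(n * 5 / 60))
  expect_equal(sum(st$fib$kind == lobulesim:::FIB_PF),
               nrow(st$lattice$nodes) * cfg$fibro$pf_per_triad)
  expect_equal(st$step, 0L)
  expect_equal(field_total(st$fields$tnf), 0)
  expect_false(any(st$kc$activated))
  # all agents are inside the patch
  expect_false(anyNA(lobulesim:::patch_member(st$hep$x, st$hep$y,
                                              st$lattice, 0)))
})

test_that("injury pulses convert hepatocytes in place", {
  cfg <- make_fixture("seven_lobule")
  cfg$injury$enabled <- FALSE
  st <- sim_init(cfg)
  n0 <- lobulesim:::pop_n(st$hep)

  s1 <- injury_pulse(st, radius = 2, kill_prob = 0)
  expect_equal(lobulesim:::pop_n(s1$hep), n0)
  expect_equal(lobulesim:::pop_n(s1$dead), 0L)

  s2 <- injury_pulse(st, radius = 2, kill_prob = 1)
  cx <- st$lattice$lobules$cx[st$hep$lobule]
  cy <- st$lattice$lobules$cy[st$hep$lobule]
  k <- sum((st$hep$x - cx)^2 + (st$hep$y - cy)^2 <= 4)
  expect_equal(lobulesim:::pop_n(s2$dead), k)
  expect_equal(lobulesim:::pop_n(s2$hep) + lobulesim:::pop_n(s2$dead), n0)

  # binomial oracle over repeated pulses on reset states
  set.seed(21)
  n_in <- k; reps <- 200; p <- 0.5
  kills <- replicate(reps, lobulesim:::pop_n(
    injury_pulse(st, radius = 2, kill_prob = p)$dead))
  expect_lt(abs(sum(kills) - n_in * reps * p),
            3 * sqrt(n_in * reps * p * (1 - p)))

  expect_error(injury_pulse(st, radius = 100, kill_prob = 1), "inradius")
})

test_that("config + seed fully determine the trajectory", {
  cfg <- make_fixture("seven_lobule")
  cfg$run$n_steps <- 20L
  run1 <- sim_init(cfg)
  for (t in 1:20) run1 <- sim_step(run1)
  run2 <- sim_init(cfg)
  for (t in 1:20) run2 <- sim_step(run2)
  expect_identical(serialize(run1, NULL), serialize(run2, NULL))
  expect_identical(census_df(run1), census_df(run2))
})

test_that("census identity holds at every step", {
  cfg <- make_fixture("seven_lobule")
  cfg$run$n_steps <- 40L
  st <- sim_init(cfg)
  for (t in 1:40) {
    st <- sim_step(st)
    expect_equal(lobulesim:::pop_n(st$hep),
                 st$ledger$hep0 - st$ledger$cum_deaths + st$ledger$cum_reps)
  }
  # an injured run produces dead agents within one pulse period
  cen <- census_df(st)
  expect_gt(max(cen$dead[seq_len(cfg$injury$period + 1)]), 0)
})

test_that("state save/load is canonical and resumes identically", {
  cfg <- make_fixture("seven_lobule")
  st <- sim_init(cfg)
  for (t in 1:12) st <- sim_step(st)

  p1 <- file.path(tempdir(), "state1.json")
  p2 <- file.path(tempdir(), "state2.json")
  save_state(st, p1)
  st_l <- load_state(p1)
  save_state(st_l, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))   # canonical round trip

  # continuing the original vs. the reloaded state gives the same future
  a <- st; b <- st_l
  for (t in 1:8) { a <- sim_step(a); b <- sim_step(b) }
  expect_equal(census_df(a), census_df(b), tolerance = 1e-12)
  expect_equal(a$hep, b$hep, tolerance = 1e-12)
  expect_equal(a$col, b$col, tolerance = 1e-12)
  expect_identical(a$rng, b$rng)
  unlink(c(p1, p2))
})

test_that("replicate aggregation: SD of a single replicate is zero", {
  cfg <- make_fixture("single_lobule")
  cfg$run$n_steps <- 10L
  res <- sim_run(cfg)
  expect_s3_class(res, "scenario_result")
  expect_true(all(res$sd == 0, na.rm = TRUE))
  expect_equal(nrow(res$mean), 11L)
})
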