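# minimal hand-built scenario_result for comparison tests
synth_result <- function(values, reps = 3, n_steps = 20, jitter = 0) {
  per <- lapply(seq_len(reps), function(r) {
    df <- data.frame(step = 0:n_steps)
    df$collagen <- values + jitter * (r - (reps + 1) / 2)
    df
  })
  m <- Reduce(`+`, lapply(per, as.matrix)) / reps
  v <- Reduce(`+`, lapply(per, function(p) (as.matrix(p) - m)^2)) /
    max(1, reps - 1)
  structure(list(config = NULL, replicates = per,
                 mean = as.data.frame(m), sd = as.data.frame(sqrt(v))),
            class = "scenario_result")
}

test_that("detect_steady_state implements the windowed relative criterion", {
  expect_equal(detect_steady_state(rep(5, 200), 50, 0.02), 0L)
  expect_true(is.na(detect_steady_state(seq_len(300), 50, 0.02)))
  expect_error(detect_steady_state(1:40, 50, 0.02), "insufficient")
  expect_error(detect_steady_state(1:300, 1, 0.02), "window")
  expect_error(detect_steady_state(1:300, 50, 2), "rel_tol")

  # saturating trajectory: exhaustive window-scan oracle agreement
  t <- 0:599
  s <- 100 * (1 - exp(-t / 60))
  expect_equal(detect_steady_state(s, 50, 0.02),
               oracle_steady_scan(s, 50, 0.02))
  # also on a noisy variant and other window widths
  set.seed(17)
  s2 <- s + rnorm(600, 0, 0.5)
  for (w in c(30, 50)) {
    expect_equal(detect_steady_state(s2, w, 0.05),
                 oracle_steady_scan(s2, w, 0.05))
  }
})

test_that("detect_steady_state is invariant to uniform scaling", {
  t <- 0:399
  s <- 40 * (1 - exp(-t / 45)) + 3
  for (f in c(0.01, 1, 250)) {
    expect_equal(detect_steady_state(f * s, 50, 0.02),
                 detect_steady_state(s, 50, 0.02))
  }
})

test_that("peak_order compares smoothed argmax steps", {
  a <- dnorm(0:100, 10, 3)
  b <- dnorm(0:100, 50, 8)
  expect_equal(peak_order(a, b), "a_first")
  expect_equal(peak_order(b, a), "b_first")
  expect_equal(peak_order(a, a), "tie")
  expect_error(peak_order(numeric(0), a), "non-empty")
  # smoothing suppresses a one-sample spike
  base <- dnorm(0:100, 60, 10)
  spiky <- base
  spiky[5] <- max(base) * 1.05
  expect_equal(peak_order(spiky, base, smooth = 11), "tie")
})

test_that("compare_scenarios ranks by mean and signs pairs", {
  a <- synth_result(rep(10, 21))
  b <- synth_result(rep(10, 21))
  cmp0 <- compare_scenarios(list(x = a, y = b), "collagen")
  expect_true(all(cmp0$pairs$sign == 0))

  lo <- synth_result(seq(0, 20, length.out = 21))
  mid <- synth_result(seq(0, 40, length.out = 21))
  hi <- synth_result(seq(0, 80, length.out = 21))
  cmp <- compare_scenarios(list(mid = mid, hi = hi, lo = lo), "collagen")
  expect_equal(cmp$table$scenario, c("lo", "mid", "hi"))
  expect_equal(cmp$at_step, 20)

  short <- synth_result(rep(1, 11), n_steps = 10)
  expect_error(compare_scenarios(list(a = a, b = short), "collagen"),
               "share")
  expect_error(compare_scenarios(list(a = a, b = b), "nope"), "unknown")
})

test_that("aggregation is permutation-invariant and recomputable from raw", {
  cfg <- make_fixture("single_lobule")
  cfg$run$n_steps <- 15L
  cfg$run$replicates <- 3L
  res <- sim_run(cfg)
  # recompute the mean from the stored per-replicate series
  m <- Reduce(`+`, lapply(res$replicates, as.matrix)) / 3
  expect_equal(as.matrix(res$mean), m, tolerance = 1e-12)
  # permuting replicates changes nothing
  perm <- res
  perm$replicates <- res$replicates[c(3, 1, 2)]
  m2 <- Reduce(`+`, lapply(perm$replicates, as.matrix)) / 3
  expect_equal(m2, m, tolerance = 1e-12)
  # per-replicate CSV round trip reproduces the aggregate
  dir <- file.path(tempdir(), "aggcheck")
  write_scenario(res, dir, name = "t")
  back <- lapply(1:3, function(r)
    read.csv(file.path(dir, sprintf("t_rep%02d.csv", r))))
  m3 <- Reduce(`+`, lapply(back, as.matrix)) / 3
  expect_equal(unname(m3[, "collagen"]), unname(m[, "collagen"]),
               tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})

test_that("trajectory_stat summarizes a series", {
  cfg <- make_fixture("single_lobule")
  cfg$run$n_steps <- 12L
  res <- sim_run(cfg)
  ts <- trajectory_stat(res, "hepatocytes")
  expect_s3_class(ts, "trajectory_stat")
  expect_true(all(ts$sd >= 0))
  expect_true(ts$peak_step >= 0 && ts$peak_step <= 12)
  expect_error(trajectory_stat(res, "nope"), "unknown")
})
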