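mkf <- function(nx = 8, ny = 7, D = 0.2, delta = 0, thr = 0.5) {
  cytokine_field("TNF", c(0, nx, 0, ny), h = 1, diffusion = D,
                 degradation = delta, threshold = thr)
}

test_that("deposit adds mass where and how it should", {
  f <- mkf()
  expect_identical(deposit(f, c(2.5, 3.5), 0)$grid, f$grid)
  f1 <- deposit(f, c(2.5, 3.5), 1.7)
  expect_equal(field_total(f1), 1.7)
  f2 <- deposit(f1, c(6.5, 1.5), 0.3)
  expect_equal(f2$grid[3, 4], 1.7)
  expect_equal(f2$grid[7, 2], 0.3)
  expect_equal(field_total(f2), 2.0)
  expect_error(deposit(f, c(100, 3), 1), "outside")
  expect_error(deposit(f, c(2, 3), -1), ">= 0")
})

test_that("construction rejects unstable or nonsensical parameters", {
  expect_error(mkf(D = 0.3), "stability")
  expect_error(mkf(delta = 1.2), "degradation")
  expect_error(mkf(thr = 0), "threshold")
})

test_that("step_field diffusion matches a dense matrix-power oracle", {
  f <- mkf(nx = 8, ny = 7, D = 0.17, delta = 0)
  f <- deposit(f, c(3.5, 2.5), 5)
  A <- oracle_diffusion_matrix(8, 7, 0.17)
  v <- as.vector(f$grid)
  g <- f
  for (k in 1:25) {
    g <- step_field(g)
    v <- A %*% v
  }
  expect_equal(as.vector(g$grid), as.vector(v), tolerance = 1e-12)
  # conservation under zero degradation
  expect_lt(abs(field_total(g) - 5) / 5, 1e-9)
  # zero field stays zero; uniform field only decays
  z <- step_field(mkf())
  expect_true(all(z$grid == 0))
  u <- mkf(delta = 0.25)
  u$grid[] <- 3
  u1 <- step_field(u)
  expect_equal(u1$grid, matrix(3 * 0.75, 8, 7), tolerance = 1e-12)
})

test_that("pure geometric decay when diffusion is off", {
  f <- mkf(D = 0, delta = 0.1)
  f <- deposit(f, c(1.5, 1.5), 2)
  v0 <- f$grid
  for (k in 1:12) f <- step_field(f)
  expect_equal(f$grid, v0 * (1 - 0.1)^12, tolerance = 1e-12)
})

test_that("above_threshold uses >= at the containing cell", {
  f <- mkf(thr = 0.5)
  expect_false(above_threshold(f, c(2.5, 3.5)))
  f$grid[3, 4] <- 0.5
  expect_true(above_threshold(f, c(2.5, 3.5)))   # boundary convention
  f2 <- deposit(mkf(thr = 0.5), c(2.5, 3.5), 2 * 0.5)
  expect_true(above_threshold(f2, c(2.5, 3.5)))
  expect_false(above_threshold(f2, c(7.5, 6.5)))
})

test_that("non-negativity holds under random operation sequences", {
  set.seed(31)
  for (rep in 1:5) {
    f <- mkf(D = runif(1, 0, 0.25), delta = runif(1, 0, 0.5))
    for (k in 1:60) {
      if (runif(1) < 0.5) {
        f <- deposit(f, c(runif(1, 0, 8), runif(1, 0, 7)), runif(1, 0, 3))
      } else {
        f <- step_field(f)
      }
      expect_gte(min(f$grid), 0)
    }
  }
})
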