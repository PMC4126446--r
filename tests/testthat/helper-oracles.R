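# Independent oracles used across the suite. These deliberately avoid the
# package's own kernels: plain-R loops, dense matrices, exhaustive scans.

# O(n^2) audit of the worst disk-pair penetration
oracle_max_overlap <- function(xy, r) {
  n <- nrow(xy)
  if (n < 2) return(0)
  worst <- 0
  for (i in seq_len(n - 1)) {
    d <- sqrt((xy[(i + 1):n, 1] - xy[i, 1])^2 +
              (xy[(i + 1):n, 2] - xy[i, 2])^2)
    pen <- r[i] + r[(i + 1):n] - d
    worst <- max(worst, pen)
  }
  worst
}

# dense matrix of one explicit diffusion step (5-point stencil, zero-flux)
oracle_diffusion_matrix <- function(nx, ny, D) {
  n <- nx * ny
  A <- matrix(0, n, n)
  id <- function(i, j) (j - 1) * nx + i
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- id(i, j)
    nb <- c(id(max(i - 1, 1), j), id(min(i + 1, nx), j),
            id(i, max(j - 1, 1)), id(i, min(j + 1, ny)))
    A[k, k] <- A[k, k] + 1 - 4 * D
    for (m in nb) A[k, m] <- A[k, m] + D
  }
  A
}

# exhaustive double-loop steady-state scan (same criterion as
# detect_steady_state, written without vectorised shortcuts)
oracle_steady_scan <- function(series, window, rel_tol, eps = 1e-9) {
  n <- length(series)
  ma <- function(t) mean(series[t:(t + window - 1)])
  last_start <- n - 2 * window + 1
  for (s in 1:last_start) {
    ok <- TRUE
    for (t in s:last_start) {
      a <- ma(t); b <- ma(t + window)
      if (abs(b - a) / max(a, eps) >= rel_tol) { ok <- FALSE; break }
    }
    if (ok) return(s - 1L)   # 0-based step
  }
  NA_integer_
}

# greedy contact-growth disk packing of one flat-top hexagon: full passes
# over every placed disk, trying a dense fan of candidate directions at
# exact contact distance, until a complete pass adds nothing (saturation)
oracle_pack_hex <- function(cx, cy, s, d, margin, n_angles = 48) {
  in_hex <- function(x, y) {
    a <- sqrt(3) / 2 * s - margin
    qx <- abs(x - cx); qy <- abs(y - cy)
    qy <= a & (sqrt(3) / 2 * qx + 0.5 * qy) <= a
  }
  px <- cx; py <- cy
  repeat {
    n0 <- length(px)
    for (i in sample.int(length(px))) {
      if (i > length(px)) next
      th <- runif(1, 0, 2 * pi) + 2 * pi * seq_len(n_angles) / n_angles
      for (t in th) {
        x <- px[i] + d * cos(t); y <- py[i] + d * sin(t)
        if (in_hex(x, y) &&
            all((px - x)^2 + (py - y)^2 >= d^2 * (1 - 1e-12))) {
          px <- c(px, x); py <- c(py, y)
        }
      }
    }
    if (length(px) == n0) break
  }
  cbind(px, py)
}

# a small simulation state a few steps into an injured run
quick_state <- function(seed = 1, steps = 10, fixture = "seven_lobule") {
  cfg <- make_fixture(fixture)
  cfg$run$seed <- seed
  st <- sim_init(cfg)
  for (t in seq_len(steps)) st <- sim_step(st)
  st
}
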