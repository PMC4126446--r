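# Trajectory post-processing: steady-state detection, peak ordering,
# replicate statistics and scenario comparison.

#' Detect the steady-state step of a time series
#'
#' Returns the first step index `s` (0-based, matching the census `step`
#' column) such that for every window start at or after `s`, the relative
#' change between the `window`-step moving average starting there and the
#' one starting a full window later is below `rel_tol`:
#' `|ma(t + window) - ma(t)| / max(ma(t), eps) < rel_tol`. Returns `NA` if
#' the criterion is never satisfied. The criterion is relative, so it is
#' invariant to uniform scaling of the series.
#'
#' @param series numeric per-step values (element 1 = step 0).
#' @param window moving-average window in steps (>= 2).
#' @param rel_tol relative change tolerance in (0, 1).
#' @param eps floor for the relative denominator.
#' @return integer step index, or `NA` if never steady.
#' @export
detect_steady_state <- function(series, window = 50L, rel_tol = 0.02,
                                eps = 1e-9) {
  if (!is.numeric(window) || window < 2) stop("window must be >= 2",
                                              call. = FALSE)
  if (rel_tol <= 0 || rel_tol >= 1) stop("rel_tol must be in (0, 1)",
                                         call. = FALSE)
  n <- length(series)
  if (n < 2L * window) {
    stop("insufficient data: series must be at least 2*window long",
         call. = FALSE)
  }
  ma <- stats::filter(series, rep(1 / window, window), sides = 1)
  ma <- ma[window:n]                 # ma[k] = mean of series[k..k+window-1]
  n_ma <- length(ma)
  lead <- window                      # compare windows a full window apart
  if (n_ma <= lead) stop("insufficient data", call. = FALSE)
  relchg <- abs(ma[(lead + 1):n_ma] - ma[seq_len(n_ma - lead)]) /
    pmax(ma[seq_len(n_ma - lead)], eps)
  ok <- relchg < rel_tol
  # first index from which all later window starts satisfy the criterion
  bad <- which(!ok)
  first <- if (length(bad) == 0L) 1L else if (max(bad) == length(ok))
    return(NA_integer_) else max(bad) + 1L
  as.integer(first - 1L)             # 0-based step of the window start
}

#' Order two series by their (smoothed) peak steps
#'
#' Smooths both series with a centred moving average and compares the
#' argmax steps.
#'
#' @param series_a,series_b numeric per-step values.
#' @param smooth centred smoothing window (odd; default 11).
#' @return `"a_first"`, `"b_first"` or `"tie"`.
#' @export
peak_order <- function(series_a, series_b, smooth = 11L) {
  if (!length(series_a) || !length(series_b)) {
    stop("series must be non-empty", call. = FALSE)
  }
  pa <- peak_step(series_a, smooth)
  pb <- peak_step(series_b, smooth)
  if (pa < pb) "a_first" else if (pb < pa) "b_first" else "tie"
}

# 0-based step of the smoothed maximum (first occurrence)
peak_step <- function(series, smooth = 11L) {
  sm <- smooth_series(series, smooth)
  which.max(sm) - 1L
}

smooth_series <- function(series, smooth = 11L) {
  if (smooth <= 1L || length(series) < 2L) return(series)
  half <- (as.integer(smooth) - 1L) %/% 2L
  n <- length(series)
  cs <- cumsum(c(0, series))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)   # shrinking centred windows
}

#' Compare scenarios on one census metric at one step
#'
#' @param results named list of [sim_run()] `scenario_result`s sharing
#'   step count and replicate count.
#' @param metric census column name (e.g. `"collagen"`).
#' @param at_step step at which to compare (default: final step).
#' @return list with `table` (scenario, mean, sd, ranked by mean) and
#'   `pairs` (data frame of pairwise mean differences and their signs;
#'   sign 0 is a tie).
#' @export
compare_scenarios <- function(results, metric, at_step = NULL) {
  stopifnot(is.list(results), length(results) >= 2L,
            !is.null(names(results)))
  nsteps <- vapply(results, function(r) nrow(r$mean), 0L)
  nreps <- vapply(results, function(r) length(r$replicates), 0L)
  if (length(unique(nsteps)) != 1L || length(unique(nreps)) != 1L) {
    stop("scenarios must share n_steps and replicate count", call. = FALSE)
  }
  if (!metric %in% names(results[[1]]$mean)) {
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  }
  if (is.null(at_step)) at_step <- nsteps[[1]] - 1L
  row <- at_step + 1L
  if (row < 1L || row > nsteps[[1]]) stop("at_step out of range", call. = FALSE)
  means <- vapply(results, function(r) r$mean[[metric]][row], 0)
  sds <- vapply(results, function(r) r$sd[[metric]][row], 0)
  ord <- order(means)
  tab <- data.frame(scenario = names(results)[ord], mean = means[ord],
                    sd = sds[ord], row.names = NULL)
  cmb <- utils::combn(names(results), 2)
  pairs <- data.frame(a = cmb[1, ], b = cmb[2, ],
                      diff = means[cmb[1, ]] - means[cmb[2, ]])
  pairs$sign <- sign(pairs$diff)
  list(metric = metric, at_step = at_step, table = tab, pairs = pairs)
}

#' Per-series trajectory statistics
#'
#' @param result a [sim_run()] `scenario_result`.
#' @param metric census column name.
#' @param window,rel_tol steady-state criterion (see
#'   [detect_steady_state()]).
#' @param smooth smoothing window for the peak.
#' @return object of class `trajectory_stat`: list with per-step `mean`
#'   and `sd`, `peak_step`, `peak_value`, `steady_state_step` (`NA` if
#'   never satisfied) and replicate count `n`.
#' @export
trajectory_stat <- function(result, metric, window = 50L, rel_tol = 0.02,
                            smooth = 11L) {
  stopifnot(inherits(result, "scenario_result"))
  m <- result$mean[[metric]]
  if (is.null(m)) stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  ss <- if (length(m) >= 2L * window + window) {
    detect_steady_state(m, window, rel_tol)
  } else NA_integer_
  structure(list(series = metric, mean = m, sd = result$sd[[metric]],
                 n = length(result$replicates),
                 peak_step = peak_step(m, smooth),
                 peak_value = max(smooth_series(m, smooth)),
                 steady_state_step = ss),
            class = "trajectory_stat")
}

#' @export
print.trajectory_stat <- function(x, ...) {
  cat(sprintf(
    "<trajectory_stat> %s (n=%d): peak %.4g at step %d; steady state at %s\n",
    x$series, x$n, x$peak_value, x$peak_step,
    ifelse(is.na(x$steady_state_step), "never",
           as.character(x$steady_state_step))))
  invisible(x)
}
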