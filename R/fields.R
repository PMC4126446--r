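# Diffusible mediator fields (TNF-alpha, TGF-beta1, HMGB1): per-factor
# concentration grids with deposition, explicit diffusion (5-point stencil,
# zero-flux boundaries), multiplicative degradation and threshold queries.
# Grid resolution defaults to one cell per hepatocyte diameter; total mass
# is sum(grid) * h^2.

#' Create a cytokine concentration field
#'
#' @param name one of `"TNF"`, `"TGF"`, `"HMGB1"`.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` of the tissue patch, or
#'   a `lobule_lattice` whose `patch_extent` is used.
#' @param h grid resolution (length per cell); default one hepatocyte
#'   diameter.
#' @param diffusion per-step spread fraction; the explicit 5-point scheme
#'   requires `diffusion <= 0.25`.
#' @param degradation per-step multiplicative decay fraction in \[0, 1\].
#' @param threshold detection level (same units as concentrations, > 0);
#'   agents "detect" the factor where concentration `>= threshold`.
#' @return object of class `cytokine_field`.
#' @export
cytokine_field <- function(name = c("TNF", "TGF", "HMGB1"), extent, h = 1,
                           diffusion = 0.2, degradation = 0.1,
                           threshold = 0.5) {
  name <- match.arg(name)
  if (inherits(extent, "lobule_lattice")) extent <- extent$patch_extent
  stopifnot(is.numeric(extent), length(extent) == 4)
  if (!is.numeric(h) || h <= 0) stop("h must be > 0", call. = FALSE)
  if (diffusion < 0 || diffusion > 0.25) {
    stop("diffusion must be in [0, 0.25] (explicit-scheme stability bound)",
         call. = FALSE)
  }
  if (degradation < 0 || degradation > 1) {
    stop("degradation must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be > 0", call. = FALSE)
  }
  x0 <- extent[1]; y0 <- extent[3]
  nx <- max(1L, as.integer(ceiling((extent[2] - x0) / h)))
  ny <- max(1L, as.integer(ceiling((extent[4] - y0) / h)))
  structure(list(name = name, grid = matrix(0, nx, ny), h = h,
                 x0 = x0, y0 = y0, nx = nx, ny = ny,
                 diffusion = diffusion, degradation = degradation,
                 threshold = threshold),
            class = "cytokine_field")
}

#' @export
print.cytokine_field <- function(x, ...) {
  cat(sprintf(
    "<cytokine_field> %s: %dx%d cells (h=%.3g), D=%.3g, delta=%.3g, total=%.4g\n",
    x$name, x$nx, x$ny, x$h, x$diffusion, x$degradation, field_total(x)))
  invisible(x)
}

# grid cell indices of positions; errors on out-of-patch points
field_cell <- function(field, x, y, clamp = FALSE) {
  ix <- floor((x - field$x0) / field$h) + 1
  iy <- floor((y - field$y0) / field$h) + 1
  if (clamp) {
    ix <- pmin(pmax(ix, 1), field$nx)
    iy <- pmin(pmax(iy, 1), field$ny)
  } else if (any(ix < 1 | ix > field$nx | iy < 1 | iy > field$ny)) {
    stop("position outside the field extent", call. = FALSE)
  }
  cbind(as.integer(ix), as.integer(iy))
}

#' Deposit an amount of factor at a position
#'
#' The grid cell containing `position` increases by `amount / h^2`, so the
#' field's total mass (`field_total`) increases by exactly `amount`.
#'
#' @param field a [cytokine_field()].
#' @param position numeric `c(x, y)`.
#' @param amount non-negative mass to add.
#' @return the updated field.
#' @export
deposit <- function(field, position, amount) {
  stopifnot(inherits(field, "cytokine_field"))
  if (!is.numeric(amount) || any(amount < 0)) {
    stop("amount must be >= 0", call. = FALSE)
  }
  ij <- field_cell(field, position[1], position[2])
  field$grid[ij] <- field$grid[ij] + amount / field$h^2
  field
}

# vectorised deposition used by the engine: positions already inside patch
deposit_many <- function(field, x, y, amounts) {
  if (length(x) == 0L) return(field)
  ij <- field_cell(field, x, y, clamp = TRUE)
  idx <- (ij[, 2] - 1L) * field$nx + ij[, 1]
  add <- rowsum(amounts / field$h^2, idx)
  at <- as.integer(rownames(add))
  field$grid[at] <- field$grid[at] + add[, 1]
  field
}

#' Advance a field one step: diffusion then degradation
#'
#' Applies one explicit diffusion step (5-point stencil with zero-flux
#' boundaries, conserving mass exactly up to float rounding) followed by
#' multiplicative decay by `1 - degradation`.
#'
#' @param field a [cytokine_field()].
#' @return the updated field.
#' @export
step_field <- function(field) {
  stopifnot(inherits(field, "cytokine_field"))
  u <- field$grid
  nx <- field$nx; ny <- field$ny
  if (field$diffusion > 0 && nx * ny > 1L) {
    up    <- u[, c(1L, seq_len(ny - 1L)), drop = FALSE]   # replicated edges
    down  <- u[, c(seq_len(ny - 1L) + 1L, ny), drop = FALSE]
    left  <- u[c(1L, seq_len(nx - 1L)), , drop = FALSE]
    right <- u[c(seq_len(nx - 1L) + 1L, nx), , drop = FALSE]
    u <- u + field$diffusion * (up + down + left + right - 4 * u)
  }
  field$grid <- u * (1 - field$degradation)
  field
}

#' Is the local concentration at or above the detection threshold?
#'
#' Pure query; uses the `>=` convention at the grid cell containing
#' `position`.
#'
#' @param field a [cytokine_field()].
#' @param position numeric `c(x, y)`.
#' @return logical.
#' @export
above_threshold <- function(field, position) {
  stopifnot(inherits(field, "cytokine_field"))
  ij <- field_cell(field, position[1], position[2])
  unname(field$grid[ij] >= field$threshold)
}

# vectorised threshold query at many positions (clamped to grid)
above_threshold_many <- function(field, x, y) {
  if (length(x) == 0L) return(logical(0))
  ij <- field_cell(field, x, y, clamp = TRUE)
  field$grid[ij] >= field$threshold
}

# threshold query at a cell-type-specific sensitivity (fraction of the
# field's detection threshold)
above_scaled <- function(field, x, y, sensitivity = 1) {
  if (length(x) == 0L) return(logical(0))
  ij <- field_cell(field, x, y, clamp = TRUE)
  field$grid[ij] >= field$threshold * sensitivity
}

#' Total mass of a field
#'
#' @param field a [cytokine_field()].
#' @return `sum(grid) * h^2`.
#' @export
field_total <- function(field) {
  sum(field$grid) * field$h^2
}

# matrix (nx x ny) of grid-cell centre coordinates above threshold
cells_above_threshold <- function(field) {
  idx <- which(field$grid >= field$threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  cbind(x = field$x0 + (idx[, 1] - 0.5) * field$h,
        y = field$y0 + (idx[, 2] - 0.5) * field$h)
}
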