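# Configuration files, state (de)serialization, CSV/PNG writers, run
# manifests and test fixtures. Configs and states are versioned JSON.

STATE_FORMAT <- "lobulesim-state"
STATE_VERSION <- 1L
CONFIG_FORMAT <- "lobulesim-config"

#' Load and validate a configuration file
#'
#' Reads a JSON configuration (nested sections as produced by
#' [save_config()]), deep-merges it over the package defaults, validates
#' it (unknown keys and out-of-range values are reported together) and
#' returns the frozen configuration.
#'
#' @param path file path.
#' @return a [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$format) && !identical(raw$format, CONFIG_FORMAT)) {
    stop(sprintf("unknown config format '%s'", raw$format), call. = FALSE)
  }
  raw$format <- NULL
  do.call(sim_config, raw)
}

#' Write a configuration file
#'
#' @param config a [sim_config()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  config <- as_sim_config(config)
  out <- c(list(format = CONFIG_FORMAT), unclass(config))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# ---- state serialization ---------------------------------------------------

# JSON has no Inf: encode non-finite lifespans with a sentinel
INF_SENTINEL <- -1

pop_to_json <- function(pop) {
  lapply(pop, function(v) {
    if (is.numeric(v)) ifelse(is.finite(v), v, INF_SENTINEL) else v
  })
}

#' Save a simulation state as versioned JSON
#'
#' The snapshot contains everything needed to resume bit-identically: the
#' configuration, all agent populations, all field grids, the census so
#' far, the step counter and the random number generator state. The
#' lattice and septal anchors are rebuilt deterministically from the
#' configuration on load.
#'
#' @param state a simulation state.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "sim_state"))
  out <- list(
    format = STATE_FORMAT, version = STATE_VERSION,
    step = state$step,
    config = unclass(state$config),
    rng = state$rng,
    ledger = state$ledger,
    hep = pop_to_json(state$hep), dead = pop_to_json(state$dead),
    kc = pop_to_json(state$kc), fib = pop_to_json(state$fib),
    col = pop_to_json(state$col),
    fields = lapply(state$fields, function(f) list(grid = f$grid)),
    census = state$census
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Load a simulation state saved by [save_state()]
#'
#' @param path file path.
#' @return a `sim_state`.
#' @export
load_state <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(raw$format, STATE_FORMAT)) {
    stop("not a lobulesim state file", call. = FALSE)
  }
  if (!identical(as.integer(raw$version), STATE_VERSION)) {
    stop(sprintf("unsupported state version %s", raw$version), call. = FALSE)
  }
  config <- do.call(sim_config, raw$config)
  config$therapy$applied <- isTRUE(raw$config$therapy$applied)
  lat <- build_patch_lattice(config)
  cls <- classify_nodes(lat)

  as_pop <- function(p, ints = character(0), infs = character(0)) {
    p <- lapply(p, function(v) if (length(v)) v else numeric(0))
    for (k in ints) p[[k]] <- as.integer(p[[k]])
    for (k in infs) p[[k]] <- ifelse(p[[k]] == INF_SENTINEL, Inf,
                                     as.numeric(p[[k]]))
    p
  }
  fields <- list()
  for (f in c("tnf", "tgf", "hmgb1")) {
    fl <- cytokine_field(toupper(sub("tnf", "TNF", sub("tgf", "TGF", f))),
                         lat, h = config$geometry$cell_diameter,
                         diffusion = config$fields[[f]]$diffusion,
                         degradation = config$fields[[f]]$degradation,
                         threshold = config$fields[[f]]$threshold)
    g <- raw$fields[[f]]$grid
    fl$grid <- matrix(as.numeric(g), fl$nx, fl$ny)
    fields[[f]] <- fl
  }
  fields$hmgb1$name <- "HMGB1"
  census <- raw$census
  if (is.null(dim(census))) census <- matrix(census, ncol = length(CENSUS_COLS))
  colnames(census) <- CENSUS_COLS
  structure(list(
    step = as.integer(raw$step), config = config, lattice = lat,
    internal_nodes = cls$internal, outer_nodes = cls$outer,
    fields = fields,
    hep = as_pop(raw$hep, ints = c("lobule", "age", "rep_count")),
    dead = as_pop(raw$dead, ints = c("lobule", "since")),
    kc = as_pop(raw$kc, ints = c("phago", "age"), infs = "lifespan"),
    fib = as_pop(raw$fib, ints = "kind"),
    col = as_pop(raw$col, ints = c("anchor_type", "anchor_id")),
    anchors = septal_anchors(lat, config),
    ledger = list(hep0 = as.integer(raw$ledger$hep0),
                  cum_deaths = as.integer(raw$ledger$cum_deaths),
                  cum_reps = as.integer(raw$ledger$cum_reps)),
    census = census,
    rng = as.integer(raw$rng)
  ), class = "sim_state")
}

# lattice from a configuration (grid or the seven-lobule ring arrangement)
build_patch_lattice <- function(config) {
  g <- config$geometry
  if (identical(g$arrangement, "ring7")) {
    s <- g$hex_side
    centers <- rbind(c(0, 0),
                     c(1.5 * s, sqrt(3) / 2 * s), c(1.5 * s, -sqrt(3) / 2 * s),
                     c(-1.5 * s, sqrt(3) / 2 * s), c(-1.5 * s, -sqrt(3) / 2 * s),
                     c(0, sqrt(3) * s), c(0, -sqrt(3) * s))
    build_lattice_from_centers(centers, s)
  } else {
    build_lattice(g$n_rows, g$n_cols, g$hex_side)
  }
}

# ---- CSV / report writers --------------------------------------------------

#' Write scenario results to CSV with a run manifest
#'
#' Writes one CSV per replicate, an aggregate CSV (per-step mean and SD of
#' every census column) and a JSON run manifest listing the configuration,
#' its fingerprint, the seeds and every output file.
#'
#' @param result a [sim_run()] `scenario_result`.
#' @param dir output directory (created if needed).
#' @param name file name stem (default: the therapy name).
#' @return the manifest, invisibly.
#' @export
write_scenario <- function(result, dir, name = result$config$therapy$name) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (r in seq_along(result$replicates)) {
    f <- file.path(dir, sprintf("%s_rep%02d.csv", name, r))
    write.csv(result$replicates[[r]], f, row.names = FALSE)
    files <- c(files, f)
  }
  agg <- cbind(result$mean,
               setNames(result$sd[, -1], paste0(names(result$sd)[-1], "_sd")))
  f <- file.path(dir, sprintf("%s_aggregate.csv", name))
  write.csv(agg, f, row.names = FALSE)
  files <- c(files, f)
  manifest <- list(
    format = "lobulesim-manifest", version = 1L,
    scenario = name,
    config = unclass(result$config),
    config_fingerprint = unname(state_fingerprint(unclass(result$config))),
    seeds = result$config$run$seed + seq_along(result$replicates) - 1L,
    package_version = as.character(utils::packageVersion("lobulesim")),
    outputs = basename(files),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mf <- file.path(dir, sprintf("%s_manifest.json", name))
  jsonlite::write_json(manifest, mf, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# ---- fixtures --------------------------------------------------------------

#' Deterministic test configurations
#'
#' * `single_lobule`: one hexagon; no internal nodes, so elastography
#'   raises an "unmeasurable lattice" error.
#' * `seven_lobule`: a centre hexagon ringed by six; the smallest patch
#'   with internal nodes.
#' * `paper_scale`: the calibrated full patch (4 x 4 lobules sized so the
#'   spiral fill emerges at ~3,857 hepatocytes).
#'
#' @param name fixture name.
#' @return a [sim_config()].
#' @export
make_fixture <- function(name = c("single_lobule", "seven_lobule",
                                  "paper_scale")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("single_lobule", "seven_lobule", "paper_scale")) {
    stop("unknown fixture; available: single_lobule, seven_lobule, paper_scale",
         call. = FALSE)
  }
  switch(name,
    single_lobule = sim_config(
      geometry = list(n_rows = 1L, n_cols = 1L, hex_side = 6),
      injury = list(radius = 2),
      run = list(n_steps = 60L)),
    seven_lobule = sim_config(
      geometry = list(arrangement = "ring7", hex_side = 6),
      injury = list(radius = 2),
      run = list(n_steps = 100L)),
    paper_scale = sim_config())
}

# ---- snapshot rendering ----------------------------------------------------

#' Draw list of a state snapshot
#'
#' The renderer's single source of truth: one row per glyph with `kind`,
#' `colour` and geometry (`x`, `y`, `r` for disks; `x`, `y`, `x2`, `y2`
#' for segments). Collagen is blue, as in a Masson's trichrome stain.
#'
#' @param state a simulation state.
#' @return data frame of glyphs.
#' @export
snapshot_draw_list <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  d <- state$config$geometry$cell_diameter
  ms <- mechanical_state(state)
  rods <- rod_geometry(ms)
  lat <- state$lattice
  seg <- data.frame(kind = "septum", colour = "grey30",
                    x = rods$x1, y = rods$y1, x2 = rods$x2, y2 = rods$y2,
                    r = NA_real_)
  mk <- function(kind, colour, x, y, r) {
    if (!length(x)) return(NULL)
    data.frame(kind = kind, colour = colour, x = x, y = y,
               x2 = NA_real_, y2 = NA_real_, r = r)
  }
  rbind(
    seg,
    mk("triad", "grey10", lat$nodes$x, lat$nodes$y,
       state$config$geometry$triad_radius * d),
    mk("hepatocyte", "wheat3", state$hep$x, state$hep$y, d / 2),
    mk("dead", "grey60", state$dead$x, state$dead$y, d / 2),
    mk("collagen", "blue", state$col$x, state$col$y, d / 2),
    mk("kupffer", "red3", state$kc$x, state$kc$y, d / 4),
    mk("fibrogenic", "darkgreen", state$fib$x, state$fib$y, d / 5)
  )
}

#' Render a state snapshot to PNG
#'
#' Draws the septal skeleton, hepatocytes, dead agents, collagen (blue),
#' Kupffer and fibrogenic cells with a legend. Pixel output is
#' deterministic for a fixed state.
#'
#' @param state a simulation state.
#' @param path output PNG path.
#' @param width,height image size in pixels.
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(state, path, width = 800L, height = 800L) {
  dl <- snapshot_draw_list(state)
  ext <- state$lattice$patch_extent
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = ext[1:2] + c(-1, 1), ylim = ext[3:4] + c(-1, 1),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("step %d", state$step))
  segs <- dl[dl$kind == "septum", ]
  graphics::segments(segs$x, segs$y, segs$x2, segs$y2, col = segs$colour,
                     lwd = 2)
  disks <- dl[dl$kind != "septum", ]
  if (nrow(disks)) {
    graphics::symbols(disks$x, disks$y, circles = disks$r, inches = FALSE,
                      add = TRUE, fg = disks$colour, bg = disks$colour)
  }
  graphics::legend("topright", bty = "n", pch = 19,
                   col = c("wheat3", "grey60", "blue", "red3", "darkgreen",
                           "grey10"),
                   legend = c("hepatocyte", "dead", "collagen", "Kupffer",
                              "fibrogenic", "triad"))
  invisible(path)
}
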