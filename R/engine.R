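# Simulation engine: configuration, initialization, the fixed-order step
# loop (injury -> agent rules -> recruitment -> fields -> mechanics ->
# census), therapy scenarios and replicate aggregation.

CENSUS_COLS <- c("step", "hepatocytes", "dead", "kc_quiescent",
                 "kc_activated", "hsc", "pf", "mf", "collagen",
                 "tnf_total", "tgf_total", "hmgb1_total",
                 "elastic_displacement")

default_config <- function() {
  list(
    geometry = list(
      arrangement = "grid",    # grid | ring7 (centre hexagon + 6 neighbours)
      n_rows = 4L, n_cols = 4L,
      hex_side = 10.60,        # calibrated so spiral_fill yields ~3857 cells
      cell_diameter = 1,
      septum_halfwidth = 0.15, # rod half thickness, x cell diameter
      rod_offset = 0.15,       # lateral offset of the side-by-side pair
      triad_radius = 0.5       # portal-triad collider radius, x diameter
    ),
    mechanics = list(
      rod_length_frac = 0.7,   # sub-segment length, x hex_side
      septum_min_frac = 0.7,   # prismatic slide window, x hex_side
      septum_max_frac = 1.2,
      tol = 1e-3,              # residual overlap tolerance, x diameter
      iterations = 10L,
      collagen_weight = 0.2    # relative mobility of anchored collagen
    ),
    hepatocyte = list(
      lifespan = c(2000, 3000),      # steps; long-lived under healthy conditions
      tnf_death_prob = 0.02,         # lumped TNF bystander death, per step
      replication_prob = 0.1,        # attempt prob when empty space detected
                                     # (regeneration is slow relative to an
                                     # injury cycle)
      max_rep_near_collagen = 2L     # replicative senescence cap
    ),
    kupffer = list(
      active_lifespan = c(800, 1200),# steps; Kupffer cells are long-lived
                                     # tissue macrophages, so activation
                                     # accumulates toward a saturating plateau
      phago_prob = 0.07,             # engulfment chance per adjacent step
      polarization_increment = 0.1,  # M1 -> M2 shift per phagocytosis event
      tnf_production = c(0.8, 1.2),  # full-strength amounts, sampled per step
      tgf_production = c(0.8, 1.2),
      tgf_inhibits_tnf = 0.7,        # max fractional damping of TNF output
                                     # by local TGF (anti-inflammatory arm)
      tgf_inhibition_k = 10,         # TGF level of half-maximal damping
      recruit_prob = 0.003,          # per HMGB1 hot spot per step
      crowding_cap = 1L              # max Kupffer cells per grid cell for
                                     # monocyte entry (saturating infiltrate)
    ),
    dead_cell = list(
      hmgb1_rate = 0.4,              # HMGB1 released per step while uncleared
      hmgb1_delay = 2L               # steps before release starts
    ),
    fibro = list(
      transform_prob = 0.005,        # HSC/PF -> myofibroblast when stimulated
      stimulus_sensitivity = 0.4,    # fibrogenic cells detect cytokines at
                                     # this fraction of the field threshold
                                     # (fibroblasts respond to far lower
                                     # levels than the bystander-death rule)
      deposit_prob = 0.8,            # collagen deposition per stimulated step
      proliferate_prob = 0.02,
      tgf_halfsat = 10,              # TGF level of half-maximal myofibroblast
                                     # response (dose-dependent above the
                                     # detection threshold)
      crowding_cap = 3L,             # max myofibroblasts per grid cell for
                                     # contact-inhibited proliferation
      reach = 3,                     # anchor search radius, x diameter
      band_width = 2.5,              # collagen extends the matrix scaffold
                                     # only within this distance of the
                                     # septal skeleton (periportal band and
                                     # bridging cords, not deep parenchyma)
      insertion_budget = 0.4,        # max penetration into pushable cells
                                     # when a deposit is inserted, x diameter
      spread = c(0.5, 1.5),          # daughter myofibroblast offset range
      hmgb1_activates = TRUE,        # HMGB1, like TNF, is a potent
                                     # fibroblast stimulant
      pf_per_triad = 2L
    ),
    fields = list(
      tnf   = list(diffusion = 0.2, degradation = 0.12, threshold = 0.5),
      tgf   = list(diffusion = 0.2, degradation = 0.03, threshold = 0.3),
      hmgb1 = list(diffusion = 0.2, degradation = 0.04, threshold = 0.45)
    ),
    injury = list(
      enabled = TRUE,
      period = 25L,                  # steps between toxic pulses
      radius = 9.1,                  # pulse radius around each lobule centre
                                     # (just under the lobule inradius, so a
                                     # pulse spans the lobule cross-section)
      kill_prob = 0.1,
      start = 1L
    ),
    therapy = list(
      name = "none",                 # none | anti_tnf | m2_enhance
      anti_tnf_factor = 3,
      m2_factor = 3,
      applied = FALSE
    ),
    elastography = list(
      interval = 20L,                # measure every so many steps (0 = never)
      impulse = 2,
      shrink = 0.05,
      iterations = 50L,
      substeps = 10L,          # impulse applied gradually (anti-tunnelling)
      mobility = 1,
      direction = "patch"            # patch | lobule
    ),
    neighborhood_radius = 1.5,       # contact neighbourhood, x diameter
    run = list(n_steps = 600L, seed = 1L, replicates = 1L)
  )
}

#' Create and validate a simulation configuration
#'
#' Starts from the package defaults (the calibrated paper-scale patch) and
#' deep-merges any overrides given as nested named lists, e.g.
#' `sim_config(run = list(n_steps = 100), injury = list(kill_prob = 0.3))`.
#' Unknown keys and out-of-range values are rejected with an aggregated
#' validation report naming every offending key.
#'
#' @param ... nested named overrides of the default configuration.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(...) {
  over <- list(...)
  cfg <- default_config()
  if (length(over)) cfg <- merge_config(cfg, over, path = "")
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

as_sim_config <- function(config) {
  if (inherits(config, "sim_config")) {
    validate_config(config)
    return(config)
  }
  do.call(sim_config, config)
}

# strict deep merge: every override key must exist in the defaults
merge_config <- function(base, over, path) {
  if (is.null(names(over)) || any(names(over) == "")) {
    stop(sprintf("configuration section '%s' must use named entries",
                 ifelse(path == "", "<top>", path)), call. = FALSE)
  }
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                        collapse = ", ")), call. = FALSE)
  }
  for (k in names(over)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], as.list(over[[k]]),
                                paste0(path, ".", k))
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(all(ok))) errs <<- c(errs, msg)
  g <- cfg$geometry
  chk(g$arrangement %in% c("grid", "ring7"),
      "geometry.arrangement must be 'grid' or 'ring7'")
  chk(g$n_rows >= 1 && g$n_cols >= 1, "geometry.n_rows/n_cols must be >= 1")
  chk(g$hex_side > 0, "geometry.hex_side must be > 0")
  chk(g$cell_diameter > 0 && g$cell_diameter < g$hex_side,
      "geometry.cell_diameter must be in (0, hex_side)")
  prob_keys <- list(
    "hepatocyte.tnf_death_prob" = cfg$hepatocyte$tnf_death_prob,
    "hepatocyte.replication_prob" = cfg$hepatocyte$replication_prob,
    "kupffer.recruit_prob" = cfg$kupffer$recruit_prob,
    "kupffer.phago_prob" = cfg$kupffer$phago_prob,
    "kupffer.tgf_inhibits_tnf" = cfg$kupffer$tgf_inhibits_tnf,
    "fibro.transform_prob" = cfg$fibro$transform_prob,
    "fibro.stimulus_sensitivity" = cfg$fibro$stimulus_sensitivity,
    "fibro.deposit_prob" = cfg$fibro$deposit_prob,
    "fibro.proliferate_prob" = cfg$fibro$proliferate_prob,
    "injury.kill_prob" = cfg$injury$kill_prob)
  for (k in names(prob_keys)) {
    v <- prob_keys[[k]]
    chk(is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1,
        sprintf("%s must be a probability in [0, 1]", k))
  }
  for (f in names(cfg$fields)) {
    ff <- cfg$fields[[f]]
    chk(ff$diffusion >= 0 && ff$diffusion <= 0.25,
        sprintf("fields.%s.diffusion must be in [0, 0.25] (stability)", f))
    chk(ff$degradation >= 0 && ff$degradation <= 1,
        sprintf("fields.%s.degradation must be in [0, 1]", f))
    chk(ff$threshold > 0, sprintf("fields.%s.threshold must be > 0", f))
  }
  rng_keys <- list("hepatocyte.lifespan" = cfg$hepatocyte$lifespan,
                   "kupffer.active_lifespan" = cfg$kupffer$active_lifespan,
                   "kupffer.tnf_production" = cfg$kupffer$tnf_production,
                   "kupffer.tgf_production" = cfg$kupffer$tgf_production,
                   "fibro.spread" = cfg$fibro$spread)
  for (k in names(rng_keys)) {
    v <- rng_keys[[k]]
    chk(is.numeric(v) && length(v) == 2 && all(v >= 0) && v[1] <= v[2],
        sprintf("%s must be a non-negative [min, max] range", k))
  }
  chk(cfg$injury$period >= 1, "injury.period must be >= 1")
  chk(cfg$injury$radius <= sqrt(3) / 2 * g$hex_side,
      "injury.radius must not exceed the lobule inradius")
  chk(cfg$therapy$name %in% c("none", "anti_tnf", "m2_enhance"),
      "therapy.name must be one of none, anti_tnf, m2_enhance")
  e <- cfg$elastography
  chk(e$interval >= 0, "elastography.interval must be >= 0")
  chk(e$impulse > 0, "elastography.impulse must be > 0")
  chk(e$shrink > 0 && e$shrink < 1, "elastography.shrink must be in (0, 1)")
  chk(e$direction %in% c("patch", "lobule"),
      "elastography.direction must be 'patch' or 'lobule'")
  chk(cfg$run$n_steps >= 0, "run.n_steps must be >= 0")
  chk(cfg$run$replicates >= 1, "run.replicates must be >= 1")
  if (length(errs)) {
    stop(paste0("invalid configuration:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %dx%d lobules (side %.3g), %d steps, therapy=%s, seed=%d, replicates=%d\n",
    x$geometry$n_rows, x$geometry$n_cols, x$geometry$hex_side,
    x$run$n_steps, x$therapy$name, x$run$seed, x$run$replicates))
  invisible(x)
}

# clearance of cell centres from septal edge lines
patch_margin <- function(cfg) {
  (cfg$geometry$septum_halfwidth + cfg$geometry$rod_offset + 0.5) *
    cfg$geometry$cell_diameter
}

#' Apply a therapy scenario to a configuration
#'
#' `anti_tnf` (neutralizing anti-TNF-alpha antibody) multiplies the TNF
#' field's degradation rate by `therapy$anti_tnf_factor`; `m2_enhance`
#' (enhanced M2 activation) multiplies the Kupffer cells' TGF-beta1
#' production range by `therapy$m2_factor`. No other parameter changes.
#' Idempotent: a configuration is marked once applied.
#'
#' @param config a [sim_config()].
#' @return the modified configuration.
#' @export
apply_therapy <- function(config) {
  config <- as_sim_config(config)
  if (isTRUE(config$therapy$applied) || config$therapy$name == "none") {
    return(config)
  }
  if (config$therapy$name == "anti_tnf") {
    f <- config$therapy$anti_tnf_factor
    if (!is.numeric(f) || f <= 1) {
      stop("therapy.anti_tnf_factor must be > 1 (increased TNF degradation)",
           call. = FALSE)
    }
    config$fields$tnf$degradation <-
      min(1, config$fields$tnf$degradation * f)
  } else if (config$therapy$name == "m2_enhance") {
    f <- config$therapy$m2_factor
    if (!is.numeric(f) || f <= 1) {
      stop("therapy.m2_factor must be > 1 (increased TGF-beta1 production)",
           call. = FALSE)
    }
    config$kupffer$tgf_production <- config$kupffer$tgf_production * f
  }
  config$therapy$applied <- TRUE
  config
}

# ---- initialization --------------------------------------------------------

#' Initialize a simulation state
#'
#' Builds the lattice, spiral-fills it with hepatocytes, seeds Kupffer
#' cells (15/60 of the hepatocyte count, uniform over the patch), hepatic
#' stellate cells (5/60, uniform within lobule interiors) and portal
#' fibroblasts (at the portal triads), zeroes all fields, and records the
#' step-0 census. Seeds the R random number generator from
#' `config$run$seed`; the returned state carries the generator state so
#' that stepping is fully reproducible.
#'
#' @param config a [sim_config()] (therapy is applied automatically).
#' @return object of class `sim_state`.
#' @export
sim_init <- function(config) {
  config <- apply_therapy(as_sim_config(config))
  set.seed(config$run$seed)
  g <- config$geometry
  d <- g$cell_diameter
  lat <- build_patch_lattice(config)
  cls <- classify_nodes(lat)

  fill <- spiral_fill(lat, d, margin = patch_margin(config))
  n_hep <- nrow(fill)
  hep <- new_hepatocytes(fill$x, fill$y, fill$lobule,
                         lifespan = runif(n_hep, config$hepatocyte$lifespan[1],
                                          config$hepatocyte$lifespan[2]))
  counts <- initialize_populations(n_hep)
  kc_xy <- sample_patch_points(lat, counts$n_kupffer, margin = 0)
  kc <- new_kupffer(kc_xy[, 1], kc_xy[, 2], activated = FALSE, m = 0,
                    lifespan = Inf)
  hsc_xy <- sample_patch_points(lat, counts$n_hsc, margin = patch_margin(config))
  pf_nodes <- lat$nodes[rep(seq_len(nrow(lat$nodes)),
                            each = config$fibro$pf_per_triad), ]
  fib <- new_fibrogenic(c(hsc_xy[, 1], pf_nodes$x),
                        c(hsc_xy[, 2], pf_nodes$y),
                        kind = c(rep(FIB_HSC, nrow(hsc_xy)),
                                 rep(FIB_PF, nrow(pf_nodes))))
  fields <- list(
    tnf = cytokine_field("TNF", lat, h = d,
                         diffusion = config$fields$tnf$diffusion,
                         degradation = config$fields$tnf$degradation,
                         threshold = config$fields$tnf$threshold),
    tgf = cytokine_field("TGF", lat, h = d,
                         diffusion = config$fields$tgf$diffusion,
                         degradation = config$fields$tgf$degradation,
                         threshold = config$fields$tgf$threshold),
    hmgb1 = cytokine_field("HMGB1", lat, h = d,
                           diffusion = config$fields$hmgb1$diffusion,
                           degradation = config$fields$hmgb1$degradation,
                           threshold = config$fields$hmgb1$threshold))

  census <- matrix(NA_real_, nrow = config$run$n_steps + 1L,
                   ncol = length(CENSUS_COLS),
                   dimnames = list(NULL, CENSUS_COLS))
  state <- structure(list(
    step = 0L, config = config, lattice = lat,
    internal_nodes = cls$internal, outer_nodes = cls$outer,
    fields = fields, hep = hep,
    dead = new_dead(numeric(0), numeric(0), integer(0)),
    kc = kc, fib = fib,
    col = new_collagen(numeric(0), numeric(0)),
    anchors = septal_anchors(lat, config),
    ledger = list(hep0 = n_hep, cum_deaths = 0L, cum_reps = 0L),
    census = census, rng = NULL
  ), class = "sim_state")
  state <- record_census(state)
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "<sim_state> step %d: %d hepatocytes, %d dead, %d KC (%d activated), %d fibrogenic, %d collagen\n",
    x$step, pop_n(x$hep), pop_n(x$dead), pop_n(x$kc), sum(x$kc$activated),
    pop_n(x$fib), pop_n(x$col)))
  invisible(x)
}

# rejection-sample n uniform points inside the lobule patch
sample_patch_points <- function(lat, n, margin = 0) {
  out <- matrix(numeric(0), 0, 2)
  ext <- lat$patch_extent
  guard <- 0L
  while (nrow(out) < n && guard < 1000L) {
    m <- max(2L * (n - nrow(out)), 16L)
    x <- runif(m, ext[1], ext[2]); y <- runif(m, ext[3], ext[4])
    ok <- !is.na(patch_member(x, y, lat, margin))
    out <- rbind(out, cbind(x[ok], y[ok]))
    guard <- guard + 1L
  }
  if (nrow(out) < n) stop("could not sample points inside the patch")
  out[seq_len(n), , drop = FALSE]
}

# fixed structural anchors for collagen deposition: portal triads (type 1)
# and sample points along every septum centre line (type 2); collagen
# deposits (type 3) are appended at run time.
septal_anchors <- function(lat, cfg) {
  d <- cfg$geometry$cell_diameter
  tri <- cbind(lat$nodes$x, lat$nodes$y)
  xs <- ys <- numeric(0); id <- integer(0)
  step <- 0.5 * d
  for (k in seq_len(nrow(lat$septa))) {
    a <- lat$septa$node_a[k]; b <- lat$septa$node_b[k]
    len <- lat$septa$length[k]
    tseq <- seq(0.1, 0.9, by = step / len)
    xs <- c(xs, lat$nodes$x[a] + (lat$nodes$x[b] - lat$nodes$x[a]) * tseq)
    ys <- c(ys, lat$nodes$y[a] + (lat$nodes$y[b] - lat$nodes$y[a]) * tseq)
    id <- c(id, rep(k, length(tseq)))
  }
  list(
    x = c(tri[, 1], xs), y = c(tri[, 2], ys),
    r = c(rep(cfg$geometry$triad_radius * d, nrow(tri)),
          # structural half-width plus a small standoff so sites offered by
          # oblique anchors still clear the boundary sub-segments
          rep((cfg$geometry$septum_halfwidth + cfg$geometry$rod_offset +
                 0.1) * d, length(xs))),
    type = c(rep(1L, nrow(tri)), rep(2L, length(xs))),
    id = c(lat$nodes$id, id)
  )
}

# ---- injury ----------------------------------------------------------------

#' Apply one pulse of centrilobular toxicity
#'
#' Each hepatocyte within `radius` of its own lobule's centre becomes a
#' dead agent with probability `kill_prob`; live + dead counts are
#' conserved by the pulse.
#'
#' @param state a simulation state.
#' @param radius pulse radius (must not exceed the lobule inradius).
#' @param kill_prob per-cell kill probability.
#' @return the updated state.
#' @export
injury_pulse <- function(state,
                         radius = state$config$injury$radius,
                         kill_prob = state$config$injury$kill_prob) {
  stopifnot(inherits(state, "sim_state"))
  if (radius > sqrt(3) / 2 * state$lattice$hex_side) {
    stop("injury radius exceeds the lobule inradius", call. = FALSE)
  }
  hep <- state$hep
  n <- pop_n(hep)
  if (n == 0L || kill_prob <= 0) return(state)
  cx <- state$lattice$lobules$cx[hep$lobule]
  cy <- state$lattice$lobules$cy[hep$lobule]
  inside <- (hep$x - cx)^2 + (hep$y - cy)^2 <= radius^2
  kill <- inside & runif(n) < kill_prob
  if (any(kill)) {
    state$dead <- pop_bind(state$dead,
                           new_dead(hep$x[kill], hep$y[kill],
                                    hep$lobule[kill], since = 0L))
    state$hep <- pop_subset(hep, !kill)
    state$ledger$cum_deaths <- state$ledger$cum_deaths + sum(kill)
  }
  state
}

# ---- step phases -----------------------------------------------------------

# occupancy of the field grid by colliding disks (counts per cell), plus
# 3x3 neighbourhood sums; used as a cheap prefilter for "empty neighbouring
# space" queries in continuous space.
occupancy_counts <- function(field, xs, ys) {
  M <- matrix(0L, field$nx, field$ny)
  if (length(xs)) {
    ij <- field_cell(field, xs, ys, clamp = TRUE)
    idx <- (ij[, 2] - 1L) * field$nx + ij[, 1]
    M[] <- tabulate(idx, nbins = field$nx * field$ny)
  }
  M
}

nbhd_sum3 <- function(M) {
  nx <- nrow(M); ny <- ncol(M)
  P <- matrix(0, nx + 2L, ny + 2L)
  P[2:(nx + 1L), 2:(ny + 1L)] <- M
  out <- matrix(0, nx, ny)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + P[di + seq_len(nx), dj + seq_len(ny)]
  }
  out
}

# collider roster for site searches: live hepatocytes, dead agents,
# collagen (disks of one cell radius) plus portal-triad disks
collider_disks <- function(state) {
  d <- state$config$geometry$cell_diameter
  lat <- state$lattice
  xy <- rbind(cbind(state$hep$x, state$hep$y),
              cbind(state$dead$x, state$dead$y),
              cbind(state$col$x, state$col$y),
              cbind(lat$nodes$x, lat$nodes$y))
  r <- c(rep(d / 2, pop_n(state$hep) + pop_n(state$dead) + pop_n(state$col)),
         rep(state$config$geometry$triad_radius * d, nrow(lat$nodes)))
  list(xy = xy, r = r)
}

hepatocyte_phase <- function(state) {
  cfg <- state$config
  d <- cfg$geometry$cell_diameter
  hep <- state$hep
  n <- pop_n(hep)
  if (n == 0L) return(state)

  tnf_ab <- above_threshold_many(state$fields$tnf, hep$x, hep$y)
  occ <- occupancy_counts(state$fields$tnf,
                          c(hep$x, state$dead$x, state$col$x),
                          c(hep$y, state$dead$y, state$col$y))
  nb <- nbhd_sum3(occ)
  ij <- field_cell(state$fields$tnf, hep$x, hep$y, clamp = TRUE)
  cell_idx <- (ij[, 2] - 1L) * nrow(nb) + ij[, 1]
  # a single-cell pore among ~10 packed neighbours must stay eligible, so
  # the cutoff sits at the jamming count of a 3x3 block
  maybe_empty <- nb[cell_idx] <= 10

  if (pop_n(state$col) > 0L) {
    colocc <- occupancy_counts(state$fields$tnf, state$col$x, state$col$y)
    col_adj <- nbhd_sum3(colocc)[cell_idx] > 0
  } else {
    col_adj <- rep(FALSE, n)
  }

  ev <- hepatocyte_step(hep, tnf_ab, maybe_empty, col_adj,
                        death_prob = cfg$hepatocyte$tnf_death_prob,
                        replication_prob = cfg$hepatocyte$replication_prob,
                        max_rep = cfg$hepatocyte$max_rep_near_collagen)
  die <- ev == "die"
  if (any(die)) {
    state$dead <- pop_bind(state$dead,
                           new_dead(hep$x[die], hep$y[die], hep$lobule[die]))
    state$ledger$cum_deaths <- state$ledger$cum_deaths + sum(die)
  }
  keep <- !die
  hep <- pop_subset(hep, keep)
  ev <- ev[keep]
  hep$age <- hep$age + 1L

  rep_idx <- which(ev == "replicate")
  if (length(rep_idx)) {
    state$hep <- hep  # colliders must include the current survivors
    coll <- collider_disks(state)
    ord <- if (length(rep_idx) > 1L) sample.int(length(rep_idx)) else 1L
    res <- cpp_find_sites(cbind(hep$x[rep_idx], hep$y[rep_idx]), ord,
                          coll$xy, coll$r,
                          state$lattice$centers, state$lattice$hex_side,
                          patch_margin(cfg), d, d / 2, 12L,
                          runif(length(rep_idx)))
    if (length(res$parent)) {
      par <- rep_idx[res$parent]
      hep$rep_count[par] <- hep$rep_count[par] + 1L
      kids <- new_hepatocytes(res$x, res$y, res$hex,
                              lifespan = runif(length(res$x),
                                               cfg$hepatocyte$lifespan[1],
                                               cfg$hepatocyte$lifespan[2]))
      hep <- pop_bind(hep, kids)
      state$ledger$cum_reps <- state$ledger$cum_reps + length(res$parent)
    }
  }
  state$hep <- hep
  state
}

kupffer_phase <- function(state) {
  cfg <- state$config
  d <- cfg$geometry$cell_diameter
  res <- kupffer_step(state$kc, state$dead,
                      radius = cfg$neighborhood_radius * d,
                      increment = cfg$kupffer$polarization_increment,
                      tnf_range = cfg$kupffer$tnf_production,
                      tgf_range = cfg$kupffer$tgf_production,
                      active_lifespan = cfg$kupffer$active_lifespan,
                      phago_prob = cfg$kupffer$phago_prob)
  kc <- res$kcs
  if (length(res$phagocytized)) {
    keep <- rep(TRUE, pop_n(state$dead))
    keep[res$phagocytized] <- FALSE
    state$dead <- pop_subset(state$dead, keep)
  }
  if (pop_n(kc) > 0L) {
    # anti-inflammatory action of local TGF-beta1: saturating, dose-
    # dependent damping of TNF secretion
    tnf_amt <- res$tnf
    if (cfg$kupffer$tgf_inhibits_tnf > 0 && any(tnf_amt > 0)) {
      f <- state$fields$tgf
      ij <- field_cell(f, kc$x, kc$y, clamp = TRUE)
      tgf_loc <- f$grid[ij]
      damp <- cfg$kupffer$tgf_inhibits_tnf *
        tgf_loc / (tgf_loc + cfg$kupffer$tgf_inhibition_k)
      tnf_amt <- tnf_amt * (1 - damp)
    }
    sec <- tnf_amt > 0
    state$fields$tnf <- deposit_many(state$fields$tnf, kc$x[sec], kc$y[sec],
                                     tnf_amt[sec])
    sec <- res$tgf > 0
    state$fields$tgf <- deposit_many(state$fields$tgf, kc$x[sec], kc$y[sec],
                                     res$tgf[sec])
    kc$age <- kc$age + 1L
    expired <- kc$activated & kc$age > kc$lifespan
    if (any(expired)) kc <- pop_subset(kc, !expired)
  }
  state$kc <- kc
  state
}

fibrogenic_phase <- function(state) {
  cfg <- state$config
  d <- cfg$geometry$cell_diameter
  fib <- state$fib
  n <- pop_n(fib)
  if (n == 0L) return(state)
  sens <- cfg$fibro$stimulus_sensitivity
  tnf_ab <- above_scaled(state$fields$tnf, fib$x, fib$y, sens)
  tgf_ab <- above_scaled(state$fields$tgf, fib$x, fib$y, sens)
  hmgb1_ab <- above_scaled(state$fields$hmgb1, fib$x, fib$y, sens)
  ev <- fibrogenic_step(fib, tnf_ab, hmgb1_ab, tgf_ab,
                        transform_prob = cfg$fibro$transform_prob,
                        deposit_prob = cfg$fibro$deposit_prob,
                        proliferate_prob = cfg$fibro$proliferate_prob,
                        hmgb1_activates = cfg$fibro$hmgb1_activates)
  fib$kind[ev$transform] <- FIB_MF

  # myofibroblast responses are dose-dependent in TGF above the detection
  # threshold (saturating), so enhanced or damped TGF shifts fibrogenesis
  tgf_gate <- function(idx) {
    if (!length(idx)) return(idx)
    f <- state$fields$tgf
    ij <- field_cell(f, fib$x[idx], fib$y[idx], clamp = TRUE)
    g <- f$grid[ij] / (f$grid[ij] + cfg$fibro$tgf_halfsat)
    idx[runif(length(idx)) < g]
  }
  dep_idx <- tgf_gate(which(ev$deposit))
  if (length(dep_idx)) {
    anc <- state$anchors
    n_col0 <- pop_n(state$col)
    # existing deposits seed further deposition only inside the periportal
    # band, so cords thicken and bridge along septa rather than invading
    # the lobule centre
    ext <- state$col$skel_dist <= cfg$fibro$band_width * d
    axy <- cbind(c(anc$x, state$col$x[ext]), c(anc$y, state$col$y[ext]))
    ar <- c(anc$r, rep(d / 2, sum(ext)))
    aty <- c(anc$type, rep(3L, sum(ext)))
    aid <- c(anc$id, which(ext))
    coll <- collider_disks(state)
    # live and dead cells are pushable (the tissue yields to new matrix);
    # existing collagen and triads are not
    soft <- c(rep(TRUE, pop_n(state$hep) + pop_n(state$dead)),
              rep(FALSE, pop_n(state$col) + nrow(state$lattice$nodes)))
    ord <- if (length(dep_idx) > 1L) sample.int(length(dep_idx)) else 1L
    ms <- mechanical_state(state)
    rods <- rod_geometry(ms)
    rod_clear <- (cfg$geometry$septum_halfwidth + 0.5) * d * 0.999
    res <- cpp_collagen_sites(cbind(fib$x[dep_idx], fib$y[dep_idx]), ord,
                              axy, ar, aty, aid, coll$xy, coll$r,
                              soft, cfg$fibro$insertion_budget * d,
                              as.matrix(rods[, c("x1", "y1", "x2", "y2")]),
                              rod_clear,
                              state$lattice$centers, state$lattice$hex_side,
                              0.35 * d, cfg$fibro$reach * d, d / 2, 1e-9 * d)
    if (length(res$x)) {
      a_id <- res$anchor_id
      neg <- res$anchor_type == 3L & a_id < 0L
      a_id[neg] <- n_col0 - a_id[neg]  # remap same-sweep deposits
      skel <- anc$type != 3L
      sd_new <- vapply(seq_along(res$x), function(i) {
        sqrt(min((anc$x[skel] - res$x[i])^2 + (anc$y[skel] - res$y[i])^2))
      }, 0)
      state$col <- pop_bind(state$col,
                            new_collagen(res$x, res$y, res$anchor_type, a_id,
                                         sd_new))
    }
  }

  pro_idx <- tgf_gate(which(ev$proliferate))
  if (length(pro_idx)) {
    # contact inhibition: no proliferation in already crowded grid cells
    f <- state$fields$tgf
    mf_all <- fib$kind == FIB_MF
    occ_mf <- occupancy_counts(f, fib$x[mf_all], fib$y[mf_all])
    ij <- field_cell(f, fib$x[pro_idx], fib$y[pro_idx], clamp = TRUE)
    roomy <- occ_mf[ij] < cfg$fibro$crowding_cap
    pro_idx <- pro_idx[roomy]
  }
  if (length(pro_idx)) {
    k <- length(pro_idx)
    rr <- runif(k, cfg$fibro$spread[1], cfg$fibro$spread[2]) * d
    th <- runif(k, 0, 2 * pi)
    nx <- fib$x[pro_idx] + rr * cos(th)
    ny <- fib$y[pro_idx] + rr * sin(th)
    inside <- !is.na(patch_member(nx, ny, state$lattice, 0))
    if (any(inside)) {
      fib <- pop_bind(fib, new_fibrogenic(nx[inside], ny[inside], FIB_MF))
    }
  }
  state$fib <- fib
  state
}

# uncleared dead agents release HMGB1 after a delay
hmgb1_phase <- function(state) {
  cfg <- state$config
  dead <- state$dead
  if (pop_n(dead) == 0L) return(state)
  dead$since <- dead$since + 1L
  emit <- dead$since > cfg$dead_cell$hmgb1_delay
  if (any(emit)) {
    state$fields$hmgb1 <- deposit_many(state$fields$hmgb1,
                                       dead$x[emit], dead$y[emit],
                                       rep(cfg$dead_cell$hmgb1_rate, sum(emit)))
  }
  state$dead <- dead
  state
}

mechanics_phase <- function(state) {
  cfg <- state$config
  tol <- cfg$mechanics$tol * cfg$geometry$cell_diameter
  ms <- mechanical_state(state)
  if (nrow(ms$disks) >= 2L) {
    worst <- cpp_max_overlap(ms$disks, ms$disk_r)
    if (worst >= tol) {
      # relax in chunks (septa rods and pinned triads included, so cells
      # cannot be pushed across lobule boundaries), stopping early once
      # residual disk overlap is below tolerance
      chunk <- as.integer(cfg$mechanics$iterations)
      for (k in seq_len(4L)) {
        res <- cpp_mech_step(ms$nodes, rep(TRUE, nrow(ms$nodes)), ms$node_r,
                             ms$septa, ms$Lmin, ms$Lmax, ms$rod_len,
                             ms$rod_halfw, ms$rod_off, ms$disks, ms$disk_r,
                             ms$disk_weight, chunk)
        ms$disks <- res$disks
        worst <- cpp_max_overlap(ms$disks, ms$disk_r)
        if (worst < tol) break
      }
      if (worst >= 0.3 * cfg$geometry$cell_diameter) {
        dump <- file.path(tempdir(),
                          sprintf("lobulesim-dump-step%d.json", state$step))
        try(save_state(state, dump), silent = TRUE)
        stop(sprintf(
          "invariant breach at step %d: collider overlap %.4g (state dump: %s)",
          state$step, worst, dump), call. = FALSE)
      }
      n_hep <- pop_n(state$hep); n_dead <- pop_n(state$dead)
      n_col <- pop_n(state$col)
      state$hep$x <- ms$disks[seq_len(n_hep), 1]
      state$hep$y <- ms$disks[seq_len(n_hep), 2]
      if (n_dead) {
        state$dead$x <- ms$disks[n_hep + seq_len(n_dead), 1]
        state$dead$y <- ms$disks[n_hep + seq_len(n_dead), 2]
      }
      if (n_col) {
        state$col$x <- ms$disks[n_hep + n_dead + seq_len(n_col), 1]
        state$col$y <- ms$disks[n_hep + n_dead + seq_len(n_col), 2]
      }
    }
  }
  if (min(vapply(state$fields, function(f) min(f$grid), 0)) < 0) {
    stop(sprintf("invariant breach at step %d: negative field value",
                 state$step), call. = FALSE)
  }
  state
}

record_census <- function(state) {
  cfg <- state$config
  e <- cfg$elastography
  disp <- NA_real_
  if (e$interval > 0L && state$step %% e$interval == 0L &&
      length(state$internal_nodes) > 0L) {
    disp <- measure_elasticity(state)$displacement
  }
  row <- c(state$step, pop_n(state$hep), pop_n(state$dead),
           sum(!state$kc$activated), sum(state$kc$activated),
           sum(state$fib$kind == FIB_HSC), sum(state$fib$kind == FIB_PF),
           sum(state$fib$kind == FIB_MF), pop_n(state$col),
           field_total(state$fields$tnf), field_total(state$fields$tgf),
           field_total(state$fields$hmgb1), disp)
  state$census[state$step + 1L, ] <- row
  state
}

#' Advance a simulation by one step
#'
#' One tick in fixed sub-phase order: (1) injury pulse if scheduled;
#' (2) agent rules (hepatocytes, Kupffer cells, fibrogenic cells, HMGB1
#' release by uncleared dead agents), each processed in randomized agent
#' order where order matters; (3) monocyte recruitment; (4) field
#' diffusion/degradation; (5) mechanics; (6) census bookkeeping. The state
#' carries its own random number generator stream: stepping restores it on
#' entry and captures it on exit, so `config + seed` fully determine the
#' trajectory.
#'
#' @param state a [sim_init()] state.
#' @return the advanced state.
#' @export
sim_step <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  if (!is.null(state$rng)) {
    assign(".Random.seed", state$rng, envir = globalenv())
  }
  cfg <- state$config
  t_now <- state$step + 1L
  if (t_now > cfg$run$n_steps) {
    state$census <- rbind(state$census, NA_real_)  # grow if stepped past plan
  }
  inj <- cfg$injury
  if (inj$enabled && t_now >= inj$start &&
      (t_now - inj$start) %% inj$period == 0L) {
    state <- injury_pulse(state, inj$radius, inj$kill_prob)
  }
  state <- hepatocyte_phase(state)
  state <- kupffer_phase(state)
  state <- fibrogenic_phase(state)
  state <- hmgb1_phase(state)
  rec <- recruit_monocytes(state$fields$hmgb1, state$lattice,
                           cfg$kupffer$recruit_prob,
                           cfg$kupffer$active_lifespan,
                           kcs = state$kc,
                           crowding_cap = cfg$kupffer$crowding_cap)
  if (pop_n(rec)) state$kc <- pop_bind(state$kc, rec)
  state$fields <- lapply(state$fields, step_field)
  state <- mechanics_phase(state)
  state$step <- t_now
  state <- record_census(state)
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

#' Census time series of a state
#'
#' @param state a simulation state.
#' @return data frame with one row per completed step (including step 0)
#'   and the standard census columns.
#' @export
census_df <- function(state) {
  as.data.frame(state$census[seq_len(state$step + 1L), , drop = FALSE])
}

# ---- replicate runner ------------------------------------------------------

#' Run a scenario with replicates and aggregate mean and SD
#'
#' Executes `config$run$replicates` independent runs (replicate `r` uses
#' seed `config$run$seed + r - 1`, so scenarios sharing a base seed are
#' paired by common random numbers), collects the per-step census of each,
#' and returns per-step mean and SD across replicates.
#'
#' @param config a [sim_config()].
#' @param progress print a line per replicate?
#' @return object of class `scenario_result`: list with `config`,
#'   `replicates` (list of census data frames), `mean` and `sd` (data
#'   frames over the census columns).
#' @export
sim_run <- function(config, progress = FALSE) {
  config <- as_sim_config(config)
  reps <- config$run$replicates
  per <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg_r <- config
    cfg_r$run$seed <- config$run$seed + r - 1L
    st <- tryCatch({
      st <- sim_init(cfg_r)
      for (t in seq_len(config$run$n_steps)) st <- sim_step(st)
      st
    }, error = function(e) {
      stop(sprintf("replicate %d failed: %s", r, conditionMessage(e)),
           call. = FALSE)
    })
    per[[r]] <- census_df(st)
    if (progress) {
      message(sprintf("replicate %d/%d done (%d collagen deposits)",
                      r, reps, tail(per[[r]]$collagen, 1)))
    }
  }
  arr <- simplify2array(lapply(per, as.matrix))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- if (reps > 1L) apply(arr, c(1, 2), stats::sd) else mean_m * 0
  structure(list(config = config,
                 replicates = per,
                 mean = as.data.frame(mean_m),
                 sd = as.data.frame(sd_m)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "<scenario_result> therapy=%s, %d replicates x %d steps; final mean collagen %.1f\n",
    x$config$therapy$name, length(x$replicates),
    nrow(x$mean) - 1L, tail(x$mean$collagen, 1)))
  invisible(x)
}
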