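# Per-type behavioural rules. Populations are stored column-wise (lists of
# parallel vectors) and all rules are vectorised over agents; the engine
# executes the returned events. Only hepatocytes, dead hepatocytes, septa,
# portal triads and collagen collide; Kupffer and fibrogenic agents co-occupy
# space freely.

# ---- population constructors -----------------------------------------------

new_hepatocytes <- function(x, y, lobule, lifespan, age = 0L, rep_count = 0L) {
  n <- length(x)
  list(x = as.numeric(x), y = as.numeric(y), lobule = as.integer(lobule),
       age = rep_len(as.integer(age), n),
       lifespan = rep_len(as.numeric(lifespan), n),
       rep_count = rep_len(as.integer(rep_count), n))
}

new_dead <- function(x, y, lobule, since = 0L) {
  n <- length(x)
  list(x = as.numeric(x), y = as.numeric(y), lobule = as.integer(lobule),
       since = rep_len(as.integer(since), n))
}

new_kupffer <- function(x, y, activated = FALSE, m = 0, phago = 0L,
                        age = 0L, lifespan = Inf) {
  n <- length(x)
  list(x = as.numeric(x), y = as.numeric(y),
       activated = rep_len(as.logical(activated), n),
       m = rep_len(as.numeric(m), n),
       phago = rep_len(as.integer(phago), n),
       age = rep_len(as.integer(age), n),
       lifespan = rep_len(as.numeric(lifespan), n))
}

# kind: 1 = HSC, 2 = portal fibroblast, 3 = myofibroblast
FIB_HSC <- 1L; FIB_PF <- 2L; FIB_MF <- 3L

new_fibrogenic <- function(x, y, kind) {
  list(x = as.numeric(x), y = as.numeric(y),
       kind = rep_len(as.integer(kind), length(x)))
}

new_collagen <- function(x, y, anchor_type = integer(0),
                         anchor_id = integer(0),
                         skel_dist = numeric(0)) {
  list(x = as.numeric(x), y = as.numeric(y),
       anchor_type = as.integer(anchor_type),
       anchor_id = as.integer(anchor_id),
       skel_dist = as.numeric(skel_dist))
}

pop_n <- function(pop) length(pop$x)

pop_subset <- function(pop, keep) lapply(pop, function(v) v[keep])

pop_bind <- function(a, b) {
  if (pop_n(a) == 0L) return(b)
  if (pop_n(b) == 0L) return(a)
  mapply(c, a, b, SIMPLIFY = FALSE)
}

# ---- initial census arithmetic ---------------------------------------------

#' Initial population counts from the hepatocyte census
#'
#' Hepatocytes are taken to be ~60% of all liver cells, Kupffer cells 15%
#' and hepatic stellate cells 5%, so the initial counts are
#' `n_kupffer = round(n_hepatocytes * 15/60)` and
#' `n_hsc = round(n_hepatocytes * 5/60)`.
#'
#' @param n_hepatocytes emergent hepatocyte count (>= 0).
#' @return list with `n_kupffer` and `n_hsc`.
#' @examples
#' initialize_populations(3857) # 964 Kupffer cells, 321 HSCs
#' @export
initialize_populations <- function(n_hepatocytes) {
  if (!is.numeric(n_hepatocytes) || n_hepatocytes < 0) {
    stop("n_hepatocytes must be >= 0", call. = FALSE)
  }
  list(n_kupffer = round(n_hepatocytes * 15 / 60),
       n_hsc = round(n_hepatocytes * 5 / 60))
}

# ---- hepatocyte rule -------------------------------------------------------

#' Hepatocyte step rule (vectorised)
#'
#' For each hepatocyte, decide one event per step: `"die"` if local
#' TNF-alpha is above threshold (with probability `death_prob`, the lumped
#' bystander effect) or if `age > lifespan`; otherwise `"replicate"` (an
#' attempt to fill an empty neighbouring site, granted with probability
#' `replication_prob`) if empty space is detected and replication is not
#' senescence-capped (a hepatocyte adjacent to collagen cannot replicate
#' more than twice); otherwise `"none"`.
#'
#' @param cells hepatocyte population (needs `age`, `lifespan`,
#'   `rep_count`); a single agent is a one-row population.
#' @param tnf_above logical per cell: local TNF-alpha at/above threshold.
#' @param empty_neighbor logical per cell: empty neighbouring space exists.
#' @param collagen_adjacent logical per cell: collagen within the contact
#'   neighbourhood.
#' @param death_prob per-step bystander death probability while TNF-alpha
#'   is above threshold.
#' @param replication_prob per-step probability that a replication-capable
#'   cell attempts to replicate.
#' @param max_rep replication cap near collagen (default 2).
#' @return character vector of events: `"none"`, `"replicate"` or `"die"`.
#' @export
hepatocyte_step <- function(cells, tnf_above, empty_neighbor,
                            collagen_adjacent, death_prob,
                            replication_prob = 1, max_rep = 2L) {
  n <- pop_n(cells)
  ev <- rep("none", n)
  if (n == 0L) return(ev)
  die <- (tnf_above & runif(n) < death_prob) | cells$age > cells$lifespan
  can_rep <- !die & empty_neighbor &
    (!collagen_adjacent | cells$rep_count < max_rep) &
    runif(n) < replication_prob
  ev[can_rep] <- "replicate"
  ev[die] <- "die"
  ev
}

# ---- Kupffer cell rule -----------------------------------------------------

#' Kupffer polarization update after phagocytosis events
#'
#' The phenotype weight `m` (0 = pure M1, 1 = pure M2) increases by a fixed
#' increment per phagocytosis event, capped at 1.
#'
#' @param m current phenotype weights in \[0, 1\].
#' @param k number of phagocytosis events applied.
#' @param increment per-event polarization increment.
#' @return updated `m`.
#' @export
polarization_update <- function(m, k, increment) {
  pmin(1, m + k * increment)
}

#' Cytokine secretion of activated Kupffer cells
#'
#' Activated cells secrete per step a TNF-alpha amount proportional to
#' `1 - m` (M1 component) and a TGF-beta1 amount proportional to `m`
#' (M2 component); quiescent cells secrete nothing.
#'
#' @param m phenotype weights.
#' @param activated logical per cell.
#' @param tnf_amount,tgf_amount full-strength per-step secretion amounts
#'   (may be vectors, e.g. sampled per event from a configured range).
#' @return list with numeric vectors `tnf` and `tgf`.
#' @export
kupffer_secretion <- function(m, activated, tnf_amount, tgf_amount) {
  act <- as.numeric(activated)
  list(tnf = act * tnf_amount * (1 - m),
       tgf = act * tgf_amount * m)
}

#' Kupffer cell step rule (population level)
#'
#' Each Kupffer cell that has an uncleared dead agent within the contact
#' neighbourhood phagocytizes the nearest one (each dead agent is cleared at
#' most once; cells are processed in random order), becomes activated,
#' increments its phagocytosis count and shifts its phenotype weight by the
#' polarization increment. All activated cells then secrete TNF-alpha and
#' TGF-beta1 amounts mixed by their phenotype weight.
#'
#' @param kcs Kupffer population.
#' @param dead dead-hepatocyte population.
#' @param radius contact neighbourhood radius.
#' @param phago_prob per-step probability that a Kupffer cell with an
#'   adjacent dead agent actually phagocytizes it this step (engulfment
#'   takes time, so clearance of a necrotic burst is gradual and can be
#'   inadequate, letting HMGB1 accumulate).
#' @param increment polarization increment per phagocytosis event.
#' @param tnf_range,tgf_range numeric `c(min, max)` full-strength secretion
#'   amounts, sampled per cell and step.
#' @param active_lifespan numeric `c(min, max)` lifespan (in steps) sampled
#'   when a resident cell becomes activated.
#' @return list with the updated population (`kcs`), the indices of cleared
#'   dead agents (`phagocytized`), and per-cell secretion (`tnf`, `tgf`).
#' @export
kupffer_step <- function(kcs, dead, radius, increment,
                         tnf_range, tgf_range, active_lifespan,
                         phago_prob = 1) {
  n <- pop_n(kcs)
  if (n == 0L) {
    return(list(kcs = kcs, phagocytized = integer(0),
                tnf = numeric(0), tgf = numeric(0)))
  }
  match_idx <- integer(n)
  if (pop_n(dead) > 0L) {
    trying <- runif(n) < phago_prob
    if (any(trying)) {
      ord <- which(trying)[sample.int(sum(trying))]
      match_idx <- cpp_match_phago(cbind(kcs$x, kcs$y), ord,
                                   cbind(dead$x, dead$y), radius)
    }
  }
  ate <- match_idx > 0L
  if (anyDuplicated(match_idx[ate])) {
    stop("internal consistency error: dead agent phagocytized twice",
         call. = FALSE)
  }
  newly <- ate & !kcs$activated
  kcs$activated <- kcs$activated | ate
  kcs$phago <- kcs$phago + as.integer(ate)
  kcs$m[ate] <- polarization_update(kcs$m[ate], 1L, increment)
  if (any(newly)) {
    kcs$lifespan[newly] <- kcs$age[newly] +
      runif(sum(newly), active_lifespan[1], active_lifespan[2])
  }
  sec <- kupffer_secretion(kcs$m, kcs$activated,
                           runif(n, tnf_range[1], tnf_range[2]),
                           runif(n, tgf_range[1], tgf_range[2]))
  list(kcs = kcs, phagocytized = match_idx[ate],
       tnf = sec$tnf, tgf = sec$tgf)
}

# ---- monocyte recruitment --------------------------------------------------

#' Recruit monocytes as activated Kupffer cells at HMGB1 hot spots
#'
#' Every grid location with HMGB1 at/above threshold spawns, with the
#' configured per-step probability, one activated Kupffer cell (entering at
#' phenotype weight m = 0) at that location. Spawns falling outside the
#' lobule patch are discarded, as are spawns into grid cells already
#' holding `crowding_cap` or more Kupffer cells (extravasation into
#' macrophage-saturated tissue stalls, which bounds the inflammatory
#' infiltrate).
#'
#' @param field the HMGB1 [cytokine_field()].
#' @param lattice the [build_lattice()] skeleton (patch membership).
#' @param prob per-site per-step recruitment probability.
#' @param active_lifespan numeric `c(min, max)` lifespan range of recruits.
#' @param kcs current Kupffer population (for the crowding test); `NULL`
#'   disables crowding.
#' @param crowding_cap max Kupffer cells per grid cell for new entry.
#' @return a Kupffer population of recruits (possibly empty).
#' @export
recruit_monocytes <- function(field, lattice, prob, active_lifespan,
                              kcs = NULL, crowding_cap = Inf) {
  hot <- cells_above_threshold(field)
  if (nrow(hot) == 0L || prob <= 0) return(new_kupffer(numeric(0), numeric(0)))
  inside <- !is.na(patch_member(hot[, 1], hot[, 2], lattice))
  hot <- hot[inside, , drop = FALSE]
  if (!is.null(kcs) && pop_n(kcs) > 0L && is.finite(crowding_cap) &&
      nrow(hot) > 0L) {
    ij <- field_cell(field, kcs$x, kcs$y, clamp = TRUE)
    occ <- matrix(tabulate((ij[, 2] - 1L) * field$nx + ij[, 1],
                           nbins = field$nx * field$ny), field$nx, field$ny)
    hij <- field_cell(field, hot[, 1], hot[, 2], clamp = TRUE)
    hot <- hot[occ[hij] < crowding_cap, , drop = FALSE]
  }
  if (nrow(hot) == 0L) return(new_kupffer(numeric(0), numeric(0)))
  spawn <- runif(nrow(hot)) < prob
  hot <- hot[spawn, , drop = FALSE]
  new_kupffer(hot[, 1], hot[, 2], activated = TRUE, m = 0, phago = 0L,
              age = 0L,
              lifespan = if (nrow(hot)) runif(nrow(hot), active_lifespan[1],
                                              active_lifespan[2]) else numeric(0))
}

# ---- fibrogenic rule -------------------------------------------------------

#' Fibrogenic cell step rule (vectorised decisions)
#'
#' HSCs and portal fibroblasts transform irreversibly into myofibroblasts
#' when they detect above-threshold TNF-alpha (optionally also HMGB1, both
#' being potent fibrogenic stimulants; controlled by `hmgb1_activates`).
#' Myofibroblasts detecting above-threshold TGF-beta1 proliferate and/or
#' attempt one collagen deposition, each with its configured probability.
#'
#' @param fib fibrogenic population (`kind`: 1 HSC, 2 portal fibroblast,
#'   3 myofibroblast).
#' @param tnf_above,hmgb1_above,tgf_above logical per cell.
#' @param transform_prob per-step transformation probability when
#'   stimulated.
#' @param deposit_prob,proliferate_prob per-step probabilities for
#'   stimulated myofibroblasts.
#' @param hmgb1_activates should HMGB1 alone stimulate transformation?
#' @return list of logical vectors `transform`, `deposit`, `proliferate`.
#' @export
fibrogenic_step <- function(fib, tnf_above, hmgb1_above, tgf_above,
                            transform_prob, deposit_prob, proliferate_prob,
                            hmgb1_activates = FALSE) {
  n <- pop_n(fib)
  if (n == 0L) {
    z <- logical(0)
    return(list(transform = z, deposit = z, proliferate = z))
  }
  stim <- tnf_above | (hmgb1_activates & hmgb1_above)
  precursor <- fib$kind != FIB_MF
  transform <- precursor & stim & runif(n) < transform_prob
  mf <- fib$kind == FIB_MF
  deposit <- mf & tgf_above & runif(n) < deposit_prob
  proliferate <- mf & tgf_above & runif(n) < proliferate_prob
  list(transform = transform, deposit = deposit, proliferate = proliferate)
}
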