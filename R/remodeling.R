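# Template-guided remodeling at the leading edge (LE) in 3D. The kinetic
# layer maps the LE onto M angular columns x glycan-ring rows along the
# meridian of the old-wall surface; insertion-degradation complexes (IDCs)
# follow the same stochastic rules as the 2D lattice model: the LE height
# per column is the contiguous germ-wall front, IDCs move processively
# around the circumference inserting at the local front site, old-wall
# template gaps (density f0) are crossed with probability ppro, failed
# attempts mark the column with an exposed-end defect repaired with
# probability prep, and idle IDCs bind a uniformly random LE column and
# initiate from the glycan end there with probability prep. Each filled
# site is realized as a mesh bead on the old-wall surface, glycan-bonded to
# its strand, peptide-bonded to the ring below, and tethered to the rigid
# old wall by a junction bond; junctions behind the IDC are severed in the
# same event (coupled mode) or after an exponential tau_delay (decoupled).
# Between event rounds the mesh relaxes by Langevin dynamics (quasi-static).

#' Initialize an engulfment simulation state
#'
#' Builds the septal disc, the old-wall surface and the kinetic
#' leading-edge state (angular columns, founding template holes, idle
#' IDCs).
#'
#' @param cfg a [simulation_config()].
#' @param rcfg a [remodeling_config()].
#' @param geom a [forespore_geometry()].
#' @return An object of class `engulf_sim_state`.
#' @export
init_engulfment <- function(cfg, rcfg, geom) {
  set.seed(cfg$seed)
  mesh <- build_septal_disc(geom, cfg)
  wall <- build_lateral_wall(geom, cfg)
  K <- length(mesh$strands)
  disc_le <- mesh$strands[[K]]$bead_ids
  M <- length(disc_le)
  n_rings_max <- max(1L, floor((meridian_length(geom) - 0.35 * cfg$ring_sep) /
                                 cfg$ring_sep))
  nidc <- rcfg$NIDC
  state <- structure(list(
    mesh = mesh, cfg = cfg, rcfg = rcfg, geom = geom, wall = wall,
    disc_le = disc_le, M = M, K = K, n_rings_max = n_rings_max,
    h = integer(M),                    # contiguous LE ring index per column
    marked = runif(M) < rcfg$f0,       # exposed-end defects (septal rim)
    gap = logical(M),                  # template gap at the front site
    bead_at = matrix(0L, 4L, M),
    idcs = data.frame(col = integer(nidc), dir = rep(1L, nidc),
                      mode = rep("idle", nidc), last_bead = integer(nidc),
                      last_ring = integer(nidc),
                      length_inserted_total = numeric(nidc),
                      stringsAsFactors = FALSE),
    jun_of = integer(mesh$n), vpep_of = integer(mesh$n),
    sever_sites = matrix(NA_real_, 0, 3),
    n_sever = 0L, n_bad_cuts = 0L, n_cut_events = 0L,
    elapsed = 0, events = 0L), class = "engulf_sim_state")
  state$gap[!state$marked] <- runif(sum(!state$marked)) < rcfg$f0
  state$jun_of[disc_le] <- seq_len(M)   # disc LE junction tethers, in order
  state
}

#' @export
print.engulf_sim_state <- function(x, ...) {
  cat(sprintf("<engulf_sim_state> M = %d columns, rings %s/%d, %d events, t = %.3g s\n",
              x$M, if (length(x$h)) max(x$h) else 0, x$n_rings_max,
              x$events, x$elapsed))
  invisible(x)
}

#' Locate the leading edge
#'
#' Returns the closed, angularly ordered ring of junction beads where the
#' newest germ-cell-wall strand is cross-linked to the old-wall template:
#' the topmost bead of every angular column (falling back to the septal rim
#' where no ring has been inserted yet). Ordering follows a fixed
#' handedness about the long axis.
#'
#' @param x an `engulf_sim_state` or an `engulf_mesh`.
#' @return integer vector of bead ids.
#' @export
locate_leading_edge <- function(x) {
  if (inherits(x, "engulf_sim_state")) {
    le <- integer(x$M)
    for (j in seq_len(x$M))
      le[j] <- if (x$h[j] >= 1L) x$bead_at[x$h[j], j] else x$disc_le[j]
    return(le)
  }
  le <- x$leading_edge
  if (!length(le)) stop("topology error: mesh has no leading edge")
  p <- mesh_pos(x)[le, , drop = FALSE]
  le[order(atan2(p[, 2], p[, 1]))]
}

ring_surface_point <- function(state, r, j) {
  theta <- 2 * pi * (j - 1) / state$M
  surface_point(state$geom, r * state$cfg$ring_sep, theta)
}

state_grow_rings <- function(state, r) {
  while (r > nrow(state$bead_at)) {
    state$bead_at <- rbind(state$bead_at,
                           matrix(0L, nrow(state$bead_at), state$M))
  }
  state
}

# sever the junction tether guarding column j of ring r-1 (or the septal
# rim for r = 1): immediately in coupled mode, after an exponential delay
# otherwise. Erroneous vertical cuts (ppcut) happen at execution time.
schedule_junction_cut <- function(state, r, j) {
  below <- if (r == 1L) state$disc_le[j] else state$bead_at[r - 1L, j]
  if (below == 0L) return(state)
  ji <- if (below <= length(state$jun_of)) state$jun_of[below] else 0L
  if (is.na(ji) || ji == 0L) return(state)
  if (state$mesh$jun[ji, "intact"] == 0) return(state)
  if (state$rcfg$coupled) {
    state <- execute_junction_cut(state, ji)
  } else {
    tcut <- state$elapsed +
      if (state$rcfg$tau_delay > 0) rexp(1, 1 / state$rcfg$tau_delay) else 0
    state$mesh$jun[ji, "sever_t"] <- min(state$mesh$jun[ji, "sever_t"], tcut)
  }
  state
}

execute_junction_cut <- function(state, ji) {
  state$n_cut_events <- state$n_cut_events + 1L
  bead <- state$mesh$jun[ji, "bead"]
  if (!state$rcfg$coupled && state$rcfg$ppcut > 0 &&
      runif(1) < state$rcfg$ppcut) {
    # erroneous cut: a vertical peptide bond is severed instead
    state$n_bad_cuts <- state$n_bad_cuts + 1L
    vi <- if (bead <= length(state$vpep_of)) state$vpep_of[bead] else 0L
    if (!is.na(vi) && vi > 0L && state$mesh$pep[vi, "intact"] > 0)
      state$mesh$pep[vi, "intact"] <- 0
    state$mesh$jun[ji, "sever_t"] <- Inf
    return(state)
  }
  state$mesh$jun[ji, "intact"] <- 0
  state$mesh$jun[ji, "sever_t"] <- Inf
  state$n_sever <- state$n_sever + 1L
  state$sever_sites <- rbind(state$sever_sites,
                             state$mesh$jun[ji, c("ax", "ay", "az")])
  state
}

#' Execute pending delayed junction degradation
#'
#' In decoupled mode (`coupled = FALSE`), junction bonds are severed at an
#' exponential waiting time with mean `tau_delay` after the strand segment
#' bridging their span was synthesized; with probability `ppcut` a cut
#' erroneously severs the vertical peptide bond of the same bead instead.
#' This processes every cut that has come due by the state clock. With
#' `tau_delay = 0` the behavior is identical to coupled mode.
#'
#' @param state an `engulf_sim_state`.
#' @param rcfg the [remodeling_config()] (defaults to the state's own).
#' @param clock time up to which cuts are executed, s (default: state time).
#' @return the updated state.
#' @export
delayed_degradation_step <- function(state, rcfg = state$rcfg,
                                     clock = state$elapsed) {
  if (rcfg$coupled) return(state)
  jn <- mesh_jun(state$mesh)
  due <- which(jn[, "intact"] > 0 & jn[, "sever_t"] <= clock)
  for (ji in due) state <- execute_junction_cut(state, ji)
  state
}

# realize the front site of column j (ring h_j + 1) as a mesh bead with
# bonds; a new strand is opened unless IDC k extended its strand into an
# adjacent column of the same ring in its previous fill
state_fill <- function(state, k, j) {
  r <- state$h[j] + 1L
  state <- state_grow_rings(state, r)
  cfg <- state$cfg
  xyz <- ring_surface_point(state, r, j)
  prev <- state$idcs$last_bead[k]
  new_strand <- !(prev > 0L && state$idcs$last_ring[k] == r &&
                    (lat_wrap(state$idcs$col[k] + state$idcs$dir[k], state$M) == j))
  strand <- if (new_strand) {
    id <- length(state$mesh$strands) + 1L
    state$mesh$strands[[id]] <- list(id = id, bead_ids = integer(0),
                                     closed = FALSE,
                                     row_index = state$K + r)
    id
  } else {
    state$mesh$strand_id[prev]
  }
  idx <- length(state$mesh$strands[[strand]]$bead_ids) + 1L
  state$mesh <- mesh_add_beads(state$mesh, xyz, strand, idx)
  id <- attr(state$mesh, "new_ids")
  state$mesh$strands[[strand]]$bead_ids <-
    c(state$mesh$strands[[strand]]$bead_ids, id)
  p <- state$mesh$pos
  if (!new_strand && prev > 0L) {
    state$mesh <- mesh_add_gly(state$mesh, prev, id,
                               sqrt(sum((p[prev, ] - p[id, ])^2)))
    ids <- state$mesh$strands[[strand]]$bead_ids
    ni <- length(ids)
    if (ni >= 3L)
      state$mesh <- mesh_add_bend(state$mesh, ids[ni - 2L], ids[ni - 1L],
                                  ids[ni], phi0 = pi - 2 * pi / state$M)
  }
  below <- if (r == 1L) state$disc_le[j] else state$bead_at[r - 1L, j]
  if (below > 0L) {
    state$mesh <- mesh_add_pep(state$mesh, id, below,
                               sqrt(sum((p[below, ] - p[id, ])^2)),
                               horizontal = FALSE)
    state$vpep_of[id] <- state$mesh$n_pep
  }
  # junction tether of the new segment to the old-wall template
  state$mesh <- mesh_add_jun(state$mesh, id, xyz, rest = 0,
                             birth = state$elapsed)
  state$jun_of[id] <- state$mesh$n_jun
  # local triangulation (quad with the side neighbour and the ring below)
  side <- state$bead_at[r, lat_wrap(j - state$idcs$dir[k], state$M)]
  below_side <- if (r == 1L) state$disc_le[lat_wrap(j - state$idcs$dir[k], state$M)]
                else state$bead_at[r - 1L, lat_wrap(j - state$idcs$dir[k], state$M)]
  c0 <- forespore_center(state$geom)
  if (side > 0L && below > 0L)
    state$mesh <- mesh_add_tri(state$mesh, c(id, side, below), c0)
  if (side > 0L && below_side > 0L && below > 0L)
    state$mesh <- mesh_add_tri(state$mesh, c(side, below_side, below), c0)
  # degradation behind the insertion (make-before-break: the replacement
  # segment now exists)
  state <- schedule_junction_cut(state, r, j)
  state$bead_at[r, j] <- id
  state$h[j] <- r
  state$marked[j] <- FALSE
  state$gap[j] <- runif(1) < state$rcfg$f0
  state$idcs$last_bead[k] <- id
  state$idcs$last_ring[k] <- r
  state$idcs$col[k] <- j
  state$idcs$length_inserted_total[k] <-
    state$idcs$length_inserted_total[k] + cfg$l0 * cfg$n_bundle
  state$events <- state$events + 1L
  state
}

#' One insertion event of a single IDC
#'
#' Applies the stochastic insertion rules for complex `k`. A polymerizing
#' IDC moves one column in its direction and appends one bead-segment
#' (length `l0`) at the local leading-edge front site there, cross-linked
#' (relaxed) to the germ-cell-wall ring below and tethered to the old-wall
#' template; the junction bond behind it is severed in the same event
#' (coupled mode) or scheduled for delayed cutting. Old-wall template gaps
#' are crossed with probability `ppro`, and defect-marked columns need
#' repair with probability `prep`; a failed attempt terminates the strand,
#' leaving an exposed-end defect, and the IDC goes idle (not an error). An
#' idle IDC binds a uniformly random column of the leading-edge ring and
#' initiates polymerization from the glycan end there with probability
#' `prep`.
#'
#' @param state an `engulf_sim_state` from [init_engulfment()].
#' @param k IDC index.
#' @param rcfg the [remodeling_config()] (defaults to the state's own).
#' @return the updated state.
#' @export
idc_insertion_event <- function(state, k, rcfg = state$rcfg) {
  if (min(state$h) >= state$n_rings_max) return(state)
  trial <- function(j) {
    q <- 1
    if (state$gap[j]) q <- q * rcfg$ppro
    if (state$marked[j]) q <- q * rcfg$prep
    q >= 1 || runif(1) < q
  }
  if (state$idcs$mode[k] == "polymerizing") {
    j <- lat_wrap(state$idcs$col[k] + state$idcs$dir[k], state$M)
    if (state$h[j] >= state$n_rings_max) {  # column at the pole: skim past
      state$idcs$col[k] <- j
      state$idcs$last_bead[k] <- 0L
    } else if (trial(j)) {
      state <- state_fill(state, k, j)
    } else {
      state$marked[j] <- TRUE
      state$idcs$mode[k] <- "idle"
    }
  } else {
    j0 <- sample.int(state$M, 1L)
    if (runif(1) < rcfg$prep && state$h[j0] < state$n_rings_max) {
      if (trial(j0)) {
        state$idcs$dir[k] <- if (runif(1) < 0.5) 1L else -1L
        state$idcs$mode[k] <- "polymerizing"
        state$idcs$last_bead[k] <- 0L
        state$idcs$col[k] <- j0
        state <- state_fill(state, k, j0)
      } else {
        state$marked[j0] <- TRUE
      }
    }
  }
  state
}

# meridian profile of the whole sac in nm: axis -> septal rings -> inserted
# rings -> remaining old wall -> pole
state_profile <- function(state) {
  mesh <- state$mesh
  p <- mesh_pos(mesh)
  prof <- matrix(NA_real_, 0, 2)
  for (k in seq_len(state$K)) {
    ids <- mesh$strands[[k]]$bead_ids
    prof <- rbind(prof, c(mean(sqrt(p[ids, 1]^2 + p[ids, 2]^2)),
                          mean(p[ids, 3])))
  }
  prof <- rbind(c(0, prof[1, 2]), prof)
  rmax <- max(state$h)
  if (rmax >= 1L) {
    for (r in seq_len(rmax)) {
      ids <- state$bead_at[r, ]
      ids <- ids[ids > 0L]
      if (length(ids))
        prof <- rbind(prof, c(mean(sqrt(p[ids, 1]^2 + p[ids, 2]^2)),
                              mean(p[ids, 3])))
    }
  }
  # close over the not-yet-engulfed old wall up to the pole
  smax <- meridian_length(state$geom)
  s_le <- min(rmax * state$cfg$ring_sep, smax)
  s_rest <- if (s_le + state$cfg$ring_sep <= smax)
    seq(s_le + state$cfg$ring_sep, smax, by = state$cfg$ring_sep) else numeric(0)
  s_rest <- unique(c(s_rest, smax))
  s_rest <- s_rest[s_rest > s_le + 1e-9]
  if (length(s_rest)) {
    sp <- surface_point(state$geom, s_rest, 0)
    prof <- rbind(prof, cbind(sp[, 1], sp[, 3]))
  }
  prof
}

state_measurements <- function(state) {
  vs <- volume_surface_by_revolution(state_profile(state), check = FALSE)
  mesh <- state$mesh
  mesh$leading_edge <- locate_leading_edge(state)
  E <- percent_engulfment(mesh)
  c(V = unname(vs["V"]) / 1e9, S = unname(vs["S"]) / 1e6, E = E)
}

#' Run an engulfment simulation
#'
#' Interleaves remodeling events with Langevin relaxation: every
#' `l0 / VIDC` seconds each IDC performs one insertion event (shuffled
#' order), pending delayed degradation is executed, and the mesh relaxes by
#' `n_relax` Euler-Maruyama steps. The trace of volume (um^3), surface area
#' (um^2) and percent engulfment is recorded every `record_every` rounds.
#' Fully reproducible under the configuration seed.
#'
#' @param cfg a [simulation_config()].
#' @param rcfg a [remodeling_config()].
#' @param geom a [forespore_geometry()].
#' @param stop list with any of `E` (stop once percent engulfment reaches
#'   this), `max_time` (s), `max_rounds`.
#' @param n_relax Langevin steps per event round.
#' @param record_every record the trace every this many rounds.
#' @return An object of class `engulf_run`: `mesh`, `trace`
#'   ([engulfment_trace()] with an `id_sep` column in decoupled mode),
#'   `idcs`, `h` (final column heights, rings), `spread_nm` (leading-edge
#'   height spread), `elapsed` (s), `events`, `stopped_by`.
#' @export
run_engulfment <- function(cfg, rcfg, geom,
                           stop = list(E = 95, max_time = Inf,
                                       max_rounds = 200000),
                           n_relax = 10L, record_every = 5L) {
  state <- init_engulfment(cfg, rcfg, geom)
  round_dt <- cfg$l0 / rcfg$VIDC
  stop_E <- if (is.null(stop$E)) 95 else stop$E
  max_time <- if (is.null(stop$max_time)) Inf else stop$max_time
  max_rounds <- if (is.null(stop$max_rounds)) 200000 else stop$max_rounds
  rec <- list()
  m0 <- state_measurements(state)
  rec[[1]] <- c(time = 0, m0, id_sep = NA_real_, spread = 0)
  stopped_by <- "max_rounds"
  rounds <- 0L
  stall_rounds <- 0L
  repeat {
    if (rounds >= max_rounds) break
    if (state$elapsed >= max_time) { stopped_by <- "max_time"; break }
    ev0 <- state$events
    if (rcfg$NIDC > 0) {
      for (k in sample.int(rcfg$NIDC)) {
        state <- idc_insertion_event(state, k)
      }
    }
    state$elapsed <- state$elapsed + round_dt
    if (!rcfg$coupled) state <- delayed_degradation_step(state)
    state$mesh <- relax_mesh(state$mesh, cfg, state$wall, nsteps = n_relax)
    rounds <- rounds + 1L
    stall_rounds <- if (state$events == ev0) stall_rounds + 1L else 0L
    if (rounds %% record_every == 0L || state$events == ev0) {
      m <- state_measurements(state)
      sep <- if (!rcfg$coupled) id_sep_now(state) else NA_real_
      rec[[length(rec) + 1]] <- c(time = state$elapsed, m, id_sep = sep,
                                  spread = max(state$h) - min(state$h))
      if (m[["E"]] >= stop_E) { stopped_by <- "engulfment"; break }
      if (min(state$h) >= state$n_rings_max) { stopped_by <- "pole"; break }
      if (rcfg$NIDC == 0 && rounds >= 20L) { stopped_by <- "no_idcs"; break }
      if (stall_rounds >= 2000L) { stopped_by <- "stall"; break }
    }
  }
  tab <- do.call(rbind, rec)
  tr <- engulfment_trace(tab[, "time"], tab[, "V"], tab[, "S"], tab[, "E"])
  tr$id_sep <- tab[, "id_sep"]
  state$mesh$leading_edge <- locate_leading_edge(state)
  state$mesh$time <- state$elapsed
  structure(list(mesh = state$mesh, trace = tr, idcs = state$idcs,
                 h = state$h,
                 # LE angular height spread: maximum over the trajectory
                 spread_nm = max(tab[, "spread"]) * cfg$ring_sep,
                 M = state$M, n_rings_max = state$n_rings_max,
                 cfg = cfg, rcfg = rcfg, geom = geom,
                 elapsed = state$elapsed, events = state$events,
                 n_cut_events = state$n_cut_events,
                 n_bad_cuts = state$n_bad_cuts,
                 stopped_by = stopped_by), class = "engulf_run")
}

# mean distance from polymerizing IDC tips to the most recently severed
# junction sites (the degradation front)
id_sep_now <- function(state, n_recent = 3L * max(state$rcfg$NIDC, 1L)) {
  if (state$n_sever == 0L) return(NA_real_)
  sites <- tail(state$sever_sites, n_recent)
  tips <- state$idcs$last_bead[state$idcs$mode == "polymerizing"]
  tips <- tips[tips > 0L]
  if (!length(tips)) tips <- state$idcs$last_bead[state$idcs$last_bead > 0L]
  if (!length(tips)) return(NA_real_)
  p <- state$mesh$pos
  mean(vapply(tips, function(b)
    min(sqrt(rowSums(sweep(sites, 2, p[b, ])^2))), numeric(1)))
}

#' @export
print.engulf_run <- function(x, ...) {
  cat(sprintf("<engulf_run> %d events over %.3g s (%.3g hr), stopped by %s\n",
              x$events, x$elapsed, x$elapsed / 3600, x$stopped_by))
  n <- nrow(x$trace)
  cat(sprintf("  final: V %.3g um^3, S %.3g um^2, E %.1f%%, LE spread %.3g nm\n",
              x$trace$V[n], x$trace$S[n], x$trace$E[n], x$spread_nm))
  invisible(x)
}

#' Random peptide degradation with synthesis stopped
#'
#' Severs every intact peptide bond (cross-links and junction tethers)
#' independently as a Poisson process at rate `prpep` (min^-1), relaxing
#' the mesh between exposure intervals and recording the forespore volume
#' trace.
#'
#' @param run an `engulf_run` (synthesis is halted; its mesh is degraded).
#' @param rcfg a [remodeling_config()] supplying `prpep`.
#' @param duration degradation time, s.
#' @param n_chunks number of exposure intervals.
#' @param n_relax Langevin steps per interval.
#' @return list with the degraded `mesh` and a `trace` data.frame
#'   (time s, V um^3, intact bond count).
#' @export
random_peptide_degradation <- function(run, rcfg, duration, n_chunks = 20L,
                                       n_relax = 50L) {
  mesh <- run$mesh
  cfg <- run$cfg
  wall <- build_lateral_wall(run$geom, cfg)
  rate_s <- rcfg$prpep / 60
  dt_chunk <- duration / n_chunks
  p_cut <- 1 - exp(-rate_s * dt_chunk)
  vol <- function(m) {
    prof <- mesh_profile(m)
    prof <- rbind(c(0, prof[1, 2]), prof, c(0, prof[nrow(prof), 2]))
    unname(volume_surface_by_revolution(prof, check = FALSE)["V"]) / 1e9
  }
  count_intact <- function(m)
    sum(mesh_pep(m)[, "intact"] > 0) +
    (if (m$n_jun) sum(mesh_jun(m)[, "intact"] > 0) else 0L)
  out <- data.frame(time = 0, V = vol(mesh), intact = count_intact(mesh))
  for (i in seq_len(n_chunks)) {
    if (p_cut > 0) {
      pp <- mesh_pep(mesh)
      alive <- which(pp[, "intact"] > 0)
      cut <- alive[runif(length(alive)) < p_cut]
      if (length(cut)) mesh$pep[cut, "intact"] <- 0
      jn <- mesh_jun(mesh)
      alive <- which(jn[, "intact"] > 0)
      cut <- alive[runif(length(alive)) < p_cut]
      if (length(cut)) mesh$jun[cut, "intact"] <- 0
    }
    mesh <- relax_mesh(mesh, cfg, wall, nsteps = n_relax)
    out <- rbind(out, data.frame(time = i * dt_chunk, V = vol(mesh),
                                 intact = count_intact(mesh)))
  }
  list(mesh = mesh, trace = out)
}
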