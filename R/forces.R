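# The six force terms of the overdamped Langevin equation
#   zeta dr_i/dt = F_spr + F_bend + F_pep + F_stoch + F_dp + F_wall
# Each term returns an n x 3 matrix of forces in pN. The conservative terms
# are exact negative gradients of the energies summed by total_energy().

#' Glycan spring forces
#'
#' Hookean force along every intra-strand glycan bond (stiffness `kgly`,
#' per-bond rest length). Forces are equal and opposite on the two beads of
#' each bond.
#'
#' @param mesh an `engulf_mesh`.
#' @param cfg a [simulation_config()].
#' @return n x 3 force matrix, pN.
#' @export
glycan_spring_force <- function(mesh, cfg) {
  gl <- mesh_gly(mesh)
  check_coincident(mesh, gl[, "a"], gl[, "b"])
  bonds_force_cpp(mesh_pos(mesh), as.integer(gl[, "a"]), as.integer(gl[, "b"]),
                  gl[, "rest"], rep(cfg$kgly, nrow(gl)))
}

#' Glycan bending forces
#'
#' Discrete worm-like-chain bending at every interior bead triple, with
#' bending modulus `lp * kBT / l0` and the spontaneous angle recorded per
#' triple (closed hoops are built with their natural polygon angle; straight
#' arcs with angle pi).
#'
#' @inheritParams glycan_spring_force
#' @return n x 3 force matrix, pN.
#' @export
glycan_bending_force <- function(mesh, cfg) {
  bd <- mesh_bend(mesh)
  if (!nrow(bd)) return(matrix(0, mesh$n, 3))
  bend_force_cpp(mesh_pos(mesh), matrix(as.integer(bd[, 1:3]), ncol = 3),
                 bd[, 4], bending_modulus(cfg))
}

#' Peptide cross-link forces
#'
#' Hookean force on every intact peptide bond (stiffness `kpep`) and on
#' every intact junction tether to the old-wall template. Severed bonds
#' contribute nothing.
#'
#' @inheritParams glycan_spring_force
#' @return n x 3 force matrix, pN.
#' @export
peptide_force <- function(mesh, cfg) {
  p <- mesh_pos(mesh)
  F <- matrix(0, mesh$n, 3)
  pp <- mesh_pep(mesh)
  pp <- pp[pp[, "intact"] > 0, , drop = FALSE]
  if (nrow(pp)) {
    check_coincident(mesh, pp[, "a"], pp[, "b"])
    F <- F + bonds_force_cpp(p, as.integer(pp[, "a"]), as.integer(pp[, "b"]),
                             pp[, "rest"], rep(cfg$kpep, nrow(pp)))
  }
  jn <- mesh_jun(mesh)
  jn <- jn[jn[, "intact"] > 0, , drop = FALSE]
  if (nrow(jn))
    F <- F + anchor_force_cpp(p, as.integer(jn[, "bead"]),
                              jn[, c("ax", "ay", "az"), drop = FALSE],
                              jn[, "rest"], cfg$kpep)
  F
}

#' Turgor pressure forces
#'
#' Distributes the pressure difference `delta_p` over the mesh surface: each
#' oriented triangle of the local surface triangulation contributes
#' `delta_p` times one third of its area vector to each of its vertices, so
#' every bead feels an outward normal force proportional to its assigned
#' surface area. Over any closed triangulated surface these forces sum to
#' the zero vector.
#'
#' @inheritParams glycan_spring_force
#' @return n x 3 force matrix, pN.
#' @export
pressure_force <- function(mesh, cfg) {
  tr <- mesh_tri(mesh)
  if (!nrow(tr)) return(matrix(0, mesh$n, 3))
  pressure_force_cpp(mesh_pos(mesh), matrix(as.integer(tr), ncol = 3),
                     cfg$delta_p)
}

#' Old-wall exclusion forces
#'
#' Zero inside the allowed region; harmonic repulsion `k_wall * penetration`
#' along the inward normal for beads that have crossed the old-wall surface.
#'
#' @inheritParams glycan_spring_force
#' @param wall a [build_lateral_wall()] surface.
#' @return n x 3 force matrix, pN.
#' @export
wall_exclusion_force <- function(mesh, wall, cfg = NULL) {
  wall_force_cpp(mesh_pos(mesh), wall$R, wall$cap_z, wall$k_wall)
}

#' Stochastic thermal forces
#'
#' I.i.d. Gaussian force per bead and component with mean 0 and variance
#' `2 kBT zeta / dt`, the fluctuation-dissipation pairing of the
#' Euler-Maruyama step. Reproducible under [set.seed()].
#'
#' @inheritParams glycan_spring_force
#' @return n x 3 force matrix, pN.
#' @export
thermal_force <- function(mesh, cfg) {
  if (cfg$kBT == 0) return(matrix(0, mesh$n, 3))
  sdv <- sqrt(2 * cfg$kBT * drag_coefficient(cfg) / cfg$dt)
  matrix(rnorm(3 * mesh$n, sd = sdv), mesh$n, 3)
}

check_coincident <- function(mesh, a, b) {
  if (!length(a)) return(invisible())
  p <- mesh_pos(mesh)
  d2 <- rowSums((p[a, , drop = FALSE] - p[b, , drop = FALSE])^2)
  if (any(d2 < 1e-24))
    stop("numerical error: coincident bonded beads")
  invisible()
}

#' All force terms of the Langevin equation
#'
#' @inheritParams glycan_spring_force
#' @param wall optional [build_lateral_wall()] surface (term is zero when
#'   omitted).
#' @param thermal include the stochastic term?
#' @return An object of class `force_field`: list with per-term n x 3
#'   matrices `spring`, `bend`, `pep`, `stoch`, `pressure`, `wall` and their
#'   component-wise sum `total`.
#' @export
compute_forces <- function(mesh, cfg, wall = NULL, thermal = TRUE) {
  terms <- list(
    spring = glycan_spring_force(mesh, cfg),
    bend = glycan_bending_force(mesh, cfg),
    pep = peptide_force(mesh, cfg),
    stoch = if (thermal) thermal_force(mesh, cfg) else matrix(0, mesh$n, 3),
    pressure = pressure_force(mesh, cfg),
    wall = if (is.null(wall)) matrix(0, mesh$n, 3)
           else wall_exclusion_force(mesh, wall, cfg))
  terms$total <- Reduce(`+`, terms)
  class(terms) <- "force_field"
  terms
}

#' @export
print.force_field <- function(x, ...) {
  mag <- vapply(x[c("spring", "bend", "pep", "stoch", "pressure", "wall")],
                function(F) max(sqrt(rowSums(F^2))), numeric(1))
  cat("<force_field> max per-bead magnitude (pN):\n")
  print(round(mag, 4))
  invisible(x)
}

#' One Euler-Maruyama step
#'
#' Updates positions as `r <- r + (F / zeta) * dt` (the stochastic force is
#' already part of `F`) and advances mesh time by `dt`. Aborts with a
#' step-size error if any bead moves farther than `0.5 * l0` in one step.
#'
#' @param mesh an `engulf_mesh`.
#' @param forces a [compute_forces()] field (or any n x 3 matrix under
#'   `$total`).
#' @param cfg a [simulation_config()].
#' @return the updated mesh.
#' @export
langevin_step <- function(mesh, forces, cfg) {
  F <- if (is.list(forces)) forces$total else forces
  disp <- F * (cfg$dt / drag_coefficient(cfg))
  worst <- sqrt(max(rowSums(disp^2)))
  if (worst > 0.5 * cfg$l0)
    stop(sprintf("step-size error: displacement %.3g nm exceeds 0.5 * l0; reduce dt",
                 worst))
  mesh$pos[seq_len(mesh$n), ] <- mesh_pos(mesh) + disp
  mesh$time <- mesh$time + cfg$dt
  mesh
}

# run nsteps of the full integrator in C++; returns the mesh with updated
# positions (and optionally samples of one bead's trajectory)
relax_mesh <- function(mesh, cfg, wall = NULL, nsteps = 100L,
                       sample_bead = 0L, sample_every = 0L) {
  gl <- mesh_gly(mesh)
  pp <- mesh_pep(mesh)
  pp <- pp[pp[, "intact"] > 0, , drop = FALSE]
  ba <- c(gl[, "a"], pp[, "a"])
  bb <- c(gl[, "b"], pp[, "b"])
  brest <- c(gl[, "rest"], pp[, "rest"])
  bk <- c(rep(cfg$kgly, nrow(gl)), rep(cfg$kpep, nrow(pp)))
  bd <- mesh_bend(mesh)
  jn <- mesh_jun(mesh)
  jn <- jn[jn[, "intact"] > 0, , drop = FALSE]
  res <- relax_cpp(mesh_pos(mesh),
                   as.integer(ba), as.integer(bb), brest, bk,
                   matrix(as.integer(bd[, 1:3]), ncol = 3), bd[, 4],
                   bending_modulus(cfg),
                   as.integer(jn[, "bead"]),
                   jn[, c("ax", "ay", "az"), drop = FALSE], jn[, "rest"],
                   cfg$kpep,
                   matrix(as.integer(mesh_tri(mesh)), ncol = 3), cfg$delta_p,
                   if (is.null(wall)) 0 else wall$R,
                   if (is.null(wall)) 0 else wall$cap_z,
                   if (is.null(wall)) 0 else wall$k_wall,
                   drag_coefficient(cfg), cfg$kBT, cfg$dt,
                   as.integer(nsteps), 0.5 * cfg$l0,
                   as.integer(sample_bead), as.integer(sample_every))
  if (!res$ok)
    stop(sprintf("step-size error after %d steps: displacement exceeded 0.5 * l0; reduce dt",
                 res$steps))
  mesh$pos[seq_len(mesh$n), ] <- res$pos
  mesh$time <- mesh$time + res$steps * cfg$dt
  attr(mesh, "samples") <- res$samples
  mesh
}
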