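cfg0 <- simulation_config()

test_that("glycan and peptide springs are Hookean with pairwise cancellation", {
  # bond at rest length: zero force
  m <- two_bead_mesh(d = 25, rest = 25)
  expect_equal(glycan_spring_force(m, cfg0), matrix(0, 2, 3))
  # stretched by 0.1 nm at kgly = 200 pN/nm: 20 pN attractive pair
  m <- two_bead_mesh(d = 25.1, rest = 25)
  F <- glycan_spring_force(m, cfg0)
  expect_equal(F[1, 1], 20, tolerance = 1e-9)
  expect_equal(F[2, 1], -20, tolerance = 1e-9)
  expect_equal(colSums(F), c(0, 0, 0))
  # peptide at 2 nm rest: zero; stretched 1 nm at kpep = 25: 25 pN pair
  m <- two_bead_pep_mesh(d = 2, rest = 2)
  expect_equal(peptide_force(m, cfg0), matrix(0, 2, 3))
  m <- two_bead_pep_mesh(d = 3, rest = 2)
  F <- peptide_force(m, cfg0)
  expect_equal(F[1, 1], 25, tolerance = 1e-9)
  expect_equal(colSums(F), c(0, 0, 0))
  # severed bonds contribute nothing
  m$pep[1, "intact"] <- 0
  expect_equal(peptide_force(m, cfg0), matrix(0, 2, 3))
  # coincident bonded beads are a numerical error
  m2 <- two_bead_mesh(d = 0, rest = 25)
  expect_error(glycan_spring_force(m2, cfg0), "coincident")
})

test_that("bending forces restore the spontaneous angle", {
  # collinear triple with straight spontaneous angle: zero force
  pos <- cbind(c(0, 25, 50), 0, 10)
  m <- chain_mesh(pos)
  expect_equal(max(abs(glycan_bending_force(m, cfg0))), 0, tolerance = 1e-12)
  # right-angle triple: net force acts to open the angle back to straight
  pos <- rbind(c(0, 0, 10), c(25, 0, 10), c(25, 25, 10))
  m <- chain_mesh(pos)
  F <- glycan_bending_force(m, cfg0)
  # end beads should be pushed to increase the bond angle at the vertex
  open_dir1 <- c(0, -1, 0)   # bead 1 moves to open the elbow
  open_dir3 <- c(1, 0, 0)
  expect_gt(sum(F[1, ] * open_dir1), 0)
  expect_gt(sum(F[3, ] * open_dir3), 0)
  expect_equal(colSums(F), c(0, 0, 0), tolerance = 1e-12)
})

test_that("hoop bending energy approaches the continuum worm-like-chain limit", {
  # hoop of 100 beads at the configured bead spacing l0: the discrete WLC
  # energy should match the continuum lp kBT L / (2 R^2)
  n <- 100
  R <- n * cfg0$l0 / (2 * pi)
  m <- hoop_mesh(n, R, phi0 = pi) # no spontaneous curvature
  kb <- engulfsim:::bending_modulus(cfg0)
  bd <- engulfsim:::mesh_bend(m)
  e <- engulfsim:::bend_energy_cpp(engulfsim:::mesh_pos(m),
                                   matrix(as.integer(bd[, 1:3]), ncol = 3),
                                   bd[, 4], kb)
  continuum <- cfg0$lp * cfg0$kBT * (2 * pi * R) / (2 * R^2)
  expect_equal(e, continuum, tolerance = 0.02)
})

test_that("conservative force terms equal minus the energy gradient", {
  set.seed(1)
  cfg <- simulation_config(seed = 1)
  geom <- test_geom()
  mesh <- build_septal_disc(geom, cfg)
  wall <- build_lateral_wall(geom, cfg)
  mesh$pos[seq_len(mesh$n), ] <- engulfsim:::mesh_pos(mesh) +
    matrix(rnorm(3 * mesh$n, sd = 2), mesh$n, 3)
  F <- compute_forces(mesh, cfg, wall, thermal = FALSE)
  Fcons <- F$spring + F$bend + F$pep + F$wall
  scale <- max(abs(Fcons))
  idx <- sample(n_beads(mesh), 10)
  for (i in idx) {
    g <- fd_force(mesh, i, function(m) total_energy(m, cfg, wall), h = 1e-4)
    expect_equal(g / scale, Fcons[i, ] / scale, tolerance = 1e-6)
  }
})

test_that("pressure forces follow the oriented-area rule", {
  # flat square patch of area 100 nm^2 at delta_p = 0.08631 pN/nm^2
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0))
  tri <- rbind(c(1, 2, 3), c(1, 3, 4))
  F <- engulfsim:::pressure_force_cpp(pos, tri, 0.08631)
  expect_equal(sum(F[, 3]), 8.631, tolerance = 1e-9)
  expect_equal(sum(abs(F[, 1:2])), 0)

  # closed sphere: forces sum to (0,0,0)
  s <- sphere_mesh(16, 24, R = 50)
  Fs <- engulfsim:::pressure_force_cpp(s$pos, s$tri, 0.08631)
  A <- 4 * pi * 50^2
  expect_lt(sqrt(sum(colSums(Fs)^2)), 1e-9 * 0.08631 * A)

  # refinement: |F| per unit area converges to delta_p as O(h^2)
  err <- sapply(c(8, 16, 32), function(nl) {
    s <- sphere_mesh(nl, 2 * nl, R = 50)
    Fs <- engulfsim:::pressure_force_cpp(s$pos, s$tri, 0.08631)
    abs(sum(sqrt(rowSums(Fs^2))) / (0.08631 * 4 * pi * 50^2) - 1)
  })
  expect_gt(err[1] / err[2], 2.5)
  expect_gt(err[2] / err[3], 2.5)
})

test_that("wall exclusion is zero inside and harmonic outside", {
  geom <- forespore_geometry(435, cap_extent = 300)
  cfg <- simulation_config()
  wall <- build_lateral_wall(geom, cfg)
  m <- two_bead_mesh(d = 25, rest = 25) # beads near the axis, inside
  expect_equal(wall_exclusion_force(m, wall), matrix(0, 2, 3))
  # bead penetrating 1 nm with k_wall = 100 pN/nm: 100 pN toward the axis
  m$pos[1, ] <- c(436, 0, 50)
  F <- wall_exclusion_force(m, wall)
  expect_equal(F[1, ], c(-100, 0, 0), tolerance = 1e-9)
  # gradient check against the half-harmonic energy
  m$pos[2, ] <- c(300, 300, 350)
  wall_energy <- function(mm) engulfsim:::wall_energy_cpp(
    engulfsim:::mesh_pos(mm), wall$R, wall$cap_z, wall$k_wall)
  Fw <- wall_exclusion_force(m, wall)
  for (i in 1:2) {
    g <- fd_force(m, i, wall_energy, h = 1e-5)
    expect_equal(g, Fw[i, ], tolerance = 1e-6 * max(1, max(abs(Fw))))
  }
})

test_that("thermal forces satisfy the fluctuation-dissipation moments", {
  cfg <- simulation_config(seed = 1)
  geom <- test_geom()
  mesh <- build_septal_disc(geom, cfg)
  expect_equal(thermal_force(mesh, simulation_config(kBT = 0)),
               matrix(0, n_beads(mesh), 3))
  set.seed(5)
  draws <- replicate(450, thermal_force(mesh, cfg))
  x <- as.numeric(draws)           # > 1e5 samples
  v_target <- 2 * cfg$kBT * drag_coefficient(cfg) / cfg$dt
  se <- sqrt(v_target / length(x))
  expect_lt(abs(mean(x)), 4 * se)
  expect_equal(var(x), v_target, tolerance = 0.02)
  set.seed(11); F1 <- thermal_force(mesh, cfg)
  set.seed(11); F2 <- thermal_force(mesh, cfg)
  expect_identical(F1, F2)
})

test_that("the Euler-Maruyama step moves beads by F dt / zeta", {
  cfg <- simulation_config(kBT = 0)
  m <- two_bead_mesh(d = 25, rest = 25)
  m0 <- engulfsim:::mesh_pos(m)
  m2 <- langevin_step(m, list(total = matrix(0, 2, 3)), cfg)
  expect_equal(engulfsim:::mesh_pos(m2), m0)
  expect_equal(m2$time, cfg$dt)
  F <- matrix(0, 2, 3); F[1, 1] <- 7
  m3 <- langevin_step(m, list(total = F), cfg)
  expect_equal(m3$pos[1, 1] - m0[1, 1], 7 * cfg$dt / drag_coefficient(cfg))
  # instability guard
  F[1, 1] <- 1e9
  expect_error(langevin_step(m, list(total = F), cfg), "step-size")
})

test_that("a bead in a harmonic trap equilibrates to kBT/k", {
  geom <- test_geom()
  m <- engulfsim:::new_mesh(geom)
  m <- engulfsim:::mesh_add_beads(m, c(0, 0, 10), 1L, 1L)
  m$strands[[1]] <- list(id = 1, bead_ids = 1L, closed = FALSE, row_index = 1)
  m <- engulfsim:::mesh_add_jun(m, 1L, c(0, 0, 10), rest = 0)
  k <- 1
  cfg <- simulation_config(kpep = k, eta_med = 1e-7, dt = 2e-7, kBT = 4.1)
  set.seed(2)
  m2 <- engulfsim:::relax_mesh(m, cfg, NULL, nsteps = 400000,
                               sample_bead = 1, sample_every = 10)
  s <- attr(m2, "samples")
  expect_equal(var(s[, 1]), cfg$kBT / k, tolerance = 0.05)
  expect_equal(var(s[, 2]), cfg$kBT / k, tolerance = 0.05)
})

test_that("zero-temperature relaxation monotonically dissipates energy", {
  set.seed(3)
  cfg <- simulation_config(kBT = 0)
  geom <- test_geom()
  mesh <- build_septal_disc(geom, cfg)
  mesh$pos[seq_len(mesh$n), ] <- engulfsim:::mesh_pos(mesh) +
    matrix(rnorm(3 * mesh$n, sd = 1.5), mesh$n, 3)
  wall <- build_lateral_wall(geom, cfg)
  cfg$delta_p <- 0 # conservative system only
  e <- total_energy(mesh, cfg, wall)
  for (i in 1:10) {
    mesh <- engulfsim:::relax_mesh(mesh, cfg, wall, nsteps = 50)
    e2 <- total_energy(mesh, cfg, wall)
    expect_lte(e2, e + 1e-9)
    e <- e2
  }
})

test_that("peptide strain bookkeeping tracks the linear elastic regime", {
  cfg <- simulation_config()
  mesh <- build_septal_disc(test_geom(), cfg)
  expect_equal(peptide_linear_fraction(mesh), 1.0)
})
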