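wt_geom <- test_geom(120, 60)

test_that("the leading edge is located as an ordered ring of junction beads", {
  cfg <- simulation_config(seed = 1)
  rcfg <- remodeling_config(NIDC = 5, f0 = 0)
  state <- init_engulfment(cfg, rcfg, wt_geom)
  le0 <- locate_leading_edge(state)
  K <- length(glycan_strands(state$mesh))
  expect_identical(le0, glycan_strands(state$mesh)[[K]]$bead_ids)

  # ordering equals a brute-force angular sort about the long axis
  mesh <- state$mesh
  mesh$leading_edge <- sample(le0) # scrambled
  le_sorted <- locate_leading_edge(mesh)
  p <- engulfsim:::mesh_pos(mesh)[le_sorted, ]
  ang <- atan2(p[, 2], p[, 1])
  d <- diff(ang)
  expect_true(all(d[d != 0] > 0 | abs(d[d != 0] + 2 * pi) < 1e-9) ||
                all(d[d != 0] < 0 | abs(d[d != 0] - 2 * pi) < 1e-9))

  # after one full insertion round the ring has advanced one ring spacing
  for (i in 1:200) state <- idc_insertion_event(state, 1 + (i - 1) %% 5)
  le1 <- locate_leading_edge(state)
  p1 <- engulfsim:::mesh_pos(state$mesh)[le1, ]
  expect_gt(mean(p1[, 3]), 0)
})

test_that("insertion events respect templates and cross gaps at rate ppro", {
  cfg <- simulation_config(seed = 2)
  rcfg <- remodeling_config(prep = 1, ppro = 1, NIDC = 1, f0 = 0)
  state <- init_engulfment(cfg, rcfg, wt_geom)
  # with intact templates and prep = ppro = 1 every event succeeds
  ev0 <- state$events
  for (i in 1:50) state <- idc_insertion_event(state, 1)
  expect_equal(state$events - ev0, 50)
  expect_true(mesh_is_valid(validate_mesh(local({
    m <- state$mesh; m$leading_edge <- locate_leading_edge(state); m
  }))))

  # a polymerizing IDC meeting a template gap succeeds with probability ppro
  rcfg7 <- remodeling_config(prep = 1, ppro = 0.7, NIDC = 1, f0 = 0)
  set.seed(33)
  base <- init_engulfment(simulation_config(seed = 3), rcfg7, wt_geom)
  base <- idc_insertion_event(base, 1) # now polymerizing
  n_try <- 4000
  succ <- 0
  set.seed(34)
  for (t in seq_len(n_try)) {
    st <- base
    j <- engulfsim:::lat_wrap(st$idcs$col[1] + st$idcs$dir[1], st$M)
    st$gap[j] <- TRUE
    ev <- st$events
    st <- idc_insertion_event(st, 1)
    if (st$events > ev) succ <- succ + 1
  }
  phat <- succ / n_try
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / n_try) + 0.001)
})

test_that("make-before-break holds and coupled remodeling keeps the mesh whole", {
  cfg <- simulation_config(seed = 4, dt = 1.2e-7)
  rcfg <- remodeling_config(prep = 1, ppro = 1, NIDC = 5, f0 = 0)
  run <- run_engulfment(cfg, rcfg, wt_geom,
                        stop = list(E = 95, max_time = 36000), n_relax = 20)
  mesh <- run$mesh
  expect_true(mesh_is_valid(validate_mesh(mesh)))
  # every severed junction guards a column whose replacement segment exists:
  # its bead must not be the top bead of its column
  jn <- engulfsim:::mesh_jun(mesh)
  severed <- jn[jn[, "intact"] == 0, "bead"]
  top_beads <- mesh$leading_edge
  expect_false(any(severed %in% top_beads))
  # engulfment is monotone after the initial septum-curving phase
  E <- run$trace$E
  tail_E <- E[-(1:2)]
  expect_true(all(diff(tail_E) > -1e-6))
})

test_that("without insertion complexes engulfment stalls", {
  cfg <- simulation_config(seed = 5)
  rcfg <- remodeling_config(NIDC = 0, f0 = 0)
  run <- run_engulfment(cfg, rcfg, wt_geom, stop = list(max_time = 500),
                        n_relax = 50)
  # E stays at its initial value up to thermal jitter of the relaxing mesh
  expect_lt(diff(range(run$trace$E)), 0.5)
  expect_identical(classify_phenotype(run)$phenotype, "stalled")
})

test_that("insertion flux equals NIDC x VIDC x n_bundle without pausing", {
  cfg <- simulation_config(seed = 6, dt = 1.2e-7)
  rcfg <- remodeling_config(prep = 1, ppro = 1, NIDC = 5, VIDC = 30, f0 = 0)
  run <- run_engulfment(cfg, rcfg, wt_geom,
                        stop = list(E = 80, max_time = 36000), n_relax = 5)
  fl <- insertion_flux(run)
  expect_equal(fl$flux, 5 * 30 * cfg$n_bundle, tolerance = 0.01)
})

test_that("mean final engulfment is non-decreasing in prep and ppro", {
  final_E <- function(p, seeds) {
    vapply(seeds, function(s) {
      cfg <- simulation_config(seed = s)
      rcfg <- remodeling_config(prep = p, ppro = p, NIDC = 5, f0 = 0.3)
      run <- run_engulfment(cfg, rcfg, wt_geom,
                            stop = list(E = 95, max_time = 40), n_relax = 2)
      tail(run$trace$E, 1)
    }, numeric(1))
  }
  e5 <- final_E(0.5, 1:20)
  e75 <- final_E(0.75, 21:40)
  e10 <- final_E(1.0, 41:60)
  expect_lte(mean(e5), mean(e75) + 0.5)
  expect_lte(mean(e75), mean(e10) + 0.5)
  expect_lt(wilcox.test(e5, e10, alternative = "less", exact = FALSE)$p.value, 0.01)
})

test_that("delayed degradation reduces to coupled mode at zero delay", {
  cfg <- simulation_config(seed = 7, dt = 1.2e-7)
  rcfg <- remodeling_config(prep = 1, ppro = 1, NIDC = 5, f0 = 0.05,
                            coupled = FALSE, tau_delay = 0)
  run <- run_engulfment(cfg, rcfg, wt_geom,
                        stop = list(E = 95, max_time = 36000), n_relax = 5)
  sep <- id_separation(run)
  late <- sep$separation[!is.na(sep$separation)]
  # separation stays within about one bead spacing of the leading edge
  expect_lt(mean(tail(late, 5)), 1.5 * cfg$l0)
})

test_that("insertion-degradation separation grows with the delay time", {
  taus <- c(0, 0.9, 9, 18) * 60 # the four printed delays, in seconds
  seps <- vapply(taus, function(tau) {
    cfg <- simulation_config(seed = 8, dt = 1.2e-7)
    rcfg <- remodeling_config(prep = 1, ppro = 1, NIDC = 5, f0 = 0.05,
                              coupled = FALSE, tau_delay = tau)
    run <- run_engulfment(cfg, rcfg, wt_geom,
                          stop = list(E = 95, max_time = 36000), n_relax = 5)
    sep <- id_separation(run)$separation
    sep <- sep[!is.na(sep)]
    mean(tail(sep, ceiling(length(sep) / 2)))
  }, numeric(1))
  expect_true(all(diff(seps) > -1e-9))
  expect_gt(seps[4], seps[1])
  # coupled-mode trajectories have no defined separation
  cfg <- simulation_config(seed = 8)
  runc <- run_engulfment(cfg, remodeling_config(NIDC = 2, f0 = 0), wt_geom,
                         stop = list(max_time = 20), n_relax = 2)
  expect_error(id_separation(runc), "coupled")
})

test_that("erroneous vertical cuts occur at rate ppcut", {
  cfg <- simulation_config(seed = 9, dt = 1.2e-7)
  rcfg <- remodeling_config(prep = 1, ppro = 1, NIDC = 5, f0 = 0.02,
                            coupled = FALSE, tau_delay = 10, ppcut = 0.1)
  run <- run_engulfment(cfg, rcfg, wt_geom,
                        stop = list(E = 95, max_time = 36000), n_relax = 5)
  n <- run$n_cut_events
  expect_gt(n, 100)
  phat <- run$n_bad_cuts / n
  expect_lt(abs(phat - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("random peptide degradation thins bonds as a Poisson process", {
  cfg <- simulation_config(seed = 10, dt = 1.2e-7)
  rcfg <- remodeling_config(prep = 1, ppro = 1, NIDC = 5, f0 = 0.05)
  run <- run_engulfment(cfg, rcfg, wt_geom,
                        stop = list(E = 95, max_time = 36000), n_relax = 20)
  # prpep = 0: bond count unchanged
  set.seed(1)
  d0 <- random_peptide_degradation(run, remodeling_config(prpep = 0, NIDC = 5),
                                   duration = 60, n_chunks = 5, n_relax = 20)
  expect_equal(d0$trace$intact[1], tail(d0$trace$intact, 1))

  # survival fraction ~ exp(-prpep t) within 3 sigma binomial bounds
  set.seed(2)
  d1 <- random_peptide_degradation(run, remodeling_config(prpep = 2.2, NIDC = 5),
                                   duration = 60, n_chunks = 10, n_relax = 5)
  n0 <- d1$trace$intact[1]
  p_surv <- exp(-2.2 / 60 * 60)
  expect_lt(abs(tail(d1$trace$intact, 1) / n0 - p_surv),
            3 * sqrt(p_surv * (1 - p_surv) / n0))

  # volume deviation from the intact control is non-decreasing in prpep at
  # matched times (printed rates 2.2, 22, 33 min^-1; exposure short enough
  # that the faster rates are not both exhausted)
  set.seed(1)
  c0 <- random_peptide_degradation(run, remodeling_config(prpep = 0, NIDC = 5),
                                   duration = 5, n_chunks = 10, n_relax = 40)
  dev <- vapply(c(2.2, 22, 33), function(pr) {
    set.seed(3)
    d <- random_peptide_degradation(run, remodeling_config(prpep = pr, NIDC = 5),
                                    duration = 5, n_chunks = 10, n_relax = 40)
    abs(tail(d$trace$V, 1) - tail(c0$trace$V, 1))
  }, numeric(1))
  expect_true(all(diff(dev) > -1e-9))
})
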