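test_that("time zero is detected at the onset of septum curving", {
  spec <- fixture_spec(curving_onset_min = 30,
                       E_schedule = data.frame(time_min = c(0, 60),
                                               E = c(5, 60)))
  fx <- synth_contour_series(spec)
  az <- align_time_zero(fx$frames)
  expect_false(az$no_onset)
  expect_equal(az$onset, fx$truth$onset_frame[1])

  # always-flat series: no onset
  flat <- fx$frames
  for (i in seq_along(flat)) flat[[i]] <- fx$frames[[1]]
  az2 <- align_time_zero(flat)
  expect_true(az2$no_onset)
  expect_true(is.na(az2$onset))
  expect_error(align_time_zero(fx$frames[1:2]), "at least 3")
})

test_that("onset detection tolerates measurement noise", {
  spec <- fixture_spec(curving_onset_min = 30,
                       E_schedule = data.frame(time_min = c(0, 60),
                                               E = c(5, 60)))
  fx <- synth_contour_series(spec)
  truth <- fx$truth$onset_frame[1]
  hits <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    set.seed(2000 + r)
    noisy <- fx$frames
    for (i in seq_along(noisy)) {
      # 10 nm point noise: the curvature jump at onset is ~5x the noise of
      # the per-frame curvature estimate
      noisy[[i]]$forespore$x <- noisy[[i]]$forespore$x +
        rnorm(nrow(noisy[[i]]$forespore), sd = 0.01)
      noisy[[i]]$forespore$y <- noisy[[i]]$forespore$y +
        rnorm(nrow(noisy[[i]]$forespore), sd = 0.01)
    }
    det <- align_time_zero(noisy)$onset
    if (!is.na(det) && abs(det - truth) <= 1) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("kymographs average normalized angular intensity profiles", {
  spec <- fixture_spec(E_schedule = data.frame(time_min = c(0, 20),
                                               E = c(30, 60)))
  fx <- synth_contour_series(spec)
  # uniform intensity: flat kymograph after normalization
  uni <- synth_intensity_painting(fx$frames, list(baseline = 2, peaks = list()))
  ky <- build_average_kymograph(list(uni))
  expect_lt(max(apply(ky$grid, 1, var), na.rm = TRUE), 1e-10)

  # a single bright spot painted at +90 degrees peaks there in every row
  spot <- synth_intensity_painting(fx$frames,
                                   list(baseline = 1,
                                        peaks = list(list(center_deg = 90,
                                                          sd_deg = 10,
                                                          height = 8))))
  ky2 <- build_average_kymograph(list(spot, spot))
  peaks <- ky2$angle[apply(ky2$grid, 1, which.max)]
  expect_true(all(abs(peaks - 90) <= 3))

  # averaging identical cells equals the single-cell kymograph
  ky1 <- build_average_kymograph(list(spot))
  expect_equal(ky2$grid, ky1$grid)
})

test_that("piecewise-cubic resampling reproduces polynomial intensity exactly", {
  set.seed(3)
  ang <- sort(runif(90, -180, 180))
  poly <- function(a) 5 + 0.01 * a + 2e-4 * a^2 - 1e-6 * a^3
  grid <- seq(-150, 150, by = 1) + 0.5 # off-node, away from the wrap seam
  v <- engulfsim:::resample_periodic(ang, poly(ang), grid)
  expect_equal(v, poly(grid), tolerance = 1e-9)
})

test_that("kymographs are equivariant under contour rotation", {
  spec <- fixture_spec(E_schedule = data.frame(time_min = c(0, 10), E = c(40, 50)))
  fx <- synth_contour_series(spec)
  spot <- synth_intensity_painting(fx$frames[1:2],
                                   list(baseline = 1,
                                        peaks = list(list(center_deg = 30,
                                                          sd_deg = 12,
                                                          height = 5))))
  ky <- build_average_kymograph(list(spot))
  # rotate the painted peak by 40 degrees: columns shift by 40 bins
  spot2 <- synth_intensity_painting(fx$frames[1:2],
                                    list(baseline = 1,
                                         peaks = list(list(center_deg = 70,
                                                           sd_deg = 12,
                                                           height = 5))))
  ky2 <- build_average_kymograph(list(spot2))
  shift <- 40
  idx <- ((seq_along(ky$angle) - 1 + shift) %% length(ky$angle)) + 1
  expect_equal(ky2$grid[, idx], ky$grid, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("gap arc length measures the uncovered side of the forespore", {
  spec <- fixture_spec(E_schedule = data.frame(time_min = c(0, 60),
                                               E = c(5, 100)))
  fx <- synth_contour_series(spec)
  rho <- spec$forespore_radius
  for (i in c(3, 7, 11)) {
    tru <- fx$truth[i, ]
    g <- gap_arc_length(fx$frames[[i]], c(tru$le_idx1, tru$le_idx2))
    expect_equal(g$angle, tru$gap_angle_rad, tolerance = 1e-9)
    # polyline arc equals the chordal sum, slightly under rho * theta
    expect_equal(g$arc, tru$gap_arc_um, tolerance = 2e-3)
    # consistency with percent engulfment on circular fixtures
    E <- percent_engulfment(list(
      center = c(tru$center_x, tru$center_y),
      le_points = as.matrix(fx$frames[[i]]$forespore[c(tru$le_idx1, tru$le_idx2),
                                                     c("x", "y")]),
      uncovered_point = c(tru$center_x, tru$center_y + rho)))
    expect_equal(E, (1 - g$angle / (2 * pi)) * 100, tolerance = 1e-9)
  }
  # fully engulfed: zero gap
  expect_equal(gap_arc_length(fx$frames[[13]], NULL)$arc, 0)
  # brute-force segment-sum oracle
  fr <- fx$frames[[5]]
  le <- c(fx$truth$le_idx1[5], fx$truth$le_idx2[5])
  fs <- fr$forespore
  n <- nrow(fs)
  seg <- sqrt(diff(c(fs$x, fs$x[1]))^2 + diff(c(fs$y, fs$y[1]))^2)
  walk <- function(i, j) { s <- 0; while (i != j) { s <- s + seg[i]; i <- i %% n + 1 }; s }
  g <- gap_arc_length(fr, le)
  expect_true(abs(g$arc - walk(le[1], le[2])) < 1e-12 ||
                abs(g$arc - walk(le[2], le[1])) < 1e-12)
  expect_error(gap_arc_length(fr, c(1, n + 10)), "not on contour")
})

test_that("leading-edge fluorescence fractions are background corrected", {
  expect_equal(gfp_le_fraction(100, 0)$fraction, 1)
  expect_equal(gfp_le_fraction(50, 50)$fraction, 0.5)
  r <- gfp_le_fraction(c(70, 72, 68), c(30, 28, 32))
  expect_equal(r$mean, 0.7, tolerance = 0.01)
  expect_warning(out <- gfp_le_fraction(10, 100, background = 2,
                                        npix_le = 10, npix_mc = 10),
                 "clipped")
  expect_equal(out$fraction, 0)
  expect_warning(z <- gfp_le_fraction(5, 5, background = 1, npix_le = 5,
                                      npix_mc = 5), "NaN")
  expect_true(is.nan(z$fraction))
  expect_error(gfp_le_fraction(-1, 5), ">= 0")
})

test_that("contour CSV files round-trip", {
  spec <- fixture_spec(E_schedule = data.frame(time_min = c(0, 10), E = c(40, 60)))
  fx <- synth_contour_series(spec)
  frames <- synth_intensity_painting(fx$frames,
                                     list(baseline = 1,
                                          peaks = list(list(center_deg = 0,
                                                            sd_deg = 20,
                                                            height = 2))))
  f <- tempfile(fileext = ".csv")
  write_contours(list(cellA = frames), f)
  back <- read_contours(f)
  expect_length(back, 1)
  expect_length(back$cellA, length(frames))
  expect_equal(back$cellA[[2]]$forespore$x, frames[[2]]$forespore$x)
  expect_equal(back$cellA[[2]]$forespore$intensity,
               frames[[2]]$forespore$intensity)
  expect_equal(back$cellA[[1]]$time, frames[[1]]$time)
})
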