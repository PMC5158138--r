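# Deterministic generators for every input the analysis consumes, so all
# modules are testable without microscopy data: sporangium contour series
# with scheduled engulfment and septum curving, noisy engulfment traces for
# chi-square fitting, and painted angular intensity distributions. Every
# fixture ships its ground truth. File formats are identical to the real
# input contracts.

#' Specification of a synthetic sporangium fixture
#'
#' @param forespore_radius um.
#' @param mother_radius,mother_length um.
#' @param E_schedule data.frame with `time_min` and `E` (percent) control
#'   points, interpolated piecewise-linearly; non-decreasing for WT-style
#'   fixtures.
#' @param frame_interval_min min.
#' @param n_points points per forespore contour.
#' @param curving_onset_min onset time of septum curving (flat before,
#'   curved after), or `NULL` for fully round forespores in all frames.
#' @param curving_ramp_frames frames over which the septal curvature ramps
#'   from flat to the forespore curvature.
#' @param sd_V,sd_S,sd_E noise standard deviations for trace fixtures.
#' @param seed RNG seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(forespore_radius = 0.4, mother_radius = 0.45,
                         mother_length = 2, E_schedule =
                           data.frame(time_min = c(0, 60), E = c(0, 100)),
                         frame_interval_min = 5, n_points = 72L,
                         curving_onset_min = NULL, curving_ramp_frames = 2L,
                         sd_V = 0.02, sd_S = 0.2, sd_E = 2, seed = 1L) {
  if (forespore_radius > mother_radius + mother_length)
    stop("impossible geometry: forespore larger than mother")
  if (any(E_schedule$E < 0 | E_schedule$E > 100))
    stop("E schedule must lie in [0, 100]")
  structure(list(forespore_radius = forespore_radius,
                 mother_radius = mother_radius,
                 mother_length = mother_length, E_schedule = E_schedule,
                 frame_interval_min = frame_interval_min,
                 n_points = as.integer(n_points),
                 curving_onset_min = curving_onset_min,
                 curving_ramp_frames = curving_ramp_frames,
                 sd_V = sd_V, sd_S = sd_S, sd_E = sd_E,
                 seed = as.integer(seed)), class = "fixture_spec")
}

schedule_E <- function(spec, t_min) {
  approx(spec$E_schedule$time_min, spec$E_schedule$E, xout = t_min,
         rule = 2)$y
}

#' Generate a synthetic sporangium contour series with ground truth
#'
#' The mother cell is a capped cylinder (flat top at y = 0), the forespore
#' a circle of radius `forespore_radius` centred at (0, forespore_radius)
#' above it. Engulfment follows the scheduled E(t): the uncovered gap is
#' centred at the forespore pole (+90 degrees in the mother-forespore
#' frame), with the two leading-edge points at the gap borders. When
#' `curving_onset_min` is set, the septal (mother-proximal) sector of the
#' forespore contour is flat before the onset and ramps to the forespore
#' curvature after it.
#'
#' @param spec a [fixture_spec()].
#' @return list with `frames` (list of [contour_frame()]s) and `truth`
#'   data.frame (per frame: time_min, E, gap_angle_rad, gap_arc_um,
#'   le_idx1, le_idx2, V_um3, S_um2, onset_frame, center_x, center_y).
#' @export
synth_contour_series <- function(spec) {
  set.seed(spec$seed)
  rho <- spec$forespore_radius
  t_end <- max(spec$E_schedule$time_min)
  times <- seq(0, t_end, by = spec$frame_interval_min)
  n <- spec$n_points
  # contour angles from the septum-facing point (-90 deg) counter-clockwise
  phi <- -pi / 2 + 2 * pi * (seq_len(n) - 1) / n
  center <- c(0, rho)
  mother <- mother_capsule(spec)
  onset_frame <- NA_integer_
  if (!is.null(spec$curving_onset_min))
    onset_frame <- which(times >= spec$curving_onset_min)[1]
  frames <- vector("list", length(times))
  truth <- list()
  for (i in seq_along(times)) {
    x <- center[1] + rho * cos(phi)
    y <- center[2] + rho * sin(phi)
    if (!is.na(onset_frame)) {
      # septal sector: sagitta interpolates flat -> full curvature
      frac <- if (i < onset_frame) 0
              else min(1, (i - onset_frame + 1) / spec$curving_ramp_frames)
      w <- 40 * pi / 180
      sect <- which(abs(((phi + pi / 2 + pi) %% (2 * pi)) - pi) <= w)
      if (length(sect) > 2) {
        cw <- rho * sin(w)                      # chord half-width
        sag_full <- rho * (1 - cos(w))          # full-curvature sagitta
        u <- (x[sect] - center[1]) / cw
        ybase <- center[2] - rho * cos(w)       # chord level
        y[sect] <- ybase - frac * sag_full * (1 - u^2)  # parabolic arc
        x[sect] <- center[1] + u * cw
      }
    }
    E <- schedule_E(spec, times[i])
    gap <- 2 * pi * (1 - E / 100)
    if (gap > 1e-9) {
      targets <- c(pi / 2 - gap / 2, pi / 2 + gap / 2)
      le_idx <- vapply(targets, function(a)
        which.min(abs(((phi - a + pi) %% (2 * pi)) - pi)), integer(1))
      ang <- atan2(y[le_idx] - center[2], x[le_idx] - center[1])
      wccw <- (ang[2] - ang[1]) %% (2 * pi)
      # the gap is the arc (from LE point 1 CCW to LE point 2) containing
      # the pole at +90 degrees
      gap_true <- if ((pi / 2 - ang[1]) %% (2 * pi) <= wccw ||
                      wccw == 0) {
        if (wccw == 0) 2 * pi else wccw
      } else 2 * pi - wccw
    } else {
      le_idx <- c(NA_integer_, NA_integer_)
      gap_true <- 0
    }
    inten <- NULL
    frames[[i]] <- contour_frame(times[i], data.frame(x = x, y = y), mother)
    truth[[i]] <- data.frame(
      time_min = times[i], E = E, gap_angle_rad = gap_true,
      gap_arc_um = rho * gap_true, le_idx1 = le_idx[1], le_idx2 = le_idx[2],
      V_um3 = 4 / 3 * pi * rho^3, S_um2 = 4 * pi * rho^2,
      onset_frame = onset_frame, center_x = center[1], center_y = center[2])
  }
  list(frames = frames, truth = do.call(rbind, truth))
}

# closed mother outline: flat top at y = 0, straight sides, rounded bottom
mother_capsule <- function(spec) {
  rm <- spec$mother_radius; L <- spec$mother_length
  th <- seq(0, pi, length.out = 16)
  data.frame(x = c(rm, rm * cos(-th), -rm),
             y = c(0, -L - rm * sin(th), 0))
}

#' Add Gaussian noise to a ground-truth engulfment trace
#'
#' Adds i.i.d. Gaussian noise per channel and records the sd columns used
#' by [chi2()]. A zero sd returns the true channel unchanged (but sd
#' columns must be positive for fitting).
#'
#' @param true_trace an [engulfment_trace()].
#' @param sd_V,sd_S,sd_E noise standard deviations (um^3, um^2, percent).
#' @param seed RNG seed.
#' @return an [engulfment_trace()] with sd columns.
#' @export
synth_noisy_traces <- function(true_trace, sd_V, sd_S, sd_E, seed = 1L) {
  set.seed(seed)
  n <- nrow(true_trace)
  engulfment_trace(true_trace$time,
                   true_trace$V + rnorm(n, sd = sd_V),
                   true_trace$S + rnorm(n, sd = sd_S),
                   pmin(pmax(true_trace$E + rnorm(n, sd = sd_E), 0), 100),
                   sd_V = rep(sd_V, n), sd_S = rep(sd_S, n),
                   sd_E = rep(sd_E, n))
}

#' Paint angular intensity distributions onto contour frames
#'
#' Per-point intensities are `baseline` plus a sum of angular Gaussians
#' (e.g. a leading-edge-centred peak mimicking LE-enriched fluorescence).
#' Angles are measured in the mother-forespore frame. Negative intensities
#' are clipped at 0 with a warning.
#'
#' @param frames list of [contour_frame()]s.
#' @param rules list with `baseline` and `peaks`, a list of
#'   `list(center_deg, sd_deg, height)` angular Gaussians.
#' @return the frames with a forespore `intensity` column.
#' @export
synth_intensity_painting <- function(frames, rules) {
  baseline <- if (is.null(rules$baseline)) 0 else rules$baseline
  for (i in seq_along(frames)) {
    ang <- contour_angles(frames[[i]])
    v <- rep(baseline, length(ang))
    for (pk in rules$peaks) {
      d <- ((ang - pk$center_deg + 180) %% 360) - 180
      v <- v + pk$height * exp(-d^2 / (2 * pk$sd_deg^2))
    }
    if (any(v < 0)) {
      warning("negative intensities clipped at 0")
      v <- pmax(v, 0)
    }
    frames[[i]]$forespore$intensity <- v
  }
  frames
}

#' Meridian profile of a synthetic forespore contour
#'
#' Extracts the (r, z) meridian (half-contour with x >= 0, ordered from the
#' septal pole upward) for use with [volume_surface_by_revolution()].
#'
#' @param frame a [contour_frame()].
#' @return two-column matrix (r, z), um.
#' @export
contour_meridian <- function(frame) {
  fs <- frame$forespore
  keep <- fs$x >= -1e-12
  r <- fs$x[keep]; z <- fs$y[keep]
  o <- order(z)
  cbind(r = pmax(r[o], 0), z = z[o])
}
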