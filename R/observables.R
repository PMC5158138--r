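# Geometric and kinetic measurements on simulation states and contours.
# Experimental-style traces use microscopy units (um^3, um^2, %, minutes in
# contour files); the mesh itself lives in nm.

#' Engulfment time-series container
#'
#' Shared by simulation output, experimental input and synthetic fixtures.
#'
#' @param time time points, s (strictly increasing).
#' @param V forespore volume, um^3.
#' @param S forespore surface area, um^2.
#' @param E percent engulfment, in \[0, 100\].
#' @param sd_V,sd_S,sd_E optional per-point standard deviations.
#' @return data.frame of class `engulfment_trace`.
#' @export
engulfment_trace <- function(time, V, S, E, sd_V = NA_real_, sd_S = NA_real_,
                             sd_E = NA_real_) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(E < -1e-9 | E > 100 + 1e-9)) stop("E must lie in [0, 100]")
  structure(data.frame(time = time, V = V, S = S, E = pmin(pmax(E, 0), 100),
                       sd_V = sd_V, sd_S = sd_S, sd_E = sd_E),
            class = c("engulfment_trace", "data.frame"))
}

#' Write / read an engulfment trace as CSV
#'
#' Columns `time_s, V_um3, S_um2, E_percent` plus `sd_*` columns when
#' standard deviations are present.
#'
#' @param trace an [engulfment_trace()].
#' @param path CSV path.
#' @return `path` (write) or an `engulfment_trace` (read).
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time, V_um3 = trace$V, S_um2 = trace$S,
                   E_percent = trace$E)
  if (!all(is.na(trace$sd_V))) {
    df$sd_V_um3 <- trace$sd_V; df$sd_S_um2 <- trace$sd_S
    df$sd_E_percent <- trace$sd_E
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  engulfment_trace(df$time_s, df$V_um3, df$S_um2, df$E_percent,
                   sd_V = if ("sd_V_um3" %in% names(df)) df$sd_V_um3 else NA_real_,
                   sd_S = if ("sd_S_um2" %in% names(df)) df$sd_S_um2 else NA_real_,
                   sd_E = if ("sd_E_percent" %in% names(df)) df$sd_E_percent else NA_real_)
}

#' Volume and surface area of a solid of revolution
#'
#' Treats the ordered profile (r, z) as the meridian of a rotationally
#' symmetric body about the z axis (the experimental convention: rotational
#' symmetry around the axis joining the mother and forespore centres of
#' mass) and integrates segment by segment with the conical-frustum
#' formulas, which are exact for piecewise-linear profiles:
#' `V = pi * integral r^2 dz`, `S = 2 pi * integral r ds`.
#'
#' @param profile two-column matrix or data.frame of (r, z) points, ordered
#'   along the meridian; r >= 0. Units of length L give V in L^3, S in L^2.
#' @param check check the profile for self-intersection (skipped for
#'   profiles longer than 2000 points).
#' @return named numeric vector `c(V, S)`.
#' @examples
#' th <- seq(0, pi, length.out = 2001)       # unit sphere meridian
#' vs <- volume_surface_by_revolution(cbind(sin(th), cos(th)))
#' @export
volume_surface_by_revolution <- function(profile, check = TRUE) {
  profile <- as.matrix(profile)
  r <- profile[, 1]; z <- profile[, 2]
  if (any(r < -1e-12)) stop("profile radii must be >= 0")
  r <- pmax(r, 0)
  n <- length(r)
  if (n < 2) stop("profile needs at least 2 points")
  if (check && n <= 2000 && profile_self_intersects(r, z))
    stop("self-intersecting profile")
  r1 <- r[-n]; r2 <- r[-1]; z1 <- z[-n]; z2 <- z[-1]
  V <- abs(sum(pi / 3 * (z2 - z1) * (r1^2 + r1 * r2 + r2^2)))
  S <- sum(pi * (r1 + r2) * sqrt((r2 - r1)^2 + (z2 - z1)^2))
  c(V = V, S = S)
}

profile_self_intersects <- function(r, z) {
  n <- length(r) - 1
  if (n < 3) return(FALSE)
  seg_int <- function(i, j) {
    p1 <- c(r[i], z[i]); p2 <- c(r[i + 1], z[i + 1])
    q1 <- c(r[j], z[j]); q2 <- c(r[j + 1], z[j + 1])
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2))
    for (j in seq((i + 2), n))
      if (seg_int(i, j)) return(TRUE)
  FALSE
}

#' Percent engulfment
#'
#' The covered angle of the forespore divided by the full angle, as a
#' percentage. For a simulation state the angle of the leading edge is
#' measured from the forespore reference centre, with the full angle pi
#' spanning septum-facing pole to distal pole; for a contour the gap angle
#' between the two leading-edge points is measured at the forespore centre:
#' `E = (1 - gap_angle / (2 pi)) * 100`.
#'
#' @param x an `engulf_mesh`, an `engulf_run`, or a list with `center`
#'   (numeric 2-vector), `le_points` (2 x 2 matrix of leading-edge
#'   coordinates) and `uncovered_point` (a point on the uncovered side).
#' @param ... unused.
#' @return percent engulfment in \[0, 100\].
#' @export
percent_engulfment <- function(x, ...) UseMethod("percent_engulfment")

#' @export
percent_engulfment.engulf_mesh <- function(x, ...) {
  le <- x$leading_edge
  if (!length(le)) stop("undefined forespore center: mesh has no leading edge")
  p <- mesh_pos(x)[le, , drop = FALSE]
  c0 <- forespore_center(x$geom)
  v <- sweep(p, 2, c0)
  # opening half-angle of the uncovered polar cap, averaged over the ring
  beta <- mean(acos(pmin(pmax(v[, 3] / sqrt(rowSums(v^2)), -1), 1)))
  unname((1 - beta / pi) * 100)
}

#' @export
percent_engulfment.engulf_run <- function(x, ...) {
  percent_engulfment(x$mesh)
}

#' @export
percent_engulfment.list <- function(x, ...) {
  if (is.null(x$center) || is.null(x$le_points))
    stop("undefined forespore center: need 'center' and 'le_points'")
  a <- atan2(x$le_points[1, 2] - x$center[2], x$le_points[1, 1] - x$center[1])
  b <- atan2(x$le_points[2, 2] - x$center[2], x$le_points[2, 1] - x$center[1])
  width_ccw <- (b - a) %% (2 * pi)
  gap <- if (!is.null(x$uncovered_point)) {
    u <- atan2(x$uncovered_point[2] - x$center[2],
               x$uncovered_point[1] - x$center[1])
    if ((u - a) %% (2 * pi) <= width_ccw) width_ccw else 2 * pi - width_ccw
  } else {
    min(width_ccw, 2 * pi - width_ccw)
  }
  unname((1 - gap / (2 * pi)) * 100)
}

#' Relative forespore pole curvature
#'
#' Fits a circle (algebraic least squares, axis-symmetric) to the polar
#' window of the forespore meridian profile and reports kappa = 1/R_fit
#' against the reference kappa0 = 1/a of the spherical cap with the same
#' base radius a (the maximal profile radius). Ratios above 1 indicate a
#' pole sharper than a sphere.
#'
#' @param x an `engulf_mesh`/`engulf_run` (profile extracted automatically;
#'   requires engulfment >= 90 percent), or a two-column (r, z) profile.
#' @param window polar fraction of the meridian used for the fit.
#' @return list of class `curvature_report` with `kappa`, `kappa0` (same
#'   reciprocal-length unit as the profile) and `ratio`.
#' @export
relative_curvature <- function(x, window = 0.2) {
  if (inherits(x, "engulf_run")) x <- x$mesh
  if (inherits(x, "engulf_mesh")) {
    if (percent_engulfment(x) < 90)
      stop("relative_curvature requires engulfment >= 90%")
    prof <- mesh_profile(x)
  } else {
    prof <- as.matrix(x)
  }
  r <- prof[, 1]; z <- prof[, 2]
  a <- max(r)
  zmax <- max(z); zmin <- min(z)
  keep <- z >= zmax - window * (zmax - zmin)
  if (sum(keep) < 3) stop("circle fit failure: too few points in polar window")
  fit <- fit_circle_axisym(r[keep], z[keep])
  if (!is.finite(fit$radius) || fit$radius <= 0)
    stop("circle fit failure")
  structure(list(kappa = 1 / fit$radius, kappa0 = 1 / a,
                 ratio = a / fit$radius), class = "curvature_report")
}

#' @export
print.curvature_report <- function(x, ...) {
  cat(sprintf("<curvature_report> kappa %.4g, kappa0 %.4g, kappa/kappa0 %.4g\n",
              x$kappa, x$kappa0, x$ratio))
  invisible(x)
}

# algebraic (Kasa) circle fit with the centre constrained to the symmetry
# axis r = 0: r^2 + z^2 = 2 z z0 + (R^2 - z0^2), linear in (z0, c)
fit_circle_axisym <- function(r, z) {
  y <- r^2 + z^2
  X <- cbind(2 * z, 1)
  coef <- qr.solve(X, y)
  z0 <- coef[1]
  R2 <- coef[2] + z0^2
  list(z0 = z0, radius = if (R2 > 0) sqrt(R2) else NaN)
}

# meridian profile (r, z) of the sac: septal rings from the centre outward,
# then inserted rings along the wall
mesh_profile <- function(mesh) {
  rows <- vapply(mesh$strands, function(s) s$row_index, numeric(1))
  ord <- order(rows)
  prof <- t(vapply(mesh$strands[ord], function(s) {
    p <- mesh_pos(mesh)[s$bead_ids, , drop = FALSE]
    c(mean(sqrt(p[, 1]^2 + p[, 2]^2)), mean(p[, 3]))
  }, numeric(2)))
  prof
}

#' Fraction of peptide bonds in the linear elastic regime
#'
#' Fraction of intact peptide bonds (cross-links and junction tethers)
#' whose extension beyond rest length is below `threshold` (1 nm, i.e. 50
#' percent of the 2 nm nominal peptide equilibrium length).
#'
#' @param mesh an `engulf_mesh`.
#' @param threshold extension threshold, nm.
#' @return fraction in \[0, 1\].
#' @export
peptide_linear_fraction <- function(mesh, threshold = 1) {
  p <- mesh_pos(mesh)
  ext <- numeric(0)
  pp <- mesh_pep(mesh)
  pp <- pp[pp[, "intact"] > 0, , drop = FALSE]
  if (nrow(pp)) {
    len <- sqrt(rowSums((p[pp[, "a"], , drop = FALSE] -
                           p[pp[, "b"], , drop = FALSE])^2))
    ext <- c(ext, len - pp[, "rest"])
  }
  jn <- mesh_jun(mesh)
  jn <- jn[jn[, "intact"] > 0, , drop = FALSE]
  if (nrow(jn)) {
    len <- sqrt(rowSums((p[jn[, "bead"], , drop = FALSE] -
                           jn[, c("ax", "ay", "az"), drop = FALSE])^2))
    ext <- c(ext, len - jn[, "rest"])
  }
  if (!length(ext)) return(NA_real_)
  mean(ext < threshold)
}

#' Glycan insertion flux
#'
#' Total single-glycan length inserted divided by elapsed active time, an
#' estimate of `NIDC * VIDC` on a per-glycan basis (each simulated filament
#' counts `n_bundle` glycans). With per-complex speeds in
#' `[v_low, v_high]`, the implied complex-count range is also reported.
#'
#' @param run an `engulf_run` from [run_engulfment()].
#' @param v_low,v_high per-complex speed interval, nm/s.
#' @return list with `flux` (nm/s), `length_total` (nm), `elapsed` (s) and
#'   `implied_complexes` (integer range).
#' @export
insertion_flux <- function(run, v_low = 20, v_high = 40) {
  if (run$elapsed <= 0) stop("zero elapsed time")
  total <- sum(run$idcs$length_inserted_total)
  flux <- total / run$elapsed
  list(flux = flux, length_total = total, elapsed = run$elapsed,
       implied_complexes = implied_complex_count(flux, flux, v_low, v_high))
}

#' Insertion-degradation separation trace
#'
#' Per recorded frame, the mean (over complexes) Euclidean distance between
#' each IDC's synthesis site and the nearest intact junction bond behind
#' it. Only defined for decoupled-mode trajectories; in coupled mode the
#' separation is zero by construction and an error is raised.
#'
#' @param run an `engulf_run` from a decoupled [run_engulfment()].
#' @return data.frame with columns `time` (s) and `separation` (nm).
#' @export
id_separation <- function(run) {
  if (isTRUE(run$rcfg$coupled))
    stop("id_separation is undefined for coupled-mode trajectories")
  data.frame(time = run$trace$time, separation = run$trace$id_sep)
}
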