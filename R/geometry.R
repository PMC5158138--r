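#' Forespore and old-cell-wall geometry
#'
#' Coordinate convention: the long axis of the sporangium is +z, the septal
#' plane is z = 0 and the forespore lies at z > 0. The rigid old cell wall
#' bounding the forespore is a cylinder of radius `cell_radius` for
#' z <= `cap_extent`, closed by a hemispherical polar cap of the same radius
#' centred at (0, 0, `cap_extent`).
#'
#' @param cell_radius cylinder radius R, nm. The default 435 nm corresponds
#'   to an inverse radius 1/R of 2.3 um^-1.
#' @param septum_position position of the septal plane along the long axis,
#'   nm (kept at 0 by the mesh builders).
#' @param cap_extent length of the cylindrical part of the forespore
#'   compartment before the polar cap, nm.
#' @param long_axis unit 3-vector of the long axis.
#' @return An object of class `forespore_geometry`.
#' @examples
#' geom <- forespore_geometry(cell_radius = 1 / 2.3e-3) # 1/R = 2.3 um^-1
#' @export
forespore_geometry <- function(cell_radius = 435, septum_position = 0,
                               cap_extent = 435, long_axis = c(0, 0, 1)) {
  if (cell_radius <= 0) stop("configuration error: cell_radius must be > 0")
  if (cap_extent < 0) stop("configuration error: cap_extent must be >= 0")
  la <- long_axis / sqrt(sum(long_axis^2))
  structure(list(cell_radius = cell_radius,
                 septum_position = septum_position,
                 cap_extent = cap_extent, long_axis = la),
            class = "forespore_geometry")
}

#' @export
print.forespore_geometry <- function(x, ...) {
  cat(sprintf("<forespore_geometry> R = %.4g nm (1/R = %.3g um^-1), cap extent %.4g nm\n",
              x$cell_radius, 1000 / x$cell_radius, x$cap_extent))
  invisible(x)
}

# meridian arc length from the septum rim (z = 0, rho = R) to the pole
meridian_length <- function(geom) {
  geom$cap_extent + pi * geom$cell_radius / 2
}

# point on the old-wall surface at meridian arc s and azimuth theta
surface_point <- function(geom, s, theta) {
  R <- geom$cell_radius; Lp <- geom$cap_extent
  s <- pmin(s, meridian_length(geom))
  on_cyl <- s <= Lp
  alpha <- pmax(s - Lp, 0) / R
  rho <- ifelse(on_cyl, R, R * cos(alpha))
  z <- ifelse(on_cyl, s, Lp + R * sin(alpha))
  cbind(rho * cos(theta), rho * sin(theta), z)
}

# z-centroid of the forespore compartment (cylinder + polar cap); used as
# the reference centre for engulfment angles
forespore_center <- function(geom) {
  R <- geom$cell_radius; Lp <- geom$cap_extent
  v_cyl <- pi * R^2 * Lp
  v_cap <- 2 * pi * R^3 / 3
  zc <- (v_cyl * Lp / 2 + v_cap * (Lp + 3 * R / 8)) / (v_cyl + v_cap)
  c(0, 0, zc)
}

#' Build the static lateral-wall surface
#'
#' The old cell wall is treated as a rigid surface: a cylinder of radius R
#' about the long axis joined smoothly to the hemispherical polar cap. The
#' returned object answers signed-distance and inward-normal queries and is
#' consumed by [wall_exclusion_force()]. Sign convention: negative inside
#' the allowed region, positive for points that have penetrated outward
#' through the wall.
#'
#' @param geom a [forespore_geometry()].
#' @param cfg a [simulation_config()] (supplies the exclusion stiffness).
#' @return An object of class `wall_surface` with fields `R`, `cap_z`
#'   (z of the cap centre) and `k_wall`.
#' @export
build_lateral_wall <- function(geom, cfg = simulation_config()) {
  structure(list(R = geom$cell_radius, cap_z = geom$cap_extent,
                 k_wall = cfg$k_wall, geom = geom),
            class = "wall_surface")
}

#' @export
print.wall_surface <- function(x, ...) {
  cat(sprintf("<wall_surface> cylinder R = %.4g nm, cap centre z = %.4g nm, k_wall = %.3g pN/nm\n",
              x$R, x$cap_z, x$k_wall))
  invisible(x)
}

#' Signed distance from the old-wall surface
#'
#' @param wall a [build_lateral_wall()] surface.
#' @param points n x 3 matrix of positions, nm.
#' @return numeric vector of signed distances, nm (positive outside the
#'   wall, negative inside the allowed region).
#' @export
wall_signed_distance <- function(wall, points) {
  points <- rbind(points)
  wall_distance_cpp(points, wall$R, wall$cap_z)
}

#' Inward normal of the old-wall surface
#'
#' @param wall a [build_lateral_wall()] surface.
#' @param points n x 3 matrix of positions, nm.
#' @return n x 3 matrix of unit normals pointing toward the long axis
#'   (i.e. back into the allowed region).
#' @export
wall_inward_normal <- function(wall, points) {
  points <- rbind(points)
  out <- matrix(0, nrow(points), 3)
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    if (p[3] <= wall$cap_z) {
      rho <- sqrt(p[1]^2 + p[2]^2)
      n <- if (rho < 1e-12) c(1, 0, 0) else c(p[1] / rho, p[2] / rho, 0)
    } else {
      d <- p - c(0, 0, wall$cap_z)
      nd <- sqrt(sum(d^2))
      n <- if (nd < 1e-12) c(0, 0, 1) else d / nd
    }
    out[i, ] <- -n
  }
  out
}
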