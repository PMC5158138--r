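# Quantification of membrane contours extracted from fluorescence movies.
# Contours are ordered (x, y) polylines in um per compartment (mother,
# forespore), implicitly closed, with optional per-point intensities.
# File format: CSV with columns
#   cell_id, frame, time_min, compartment, point_index, x_um, y_um[, intensity]

#' Construct a single membrane-contour frame
#'
#' @param time frame time, min.
#' @param forespore data.frame with x, y (um) and optional intensity.
#' @param mother data.frame with x, y (um) and optional intensity.
#' @return object of class `contour_frame`.
#' @export
contour_frame <- function(time, forespore, mother = NULL) {
  for (df in list(forespore, mother)) {
    if (!is.null(df) && nrow(df) < 8)
      stop("contour needs at least 8 points")
  }
  structure(list(time = time, forespore = forespore, mother = mother),
            class = "contour_frame")
}

#' Read / write contour series CSV
#'
#' @param path CSV file.
#' @return `read_contours`: named list of cells, each a list of
#'   `contour_frame`s ordered by time. `write_contours`: `path`.
#' @export
read_contours <- function(path) {
  df <- read.csv(path)
  need <- c("cell_id", "frame", "time_min", "compartment", "point_index",
            "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("contour CSV must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (cid in unique(df$cell_id)) {
    dc <- df[df$cell_id == cid, ]
    frames <- list()
    for (fr in sort(unique(dc$frame))) {
      dd <- dc[dc$frame == fr, ]
      get <- function(comp) {
        ds <- dd[dd$compartment == comp, ]
        if (!nrow(ds)) return(NULL)
        ds <- ds[order(ds$point_index), ]
        res <- data.frame(x = ds$x_um, y = ds$y_um)
        if ("intensity" %in% names(ds)) res$intensity <- ds$intensity
        res
      }
      frames[[length(frames) + 1]] <-
        contour_frame(dd$time_min[1], get("forespore"), get("mother"))
    }
    out[[as.character(cid)]] <- frames
  }
  out
}

#' @rdname read_contours
#' @param cells named list of cells as returned by [read_contours()].
#' @export
write_contours <- function(cells, path) {
  rows <- list()
  for (cid in names(cells)) {
    for (fr in seq_along(cells[[cid]])) {
      frame <- cells[[cid]][[fr]]
      for (comp in c("forespore", "mother")) {
        df <- frame[[comp]]
        if (is.null(df)) next
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = cid, frame = fr, time_min = frame$time,
          compartment = comp, point_index = seq_len(nrow(df)) - 1L,
          x_um = df$x, y_um = df$y,
          intensity = if ("intensity" %in% names(df)) df$intensity else NA)
      }
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

poly_centroid <- function(df) c(mean(df$x), mean(df$y))

# curvature (1/um) of the septal mid-profile: quadratic fit, in the frame
# of the local chord, to the fraction of forespore contour points closest
# to the mother centroid (robust against point noise, unlike a circle fit
# through a near-flat arc)
septal_curvature <- function(frame, frac = 0.25) {
  fs <- frame$forespore
  mc <- if (!is.null(frame$mother)) poly_centroid(frame$mother)
        else c(mean(fs$x), min(fs$y) - 1)
  d <- sqrt((fs$x - mc[1])^2 + (fs$y - mc[2])^2)
  keep <- order(d)[seq_len(max(7L, round(frac * nrow(fs))))]
  x <- fs$x[keep]; y <- fs$y[keep]
  # rotate so the chord (principal axis) is horizontal
  xc <- x - mean(x); yc <- y - mean(y)
  sv <- svd(cbind(xc, yc))
  u <- cbind(xc, yc) %*% sv$v
  fit <- tryCatch(stats::lm.fit(cbind(1, u[, 1], u[, 1]^2), u[, 2]),
                  error = function(e) NULL)
  if (is.null(fit)) return(0)
  c1 <- fit$coefficients[2]; c2 <- fit$coefficients[3]
  if (!is.finite(c2)) return(0)
  abs(2 * c2) / (1 + c1^2)^1.5
}

# unconstrained Kasa circle fit in the plane
fit_circle_2d <- function(x, y) {
  X <- cbind(2 * x, 2 * y, 1)
  coef <- tryCatch(qr.solve(X, x^2 + y^2), error = function(e) rep(NaN, 3))
  r2 <- coef[3] + coef[1]^2 + coef[2]^2
  list(cx = coef[1], cy = coef[2],
       radius = if (is.finite(r2) && r2 > 0) sqrt(r2) else Inf)
}

#' Detect the onset of septum curving (time zero)
#'
#' Movies are aligned at the onset of septum curving. The septal
#' mid-profile curvature is estimated per frame by a circle fit to the
#' mother-proximal portion of the forespore contour; the onset is the first
#' frame whose curvature exceeds the flat-septum baseline (median of the
#' first `baseline_frames` frames) by `threshold`.
#'
#' @param frames list of `contour_frame`s, time-ordered.
#' @param threshold curvature increase over baseline, 1/um.
#' @param baseline_frames frames used for the flat-septum baseline.
#' @return list with `onset` (frame index, or NA), `time` (min, or NA),
#'   `curvature` (per-frame values) and `no_onset` flag.
#' @export
align_time_zero <- function(frames, threshold = 0.5, baseline_frames = 3L) {
  if (length(frames) < 3) stop("need at least 3 frames")
  kappa <- vapply(frames, septal_curvature, numeric(1))
  base <- median(kappa[seq_len(min(baseline_frames, length(kappa)))])
  hit <- which(kappa > base + threshold)
  if (!length(hit))
    return(list(onset = NA_integer_, time = NA_real_, curvature = kappa,
                no_onset = TRUE))
  list(onset = hit[1],
       time = frames[[hit[1]]]$time,
       curvature = kappa, no_onset = FALSE)
}

# angles (degrees, in [-180, 180)) of forespore contour points in the
# mother-forespore frame: origin at the forespore centroid, 0 at the point
# nearest the mother centre of mass, positive counter-clockwise
contour_angles <- function(frame) {
  fs <- frame$forespore
  fc <- poly_centroid(fs)
  mc <- if (!is.null(frame$mother)) poly_centroid(frame$mother)
        else c(fc[1], fc[2] - 1)
  a0 <- atan2(mc[2] - fc[2], mc[1] - fc[1])
  a <- atan2(fs$y - fc[2], fs$x - fc[1]) - a0
  ((a * 180 / pi + 180) %% 360) - 180
}

# periodic resampling of intensity vs angle by local third-order
# (4-point Lagrange) interpolation with periodic wrap; being local, it
# reproduces polynomial intensity profiles up to cubic exactly
resample_periodic <- function(angle, intensity, grid) {
  o <- order(angle)
  a <- angle[o]; y <- intensity[o]
  keep <- c(TRUE, diff(a) > 1e-9)
  a <- a[keep]; y <- y[keep]
  n <- length(a)
  if (n < 4) return(approx(c(a - 360, a, a + 360), rep(y, 3), xout = grid,
                           rule = 2)$y)
  ap <- c(a - 360, a, a + 360)
  yp <- rep(y, 3)
  i1 <- findInterval(grid, ap) # grid in [-180, 180) falls inside the pad
  out <- numeric(length(grid))
  for (q in seq_along(grid)) {
    id <- (i1[q] - 1):(i1[q] + 2)
    x <- ap[id]; v <- yp[id]; g <- grid[q]
    s <- 0
    for (m in 1:4) {
      L <- 1
      for (r in setdiff(1:4, m)) L <- L * (g - x[r]) / (x[m] - x[r])
      s <- s + v[m] * L
    }
    out[q] <- s
  }
  out
}

#' Build a population-average kymograph
#'
#' For every aligned frame of every cell, forespore contour intensities are
#' normalized by the cell's mean contour intensity, mapped to angles in the
#' mother-forespore frame, resampled onto a common angle grid by
#' piecewise-cubic interpolation with periodic wrap, and averaged across
#' cells per (angle, time) bin. Bins with no contributing cell are missing
#' (NA), not zero.
#'
#' @param cells list of cells, each a time-ordered list of `contour_frame`s
#'   already aligned at time zero (frame i of every cell is averaged with
#'   frame i of every other cell).
#' @param angle_bin grid spacing, degrees.
#' @return object of class `kymograph`: `angle` (bin centres, degrees),
#'   `time` (min), `grid` (time x angle matrix of normalized intensity),
#'   `n_cells`.
#' @export
build_average_kymograph <- function(cells, angle_bin = 1) {
  grid <- seq(-180, 180 - angle_bin, by = angle_bin)
  n_frames <- min(vapply(cells, length, integer(1)))
  acc <- matrix(0, n_frames, length(grid))
  cnt <- matrix(0L, n_frames, length(grid))
  times <- numeric(n_frames)
  for (cell in cells) {
    for (i in seq_len(n_frames)) {
      frame <- cell[[i]]
      times[i] <- frame$time
      if (is.null(frame$forespore$intensity)) next
      inten <- frame$forespore$intensity
      m <- mean(inten)
      if (m <= 0) next
      v <- resample_periodic(contour_angles(frame), inten / m, grid)
      ok <- is.finite(v)
      acc[i, ok] <- acc[i, ok] + v[ok]
      cnt[i, ok] <- cnt[i, ok] + 1L
    }
  }
  g <- acc / ifelse(cnt > 0, cnt, NA)
  structure(list(angle = grid, time = times, grid = g,
                 n_cells = length(cells)), class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d time rows x %d angle bins, average of %d cell(s)\n",
              nrow(x$grid), length(x$angle), x$n_cells))
  invisible(x)
}

#' Gap arc length between the two leading-edge points
#'
#' Arc length along the forespore contour between the two leading-edge
#' points of the engulfing membrane, measured on the uncovered side; zero
#' when fully engulfed. Also reports the gap angle at the forespore
#' centroid.
#'
#' @param frame a `contour_frame`.
#' @param le_idx integer pair: indices of the LE points on the forespore
#'   contour (1-based). Use `NULL` for a fully engulfed cell (gap 0).
#' @param uncovered_ref optional (x, y) point on the uncovered side; by
#'   default the forespore point farthest from the mother centroid.
#' @return list with `arc` (um) and `angle` (radians).
#' @export
gap_arc_length <- function(frame, le_idx, uncovered_ref = NULL) {
  fs <- frame$forespore
  n <- nrow(fs)
  if (is.null(le_idx)) return(list(arc = 0, angle = 0))
  if (any(le_idx < 1 | le_idx > n)) stop("LE points not on contour")
  fc <- poly_centroid(fs)
  if (is.null(uncovered_ref)) {
    mc <- if (!is.null(frame$mother)) poly_centroid(frame$mother) else fc - c(0, 1)
    d <- sqrt((fs$x - mc[1])^2 + (fs$y - mc[2])^2)
    uncovered_ref <- c(fs$x[which.max(d)], fs$y[which.max(d)])
  }
  seg <- sqrt(diff(c(fs$x, fs$x[1]))^2 + diff(c(fs$y, fs$y[1]))^2)
  i <- le_idx[1]; j <- le_idx[2]
  path_fwd <- function(i, j) { # arc walking i -> j in increasing index
    if (i == j) return(list(arc = 0, idx = integer(0)))
    idx <- if (i < j) i:(j - 1) else c(i:n, seq_len(j - 1))
    list(arc = sum(seg[idx]), idx = idx)
  }
  fwd <- path_fwd(i, j)
  bwd <- path_fwd(j, i)
  # pick the side containing the uncovered reference point
  ref_i <- which.min((fs$x - uncovered_ref[1])^2 + (fs$y - uncovered_ref[2])^2)
  on_fwd <- ref_i %in% fwd$idx
  arc <- if (on_fwd) fwd$arc else bwd$arc
  ang_pts <- atan2(fs$y[c(i, j)] - fc[2], fs$x[c(i, j)] - fc[1])
  w <- (ang_pts[2] - ang_pts[1]) %% (2 * pi)
  ang_ref <- atan2(uncovered_ref[2] - fc[2], uncovered_ref[1] - fc[1])
  gap_angle <- if ((ang_ref - ang_pts[1]) %% (2 * pi) <= w) w else 2 * pi - w
  list(arc = arc, angle = gap_angle)
}

#' Fraction of fluorescence at the leading edge
#'
#' `(ILE - bg) / ((ILE - bg) + (IMC - bg))` per sporangium, where `ILE` and
#' `IMC` are summed intensities over the leading-edge and mother-cell
#' regions and the background is subtracted as mean-per-pixel times region
#' size. Negative background-subtracted totals are clipped to 0 with a
#' warning. Vectorized over sporangia; also reports mean and SEM.
#'
#' @param ILE summed LE intensity (vector over sporangia).
#' @param IMC summed mother-cell intensity.
#' @param background mean background intensity per pixel.
#' @param npix_le,npix_mc region sizes in pixels.
#' @return list with `fraction` (per sporangium; NaN flagged when both
#'   compartments are empty), `mean`, `sem`.
#' @export
gfp_le_fraction <- function(ILE, IMC, background = 0, npix_le = 0,
                            npix_mc = 0) {
  if (any(ILE < 0 | IMC < 0)) stop("intensities must be >= 0")
  le <- ILE - background * npix_le
  mc <- IMC - background * npix_mc
  if (any(le < 0) || any(mc < 0)) {
    warning("background subtraction left negative totals; clipped at 0")
    le <- pmax(le, 0); mc <- pmax(mc, 0)
  }
  tot <- le + mc
  if (any(tot == 0))
    warning("both compartments zero after background subtraction; NaN returned")
  f <- ifelse(tot > 0, le / tot, NaN)
  list(fraction = f, mean = mean(f, na.rm = TRUE),
       sem = if (sum(is.finite(f)) > 1)
         sd(f[is.finite(f)]) / sqrt(sum(is.finite(f))) else NA_real_)
}
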