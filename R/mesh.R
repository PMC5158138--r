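# Internal mesh representation. Beads live in a growable n x 3 position
# matrix; bonds, bending triples, junction tethers and surface triangles are
# growable index matrices with fill counters, so remodeling events append in
# amortized O(1). Bead ids are row indices and are never reused; severed
# bonds are flagged, never deleted, so a removed bond cannot be re-created.

new_mesh <- function(geom, cap_beads = 256L) {
  structure(list(
    pos = matrix(NA_real_, cap_beads, 3),
    n = 0L,
    strand_id = integer(cap_beads),
    idx_on_strand = integer(cap_beads),
    strands = list(),                 # list(id, bead_ids, closed, row_index)
    gly = matrix(NA_real_, 0, 3, dimnames = list(NULL, c("a", "b", "rest"))),
    n_gly = 0L,
    bend = matrix(NA_real_, 0, 4, dimnames = list(NULL, c("i", "j", "k", "phi0"))),
    n_bend = 0L,
    pep = matrix(NA_real_, 0, 5,
                 dimnames = list(NULL, c("a", "b", "rest", "horizontal", "intact"))),
    n_pep = 0L,
    jun = matrix(NA_real_, 0, 8,
                 dimnames = list(NULL, c("bead", "ax", "ay", "az", "rest",
                                         "intact", "birth", "sever_t"))),
    n_jun = 0L,
    tri = matrix(NA_integer_, 0, 3),
    n_tri = 0L,
    leading_edge = integer(0),
    time = 0,
    geom = geom), class = "engulf_mesh")
}

grow_mat <- function(m, need, ncols) {
  if (nrow(m) >= need) return(m)
  add <- max(need - nrow(m), nrow(m), 64L)
  rbind(m, matrix(m[0, ][1], add, ncols,
                  dimnames = list(NULL, colnames(m))))
}

mesh_add_beads <- function(mesh, xyz, strand_id, idx_on_strand) {
  xyz <- rbind(xyz)
  k <- nrow(xyz)
  need <- mesh$n + k
  if (need > nrow(mesh$pos)) {
    add <- max(need - nrow(mesh$pos), nrow(mesh$pos))
    mesh$pos <- rbind(mesh$pos, matrix(NA_real_, add, 3))
    mesh$strand_id <- c(mesh$strand_id, integer(add))
    mesh$idx_on_strand <- c(mesh$idx_on_strand, integer(add))
  }
  ids <- mesh$n + seq_len(k)
  mesh$pos[ids, ] <- xyz
  mesh$strand_id[ids] <- strand_id
  mesh$idx_on_strand[ids] <- idx_on_strand
  mesh$n <- mesh$n + k
  attr(mesh, "new_ids") <- ids
  mesh
}

mesh_add_gly <- function(mesh, a, b, rest) {
  k <- length(a)
  mesh$gly <- grow_mat(mesh$gly, mesh$n_gly + k, 3)
  mesh$gly[mesh$n_gly + seq_len(k), ] <- cbind(a, b, rest)
  mesh$n_gly <- mesh$n_gly + k
  mesh
}

mesh_add_bend <- function(mesh, i, j, k, phi0) {
  m <- length(i)
  mesh$bend <- grow_mat(mesh$bend, mesh$n_bend + m, 4)
  mesh$bend[mesh$n_bend + seq_len(m), ] <- cbind(i, j, k, phi0)
  mesh$n_bend <- mesh$n_bend + m
  mesh
}

mesh_add_pep <- function(mesh, a, b, rest, horizontal) {
  k <- length(a)
  mesh$pep <- grow_mat(mesh$pep, mesh$n_pep + k, 5)
  mesh$pep[mesh$n_pep + seq_len(k), ] <-
    cbind(a, b, rest, as.numeric(horizontal), 1)
  mesh$n_pep <- mesh$n_pep + k
  mesh
}

mesh_add_jun <- function(mesh, bead, anchor, rest, birth = 0, sever_t = Inf) {
  k <- length(bead)
  anchor <- rbind(anchor)
  mesh$jun <- grow_mat(mesh$jun, mesh$n_jun + k, 8)
  mesh$jun[mesh$n_jun + seq_len(k), ] <-
    cbind(bead, anchor, rest, 1, birth, sever_t)
  mesh$n_jun <- mesh$n_jun + k
  mesh
}

mesh_add_tri <- function(mesh, tri, center) {
  tri <- rbind(tri)
  # orient each triangle so its area vector points away from `center`
  p <- mesh$pos
  for (t in seq_len(nrow(tri))) {
    a <- tri[t, 1]; b <- tri[t, 2]; cc <- tri[t, 3]
    u <- p[b, ] - p[a, ]; v <- p[cc, ] - p[a, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    ctr <- (p[a, ] + p[b, ] + p[cc, ]) / 3
    if (sum(nrm * (ctr - center)) < 0) tri[t, ] <- tri[t, c(1, 3, 2)]
  }
  k <- nrow(tri)
  mesh$tri <- grow_mat(mesh$tri, mesh$n_tri + k, 3)
  mesh$tri[mesh$n_tri + seq_len(k), ] <- tri
  mesh$n_tri <- mesh$n_tri + k
  mesh
}

# active views
mesh_pos <- function(mesh) mesh$pos[seq_len(mesh$n), , drop = FALSE]
mesh_gly <- function(mesh) mesh$gly[seq_len(mesh$n_gly), , drop = FALSE]
mesh_pep <- function(mesh) mesh$pep[seq_len(mesh$n_pep), , drop = FALSE]
mesh_jun <- function(mesh) mesh$jun[seq_len(mesh$n_jun), , drop = FALSE]
mesh_tri <- function(mesh) mesh$tri[seq_len(mesh$n_tri), , drop = FALSE]
mesh_bend <- function(mesh) mesh$bend[seq_len(mesh$n_bend), , drop = FALSE]

#' Number of beads in a mesh
#' @param mesh an `engulf_mesh`.
#' @return integer bead count.
#' @export
n_beads <- function(mesh) mesh$n

#' Bead table of a mesh
#' @param mesh an `engulf_mesh`.
#' @return data.frame with id, x, y, z (nm), strand_id, index_on_strand.
#' @export
beads <- function(mesh) {
  p <- mesh_pos(mesh)
  data.frame(id = seq_len(mesh$n), x = p[, 1], y = p[, 2], z = p[, 3],
             strand_id = mesh$strand_id[seq_len(mesh$n)],
             index_on_strand = mesh$idx_on_strand[seq_len(mesh$n)])
}

#' Peptide-bond table of a mesh
#'
#' Bead-to-bead peptide cross-links. Orientation "horizontal" links
#' neighbouring hoops of the same wall layer or a new strand to the old-wall
#' template; "vertical" links successive newly inserted strands.
#'
#' @param mesh an `engulf_mesh`.
#' @return data.frame with bead_a, bead_b, orientation, rest_length, intact.
#' @export
peptide_bonds <- function(mesh) {
  pp <- mesh_pep(mesh)
  data.frame(bead_a = pp[, "a"], bead_b = pp[, "b"],
             orientation = ifelse(pp[, "horizontal"] > 0, "horizontal", "vertical"),
             rest_length = pp[, "rest"], intact = pp[, "intact"] > 0)
}

#' Glycan strands of a mesh
#' @param mesh an `engulf_mesh`.
#' @return list of strands, each with id, bead_ids, closed, row_index.
#' @export
glycan_strands <- function(mesh) mesh$strands

#' @export
print.engulf_mesh <- function(x, ...) {
  cat(sprintf("<engulf_mesh> %d beads, %d strands, %d glycan bonds, %d peptide bonds (%d intact), %d junction tethers (%d intact)\n",
              x$n, length(x$strands), x$n_gly, x$n_pep,
              sum(mesh_pep(x)[, "intact"] > 0), x$n_jun,
              if (x$n_jun) sum(mesh_jun(x)[, "intact"] > 0) else 0L))
  cat(sprintf("  leading edge: %d beads; time %.4g s\n",
              length(x$leading_edge), x$time))
  invisible(x)
}

# triangulate the annulus between two concentric bead rings given their
# azimuth angles; returns an integer matrix of triangles (unoriented)
annulus_triangles <- function(inner_ids, inner_ang, outer_ids, outer_ang) {
  ni <- length(inner_ids); no <- length(outer_ids)
  oi <- order(inner_ang); oo <- order(outer_ang)
  I <- inner_ids[oi]; A <- inner_ang[oi]
  O <- outer_ids[oo]; B <- outer_ang[oo]
  tris <- matrix(NA_integer_, ni + no, 3)
  p <- 1L; q <- 1L; t <- 0L
  nextA <- function(p) if (p < ni) A[p + 1] else A[1] + 2 * pi
  nextB <- function(q) if (q < no) B[q + 1] else B[1] + 2 * pi
  while (p <= ni || q <= no) {
    adv_inner <- if (p > ni) FALSE else if (q > no) TRUE else nextA(p) <= nextB(q)
    t <- t + 1L
    ip <- ((p - 1L) %% ni) + 1L
    iq <- ((q - 1L) %% no) + 1L
    if (adv_inner) {
      ip2 <- (ip %% ni) + 1L
      tris[t, ] <- c(I[ip], I[ip2], O[iq])
      p <- p + 1L
    } else {
      iq2 <- (iq %% no) + 1L
      tris[t, ] <- c(I[ip], O[iq2], O[iq])
      q <- q + 1L
    }
  }
  tris[seq_len(t), , drop = FALSE]
}

#' Build the septal disc mesh
#'
#' Constructs the flat septum as concentric closed glycan hoops in the plane
#' z = 0, cross-linked hoop-to-hoop by peptide bonds. All bonds are created
#' at their as-built separation and closed hoops carry their natural
#' spontaneous bending angle, so a freshly built disc has zero potential
#' energy. The outermost hoop is registered as the leading edge and tethered
#' to the old-wall rim by junction bonds.
#'
#' @param geom a [forespore_geometry()].
#' @param cfg a [simulation_config()].
#' @return An `engulf_mesh` at time 0.
#' @examples
#' mesh <- build_septal_disc(forespore_geometry(100, cap_extent = 50),
#'                           simulation_config())
#' @export
build_septal_disc <- function(geom, cfg = simulation_config()) {
  R <- geom$cell_radius
  if (R < 2 * cfg$l0)
    stop("configuration error: degenerate geometry (cell_radius < 2 * l0)")
  K <- floor(R / cfg$ring_sep)
  if (K < 3)
    stop("configuration error: geometry yields fewer than 3 strand rings")
  spacing <- R / K
  mesh <- new_mesh(geom)
  c0 <- forespore_center(geom)
  ring_ids <- vector("list", K)
  ring_ang <- vector("list", K)
  for (k in seq_len(K)) {
    r_k <- k * spacing
    n_k <- max(3L, round(2 * pi * r_k / cfg$l0))
    ang <- 2 * pi * (seq_len(n_k) - 1) / n_k
    xyz <- cbind(r_k * cos(ang), r_k * sin(ang), 0)
    mesh <- mesh_add_beads(mesh, xyz, strand_id = k,
                           idx_on_strand = seq_len(n_k))
    ids <- attr(mesh, "new_ids")
    ring_ids[[k]] <- ids; ring_ang[[k]] <- ang
    mesh$strands[[k]] <- list(id = k, bead_ids = ids, closed = TRUE,
                              row_index = k)
    nxt <- c(ids[-1], ids[1])
    mesh <- mesh_add_gly(mesh, ids, nxt, rest = 2 * r_k * sin(pi / n_k))
    prv <- c(ids[n_k], ids[-n_k])
    mesh <- mesh_add_bend(mesh, prv, ids, nxt, phi0 = pi - 2 * pi / n_k)
  }
  # hoop-to-hoop peptide bonds: each bead of the smaller (inner) hoop links
  # to the angularly nearest bead of the outer hoop
  p <- mesh_pos(mesh)
  for (k in seq_len(K - 1)) {
    inner <- ring_ids[[k]]; outer <- ring_ids[[k + 1]]
    ai <- ring_ang[[k]]; ao <- ring_ang[[k + 1]]
    part <- vapply(ai, function(a) {
      d <- abs(((ao - a + pi) %% (2 * pi)) - pi)
      outer[which.min(d)]
    }, integer(1))
    rest <- sqrt(rowSums((p[inner, , drop = FALSE] -
                            p[part, , drop = FALSE])^2))
    mesh <- mesh_add_pep(mesh, inner, part, rest, horizontal = TRUE)
    mesh <- mesh_add_tri(mesh, annulus_triangles(inner, ai, outer, ao), c0)
  }
  le <- ring_ids[[K]]
  mesh$leading_edge <- le
  mesh <- mesh_add_jun(mesh, le, mesh_pos(mesh)[le, , drop = FALSE], rest = 0)
  mesh$time <- 0
  mesh
}

#' Validate mesh invariants
#'
#' Reports violated structural invariants: out-of-range or dangling bond
#' references, duplicated (strand, index) pairs, non-finite positions,
#' disconnected components of the bead graph (glycan bonds plus intact
#' peptide bonds) and a leading edge that is not a single angularly ordered
#' ring. An empty report means the mesh is valid.
#'
#' @param mesh an `engulf_mesh`.
#' @return An object of class `validation_report` with a `violations`
#'   data.frame (columns `check`, `detail`).
#' @export
validate_mesh <- function(mesh) {
  bad <- list()
  note <- function(check, detail) bad[[length(bad) + 1L]] <<-
      data.frame(check = check, detail = detail)
  n <- mesh$n
  p <- mesh_pos(mesh)
  if (n > 0 && any(!is.finite(p)))
    note("finite_positions", sprintf("%d non-finite coordinates", sum(!is.finite(p))))
  key <- paste(mesh$strand_id[seq_len(n)], mesh$idx_on_strand[seq_len(n)])
  if (anyDuplicated(key))
    note("unique_strand_index", sprintf("%d duplicated (strand, index) pairs",
                                        sum(duplicated(key))))
  gl <- mesh_gly(mesh)
  if (mesh$n_gly && (any(gl[, "a"] < 1 | gl[, "a"] > n) ||
                     any(gl[, "b"] < 1 | gl[, "b"] > n)))
    note("glycan_bond_refs", "glycan bond references a nonexistent bead")
  pp <- mesh_pep(mesh)
  dangling <- which(pp[, "a"] < 1 | pp[, "a"] > n | pp[, "b"] < 1 | pp[, "b"] > n)
  if (length(dangling))
    note("peptide_bond_refs",
         sprintf("peptide bond(s) %s reference a nonexistent bead",
                 paste(dangling, collapse = ", ")))
  if (mesh$n_pep && any(pp[, "a"] == pp[, "b"]))
    note("peptide_self_bond", "peptide bond joins a bead to itself")
  # connectivity over glycan bonds + intact peptide bonds
  if (n > 1) {
    ea <- c(gl[, "a"], pp[pp[, "intact"] > 0 & !(seq_len(mesh$n_pep) %in% dangling), "a"])
    eb <- c(gl[, "b"], pp[pp[, "intact"] > 0 & !(seq_len(mesh$n_pep) %in% dangling), "b"])
    comp <- graph_components(n, ea, eb)
    if (comp > 1)
      note("connected", sprintf("mesh graph has %d components", comp))
  }
  le <- mesh$leading_edge
  if (length(le)) {
    if (anyDuplicated(le) || any(le < 1 | le > n)) {
      note("leading_edge_ring", "leading edge has duplicate or invalid beads")
    } else if (length(le) > 2) {
      ang <- atan2(p[le, 2], p[le, 1])
      d <- diff(c(ang, ang[1]))
      d <- (d + pi) %% (2 * pi) - pi
      # an ordered ring winds the axis exactly once
      if (abs(abs(sum(d)) - 2 * pi) > 1e-6)
        note("leading_edge_ring", "leading edge is not an ordered ring about the axis")
    }
  } else {
    note("leading_edge_ring", "leading edge is empty")
  }
  out <- structure(list(
    violations = if (length(bad)) do.call(rbind, bad)
    else data.frame(check = character(0), detail = character(0))),
    class = "validation_report")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x$violations) == 0) {
    cat("<validation_report> mesh valid (no violations)\n")
  } else {
    cat("<validation_report>", nrow(x$violations), "violation(s):\n")
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s\n", x$violations$check[i], x$violations$detail[i]))
  }
  invisible(x)
}

#' Is a mesh valid?
#' @param report a [validate_mesh()] report.
#' @return logical.
#' @export
mesh_is_valid <- function(report) nrow(report$violations) == 0

# connected components by breadth-first search
graph_components <- function(n, ea, eb) {
  adj_from <- c(ea, eb); adj_to <- c(eb, ea)
  o <- order(adj_from)
  adj_from <- adj_from[o]; adj_to <- adj_to[o]
  starts <- c(1, cumsum(tabulate(adj_from, n)) + 1)
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (starts[v] <= starts[v + 1] - 1) {
        nb <- adj_to[starts[v]:(starts[v + 1] - 1)]
        new <- nb[!seen[nb]]
        seen[new] <- TRUE
        queue <- c(queue, new)
      }
    }
  }
  comps
}

#' Total potential energy of a mesh
#'
#' Sum of the conservative contributions: glycan springs, bending, intact
#' peptide bonds, junction tethers and (when a wall is supplied) the
#' old-wall exclusion. The pressure term is an external driving force and
#' carries no potential here.
#'
#' @param mesh an `engulf_mesh`.
#' @param cfg a [simulation_config()].
#' @param wall optional [build_lateral_wall()] surface.
#' @return energy in pN nm.
#' @export
total_energy <- function(mesh, cfg, wall = NULL) {
  p <- mesh_pos(mesh)
  gl <- mesh_gly(mesh)
  e <- bonds_energy_cpp(p, as.integer(gl[, "a"]), as.integer(gl[, "b"]),
                        gl[, "rest"], rep(cfg$kgly, nrow(gl)))
  bd <- mesh_bend(mesh)
  if (nrow(bd))
    e <- e + bend_energy_cpp(p, matrix(as.integer(bd[, 1:3]), ncol = 3),
                             bd[, 4], bending_modulus(cfg))
  pp <- mesh_pep(mesh)
  pp <- pp[pp[, "intact"] > 0, , drop = FALSE]
  if (nrow(pp))
    e <- e + bonds_energy_cpp(p, as.integer(pp[, "a"]), as.integer(pp[, "b"]),
                              pp[, "rest"], rep(cfg$kpep, nrow(pp)))
  jn <- mesh_jun(mesh)
  jn <- jn[jn[, "intact"] > 0, , drop = FALSE]
  if (nrow(jn))
    e <- e + anchor_energy_cpp(p, as.integer(jn[, "bead"]),
                               jn[, c("ax", "ay", "az"), drop = FALSE],
                               jn[, "rest"], cfg$kpep)
  if (!is.null(wall))
    e <- e + wall_energy_cpp(p, wall$R, wall$cap_z, wall$k_wall)
  e
}

bending_modulus <- function(cfg) cfg$lp * cfg$kBT / cfg$l0

#' Write a mesh snapshot to a directory of plain-text tables
#'
#' Layout: `beads.csv` (id, x, y, z, strand, index), `strands.csv`,
#' `glycan_bonds.csv`, `peptide_bonds.csv` (a, b, orientation, rest_length,
#' intact), `junctions.csv`, `leading_edge.csv`, `triangles.csv` and
#' `meta.yaml` (time_s, geometry).
#'
#' @param mesh an `engulf_mesh`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mesh_snapshot <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  w(beads(mesh), "beads.csv")
  w(do.call(rbind, lapply(mesh$strands, function(s)
    data.frame(id = s$id, closed = s$closed, row_index = s$row_index,
               bead_ids = paste(s$bead_ids, collapse = " ")))), "strands.csv")
  gl <- mesh_gly(mesh)
  w(data.frame(a = gl[, "a"], b = gl[, "b"], rest_length = gl[, "rest"]),
    "glycan_bonds.csv")
  w(peptide_bonds(mesh), "peptide_bonds.csv")
  jn <- mesh_jun(mesh)
  w(data.frame(bead = jn[, "bead"], ax = jn[, "ax"], ay = jn[, "ay"],
               az = jn[, "az"], rest_length = jn[, "rest"],
               intact = jn[, "intact"] > 0, birth_s = jn[, "birth"]),
    "junctions.csv")
  w(data.frame(bead = mesh$leading_edge), "leading_edge.csv")
  tr <- mesh_tri(mesh)
  w(data.frame(a = tr[, 1], b = tr[, 2], c = tr[, 3]), "triangles.csv")
  bd <- mesh_bend(mesh)
  w(data.frame(i = bd[, 1], j = bd[, 2], k = bd[, 3], phi0 = bd[, 4]),
    "bend_triples.csv")
  yaml::write_yaml(list(time_s = mesh$time,
                        cell_radius_nm = mesh$geom$cell_radius,
                        cap_extent_nm = mesh$geom$cap_extent),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a mesh snapshot written by [write_mesh_snapshot()]
#'
#' @param dir snapshot directory.
#' @return An `engulf_mesh`.
#' @export
read_mesh_snapshot <- function(dir) {
  r <- function(f) read.csv(file.path(dir, f))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  geom <- forespore_geometry(meta$cell_radius_nm, cap_extent = meta$cap_extent_nm)
  b <- r("beads.csv")
  mesh <- new_mesh(geom, cap_beads = nrow(b))
  mesh <- mesh_add_beads(mesh, as.matrix(b[, c("x", "y", "z")]),
                         b$strand_id, b$index_on_strand)
  st <- r("strands.csv")
  for (i in seq_len(nrow(st)))
    mesh$strands[[i]] <- list(id = st$id[i],
                              bead_ids = as.integer(strsplit(st$bead_ids[i], " ")[[1]]),
                              closed = st$closed[i], row_index = st$row_index[i])
  gl <- r("glycan_bonds.csv")
  if (nrow(gl)) mesh <- mesh_add_gly(mesh, gl$a, gl$b, gl$rest_length)
  pp <- r("peptide_bonds.csv")
  if (nrow(pp)) {
    mesh <- mesh_add_pep(mesh, pp$bead_a, pp$bead_b, pp$rest_length,
                         pp$orientation == "horizontal")
    mesh$pep[seq_len(nrow(pp)), "intact"] <- as.numeric(pp$intact)
  }
  jn <- r("junctions.csv")
  if (nrow(jn)) {
    mesh <- mesh_add_jun(mesh, jn$bead, as.matrix(jn[, c("ax", "ay", "az")]),
                         jn$rest_length, birth = jn$birth_s)
    mesh$jun[seq_len(nrow(jn)), "intact"] <- as.numeric(jn$intact)
  }
  bd <- r("bend_triples.csv")
  if (nrow(bd)) mesh <- mesh_add_bend(mesh, bd$i, bd$j, bd$k, bd$phi0)
  tr <- r("triangles.csv")
  if (nrow(tr)) {
    mesh$tri <- grow_mat(mesh$tri, nrow(tr), 3)
    mesh$tri[seq_len(nrow(tr)), ] <- as.matrix(tr[, c("a", "b", "c")])
    mesh$n_tri <- nrow(tr)
  }
  mesh$leading_edge <- r("leading_edge.csv")$bead
  mesh$time <- meta$time_s
  mesh
}
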