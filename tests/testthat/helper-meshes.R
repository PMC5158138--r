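# Small meshes and independent oracles used across the suite. All fixtures
# are built in code; no data files.

test_geom <- function(R = 120, Lp = 60) forespore_geometry(R, cap_extent = Lp)

# raw 2-bead mesh joined by one glycan bond (rest length `rest`)
two_bead_mesh <- function(d, rest, geom = test_geom()) {
  m <- engulfsim:::new_mesh(geom)
  m <- engulfsim:::mesh_add_beads(m, rbind(c(0, 0, 10), c(d, 0, 10)), 1L, 1:2)
  m$strands[[1]] <- list(id = 1L, bead_ids = 1:2, closed = FALSE, row_index = 1)
  engulfsim:::mesh_add_gly(m, 1L, 2L, rest)
}

# raw 2-bead mesh joined by one (vertical) peptide bond
two_bead_pep_mesh <- function(d, rest, geom = test_geom()) {
  m <- engulfsim:::new_mesh(geom)
  m <- engulfsim:::mesh_add_beads(m, rbind(c(0, 0, 10), c(d, 0, 10)), 1L, 1:2)
  m$strands[[1]] <- list(id = 1L, bead_ids = 1:2, closed = FALSE, row_index = 1)
  engulfsim:::mesh_add_pep(m, 1L, 2L, rest, horizontal = FALSE)
}

# open chain of n beads along x with spontaneous angle phi0 (pi = straight)
chain_mesh <- function(pos, phi0 = pi, geom = test_geom()) {
  n <- nrow(pos)
  m <- engulfsim:::new_mesh(geom)
  m <- engulfsim:::mesh_add_beads(m, pos, 1L, seq_len(n))
  m$strands[[1]] <- list(id = 1L, bead_ids = seq_len(n), closed = FALSE,
                         row_index = 1)
  m <- engulfsim:::mesh_add_gly(m, seq_len(n - 1), 2:n,
                                sqrt(rowSums((pos[-1, , drop = FALSE] -
                                                pos[-n, , drop = FALSE])^2)))
  if (n >= 3)
    m <- engulfsim:::mesh_add_bend(m, 1:(n - 2), 2:(n - 1), 3:n,
                                   rep(phi0, n - 2))
  m
}

# closed regular hoop of n beads, radius R, in the z = z0 plane
hoop_mesh <- function(n, R, z0 = 10, phi0 = pi, geom = test_geom(500, 100)) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(R * cos(ang), R * sin(ang), z0)
  m <- engulfsim:::new_mesh(geom)
  m <- engulfsim:::mesh_add_beads(m, pos, 1L, seq_len(n))
  m$strands[[1]] <- list(id = 1L, bead_ids = seq_len(n), closed = TRUE,
                         row_index = 1)
  nxt <- c(2:n, 1L)
  m <- engulfsim:::mesh_add_gly(m, seq_len(n), nxt, 2 * R * sin(pi / n))
  prv <- c(n, seq_len(n - 1))
  engulfsim:::mesh_add_bend(m, prv, seq_len(n), nxt, rep(phi0, n))
}

# raw closed lat-long sphere mesh (positions + outward-oriented triangles)
sphere_mesh <- function(n_lat = 16, n_lon = 24, R = 50) {
  th <- seq(0, pi, length.out = n_lat + 2)[2:(n_lat + 1)]
  pos <- do.call(rbind, lapply(th, function(t)
    cbind(R * sin(t) * cos(2 * pi * (0:(n_lon - 1)) / n_lon),
          R * sin(t) * sin(2 * pi * (0:(n_lon - 1)) / n_lon),
          R * cos(t))))
  pos <- rbind(pos, c(0, 0, R), c(0, 0, -R))
  id <- function(i, j) (i - 1) * n_lon + ((j - 1) %% n_lon) + 1
  tri <- list()
  for (i in 1:(n_lat - 1)) for (j in 1:n_lon) {
    tri[[length(tri) + 1]] <- c(id(i, j), id(i, j + 1), id(i + 1, j))
    tri[[length(tri) + 1]] <- c(id(i, j + 1), id(i + 1, j + 1), id(i + 1, j))
  }
  apx <- n_lat * n_lon + 1
  for (j in 1:n_lon) {
    tri[[length(tri) + 1]] <- c(apx, id(1, j), id(1, j + 1))
    tri[[length(tri) + 1]] <- c(apx + 1, id(n_lat, j + 1), id(n_lat, j))
  }
  tri <- do.call(rbind, tri)
  for (t in seq_len(nrow(tri))) { # orient area vectors outward
    a <- pos[tri[t, 1], ]; b <- pos[tri[t, 2], ]; cc <- pos[tri[t, 3], ]
    u <- b - a; v <- cc - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    if (sum(nrm * (a + b + cc) / 3) < 0) tri[t, ] <- tri[t, c(1, 3, 2)]
  }
  list(pos = pos, tri = tri, R = R)
}

# central finite-difference gradient of an energy functional at bead i
fd_force <- function(mesh, i, energy, h = 1e-4) {
  g <- numeric(3)
  for (d in 1:3) {
    m1 <- mesh; m1$pos[i, d] <- m1$pos[i, d] + h
    m2 <- mesh; m2$pos[i, d] <- m2$pos[i, d] - h
    g[d] <- -(energy(m1) - energy(m2)) / (2 * h)
  }
  g
}

# union-find oracle for connected components
uf_components <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  parent <- seq_len(n)
  findr <- function(x) { r <- x; while (parent[r] != r) r <- parent[r]; r }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- findr(edges[e, 1]); b <- findr(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), findr, integer(1))))
}
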