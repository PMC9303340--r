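#' Synthetic hepatocyte meshes and the microstructure grid
#'
#' Hepatocytes are modelled as right prisms with regular square, pentagonal or
#' hexagonal bases, characterised by a single length L: both the base-to-base
#' height and the diameter of the base circumcircle equal L. Shape variability
#' is introduced by randomly displacing the base-polygon vertices in-plane
#' (zero-mean normal displacements, sd = 0.1 L by default) and re-extruding.
#'
#' @name geometry
NULL

# ---- polygon utilities -------------------------------------------------------

polygon_signed_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

segments_intersect <- function(a1, a2, b1, b2) {
  d1 <- a2 - a1; d2 <- b2 - b1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(FALSE)
  t <- ((b1[1] - a1[1]) * d2[2] - (b1[2] - a1[2]) * d2[1]) / den
  u <- ((b1[1] - a1[1]) * d1[2] - (b1[2] - a1[2]) * d1[1]) / den
  eps <- 1e-12
  t > eps && t < 1 - eps && u > eps && u < 1 - eps
}

is_simple_polygon <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  idx <- function(k) ((k - 1) %% n) + 1
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (they share a vertex)
      if (j == i || idx(j + 1) == i || idx(i + 1) == j) next
      if (segments_intersect(p[i, ], p[idx(i + 1), ], p[j, ], p[idx(j + 1), ]))
        return(FALSE)
    }
  }
  TRUE
}

point_in_tri2d <- function(q, a, b, c) {
  s1 <- (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
  s2 <- (c[1] - b[1]) * (q[2] - b[2]) - (c[2] - b[2]) * (q[1] - b[1])
  s3 <- (a[1] - c[1]) * (q[2] - c[2]) - (a[2] - c[2]) * (q[1] - c[1])
  eps <- -1e-12
  (s1 >= eps && s2 >= eps && s3 >= eps)
}

# Ear-clipping triangulation of a simple CCW polygon; returns an (n-2) x 3
# matrix of vertex indices. Deterministic and robust for mild perturbations.
ear_clip <- function(p) {
  n <- nrow(p)
  stopifnot(n >= 3)
  active <- seq_len(n)
  tris <- matrix(0L, nrow = n - 2, ncol = 3)
  k <- 0L
  guard <- 0L
  while (length(active) > 3) {
    m <- length(active)
    clipped <- FALSE
    for (ii in seq_len(m)) {
      i0 <- active[((ii - 2) %% m) + 1]
      i1 <- active[ii]
      i2 <- active[(ii %% m) + 1]
      a <- p[i0, ]; b <- p[i1, ]; c <- p[i2, ]
      cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (cross <= 1e-14) next            # reflex or degenerate corner
      others <- setdiff(active, c(i0, i1, i2))
      blocked <- FALSE
      for (o in others) if (point_in_tri2d(p[o, ], a, b, c)) { blocked <- TRUE; break }
      if (blocked) next
      k <- k + 1L
      tris[k, ] <- c(i0, i1, i2)
      active <- active[-ii]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      guard <- guard + 1L
      if (guard > 2L) stop("ear_clip: polygon could not be triangulated")
    }
  }
  k <- k + 1L
  tris[k, ] <- active
  tris
}

# ---- prism construction ------------------------------------------------------

regular_base <- function(base_sides, L) {
  r <- L / 2
  ang <- 2 * pi * (seq_len(base_sides) - 1) / base_sides
  cbind(r * cos(ang), r * sin(ang))
}

extrude_base <- function(base, L, L_nominal, base_sides, shape_id) {
  if (polygon_signed_area(base) < 0) base <- base[rev(seq_len(nrow(base))), ]
  n <- nrow(base)
  h <- L / 2
  verts <- rbind(cbind(base, -h), cbind(base, +h))
  bt <- ear_clip(base)
  faces <- rbind(
    bt[, c(1, 3, 2), drop = FALSE],          # bottom, outward -z
    bt + n,                                  # top, outward +z
    do.call(rbind, lapply(seq_len(n), function(i) {
      j <- (i %% n) + 1
      rbind(c(i, j, j + n), c(i, j + n, i + n))
    }))
  )
  mesh <- structure(
    list(vertices = verts, faces = faces, L_nominal = L_nominal,
         base_sides = base_sides, shape_id = shape_id, base_polygon = base),
    class = "tri_mesh")
  # recentre at the solid's centroid so perturbed cells stay centred
  ctr <- mesh_centroid(mesh)
  mesh$vertices <- sweep(mesh$vertices, 2, ctr)
  mesh
}

#' Build an unperturbed regular prism cell
#'
#' The base polygon is regular with circumcircle diameter `L`; the prism
#' height is also `L`; the centroid sits at the origin.
#'
#' @param base_sides Number of base-polygon sides: 4, 5 or 6.
#' @param L Characteristic length in micrometres (> 0).
#' @return A `tri_mesh`: list with `vertices` (V x 3, um), `faces`
#'   (F x 3 vertex indices, outward-oriented), `L_nominal`, `base_sides`,
#'   `shape_id` and the 2-D `base_polygon`.
#' @examples
#' m <- make_prism(6, 30)
#' mesh_volume(m)  # (3*sqrt(3)/2) * 15^2 * 30
#' @export
make_prism <- function(base_sides, L) {
  if (!base_sides %in% c(4L, 5L, 6L)) stop("base_sides must be 4, 5 or 6")
  if (!is.finite(L) || L <= 0) stop("L must be positive")
  extrude_base(regular_base(base_sides, L), L, L, as.integer(base_sides), 0L)
}

#' Perturb a prism cell's base polygon
#'
#' Displaces the base-polygon vertices in-plane by independent zero-mean
#' normal draws with standard deviation `sigma_frac * L_nominal`, then
#' re-extrudes to height L (both bases share the perturbed footprint). If a
#' draw produces a self-intersecting base, a fresh sub-seed is tried, up to
#' `max_retry` times.
#'
#' @param mesh A `tri_mesh` from [make_prism()].
#' @param sigma_frac Displacement sd as a fraction of `L_nominal` (default 0.1).
#' @param seed Integer seed; the result is deterministic for a fixed seed.
#' @param shape_id Identifier stored on the output (default `mesh$shape_id + 1`).
#' @param max_retry Bounded number of re-draws on self-intersection.
#' @return A watertight `tri_mesh`.
#' @export
perturb_cell <- function(mesh, sigma_frac = 0.1, seed = 1L,
                         shape_id = mesh$shape_id + 1L, max_retry = 20L) {
  stopifnot(inherits(mesh, "tri_mesh"), sigma_frac >= 0)
  L <- mesh$L_nominal
  base <- mesh$base_polygon
  if (sigma_frac == 0) {
    out <- mesh
    out$shape_id <- as.integer(shape_id)
    return(out)
  }
  for (attempt in seq_len(max_retry)) {
    d <- with_seed(derive_seed(seed, attempt - 1L),
                   matrix(rnorm(length(base), sd = sigma_frac * L), ncol = 2))
    cand <- base + d
    if (abs(polygon_signed_area(cand)) < 1e-6 * L^2) next
    if (!is_simple_polygon(cand)) next
    m <- tryCatch(extrude_base(cand, L, L, mesh$base_sides, as.integer(shape_id)),
                  error = function(e) NULL)
    if (!is.null(m) && is_watertight(m)) return(m)
  }
  stop("perturb_cell: no valid perturbation found within retry budget")
}

#' Generate the shape ensemble for one cell size
#'
#' Produces `3 * perturb_per_base` unique shapes (square, pentagonal and
#' hexagonal bases, each perturbed `perturb_per_base` times). The default
#' replicates the 15-shape ensemble (3 base types x 5 perturbations).
#'
#' @param L Characteristic length (um).
#' @param perturb_per_base Perturbations per base type (default 5).
#' @param sigma_frac Perturbation scale (default 0.1).
#' @param seed Integer seed.
#' @return List of `tri_mesh` objects with `shape_id` 0..S-1.
#' @export
make_cell_shapes <- function(L, perturb_per_base = 5L, sigma_frac = 0.1,
                             seed = 1L) {
  shapes <- list()
  sid <- 0L
  for (bs in c(4L, 5L, 6L)) {
    proto <- make_prism(bs, L)
    for (p in seq_len(perturb_per_base)) {
      shapes[[sid + 1L]] <- perturb_cell(
        proto, sigma_frac = sigma_frac,
        seed = derive_seed(seed, bs * 1000L + p), shape_id = sid)
      sid <- sid + 1L
    }
  }
  shapes
}

# ---- mesh measures and checks ------------------------------------------------

face_cross_sum <- function(mesh, f) {
  v <- mesh$vertices
  a <- v[mesh$faces[f, 1], ]; b <- v[mesh$faces[f, 2], ]; c <- v[mesh$faces[f, 3], ]
  crossprod_3 <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                                  u[3] * w[1] - u[1] * w[3],
                                  u[1] * w[2] - u[2] * w[1])
  list(a = a, b = b, c = c, cr = crossprod_3(b - a, c - a))
}

#' Enclosed volume of a watertight mesh
#'
#' Signed divergence-theorem volume; positive for consistent outward
#' orientation.
#'
#' @param mesh A `tri_mesh` (or any list with `vertices`/`faces`).
#' @return Volume in cubic micrometres.
#' @export
mesh_volume <- function(mesh) {
  if (!is_watertight(mesh)) stop("mesh_volume: mesh is not watertight")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
             a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
             a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  if (vol <= 0) stop("mesh_volume: non-positive signed volume (orientation?)")
  vol
}

mesh_centroid <- function(mesh) {
  # volume-weighted centroid via tetrahedra against the origin
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
          a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
          a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  w <- det6 / 6
  ctr <- (a + b + c) / 4 * w  # tetra centroid = (0+a+b+c)/4
  colSums(ctr) / sum(w)
}

#' Watertightness check
#'
#' Every undirected edge must be shared by exactly two faces, traversed in
#' opposite directions (consistent orientation).
#'
#' @param mesh A `tri_mesh`.
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tab <- table(key)
  if (any(tab != 2)) return(FALSE)
  dir_key <- paste(he[, 1], he[, 2])
  !any(duplicated(dir_key))  # each directed edge once => opposite traversal
}

#' Euler characteristic V - E + F
#'
#' @param mesh A `tri_mesh`.
#' @return Integer; 2 for a closed genus-0 surface.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- length(unique(paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))))
  nrow(mesh$vertices) - e + nrow(f)
}

#' Point containment test
#'
#' Ray-crossing parity with watertight-safe handling of grazing rays; points
#' within `tol` of the surface count as inside.
#'
#' @param mesh A `tri_mesh`.
#' @param points N x 3 matrix of coordinates (um).
#' @param tol Surface tolerance in um (default 1e-6).
#' @return Logical vector of length N.
#' @export
inside_mesh <- function(mesh, points, tol = 1e-6) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_inside_points(mesh$vertices, matrix(as.integer(mesh$faces), ncol = 3),
                    points, tol)
}

#' Monte Carlo volume estimate (oracle for mesh_volume)
#'
#' Uniform sampling in the bounding box with the containment test; used as an
#' independent check on the divergence-theorem volume.
#'
#' @param mesh A `tri_mesh`.
#' @param n Number of sample points.
#' @param seed Integer seed.
#' @return Estimated volume (um^3).
#' @export
mesh_volume_mc <- function(mesh, n = 2e5, seed = 1L) {
  v <- mesh$vertices
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  pts <- with_seed(seed, matrix(runif(3 * n), ncol = 3))
  pts <- sweep(sweep(pts, 2, hi - lo, "*"), 2, lo, "+")
  mean(inside_mesh(mesh, pts, tol = 0)) * prod(hi - lo)
}

# ---- microstructure grid -----------------------------------------------------

#' Build the (D0, L) microstructure grid
#'
#' The default grid spans L in 11..59 um (step 1.5, 33 values) and D0 in
#' 0.20..2.40 um^2/ms (step 0.05, 45 values). A grid point is a valid centre
#' when its pooling neighborhood Omega -- `omega_halfwidth` grid steps in each
#' axis, so a (2h+1) x (2h+1) block -- lies entirely on the grid; with the
#' defaults this leaves 41 x 29 = 1189 centres.
#'
#' @param L_min,L_max,L_step Cell-size lattice (um).
#' @param D0_min,D0_max,D0_step Intrinsic-diffusivity lattice (um^2/ms).
#' @param omega_halfwidth Neighborhood half-width in grid steps (default 2).
#' @return A `micro_grid`: `L_values`, `D0_values`, steps, `omega_halfwidth`
#'   and `centers` (data.frame with indices `i` into D0, `j` into L, and the
#'   values `d0`, `l`).
#' @examples
#' g <- build_grid()
#' nrow(g$centers)  # 1189
#' @export
build_grid <- function(L_min = 11, L_max = 60, L_step = 1.5,
                       D0_min = 0.20, D0_max = 2.40, D0_step = 0.05,
                       omega_halfwidth = 2L) {
  L_values <- round(seq(L_min, L_max, by = L_step), 6)
  D0_values <- round(seq(D0_min, D0_max, by = D0_step), 6)
  h <- as.integer(omega_halfwidth)
  nd <- length(D0_values); nl <- length(L_values)
  if (nd < 2 * h + 1 || nl < 2 * h + 1)
    stop("grid too small for the requested omega_halfwidth")
  ii <- (h + 1):(nd - h)
  jj <- (h + 1):(nl - h)
  centers <- expand.grid(i = ii, j = jj, KEEP.OUT.ATTRS = FALSE)
  centers$d0 <- D0_values[centers$i]
  centers$l <- L_values[centers$j]
  structure(list(L_values = L_values, D0_values = D0_values,
                 L_step = L_step, D0_step = D0_step,
                 omega_halfwidth = h, centers = centers),
            class = "micro_grid")
}

#' Pooling neighborhood of a grid centre
#'
#' @param grid A `micro_grid`.
#' @param i,j Centre indices into `D0_values` and `L_values`.
#' @return Data frame of the (2h+1)^2 Omega members (`i`, `j`, `d0`, `l`).
#' @export
omega_members <- function(grid, i, j) {
  h <- grid$omega_halfwidth
  m <- expand.grid(i = i + (-h:h), j = j + (-h:h), KEEP.OUT.ATTRS = FALSE)
  if (any(m$i < 1 | m$i > length(grid$D0_values) |
          m$j < 1 | m$j > length(grid$L_values)))
    stop("omega_members: neighborhood falls off the grid")
  m$d0 <- grid$D0_values[m$i]
  m$l <- grid$L_values[m$j]
  m
}

#' Read or write a grid definition
#'
#' YAML/JSON config with keys `L_min`, `L_max`, `L_step`, `D0_min`, `D0_max`,
#' `D0_step`, `omega_halfwidth`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `grid_from_config` returns a `micro_grid`.
#' @export
grid_from_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  build_grid(L_min = cfg$L_min, L_max = cfg$L_max, L_step = cfg$L_step,
             D0_min = cfg$D0_min, D0_max = cfg$D0_max, D0_step = cfg$D0_step,
             omega_halfwidth = cfg$omega_halfwidth %||% 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- OFF / PLY (ASCII) -------------------------------------------------------

#' Mesh export and import in OFF and PLY (ASCII)
#'
#' @param mesh A `tri_mesh`.
#' @param path Output file.
#' @rdname mesh_io
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1, function(r) paste(c(3L, r - 1L), collapse = " ")), con)
}

#' @rdname mesh_io
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  stopifnot(trimws(ln[1]) == "OFF")
  hd <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- hd[1]; nf <- hd[2]
  verts <- matrix(as.numeric(unlist(strsplit(trimws(ln[3:(2 + nv)]), "\\s+"))),
                  ncol = 3, byrow = TRUE)
  fl <- strsplit(trimws(ln[(3 + nv):(2 + nv + nf)]), "\\s+")
  faces <- t(vapply(fl, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  structure(list(vertices = verts, faces = faces, L_nominal = NA_real_,
                 base_sides = NA_integer_, shape_id = NA_integer_,
                 base_polygon = NULL), class = "tri_mesh")
}

#' @rdname mesh_io
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1, function(r) paste(c(3L, r - 1L), collapse = " ")), con)
}

#' @rdname mesh_io
#' @export
read_ply <- function(path) {
  ln <- readLines(path)
  stopifnot(trimws(ln[1]) == "ply")
  nv <- as.integer(sub("element vertex ", "", ln[grep("^element vertex", ln)]))
  nf <- as.integer(sub("element face ", "", ln[grep("^element face", ln)]))
  i0 <- grep("^end_header", ln)[1]
  verts <- matrix(as.numeric(unlist(strsplit(trimws(ln[(i0 + 1):(i0 + nv)]), "\\s+"))),
                  ncol = 3, byrow = TRUE)
  fl <- strsplit(trimws(ln[(i0 + nv + 1):(i0 + nv + nf)]), "\\s+")
  faces <- t(vapply(fl, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  structure(list(vertices = verts, faces = faces, L_nominal = NA_real_,
                 base_sides = NA_integer_, shape_id = NA_integer_,
                 base_polygon = NULL), class = "tri_mesh")
}
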