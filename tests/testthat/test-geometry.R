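test_that("prisms have the stated closed-form volumes and closed topology", {
  # square prism: base side L/sqrt(2), so volume L^3/2
  m4 <- make_prism(4, 20)
  expect_equal(mesh_volume(m4), 20^3 / 2, tolerance = 1e-12)
  # hexagonal prism: (3*sqrt(3)/2) * (L/2)^2 * L
  for (L in c(11, 30, 59)) {
    m6 <- make_prism(6, L)
    expect_equal(mesh_volume(m6), 3 * sqrt(3) / 2 * (L / 2)^2 * L,
                 tolerance = 1e-12)
  }
  for (bs in 4:6) {
    m <- make_prism(bs, 25)
    expect_true(is_watertight(m))
    expect_identical(euler_characteristic(m), 2L)
    expect_equal(max(abs(mesh_centroid(m))), 0, tolerance = 1e-9)
  }
  expect_error(make_prism(3, 20), "base_sides")
  expect_error(make_prism(4, -1), "positive")
})

test_that("mesh volume is translation invariant and matches a sampling oracle", {
  m <- perturb_cell(make_prism(5, 20), 0.1, seed = 9)
  v0 <- mesh_volume(m)
  shifted <- m
  shifted$vertices <- sweep(m$vertices, 2, c(5.5, -3.1, 100), "+")
  expect_equal(mesh_volume(shifted), v0, tolerance = 1e-10)

  # Monte Carlo containment oracle within 1% for the full 15-shape ensemble
  shapes <- make_cell_shapes(20, perturb_per_base = 5L, seed = 21L)
  expect_length(shapes, 15L)
  for (s in shapes) {
    expect_true(is_watertight(s))
    expect_identical(euler_characteristic(s), 2L)
    expect_equal(mesh_volume_mc(s, n = 2e5, seed = 5L) / mesh_volume(s), 1,
                 tolerance = 0.01)
  }
})

test_that("perturbation is deterministic, bounded and honours sigma = 0", {
  proto <- make_prism(6, 30)
  p0 <- perturb_cell(proto, 0, seed = 1)
  expect_equal(p0$vertices, proto$vertices)
  a <- perturb_cell(proto, 0.1, seed = 42)
  b <- perturb_cell(proto, 0.1, seed = 42)
  expect_identical(a$vertices, b$vertices)
  c <- perturb_cell(proto, 0.1, seed = 43)
  expect_false(isTRUE(all.equal(a$vertices, c$vertices)))
  # volume sanity band at sigma = 0.1 L: 50%..200% of the unperturbed volume
  v_ref <- mesh_volume(proto)
  for (seed in 1:10) {
    v <- mesh_volume(perturb_cell(proto, 0.1, seed = seed))
    expect_gt(v, 0.5 * v_ref)
    expect_lt(v, 2.0 * v_ref)
  }
})

test_that("shape ensembles contain 3 base types x perturbations", {
  shapes <- make_cell_shapes(15, perturb_per_base = 2L, seed = 2L)
  expect_length(shapes, 6L)
  expect_identical(vapply(shapes, `[[`, integer(1), "base_sides"),
                   rep(c(4L, 5L, 6L), each = 2L))
  expect_identical(vapply(shapes, `[[`, integer(1), "shape_id"), 0:5)
})

test_that("microstructure grid has 1189 valid centres with on-grid neighborhoods", {
  g <- build_grid()
  expect_length(g$L_values, 33L)
  expect_length(g$D0_values, 45L)
  expect_identical(nrow(g$centers), (45L - 4L) * (33L - 4L))
  expect_identical(nrow(g$centers), 1189L)
  # every Omega member of a valid centre lies on the grid
  om <- omega_members(g, g$centers$i[1], g$centers$j[1])
  expect_identical(nrow(om), 25L)
  expect_true(all(om$d0 %in% g$D0_values))
  expect_true(all(om$l %in% g$L_values))
  # the neighborhood spans +/- 2 steps
  ctr <- subset(g$centers, abs(d0 - 1.20) < 1e-9 & abs(l - 35.0) < 1e-9)
  om2 <- omega_members(g, ctr$i, ctr$j)
  expect_setequal(round(unique(om2$l), 6), c(32.0, 33.5, 35.0, 36.5, 38.0))
  expect_setequal(round(unique(om2$d0), 6), c(1.10, 1.15, 1.20, 1.25, 1.30))
  # the corner grid point is not a centre (Omega would fall off-grid)
  expect_false(any(g$centers$d0 == 0.20 & g$centers$l == 11))
  expect_error(omega_members(g, 1L, 1L), "off the grid")
})

test_that("OFF and PLY round-trips preserve geometry", {
  m <- perturb_cell(make_prism(4, 22), 0.1, seed = 5)
  for (io in list(c(write_off, read_off), c(write_ply, read_ply))) {
    f <- tempfile(fileext = ".mesh")
    io[[1]](m, f)
    m2 <- io[[2]](f)
    expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-12)
    expect_identical(matrix(as.integer(m2$faces), ncol = 3),
                     matrix(as.integer(m$faces), ncol = 3))
    expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-10)
    unlink(f)
  }
})

test_that("grid configs read back from YAML and JSON", {
  fy <- tempfile(fileext = ".yaml")
  writeLines(c("L_min: 11", "L_max: 60", "L_step: 1.5", "D0_min: 0.2",
               "D0_max: 2.4", "D0_step: 0.05", "omega_halfwidth: 2"), fy)
  g <- grid_from_config(fy)
  expect_identical(nrow(g$centers), 1189L)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(L_min = 20, L_max = 32, L_step = 3, D0_min = 0.8,
                            D0_max = 1.2, D0_step = 0.1),
                       fj, auto_unbox = TRUE)
  g2 <- grid_from_config(fj)
  expect_identical(nrow(g2$centers), 1L)
  unlink(c(fy, fj))
})
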