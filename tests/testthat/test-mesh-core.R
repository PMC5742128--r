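# Mesh data model, voxel subdivision, region topology and surface geodesics.

test_that("mesh I/O round-trips vertices, tets and labels", {
  lab <- array(c("bone", "saline"), c(2, 1, 1))
  m <- voxel_to_tetmesh(lab, 1e-3)
  path <- file.path(tempdir(), "roundtrip.vtk")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_equal(m2$vertices, m$vertices)
  expect_equal(m2$tets, m$tets)
  expect_equal(m2$region, m$region)

  # single tet file
  single <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                     matrix(1:4, 1), "bone")
  write_mesh(single, path)
  s2 <- read_mesh(path)
  expect_equal(nrow(s2$vertices), 4)
  expect_equal(nrow(s2$tets), 1)
  expect_equal(s2$region, "bone")
})

test_that("validation rejects tets that claim a face through coincident vertices", {
  # two tets share only an edge (vertices 2,3) but duplicate coordinates make
  # them geometrically share a whole face
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(0, 0, 0),                       # duplicate of vertex 1
             c(0, 0, -1))
  tets <- rbind(c(1, 2, 3, 4), c(5, 2, 3, 6))
  expect_error(tet_mesh(v, tets, c("a", "a")), "coincident|duplicated")

  # face shared by >2 tets is also rejected
  v3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, -1),
              c(1, 1, 1))
  t3 <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 5), c(1, 2, 3, 6))
  expect_error(tet_mesh(v3, t3, c("a", "a", "a")), "shared by 3")
})

test_that("voxel subdivision conserves per-label volume and is conforming", {
  m1 <- voxel_to_tetmesh(array("x", c(1, 1, 1)), 1)
  expect_equal(nrow(m1$tets), 6)
  expect_equal(sum(tet_volumes(m1)), 1, tolerance = 1e-12)

  lab <- array(c("A", "B"), c(2, 1, 1))
  m2 <- voxel_to_tetmesh(lab, 1)
  expect_equal(sum(tet_volumes(m2)[m2$region == "A"]), 1, tolerance = 1e-12)
  expect_equal(sum(tet_volumes(m2)[m2$region == "B"]), 1, tolerance = 1e-12)

  # random label field: per-label volume conservation + conformity census
  set.seed(42)
  lab3 <- array(sample(c("p", "q", NA), 4 * 3 * 5, replace = TRUE), c(4, 3, 5))
  h <- c(1e-3, 2e-3, 0.5e-3)
  m3 <- voxel_to_tetmesh(lab3, h)
  for (lev in c("p", "q")) {
    expect_equal(sum(tet_volumes(m3)[m3$region == lev]),
                 sum(lab3 == lev, na.rm = TRUE) * prod(h), tolerance = 1e-12)
  }
  cnt <- vestim:::face_census(m3)$count
  expect_true(all(cnt <= 2))

  expect_error(voxel_to_tetmesh(array("x", c(2, 2, 2)), c(1, 2)), "per-axis")
})

test_that("hollow-cube boundary faces match the brute-force voxel census", {
  lab <- array("X", c(3, 3, 3))
  lab[2, 2, 2] <- NA
  m <- voxel_to_tetmesh(lab, 1)
  # oracle: count exposed voxel faces directly on the label grid
  filled <- !is.na(lab)
  exposed <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    if (!filled[i, j, k]) next
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      nb <- c(i, j, k) + d
      if (any(nb < 1 | nb > 3) || !filled[nb[1], nb[2], nb[3]])
        exposed <- exposed + 1
    }
  }
  fc <- vestim:::face_census(m)
  expect_equal(sum(fc$count == 1), 2 * exposed)  # each quad face = 2 triangles
})

test_that("region interfaces and boundaries agree with exhaustive face scans", {
  lab <- array(c("A", "B"), c(2, 1, 1))
  m <- voxel_to_tetmesh(lab, 1)
  p <- region_interface(m, "A", "B")
  expect_equal(patch_size(p), 2)          # shared quad face = 2 triangles
  expect_true(all(abs(p$normals - rep(c(1, 0, 0), each = 2)) < 1e-12))

  # opposite orientation: same faces, flipped normals
  q <- region_interface(m, "B", "A")
  key <- function(f) sort(apply(f, 1, function(r) paste(sort(r), collapse = "-")))
  expect_equal(key(p$faces), key(q$faces))
  expect_equal(colMeans(q$normals), -colMeans(p$normals))

  # regions not in contact
  lab2 <- array(c("A", "gap", "B"), c(3, 1, 1))
  m2 <- voxel_to_tetmesh(lab2, 1)
  expect_equal(patch_size(region_interface(m2, "A", "B")), 0)
  expect_error(region_interface(m2, "A", "nope"), "unknown region")

  # phantom nerve/endolymph interface area equals a brute-force face scan
  ph <- fx_phantom()
  p3 <- region_interface(ph, "nerve_target", "endolymph")
  ft <- vestim:::tet_face_table(ph)
  fc <- vestim:::face_census(ph, ft)
  o <- fc$order; cnt <- fc$count; ends <- cumsum(cnt)
  two <- which(cnt == 2)
  r1 <- o[ends[two] - 1L]; r2 <- o[ends[two]]
  reg1 <- ph$region[ft$tet[r1]]; reg2 <- ph$region[ft$tet[r2]]
  hit <- (reg1 == "nerve_target" & reg2 == "endolymph") |
         (reg2 == "nerve_target" & reg1 == "endolymph")
  area_oracle <- sum(vestim:::tri_areas(ph$vertices,
                                        ft$sorted[r1[hit], , drop = FALSE]))
  expect_equal(sum(patch_areas(ph, p3)), area_oracle, tolerance = 1e-12)

  # single-tet region boundary = its 4 faces
  mono <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                   matrix(1:4, 1), "solo")
  expect_equal(patch_size(region_boundary(mono, "solo")), 4)

  # saline shell against the exterior is the outer surface only
  ext <- region_boundary(ph, "saline", "exterior")
  expect_gt(patch_size(ext), 0)
  rad <- sqrt(rowSums(ph$vertices[patch_vertices(ext), , drop = FALSE]^2))
  expect_gt(min(rad), 0.030)   # all outer-surface vertices near r = 35 mm

  # fully surrounded region has no exterior faces
  inner <- region_boundary(ph, "endolymph", "exterior")
  expect_equal(patch_size(inner), 0)
})

test_that("geodesic patches follow Dijkstra distances and are monotone in radius", {
  cyl <- fx_cylinder()
  bnd <- region_boundary(cyl, "nerve")
  verts <- patch_vertices(bnd)
  seed <- verts[which.min(rowSums(sweep(cyl$vertices[verts, , drop = FALSE],
                                        2, c(0, 0, 0.01))^2))]

  # radius 0: exactly the triangles incident to the seed
  p0 <- surface_geodesic_patch(cyl, bnd, seed, 0)
  inc <- rowSums(matrix(bnd$faces %in% seed, ncol = 3)) > 0
  expect_equal(patch_size(p0), sum(inc))

  # huge radius: whole surface
  pall <- surface_geodesic_patch(cyl, bnd, seed, 1)
  expect_equal(patch_size(pall), patch_size(bnd))

  # monotone in radius
  radii <- c(0.5e-3, 1e-3, 2e-3, 4e-3, 8e-3)
  sizes <- vapply(radii, function(r)
    patch_size(surface_geodesic_patch(cyl, bnd, seed, r)), numeric(1))
  expect_true(all(diff(sizes) >= 0))

  # triangle selection matches the from-scratch Dijkstra oracle
  r <- 3e-3
  pk <- surface_geodesic_patch(cyl, bnd, seed, r)
  d <- oracle_surface_distances(cyl, bnd, seed)
  dist_of <- numeric(nrow(cyl$vertices))
  dist_of[as.integer(names(d))] <- d
  f <- bnd$faces
  within <- dist_of[f[, 1]] <= r & dist_of[f[, 2]] <= r & dist_of[f[, 3]] <= r
  keep <- within | inc
  key <- function(fc) sort(apply(fc, 1, function(x) paste(sort(x), collapse = "-")))
  expect_equal(key(pk$faces), key(f[keep, , drop = FALSE]))

  expect_error(surface_geodesic_patch(cyl, bnd, 10 * nrow(cyl$vertices), 1e-3),
               "seed vertex")
})
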