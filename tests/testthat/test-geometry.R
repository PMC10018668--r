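test_that("icosphere sampling is on the unit sphere with the expected counts", {
  for (k in 0:3) {
    v <- icosphere(k)
    expect_identical(nrow(v), as.integer(10 * 4^k + 2))
    expect_equal(sqrt(rowSums(v^2)), rep(1, nrow(v)), tolerance = 1e-12)
  }
  # inversion symmetry: the point set contains the antipode of every point
  v <- icosphere(2)
  key <- function(m) apply(round(m, 9), 1, paste, collapse = ",")
  expect_setequal(key(v), key(-v))
})

test_that("sphere targets carry analytic volume, area and on-sphere samples", {
  t <- sphere_target(c(3, -2, 7), 10, label = "a")
  expect_equal(t$volume, pi / 6 * 1000, tolerance = 1e-9)
  expect_equal(t$surface_area, pi * 100, tolerance = 1e-9)
  r <- sqrt(colSums((t(t$points) - c(3, -2, 7))^2))
  expect_equal(r, rep(5, length(r)), tolerance = 1e-6)
  expect_lt(max(abs(colMeans(t$points) - c(3, -2, 7))), 0.01)
  # >= 1 sample per mm^2 by default: area 314.2 -> 642-vertex icosphere
  expect_gte(nrow(t$points), t$surface_area)
  expect_identical(nrow(t$points), 642L)
  expect_error(sphere_target(c(0, 0, 0), -1), "positive")
})

test_that("reference isocenters follow the volume/surface weighting rules", {
  ts <- target_set(
    coarse_sphere(c(0, 0, 0), 5, "a"),
    coarse_sphere(c(100, 0, 0), 10, "b")
  )
  expect_equal(center_of_geometry(ts), c(50, 0, 0))
  # volume weights ~ D^3: x = 100*1000/(125+1000); surface ~ D^2: x = 100*100/125
  expect_equal(center_of_volume(ts)[1], 100 * 1000 / 1125, tolerance = 1e-9)
  expect_equal(center_of_surface(ts)[1], 80, tolerance = 1e-9)
  # COS strictly between COG and COV when one target is larger
  expect_gt(center_of_surface(ts)[1], center_of_geometry(ts)[1])
  expect_lt(center_of_surface(ts)[1], center_of_volume(ts)[1])
  # identical targets: all three coincide with the midpoint
  eq <- target_set(coarse_sphere(c(0, 0, 0), 8, "a"),
                   coarse_sphere(c(60, 0, 0), 8, "b"))
  expect_equal(center_of_volume(eq), center_of_geometry(eq), tolerance = 1e-9)
  expect_equal(center_of_surface(eq), center_of_geometry(eq), tolerance = 1e-9)
  one <- target_set(coarse_sphere(c(4, 5, 6), 12, "only"))
  expect_equal(center_of_volume(one), c(4, 5, 6))
})

test_that("reference isocenters are equivariant under rigid motion", {
  th <- 0.6
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(7, -3, 11)
  mk <- function(centers) {
    target_set(lapply(seq_len(nrow(centers)), function(i) {
      coarse_sphere(centers[i, ], c(5, 10, 15)[i], paste0("t", i))
    }))
  }
  centers <- rbind(c(0, 0, 0), c(80, 0, 0), c(30, 50, 0))
  moved <- sweep(centers %*% t(rot), 2, shift, "+")
  for (fn in list(center_of_geometry, center_of_volume, center_of_surface)) {
    expect_equal(fn(mk(moved)), as.numeric(fn(mk(centers)) %*% t(rot)) + shift,
                 tolerance = 1e-9)
  }
})

test_that("reference isocenters stay inside the centroid convex hull", {
  ts <- phantom_targets("triplet-5-10-20")
  for (p in list(center_of_geometry(ts), center_of_volume(ts),
                 center_of_surface(ts))) {
    # hull of (100,0,0),(0,100,0),(0,0,100): nonnegative coords, sum <= 100
    expect_true(all(p >= -1e-9))
    expect_lte(sum(p), 100 + 1e-9)
  }
})

test_that("surface sampling density barely moves the reference points", {
  lo <- target_set(sphere_target(c(0, 0, 0), 6, "a", density = 1),
                   sphere_target(c(90, 0, 0), 15, "b", density = 1))
  hi <- target_set(sphere_target(c(0, 0, 0), 6, "a", density = 2),
                   sphere_target(c(90, 0, 0), 15, "b", density = 2))
  expect_lt(max(abs(center_of_surface(lo) - center_of_surface(hi))), 0.1)
})

test_that("mesh properties match closed forms and reject bad meshes", {
  cm <- cube_mesh()
  p <- mesh_properties(cm$vertices, cm$faces)
  expect_equal(p$volume, 1, tolerance = 1e-12)
  expect_equal(p$surface_area, 6, tolerance = 1e-12)
  expect_equal(p$centroid, c(0.5, 0.5, 0.5), tolerance = 1e-12)
  # subdivided icosahedron of diameter 10 approaches the sphere volume
  ico <- icosphere(4, faces = TRUE)
  p2 <- mesh_properties(ico$vertices * 5, ico$faces)
  expect_equal(p2$volume, pi / 6 * 1000, tolerance = 5e-3)
  # inward orientation reported
  expect_error(mesh_properties(cm$vertices, cm$faces[, c(1, 3, 2)]),
               "oriented inward")
  # open mesh rejected
  expect_error(mesh_properties(cm$vertices, cm$faces[-1, ]), "not closed")
})

test_that("OFF and ASCII STL meshes round-trip through the readers", {
  cm <- cube_mesh(scale = 2, shift = c(1, 1, 1))
  off <- tempfile(fileext = ".off")
  writeLines(c(
    "OFF",
    sprintf("%d %d 0", nrow(cm$vertices), nrow(cm$faces)),
    apply(cm$vertices, 1, paste, collapse = " "),
    apply(cm$faces - 1, 1, function(f) paste(c(3, f), collapse = " "))
  ), off)
  m1 <- read_mesh(off)
  expect_equal(mesh_properties(m1$vertices, m1$faces)$volume, 8, tolerance = 1e-9)

  stl <- tempfile(fileext = ".stl")
  tri_lines <- unlist(lapply(seq_len(nrow(cm$faces)), function(i) {
    vv <- cm$vertices[cm$faces[i, ], , drop = FALSE]
    c("facet normal 0 0 0", "outer loop",
      apply(vv, 1, function(p) paste("vertex", paste(p, collapse = " "))),
      "endloop", "endfacet")
  }))
  writeLines(c("solid cube", tri_lines, "endsolid cube"), stl)
  m2 <- read_mesh(stl)
  expect_identical(nrow(m2$vertices), 8L)
  expect_equal(mesh_properties(m2$vertices, m2$faces)$volume, 8, tolerance = 1e-9)
  tgt <- mesh_target(m2$vertices, m2$faces, label = "cube")
  expect_equal(tgt$centroid, c(2, 2, 2), tolerance = 1e-9)
  expect_error(read_mesh(tempfile(fileext = ".ply")), "not found")
})

test_that("phantom configurations place the documented spheres", {
  pair <- phantom_targets("pair-5-10")
  expect_identical(pair$n, 2L)
  d <- sqrt(sum((pair$targets[[2]]$centroid - pair$targets[[1]]$centroid)^2))
  expect_equal(d, 100)
  tri <- phantom_targets("triplet-5-10-20")
  cents <- t(sapply(tri$targets, `[[`, "centroid"))
  expect_equal(unname(cents), rbind(c(100, 0, 0), c(0, 100, 0), c(0, 0, 100)))
  expect_equal(center_of_geometry(tri), rep(100 / 3, 3), tolerance = 1e-9)
  hex <- phantom_targets("hex")
  diams <- sapply(hex$targets, function(t) t$sphere$diameter)
  expect_equal(sort(diams), c(4, 8, 10, 12, 16, 18))
  expect_error(phantom_targets("nonsense"), "unknown phantom")
})
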