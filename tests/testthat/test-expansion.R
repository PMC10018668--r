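test_that("rasterized sphere volume converges to the closed form", {
  ts <- target_set(sphere_target(c(0, 0, 0), 10, "s"))
  g <- rasterize_ctv(ts, spacing = 0.5)
  expect_equal(occupied_volume(g), pi / 6 * 1000, tolerance = 0.01)
})

test_that("disjoint targets rasterize to the sum of their voxel counts", {
  a <- coarse_sphere(c(0, 0, 0), 8, "a")
  b <- coarse_sphere(c(40, 0, 0), 12, "b")
  both <- rasterize_ctv(target_set(a, b), spacing = 1)
  va <- occupied_volume(rasterize_ctv(target_set(a), spacing = 1))
  vb <- occupied_volume(rasterize_ctv(target_set(b), spacing = 1))
  expect_equal(occupied_volume(both), va + vb)
})

test_that("zero rotational uncertainty gives a uniform, isocenter-independent shell", {
  ts <- target_set(sphere_target(c(0, 0, 0), 10, "s"))
  u0 <- setup_uncertainty(m_s = 2, sigma_d = 0)
  v1 <- margin_volume(ts, c(0, 0, 0), u0, spacing = 0.5)
  v2 <- margin_volume(ts, c(150, -40, 12), u0, spacing = 0.5)
  expect_identical(v1$v_margin, v2$v_margin)  # identical occupancy counts
  shell <- 4 / 3 * pi * (7^3 - 5^3)
  # default sampling (>=1 pt/mm^2): small union-of-balls sag under-fills a bit
  expect_equal(v1$v_margin, shell, tolerance = 0.025)
  # denser sampling isolates voxelization error: within 1% of the closed form
  dense <- target_set(sphere_target(c(0, 0, 0), 10, "s", density = 4))
  vd <- margin_volume(dense, c(0, 0, 0), u0, spacing = 0.5)
  expect_equal(vd$v_margin, shell, tolerance = 0.01)
})

test_that("PTV occupancy matches a brute-force triple-loop oracle", {
  ts <- target_set(
    coarse_sphere(c(0, 0, 0), 6, "a", subdivisions = 1),
    coarse_sphere(c(18, 4, -2), 9, "b", subdivisions = 1)
  )
  u <- setup_uncertainty(m_s = 2, sigma_d = 1.5)
  iso <- c(-10, 0, 0)
  g <- expand_ptv(ts, iso, u, spacing = 2)
  expect_identical(g$occupancy, brute_force_ptv(ts, iso, u, g))
})

test_that("PTV contains the CTV and the margin volume is their difference", {
  ts <- target_set(coarse_sphere(c(0, 0, 0), 6, "a"),
                   coarse_sphere(c(50, 0, 0), 12, "b"))
  u <- setup_uncertainty(m_s = 2, sigma_d = 1)
  ptv <- expand_ptv(ts, c(25, 0, 0), u, spacing = 1)
  ctv <- rasterize_ctv(ts, spacing = 1, grid = ptv)
  expect_true(all(ptv$occupancy[ctv$occupancy]))
  mv <- margin_volume(ts, c(25, 0, 0), u, spacing = 1)
  expect_gte(mv$v_ptv, mv$v_ctv)
  expect_equal(mv$v_margin, mv$v_ptv - mv$v_ctv)
  # grouped local-grid accounting equals the single global grid
  expect_equal(mv$v_margin, occupied_volume(ptv) - occupied_volume(ctv))
})

test_that("per-target breakdown is consistent for well-separated targets", {
  ts <- target_set(coarse_sphere(c(0, 0, 0), 6, "a"),
                   coarse_sphere(c(60, 0, 0), 10, "b"))
  u <- setup_uncertainty(m_s = 2, sigma_d = 1)
  mv <- margin_volume(ts, c(30, 0, 0), u, spacing = 1, per_target = TRUE)
  expect_identical(nrow(mv$per_target), 2L)
  expect_equal(sum(mv$per_target$v_margin), mv$v_margin)
  expect_equal(sum(mv$per_target$v_ctv), mv$v_ctv)
})

test_that("margin volume grows with either uncertainty component", {
  ts <- target_set(coarse_sphere(c(0, 0, 0), 8, "a"),
                   coarse_sphere(c(60, 0, 0), 8, "b"))
  iso <- c(30, 0, 0)
  v_by_sd <- sapply(c(0, 0.5, 1, 2), function(sd) {
    margin_volume(ts, iso, setup_uncertainty(m_s = 2, sigma_d = sd),
                  spacing = 1)$v_margin
  })
  expect_true(all(diff(v_by_sd) > 0))
  v_by_ms <- sapply(c(1, 2, 3), function(ms) {
    margin_volume(ts, iso, setup_uncertainty(m_s = ms, sigma_d = 1),
                  spacing = 1)$v_margin
  })
  expect_true(all(diff(v_by_ms) > 0))
})

test_that("moving the isocenter away from a target never shrinks its shell", {
  t1 <- coarse_sphere(c(0, 0, 0), 10, "a")
  ts <- target_set(t1)
  u <- setup_uncertainty(m_s = 2, sigma_d = 1)
  near <- margin_volume(ts, c(10, 0, 0), u, spacing = 0.5)$v_margin
  far <- margin_volume(ts, c(80, 0, 0), u, spacing = 0.5)$v_margin
  expect_gte(far, near)
})

test_that("halving the voxel spacing changes the margin volume by under 1%", {
  ts <- phantom_targets("pair-6-15")
  u <- setup_uncertainty(m_s = 2, sigma_d = 0.5)
  iso <- center_of_geometry(ts)
  v05 <- margin_volume(ts, iso, u, spacing = 0.5)$v_margin
  v025 <- margin_volume(ts, iso, u, spacing = 0.25)$v_margin
  expect_lt(abs(v05 - v025) / v025, 0.01)
})

test_that("mesh targets rasterize like their analytic counterpart", {
  cm <- cube_mesh(scale = 10)
  tgt <- mesh_target(cm$vertices, cm$faces, "cube")
  g <- rasterize_ctv(target_set(tgt), spacing = 0.5)
  expect_equal(occupied_volume(g), 1000, tolerance = 0.01)
})
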