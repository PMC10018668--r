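test_that("objective is constant over isocenters without rotational error", {
  ts <- target_set(coarse_sphere(c(0, 0, 0), 8, "a"),
                   coarse_sphere(c(50, 0, 0), 8, "b"))
  f <- margin_objective(ts, setup_uncertainty(m_s = 2, sigma_d = 0), spacing = 1)
  expect_identical(f(c(0, 0, 0)), f(c(50, 30, -20)))
  expect_identical(attr(f, "count")(), 2L)
})

test_that("grid search finds the midpoint for equal spheres", {
  ts <- target_set(coarse_sphere(c(0, 0, 0), 10, "a"),
                   coarse_sphere(c(60, 0, 0), 10, "b"))
  u <- setup_uncertainty(m_s = 2, sigma_d = 1)
  g <- grid_search_isocenter(ts, u, step = 2, spacing = 1)
  expect_lte(abs(g$position[1] - 30), 2)
  expect_equal(g$position[2:3], c(0, 0))
  # mirror symmetry of the objective about the midpoint
  v <- g$samples$v_margin
  expect_equal(v, rev(v), tolerance = 1e-9)
})

test_that("segment and 3-D box searches agree for two targets", {
  ts <- target_set(coarse_sphere(c(0, 0, 0), 6, "a"),
                   coarse_sphere(c(40, 0, 0), 12, "b"))
  u <- setup_uncertainty(m_s = 2, sigma_d = 1.5)
  seg <- grid_search_isocenter(ts, u, step = 2, spacing = 1, restriction = "segment")
  box <- grid_search_isocenter(ts, u, step = 2, spacing = 1, restriction = "box")
  expect_lte(abs(seg$position[1] - box$position[1]), 2)
  expect_error(grid_search_isocenter(target_set(coarse_sphere(c(0, 0, 0), 5, "x"),
                                                coarse_sphere(c(1, 0, 0), 5, "y"),
                                                coarse_sphere(c(2, 0, 0), 5, "z")),
                                     u, restriction = "segment"),
               "two targets")
})

test_that("unequal spheres pull the optimum toward the larger target", {
  ts <- phantom_targets("pair-5-20")
  u <- setup_uncertainty(m_s = 2, sigma_d = 1)
  g <- grid_search_isocenter(ts, u, step = 2, spacing = 1)
  expect_gt(g$position[1], 50)  # strictly on the D2 side of the midpoint
})

test_that("ASA incumbent is monotone and runs are seed-reproducible", {
  ts <- target_set(coarse_sphere(c(0, 0, 0), 5, "a"),
                   coarse_sphere(c(40, 0, 0), 14, "b"))
  u <- setup_uncertainty(m_s = 2, sigma_d = 1)
  cfg <- asa_config(seed = 11, max_evals = 250, patience = 120, spacing = 1)
  a1 <- asa_optimize(ts, u, cfg)
  a2 <- asa_optimize(ts, u, cfg)
  expect_identical(a1$position, a2$position)
  expect_identical(a1$trace, a2$trace)
  expect_true(all(diff(a1$trace$incumbent) <= 0))
  expect_true(all(a1$position >= search_bounds(ts)$lower - 1e-9))
  expect_true(all(a1$position <= search_bounds(ts)$upper + 1e-9))
})

test_that("ASA does not disturb the caller's RNG stream", {
  ts <- target_set(coarse_sphere(c(0, 0, 0), 5, "a"),
                   coarse_sphere(c(30, 0, 0), 10, "b"))
  u <- setup_uncertainty(m_s = 2, sigma_d = 1)
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(asa_optimize(ts, u, asa_config(seed = 5, max_evals = 40,
                                           patience = 40, spacing = 2)))
  expect_identical(runif(1), before)
})

test_that("ASA matches the reference points for equal spheres and beats them otherwise", {
  eq <- target_set(coarse_sphere(c(0, 0, 0), 10, "a"),
                   coarse_sphere(c(60, 0, 0), 10, "b"))
  u <- setup_uncertainty(m_s = 2, sigma_d = 1)
  a <- asa_optimize(eq, u, asa_config(seed = 3, max_evals = 400, patience = 200,
                                      spacing = 1))
  expect_lt(abs(a$position[1] - 30), 2)

  ts <- phantom_targets("pair-5-20")
  tab <- compare_isocenters(ts, u, seed = 2,
                            methods = c("COG", "COV", "COS", "ASA"),
                            spacing_opt = 1, spacing_final = 1)
  refs <- tab$v_margin[tab$label %in% c("COG", "COV", "COS")]
  expect_lte(tab$v_margin[tab$label == "ASA"], min(refs))
})

test_that("different seeds land on the same flat-basin value", {
  ts <- phantom_targets("pair-5-20")
  u <- setup_uncertainty(m_s = 2, sigma_d = 1)
  vc <- margin_volume(ts, center_of_geometry(ts), u, spacing = 0.5)$v_margin
  norms <- sapply(c(1, 2), function(s) {
    a <- asa_optimize(ts, u, asa_config(seed = s, spacing = 1),
                      spacing_final = 0.5)
    a$v_margin / vc
  })
  expect_lt(abs(diff(norms)), 0.005)
})

test_that("comparison table is normalized to the COG row", {
  ts <- target_set(coarse_sphere(c(0, 0, 0), 6, "a"),
                   coarse_sphere(c(40, 0, 0), 10, "b"))
  u <- setup_uncertainty(m_s = 2, sigma_d = 1)
  tab <- compare_isocenters(ts, u, seed = 1, methods = c("COG", "COV", "COS", "NSO"),
                            spacing_opt = 1, spacing_final = 1, step = 2)
  expect_identical(tab$normalized_to_cog[tab$label == "COG"], 1)
  expect_setequal(tab$label, c("COG", "COV", "COS", "NSO"))
  expect_true(all(tab$v_margin > 0))
})
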