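test_that("unloaded unstretched reference is in equilibrium with zero stress", {
  mats1 <- tissue_materials(lambda_z = 1)
  inel <- inelastic_state(mesh_small, 1, lambda_cs = 1)
  sol <- solve_equilibrium(mesh_small, mats1, inel, 0)
  expect_lt(max(abs(sol$u)), 1e-7)
  expect_lt(max(abs(sol$fields[, c("sigma_xx", "sigma_yy", "sigma_xy",
                                   "sigma_zz")])), 1e-6)
  expect_equal(sol$A_s, lumen_reference_area(mesh_small), tolerance = 1e-8)
})

test_that("neo-Hookean annulus inflation matches the 1D tube oracle", {
  inel <- inelastic_state(mesh_small, 1, lambda_cs = 1)
  sol <- solve_equilibrium(mesh_small, mats_nh, inel, 100)
  r_o <- oracle_tube_1d(geom_std, mats_nh, 1, 1, 100)
  expect_lt(abs(sol$r_i / r_o - 1), 0.01)
})

test_that("full-material basal inflation matches the oracle within 1%", {
  inel <- inelastic_state(mesh_med, 0.75, xi_c = 0.15)
  sol <- solve_equilibrium(mesh_med, mats_std, inel, 100)
  r_o <- oracle_tube_1d(geom_std, mats_std, 0.75,
                        collagen_straightening(0.75, 0.15), 100)
  expect_lt(abs(sol$r_i / r_o - 1), 0.01)
})

test_that("perturbed-Lagrangian consistency: p = kappa (J - 1), |J - 1| small", {
  inel <- inelastic_state(mesh_small, 0.75, xi_c = 0.15)
  sol <- solve_equilibrium(mesh_small, mats_std, inel, 120)
  expect_equal(as.numeric(sol$pe), 1e5 * (as.numeric(sol$Jbar) - 1),
               tolerance = 1e-8)
  expect_lt(max(abs(sol$Jbar - 1)), 1e-3)
})

test_that("pressure-area curve rises and contraction narrows the lumen", {
  sw <- sweep_pressure_area(mesh_small, mats_std,
                            inelastic_state(mesh_small, 0.75, xi_c = 0.15),
                            p_max = 250, n_p = 5)
  expect_true(all(diff(sw$A) > 0))
  A_at <- vapply(c(0.65, 0.75, 0.9), function(la) {
    solve_equilibrium(mesh_small, mats_std,
                      inelastic_state(mesh_small, la, xi_c = 0.15), 100)$A_s
  }, 0)
  expect_true(all(diff(A_at) > 0))
})

test_that("collagen straightening controls the high-pressure tone separation", {
  # with xi_c = 0 the pressure-radius curves for different tone converge at
  # high pressure; with xi_c = 0.15 they stay apart (oracle, fast)
  r0 <- vapply(c(0.75, 1.3), function(la)
    oracle_tube_1d(geom_std, mats_std, la, 1, 250), 0)
  r15 <- vapply(c(0.75, 1.3), function(la)
    oracle_tube_1d(geom_std, mats_std, la,
                   collagen_straightening(la, 0.15), 250), 0)
  expect_lt(abs(r0[1] / r0[2] - 1), 0.06)
  expect_gt(1 - r15[1] / r15[2], 0.12)
})

test_that("lumen area: rigid inflation and triangulation cross-check", {
  m <- mesh_small
  nn <- nrow(m$coords)
  r <- sqrt(rowSums(m$coords^2))
  u <- as.numeric(t(m$coords * (0.5 / r)))  # uniform +0.5 mm radial
  sol <- list(u = u)
  class(sol) <- "mechanical_solution"
  A <- compute_lumen_area(sol, m)
  A_circle_faceted <- lumen_reference_area(m) * (6.05 / 5.55)^2
  expect_equal(A, A_circle_faceted, tolerance = 1e-10)

  set.seed(42)
  u2 <- rnorm(2 * nn, sd = 0.05)
  xy <- m$coords[m$inner_loop, ] + cbind(u2[2 * m$inner_loop - 1],
                                         u2[2 * m$inner_loop])
  expect_equal(polygon_area(xy), tri_area(xy), tolerance = 1e-12)
})

test_that("tube oracle is self-convergent in the quadrature", {
  r1 <- oracle_tube_1d(geom_std, mats_std, 0.75, 0.9625, 120, n_quad = 100)
  r2 <- oracle_tube_1d(geom_std, mats_std, 0.75, 0.9625, 120, n_quad = 400)
  expect_lt(abs(r1 / r2 - 1), 1e-6)
  expect_equal(oracle_tube_1d(geom_std, tissue_materials(lambda_z = 1),
                              1, 1, 0), 5.55, tolerance = 1e-6)
})
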