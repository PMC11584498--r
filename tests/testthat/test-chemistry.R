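test_that("basal ROS closure reproduces the tabulated values exactly", {
  cl <- basal_ros_closure(80, 10, 1.01, 4)
  expect_equal(cl$C_ROS_b, 1.7475, tolerance = 1e-12)
  expect_equal(cl$P_ROS_b, 69.9, tolerance = 1e-12)
  # the closure satisfies both homogeneous steady balances
  expect_equal(-1.01 * 10 - 4 * 10 * cl$C_ROS_b + 80, 0, tolerance = 1e-12)
  expect_equal(-4 * 10 * cl$C_ROS_b + cl$P_ROS_b, 0, tolerance = 1e-12)
  expect_error(basal_ros_closure(8, 10, 1.01, 4), "non-positive")
})

test_that("endothelial production follows the Michaelis-Menten shear law", {
  kin <- kin_std
  expect_equal(endothelial_NO_production(kin$tau_b, kin, 0), 80)
  expect_equal(endothelial_NO_production(kin$tau_b, kin, 0.9), 80)
  sens <- 75 * 90 / 95.5
  p_up <- endothelial_NO_production(1.5 * 1.74, kinetics_params(tau_b = 1.74))
  expect_equal(p_up, 80 + sens * 0.87, tolerance = 1e-12)
  expect_equal(p_up, 141.5, tolerance = 1e-3)
  p_dys <- endothelial_NO_production(1.5 * 1.74,
                                     kinetics_params(tau_b = 1.74), 0.9)
  expect_equal(p_dys, 80 + 0.1 * sens * 0.87, tolerance = 1e-12)
  expect_error(endothelial_NO_production(0, kin, floor_frac = NULL),
               "non-positive")
})

test_that("endothelial concentrations: basal closure and ROS invariance", {
  kin <- kin_std
  ec <- endothelial_concentrations(80, kin)
  expect_equal(ec$C_NO_e, 10, tolerance = 1e-12)
  expect_equal(ec$C_ROS_e, kin$C_ROS_b, tolerance = 1e-12)
  ec2 <- endothelial_concentrations(141.5, kin)
  expect_equal(ec2$P_ROS_e, 69.9 * 141.5 / 80, tolerance = 1e-12)
  expect_equal(ec2$C_NO_e, 17.7, tolerance = 1e-2)
  ec3 <- endothelial_concentrations(18.5, kin)
  expect_equal(ec3$C_NO_e, 2.31, tolerance = 1e-2)
  # endothelial ROS equals its basal value at every production level
  for (p in c(20, 50, 80, 150, 300))
    expect_equal(endothelial_concentrations(p, kin)$C_ROS_e, kin$C_ROS_b,
                 tolerance = 1e-12)
})

test_that("NO-to-active-stretch sigmoid passes through the basal point with exact limits", {
  tone <- tone_std
  expect_equal(tone$c_lambda, 0.16 / 0.55, tolerance = 1e-12)
  expect_equal(tone$b_lambda, 0.71 * 0.16 / 1.1, tolerance = 1e-12)
  expect_equal(tone$a_lambda, 0.59 + 0.71 * 0.16 / 1.1, tolerance = 1e-12)
  expect_equal(c(tone$c_lambda, tone$b_lambda, tone$a_lambda),
               c(0.290909, 0.103273, 0.693273), tolerance = 1e-5)
  expect_equal(active_stretch_from_NO(10, tone), 0.75, tolerance = 1e-14)
  expect_equal(active_stretch_from_NO(1e6, tone), 1.3, tolerance = 1e-10)
  expect_equal(active_stretch_from_NO(0, tone), 0.59, tolerance = 1e-12)
  cs <- seq(8, 12, by = 0.05)       # strict growth around the basal point
  la <- active_stretch_from_NO(cs, tone)
  expect_true(all(diff(la) > 0))
  la_wide <- active_stretch_from_NO(seq(0, 40, by = 0.25), tone)
  expect_true(all(diff(la_wide) >= 0))  # saturates at the bounds
  expect_true(all(la_wide >= 0.59 & la_wide <= 1.3))
})

test_that("collagen straightening transfer", {
  expect_equal(collagen_straightening(0.75, 0.15), 0.9625)
  expect_equal(collagen_straightening(runif(5, 0.6, 1.3), 0), rep(1, 5))
  expect_equal(collagen_straightening(1, runif(5)), rep(1, 5))
})

test_that("element averaging of nodal fields", {
  m <- fix_unit$mesh
  v <- rep(3.3, nrow(m$coords))
  expect_equal(element_average_NO(v, m), rep(3.3, nrow(m$elems)))
  set.seed(3)
  v2 <- rnorm(nrow(m$coords))
  avg <- element_average_NO(v2, m)
  e5 <- m$elems[5, ]
  expect_equal(avg[5], mean(v2[e5]), tolerance = 1e-14)
})

test_that("uniform basal fields are an exact steady state of the RD system", {
  m <- mesh_med
  kin <- kin_std
  op <- transport_operator(m, NULL, kin)
  bc <- list(C_NO_e = kin$C_NO_b, C_ROS_e = kin$C_ROS_b)
  f0 <- basal_species_fields(m, kin)
  f1 <- step_reaction_diffusion(f0, op, bc, 60, kin)
  expect_equal(max(abs(f1$C_NO - kin$C_NO_b)), 0, tolerance = 1e-10)
  expect_equal(max(abs(f1$C_ROS - kin$C_ROS_b)), 0, tolerance = 1e-10)
  ss <- steady_state_fields(op, bc, kin)
  expect_equal(max(abs(ss$C_NO - kin$C_NO_b)), 0, tolerance = 1e-10)
})

test_that("steady fields match a dense radial oracle on a resolved problem", {
  # diffusion scaled up so the reaction boundary layer spans the wall
  kin <- kinetics_params(D_NO = 84800, D_ROS = 84800)
  m <- build_cross_section_mesh(geom_std, 8, 4, 32)
  op <- transport_operator(m, NULL, kin)
  pe <- endothelial_NO_production(1.5 * kin$tau_b, kin)
  ec <- endothelial_concentrations(pe, kin)
  ss <- steady_state_fields(op, ec, kin)
  orc <- radial_rd_oracle(kin, ec$C_NO_e, ec$C_ROS_e)
  nodes <- (0:12) * 32 + 1
  r_fe <- sqrt(rowSums(m$coords[nodes, ]^2))
  no_fe <- ss$C_NO[nodes]
  no_or <- approx(orc$r, orc$C_NO, xout = r_fe)$y
  expect_lt(max(abs(no_fe - no_or) / no_or), 0.01)
  # comparison principle: interior NO between basal and endothelial values
  expect_true(all(ss$C_NO[op$active] > kin$C_NO_b - 1e-6))
  expect_true(all(ss$C_NO[op$active] < ec$C_NO_e + 1e-6))
  # long-time transient approaches the steady solution
  f <- basal_species_fields(m, kin)
  for (i in 1:40) f <- step_reaction_diffusion(f, op, ec, 30, kin)
  expect_lt(max(abs(f$C_NO - ss$C_NO)) / kin$C_NO_b, 1e-3)
})

test_that("total content is conserved without reactions and fluxes", {
  m <- fix_unit$mesh
  kin <- kin_std
  op <- transport_operator(m, NULL, kin)
  # strip reactions/sources and the Dirichlet boundary (all-Neumann)
  kin0 <- kin
  kin0$eta_NO <- 0; kin0$K_RNS <- 0; kin0$P_NO_b <- 0; kin0$P_ROS_b <- 0
  op$free <- op$active
  op$dirichlet <- integer(0)
  set.seed(11)
  f <- structure(list(C_NO = runif(nrow(m$coords), 5, 15),
                      C_ROS = runif(nrow(m$coords), 1, 3), time = 0),
                 class = "species_fields")
  tot0 <- sum(op$M %*% f$C_NO)
  f1 <- step_reaction_diffusion(f, op, list(C_NO_e = 0, C_ROS_e = 0), 10,
                                kin0, n_sub = 1)
  expect_equal(sum(op$M %*% f1$C_NO) / tot0, 1, tolerance = 1e-10)
  # diffusion contracts the mass-weighted fluctuation energy
  mbar <- as.numeric(tot0 / sum(Matrix::diag(op$M)))
  en <- function(v) sum(Matrix::diag(op$M) * (v - mbar)^2)
  expect_lt(en(f1$C_NO), en(f$C_NO))
})

test_that("implicit stepping is stable from 0.1 s to 60 s", {
  m <- fix_unit$mesh
  kin <- kin_std
  op <- transport_operator(m, NULL, kin)
  pe <- endothelial_NO_production(1.3 * kin$tau_b, kin)
  ec <- endothelial_concentrations(pe, kin)
  for (dt in c(0.1, 1, 10, 60)) {
    f <- basal_species_fields(m, kin)
    for (i in 1:5) f <- step_reaction_diffusion(f, op, ec, dt, kin, n_sub = 1)
    # no oscillatory blow-up: bounded, positive fields at every step size
    # (the physical boundary layer is thinner than the coarse elements, so
    # small spatial undershoots below the basal plateau are expected)
    expect_true(all(is.finite(f$C_NO)))
    expect_true(all(f$C_NO > 0))
    expect_true(all(f$C_NO <= ec$C_NO_e + 1e-6))
    expect_true(all(f$C_NO >= kin$C_NO_b - 0.5 * (ec$C_NO_e - kin$C_NO_b)))
  }
})

test_that("calcified elements carry no transport and their core stays frozen", {
  m <- tag_calcification(mesh_med, 1 / 3, 1)
  kin <- kin_std
  op <- transport_operator(m, NULL, kin)
  expect_gt(length(op$frozen), 0)
  pe <- endothelial_NO_production(1.5 * kin$tau_b, kin)
  ec <- endothelial_concentrations(pe, kin)
  ss <- steady_state_fields(op, ec, kin)
  expect_equal(ss$C_NO[op$frozen], rep(kin$C_NO_b, length(op$frozen)))
  # healthy-side intima nodes carry the Dirichlet value
  expect_true(all(abs(ss$C_NO[op$dirichlet] - ec$C_NO_e) < 1e-9))
})
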