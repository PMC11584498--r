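test_that("surrogate fit recovers known sigmoid parameters", {
  p <- seq(0, 250, length.out = 11)
  A <- 40 / (1 + exp(-4 * (p / 100 - 1))) + 90
  s <- fit_surrogate(data.frame(p = p, A = A))
  expect_equal(s$a, 40, tolerance = 1e-6)
  expect_equal(s$b, 4, tolerance = 1e-6)
  expect_equal(s$c, 100, tolerance = 1e-6)
  expect_equal(s$d, 90, tolerance = 1e-6)
  expect_lt(s$rms, 1e-8)
  # analytic derivative at p = c
  h <- 1e-4
  dAdp <- (surrogate_area(s, 100 + h) - surrogate_area(s, 100 - h)) / (2 * h)
  expect_equal(dAdp, 40 * 4 / (4 * 100), tolerance = 1e-6)
})

test_that("resistance and compliance derive from the surrogate", {
  s <- structure(list(a = 40, b = 4, c = 100, d = 90, rms = 0,
                      p_range = c(0, 250)), class = "surrogate_ap")
  rc <- resistance_compliance(s, 100, ell_S = 300, mu_b = 3.5e-3)
  expect_equal(rc$A, 110)
  expect_equal(rc$R_S, poiseuille_resistance(110, 300, 3.5e-3))
  expect_equal(rc$C_S, 300 * 40 * 4 / (4 * 100) * 1e-3, tolerance = 1e-12)
})

test_that("Steffensen iteration: fixed points, affine exactness, tolerance", {
  # immediate fixed point
  out <- aitken_steffensen_solve(function(x) x, 1.74)
  expect_equal(out$tau, 1.74)
  expect_equal(out$err, 0)
  expect_equal(out$iterations, 1)
  # one-step exactness on affine maps
  out2 <- aitken_steffensen_solve(function(x) 0.5 * x + 1, 1, tol = 1e-12)
  expect_equal(out2$tau, 2, tolerance = 1e-12)
  expect_lte(out2$iterations, 2)
  # constant map (zero-derivative edge case)
  out3 <- aitken_steffensen_solve(function(x) 3.2, 1, tol = 1e-12)
  expect_equal(out3$tau, 3.2, tolerance = 1e-12)
  # smooth nonlinear map converges in a handful of iterations
  out4 <- aitken_steffensen_solve(function(x) cos(x), 1, tol = 1e-10)
  expect_equal(out4$tau, 0.7390851, tolerance = 1e-6)
  expect_lte(out4$iterations, 6)
  # a map with no fixed point errors out with a trace
  expect_error(
    aitken_steffensen_solve(function(x) x + 1, 1, tol = 1e-14,
                            max_iter = 5),
    "did not converge")
})

test_that("basal homeostasis is an exact fixed point of the coupled map", {
  cfg <- fix_unit$config
  ctx <- build_context(cfg, mesh = fix_unit$mesh)
  g1 <- evaluate_g(ctx$kin$tau_b, ctx, dt = NULL)
  # exact up to the inner Newton tolerances (the basal closure leaves a
  # ~1e-15 float residue in C_NO_e that propagates through the FE solves)
  expect_equal(g1$tau, ctx$kin$tau_b, tolerance = 1e-7)
  expect_equal(g1$fields$C_NO, rep(ctx$kin$C_NO_b, nrow(fix_unit$mesh$coords)),
               tolerance = 1e-10)
  expect_lt(max(abs(g1$inelastic$lambda_a[fix_unit$mesh$region == 0] - 0.75)),
            1e-9)
  # transient chemistry preserves the fixed point as well
  g2 <- evaluate_g(ctx$kin$tau_b, ctx, dt = 30)
  expect_equal(g2$tau, ctx$kin$tau_b, tolerance = 1e-7)
})

test_that("g is pure in the cached state: repeated evaluation is identical", {
  cfg <- fix_unit$config
  ctx <- build_context(cfg, mesh = fix_unit$mesh)
  tau_probe <- 1.2 * ctx$kin$tau_b
  a <- evaluate_g(tau_probe, ctx, dt = 20)
  b <- evaluate_g(tau_probe, ctx, dt = 20)
  # chemistry restarts from the cached fields: bitwise reproducible
  expect_identical(a$fields$C_NO, b$fields$C_NO)
  # mechanics agrees to the Newton tolerance (warm starts differ)
  expect_equal(a$tau, b$tau, tolerance = 1e-6)
  # the cached chemical state was not advanced by the evaluations
  expect_equal(ctx$fields$C_NO, rep(ctx$kin$C_NO_b, nrow(fix_unit$mesh$coords)))
})

test_that("0D operating pressures stay inside the swept range at basal state", {
  cfg <- fix_unit$config
  ctx <- build_context(cfg, mesh = fix_unit$mesh)
  ser <- ctx$basal$series
  expect_true(all(ser$pS >= 0 & ser$pS <= cfg$coupling$p_max))
  expect_true(all(ser$r > 0))
})

test_that("slow-time driver holds a constant basal schedule steady", {
  cfg <- fix_unit$config
  ctx <- build_context(cfg, mesh = fix_unit$mesh)
  sched <- list(kind = "transient", name = "basal_hold", calcified = FALSE,
                regulation = TRUE, alpha_dys = 0,
                f_h = function(t) 1, t_k = c(30, 60, 90), dt0 = 30)
  out <- slow_time_loop(sched, ctx)
  expect_equal(out$trajectory$tau, rep(ctx$kin$tau_b, 3), tolerance = 1e-6)
  expect_equal(out$trajectory$mean_lambda_a, rep(0.75, 3), tolerance = 1e-8)
  expect_true(all(out$trajectory$err < cfg$coupling$tol))
})
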