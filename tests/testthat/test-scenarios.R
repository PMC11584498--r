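test_that("default configuration carries the tabulated parameter values", {
  cfg <- default_config()
  expect_equal(cfg$smc$C_smc, 100)
  expect_equal(cfg$kinetics$K_RNS, 4)
  expect_equal(cfg$network$R1, 0.1)
  expect_equal(cfg$network$C3, 0.001)
  expect_equal(cfg$network$V_h, 5.6 * 1000 / 60)
  expect_equal(cfg$tone$lambda_minus, 0.59)
  expect_equal(cfg$calcified$c2, -228)
})

test_that("config loading: defaults, units, unknown keys, round trip", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  cfg <- load_config(empty)
  expect_equal(cfg$ecm$kappa, default_config()$ecm$kappa)

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ecm:", "  kappa:", "    value: 100", "    unit: MPa"), f)
  expect_equal(load_config(f)$ecm$kappa, 1e5)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("network:", "  viscocity: 1"), bad)
  expect_error(load_config(bad), "viscocity")

  rt <- withr::local_tempfile(fileext = ".yaml")
  cfg0 <- default_config()
  save_config(cfg0, rt)
  cfg1 <- load_config(rt)
  expect_equal(cfg1, cfg0, tolerance = 1e-12)
})

test_that("scenario schedules reproduce the prescribed shapes", {
  cfg <- default_config()
  hr <- make_scenario("heart_rate_ramp", cfg)
  expect_equal(hr$f_h(c(0, 500, 720, 1400, 1560, 3600)),
               c(1, 1, 2, 2, 3, 3))
  expect_true(all(diff(hr$t_k) > 0))
  expect_equal(max(hr$t_k), 3600)

  up <- make_scenario("local_tawss_up", cfg, tau_b = 1.7)
  expect_equal(up$tau_bar(120), 1.5 * 1.7)
  expect_equal(up$tau_bar(0), 1.7)
  expect_equal(up$tau_bar(1e4), 1.5 * 1.7)
  dn <- make_scenario("local_tawss_down", cfg, tau_b = 1.7)
  expect_equal(dn$tau_bar(120), 0.5 * 1.7)

  eq <- make_scenario("basal_equilibrium", cfg)
  expect_identical(eq$kind, "equilibrium")
  expect_false(eq$calcified)
  fz <- make_scenario("calcified_equilibrium_frozen", cfg)
  expect_true(fz$calcified)
  expect_false(fz$regulation)

  expect_error(make_scenario("nope", cfg), "available")
})

test_that("fixtures: unit mesh invariants and production element count", {
  m <- fix_unit$mesh
  expect_equal(nrow(m$elems), 8 * 4)
  expect_true(all(element_areas(m) > 0))
  mi <- make_fixture("integration")$mesh
  expect_lt(abs(nrow(mi$elems) / 1500 - 1), 0.2)
})

test_that("local prescribed-TAWSS scenario relaxes the wall as NO rises", {
  cfg <- fix_unit$config
  cfg$scenario$duration <- 240
  ctx <- build_context(cfg, mesh = fix_unit$mesh)
  sched <- make_scenario("local_tawss_up", cfg, tau_b = ctx$kin$tau_b)
  out <- slow_time_loop(sched, ctx)
  tr <- out$trajectory
  expect_equal(tr$tau[nrow(tr)], 1.5 * ctx$kin$tau_b, tolerance = 1e-12)
  expect_gt(tr$C_NO_e[nrow(tr)], 1.5 * ctx$kin$C_NO_b)
  expect_gt(tr$mean_lambda_a[nrow(tr)], 0.75)   # vasodilation
  expect_true(all(diff(tr$mean_C_NO) > -1e-9))
})

test_that("outputs are written, well formed, and bit-reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- fix_unit$config
  cfg$scenario$duration <- 180
  res1 <- run_scenario("local_tawss_up", cfg, mesh = fix_unit$mesh)
  res2 <- run_scenario("local_tawss_up", cfg, mesh = fix_unit$mesh)
  p1 <- write_outputs(res1, cfg, dir = dir1)
  p2 <- write_outputs(res2, cfg, dir = dir2)
  expect_true(file.exists(p1$trajectory))
  expect_true(file.exists(p1$summary))
  expect_true(file.exists(p1$vtu))
  expect_identical(readLines(p1$trajectory), readLines(p2$trajectory))
  doc <- xml2::read_xml(p1$vtu)
  expect_equal(xml2::xml_name(doc), "VTKFile")
  js <- jsonlite::read_json(p1$summary)
  expect_equal(js$scenario, "local_tawss_up")
  expect_true(is.numeric(js$tau_basal_Pa))
  expect_equal(js$config$smc$C_smc, 100)
})
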