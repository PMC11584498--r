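# Global-local coupling: the transfer function g maps a TAWSS guess through
# endothelial chemistry, reaction-diffusion transport, tone-dependent
# mechanics, the pressure-area surrogate and the 0D network back to a TAWSS.
# Its fixed point at each slow-time step is found by Aitken-Steffensen
# iteration; the basal state is a fixed point by construction because the
# basal TAWSS is itself computed from the model.

#' Build a coupling context
#'
#' Assembles mesh, materials and parameters, computes the basal reference
#' (sweep, surrogate, 0D run and the model's own basal TAWSS), and caches the
#' chemical and mechanical state used to restart inner iterations.
#'
#' @param config a [default_config()]-style list
#' @param calcified tag a calcified sector of the media
#' @param alpha_dys endothelial dysfunction level in `[0, 1]`
#' @param regulation if `FALSE`, the active stretch is frozen at its basal
#'   value (no chemo-mechanical feedback)
#' @param mesh optional pre-built `vessel_mesh` (healthy); calcification is
#'   tagged here when requested
#' @param basal optional pre-computed [basal_reference()] (must match the
#'   healthy version of `mesh`)
#' @return list of class `coupling_context`
#' @export
build_context <- function(config = default_config(), calcified = FALSE,
                          alpha_dys = 0, regulation = TRUE, mesh = NULL,
                          basal = NULL) {
  geom <- do.call(cross_section_geometry, config$geometry)
  if (is.null(mesh))
    mesh <- build_cross_section_mesh(geom, config$mesh$n_radial_media,
                                     config$mesh$n_radial_adventitia,
                                     config$mesh$n_circ, config$mesh$seed)
  materials <- tissue_materials(
    ecm = do.call(ecm_params, config$ecm),
    smc = do.call(smc_params, config$smc),
    calc = calcified_params(config$calcified$c1, config$calcified$c2,
                            config$calcified$c3, config$calcified$kappa),
    lambda_z = geom$lambda_z)
  kin <- do.call(kinetics_params, config$kinetics)
  tone <- do.call(tone_params, c(config$tone,
                                 list(C_NO_b = config$kinetics$C_NO_b)))
  net <- do.call(network_params, config$network)

  if (is.null(basal))
    basal <- basal_reference(mesh, materials, kin, tone, net, geom, config)
  kin$tau_b <- basal$tau_b  # the model's own basal TAWSS closes the loop

  mesh_run <- if (calcified)
    tag_calcification(mesh, config$calcified$angular_fraction,
                      config$calcified$radial_extent) else mesh

  ctx <- list(config = config, geom = geom, mesh = mesh_run,
              materials = materials, kin = kin, tone = tone, net = net,
              alpha_dys = alpha_dys, regulation = regulation,
              calcified = calcified, basal = basal,
              f_h = net$f_h_b,
              fields = basal_species_fields(mesh_run, kin),
              tau_prev = basal$tau_b, p_mean = basal$p_mean)
  # mutable numerical warm-start cache (Newton initial guesses only; the
  # physical state committed between slow steps lives in the context list)
  ctx$cache <- new.env(parent = emptyenv())
  ctx$cache$sweep_u <- attr(basal$pairs, "u_list")
  # cached deformation (at the basal mean pressure) and transport operator
  inel <- inelastic_state(mesh_run, tone$lambda_b, xi_c = tone$xi_c)
  def <- solve_equilibrium(mesh_run, materials, inel, basal$p_mean,
                           u0 = ctx$cache$sweep_u[[4]])
  ctx$deformation <- def
  ctx$op <- transport_operator(mesh_run, def, kin)
  ctx$warm_u <- def$u
  class(ctx) <- "coupling_context"
  ctx
}

#' Basal reference of the healthy cross section
#'
#' Sweeps the healthy mesh at uniform basal tone, fits the surrogate, runs
#' the 0D network at the basal heart rate and measures the basal TAWSS, mean
#' pressure and systolic-diastolic amplitude.
#'
#' @param mesh healthy `vessel_mesh`
#' @param materials,kin,tone,net parameter bundles
#' @param geom a [cross_section_geometry()]
#' @param config configuration list (for `coupling$p_max`, `coupling$n_p`)
#' @return list with `tau_b`, `surrogate`, `series`, `p_mean`, `amp`, `pairs`
#' @export
basal_reference <- function(mesh, materials, kin, tone, net, geom, config) {
  inel <- inelastic_state(mesh, tone$lambda_b, xi_c = tone$xi_c)
  pairs <- sweep_pressure_area(mesh, materials, inel,
                               p_max = config$coupling$p_max,
                               n_p = config$coupling$n_p)
  surr <- fit_surrogate(pairs)
  ser <- backward_euler_run(net, net$f_h_b, surr, ell_S = geom$ell_S)
  list(tau_b = tawss(ser$tau, ser$t_h),
       surrogate = surr, series = ser,
       p_mean = mean_pressure(ser), amp = pulse_amplitude(ser),
       pairs = pairs)
}

mean_pressure <- function(series) {
  n <- nrow(series)
  dt <- diff(series$t_h)
  sum(dt * (series$pS[-1] + series$pS[-n]) / 2) /
    (series$t_h[n] - series$t_h[1])
}

pulse_amplitude <- function(series) max(series$pS) - min(series$pS)

#' One pass of the coupled transfer function g
#'
#' Maps a TAWSS guess to a new TAWSS: endothelial production and Dirichlet
#' concentrations, reaction-diffusion over the slow step (restarted from the
#' cached state; steady solve when `dt` is `NULL`), element-wise tone update,
#' FE pressure sweep, surrogate fit, and a 0D heartbeat run. Pure in the
#' cached state: the context is not modified.
#'
#' @param tau_guess TAWSS guess (Pa)
#' @param ctx a [build_context()]
#' @param dt slow-time step (s), or `NULL` for the steady chemistry limit
#' @return list with the new `tau`, the proposed `fields`, `surrogate`,
#'   `inelastic`, fast-scale `series` and summary pressures
#' @export
evaluate_g <- function(tau_guess, ctx, dt = NULL) {
  kin <- ctx$kin
  P_NO_e <- endothelial_NO_production(tau_guess, kin, ctx$alpha_dys)
  ec <- endothelial_concentrations(P_NO_e, kin)
  fields <- if (is.null(dt))
    steady_state_fields(ctx$op, ec, kin, init = ctx$fields)
  else
    step_reaction_diffusion(ctx$fields, ctx$op, ec, dt, kin)
  la <- if (ctx$regulation)
    active_stretch_from_NO(element_average_NO(fields, ctx$mesh), ctx$tone)
  else rep(ctx$tone$lambda_b, nrow(ctx$mesh$elems))
  inel <- inelastic_state(ctx$mesh, la, xi_c = ctx$tone$xi_c)
  pairs <- sweep_pressure_area(ctx$mesh, ctx$materials, inel,
                               p_max = ctx$config$coupling$p_max,
                               n_p = ctx$config$coupling$n_p,
                               warm_u = ctx$cache$sweep_u)
  ctx$cache$sweep_u <- attr(pairs, "u_list")
  surr <- fit_surrogate(pairs)
  ser <- backward_euler_run(ctx$net, ctx$f_h, surr, ell_S = ctx$geom$ell_S)
  list(tau = tawss(ser$tau, ser$t_h), fields = fields, surrogate = surr,
       inelastic = inel, series = ser, P_NO_e = P_NO_e, C_NO_e = ec$C_NO_e,
       p_mean = mean_pressure(ser), amp = pulse_amplitude(ser),
       pairs = pairs, sweep_u = attr(pairs, "u_list"))
}

#' Aitken-Steffensen fixed-point solve
#'
#' Derivative-free acceleration of `tau = g(tau)`; exact in one update for
#' affine maps. Convergence is monitored on the endothelial NO concentration
#' associated with successive TAWSS guesses, relative to the basal
#' concentration; if the error grows between iterations the next guess is
#' re-initialized at the midpoint (safeguard).
#'
#' @param g function of a scalar TAWSS returning either a scalar or a list
#'   with component `tau`
#' @param tau_init initial guess (Pa); use the previous converged TAWSS
#' @param tol tolerance on the relative NO-concentration error
#' @param max_iter maximum outer iterations
#' @param C_of_tau map from TAWSS to the monitored concentration (defaults
#'   to the identity, with unit basal scale)
#' @param C_basal scale of the error measure
#' @return list with `tau`, `state` (the g-output at `tau`), `iterations`,
#'   `err`, `n_eval` and the iteration `trace`
#' @export
aitken_steffensen_solve <- function(g, tau_init, tol = 1e-3, max_iter = 25,
                                    C_of_tau = identity, C_basal = 1) {
  memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  G <- function(tau) {
    key <- sprintf("%.15g", tau)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- g(tau)
    st <- if (is.list(out)) out else list(tau = out)
    n_eval <<- n_eval + 1L
    memo[[key]] <- st
    st
  }
  tau_j <- tau_init
  err_prev <- Inf
  trace <- data.frame(iter = integer(), tau = numeric(), g_tau = numeric(),
                      err = numeric())
  for (j in seq_len(max_iter)) {
    s1 <- G(tau_j)
    if (abs(s1$tau - tau_j) <= 1e-12 * max(1, abs(tau_j))) {
      trace <- rbind(trace, data.frame(iter = j, tau = tau_j, g_tau = s1$tau,
                                       err = 0))
      return(list(tau = tau_j, state = s1, iterations = j, err = 0,
                  n_eval = n_eval, trace = trace))
    }
    s2 <- G(s1$tau)
    denom <- s2$tau - 2 * s1$tau + tau_j
    tau_next <- if (abs(denom) < 1e-12 * max(1, abs(tau_j))) s1$tau else
      tau_j - (s1$tau - tau_j)^2 / denom
    err <- abs(C_of_tau(tau_next) - C_of_tau(tau_j)) / C_basal
    if (err > err_prev) tau_next <- (tau_next + tau_j) / 2  # safeguard
    trace <- rbind(trace, data.frame(iter = j, tau = tau_j, g_tau = s1$tau,
                                     err = err))
    if (err < tol)
      return(list(tau = tau_next, state = G(tau_next), iterations = j,
                  err = err, n_eval = n_eval, trace = trace))
    err_prev <- err
    tau_j <- tau_next
  }
  stop("Aitken-Steffensen did not converge; trace:\n",
       paste(utils::capture.output(print(trace)), collapse = "\n"),
       call. = FALSE)
}

# commit a converged g-output into the context (cached state for the next
# slow step): species fields, TAWSS, and the deformation/transport metric at
# the new mean pressure
commit_state <- function(ctx, state) {
  ctx$fields <- state$fields
  ctx$tau_prev <- state$tau
  ctx$p_mean <- state$p_mean
  def <- solve_equilibrium(ctx$mesh, ctx$materials, state$inelastic,
                           state$p_mean, u0 = ctx$warm_u)
  ctx$deformation <- def
  ctx$warm_u <- def$u
  ctx$op <- transport_operator(ctx$mesh, def, ctx$kin)
  ctx$last_state <- state
  ctx
}

c_of_tau_fun <- function(ctx) {
  function(tau) {
    p <- endothelial_NO_production(tau, ctx$kin, ctx$alpha_dys)
    endothelial_concentrations(p, ctx$kin)$C_NO_e
  }
}

#' Coupled equilibrium under constant conditions
#'
#' Steady-chemistry fixed point of the global-local system, with an outer
#' loop updating the transport metric to the deformation at the converged
#' mean pressure.
#'
#' @param ctx a [build_context()]
#' @param tol Steffensen tolerance (relative NO concentration)
#' @param outer_tol relative TAWSS change ending the outer metric loop
#' @param max_outer maximum outer iterations
#' @return list with the converged `tau`, the final g-output `state`, and
#'   the updated context
#' @export
solve_coupled_equilibrium <- function(ctx, tol = NULL, outer_tol = 1e-4,
                                      max_outer = 8) {
  if (is.null(tol)) tol <- ctx$config$coupling$tol
  tau <- ctx$tau_prev
  for (outer in seq_len(max_outer)) {
    st <- aitken_steffensen_solve(function(x) evaluate_g(x, ctx, dt = NULL),
                                  tau, tol = tol,
                                  max_iter = ctx$config$coupling$max_iter,
                                  C_of_tau = c_of_tau_fun(ctx),
                                  C_basal = ctx$kin$C_NO_b)
    ctx <- commit_state(ctx, st$state)
    if (abs(st$tau - tau) <= outer_tol * max(1e-12, abs(tau)) && outer > 1)
      return(list(tau = st$tau, state = st$state, ctx = ctx,
                  outer = outer, iterations = st$iterations))
    tau <- st$tau
  }
  list(tau = tau, state = ctx$last_state, ctx = ctx, outer = max_outer,
       iterations = NA_integer_)
}

#' Slow-time driver of the coupled model
#'
#' Resolves the TAWSS fixed point at each slow-time step of a scenario
#' schedule, committing the chemical and mechanical state between steps.
#' For local-only schedules (prescribed TAWSS) the 0D network and the fixed
#' point are bypassed.
#'
#' @param schedule a [make_scenario()] schedule
#' @param ctx a [build_context()] (its `calcified`/`alpha_dys` flags should
#'   match the schedule)
#' @return list with the per-step `trajectory` data.frame and the final
#'   context
#' @export
slow_time_loop <- function(schedule, ctx) {
  t_k <- schedule$t_k
  rows <- vector("list", length(t_k))
  tol <- ctx$config$coupling$tol
  for (k in seq_along(t_k)) {
    t <- t_k[k]
    dt <- if (k == 1) schedule$dt0 else t - t_k[k - 1]
    if (identical(schedule$kind, "local")) {
      tau <- schedule$tau_bar(t)
      pe <- endothelial_NO_production(tau, ctx$kin, ctx$alpha_dys)
      ec <- endothelial_concentrations(pe, ctx$kin)
      ctx$fields <- step_reaction_diffusion(ctx$fields, ctx$op, ec, dt,
                                            ctx$kin)
      la <- active_stretch_from_NO(element_average_NO(ctx$fields, ctx$mesh),
                                   ctx$tone)
      mean_no <- mean(ctx$fields$C_NO[ctx$op$active])
      rows[[k]] <- data.frame(t = t, tau = tau, C_NO_e = ec$C_NO_e,
                              mean_C_NO = mean_no,
                              mean_lambda_a = mean(la[ctx$mesh$region == 0]),
                              p_mean = NA, p_sys = NA, p_dia = NA,
                              iterations = 0L, err = 0)
      ctx$tau_prev <- tau
      next
    }
    ctx$f_h <- schedule$f_h(t)
    st <- aitken_steffensen_solve(function(x) evaluate_g(x, ctx, dt = dt),
                                  ctx$tau_prev, tol = tol,
                                  max_iter = ctx$config$coupling$max_iter,
                                  C_of_tau = c_of_tau_fun(ctx),
                                  C_basal = ctx$kin$C_NO_b)
    ctx <- commit_state(ctx, st$state)
    ser <- st$state$series
    rows[[k]] <- data.frame(
      t = t, tau = st$tau, C_NO_e = st$state$C_NO_e,
      mean_C_NO = mean(st$state$fields$C_NO[ctx$op$active]),
      mean_lambda_a = mean(st$state$inelastic$lambda_a[ctx$mesh$region == 0]),
      p_mean = st$state$p_mean, p_sys = max(ser$pS), p_dia = min(ser$pS),
      iterations = st$iterations, err = st$err)
  }
  list(trajectory = do.call(rbind, rows), ctx = ctx)
}
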