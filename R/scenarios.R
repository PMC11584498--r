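# Scenario schedules: basal and calcified equilibria, prescribed-TAWSS local
# experiments, and heart-rate ramps with optional endothelial dysfunction.

piecewise_linear <- function(ts, vs) {
  force(ts); force(vs)
  function(t) stats::approx(ts, vs, xout = pmin(pmax(t, ts[1]),
                                                ts[length(ts)]))$y
}

schedule_times <- function(breaks, is_ramp, dt_ramp, dt_plateau) {
  t_k <- numeric(0)
  for (i in seq_len(length(breaks) - 1)) {
    dt <- if (is_ramp[i]) dt_ramp else dt_plateau
    n <- max(1L, ceiling((breaks[i + 1] - breaks[i]) / dt))
    t_k <- c(t_k, breaks[i] + (breaks[i + 1] - breaks[i]) * seq_len(n) / n)
  }
  t_k
}

#' Build a scenario schedule
#'
#' Known scenarios:
#' * `basal_equilibrium`, `calcified_equilibrium`,
#'   `calcified_equilibrium_frozen`: constant basal inputs; equilibrium runs
#'   (the frozen variant disables tone regulation).
#' * `local_tawss_up` / `local_tawss_down`: local-only experiment with the
#'   TAWSS ramped linearly by +-50% of basal over 2 minutes, then held.
#' * `heart_rate_ramp`: piecewise-linear heart rate through 60, 120 and
#'   180 bpm over one hour (plateaus reached at 0, 12 and 26 minutes),
#'   optionally with endothelial dysfunction via `config$scenario$alpha_dys`.
#'
#' @param name scenario name
#' @param config a [default_config()] list
#' @param tau_b basal TAWSS (Pa), needed by the local schedules
#' @return a schedule list consumed by [slow_time_loop()]
#' @export
make_scenario <- function(name, config = default_config(), tau_b = NULL) {
  cp <- config$coupling
  known <- c("basal_equilibrium", "calcified_equilibrium",
             "calcified_equilibrium_frozen", "local_tawss_up",
             "local_tawss_down", "heart_rate_ramp")
  if (!name %in% known)
    stop("unknown scenario '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  fb <- config$network$f_h_b
  if (name %in% c("basal_equilibrium", "calcified_equilibrium",
                  "calcified_equilibrium_frozen")) {
    return(list(kind = "equilibrium", name = name,
                calcified = grepl("calcified", name),
                regulation = !grepl("frozen", name),
                alpha_dys = config$scenario$alpha_dys,
                f_h = function(t) fb,
                t_k = c(60, 120), dt0 = 60))
  }
  if (grepl("^local_tawss", name)) {
    if (is.null(tau_b)) stop("local schedules need tau_b", call. = FALSE)
    sgn <- if (grepl("up$", name)) 1 else -1
    Tend <- min(config$scenario$duration, 900)
    tau_fun <- function(t) tau_b * (1 + sgn * 0.5 * pmin(pmax(t, 0), 120) / 120)
    t_k <- schedule_times(c(0, 120, Tend), c(TRUE, FALSE),
                          cp$dt_ramp, cp$dt_plateau)
    return(list(kind = "local", name = name, calcified = FALSE,
                regulation = TRUE, alpha_dys = config$scenario$alpha_dys,
                tau_bar = tau_fun, t_k = t_k, dt0 = t_k[1]))
  }
  # heart_rate_ramp: plateaus at f_b, 2 f_b, 3 f_b
  breaks <- c(0, 600, 720, 1440, 1560, 3600)
  fvals <- fb * c(1, 1, 2, 2, 3, 3)
  f_fun <- piecewise_linear(breaks, fvals)
  t_k <- schedule_times(breaks, c(FALSE, TRUE, FALSE, TRUE, FALSE),
                        cp$dt_ramp, cp$dt_plateau)
  list(kind = "transient", name = name, calcified = FALSE,
       regulation = TRUE, alpha_dys = config$scenario$alpha_dys,
       f_h = f_fun, t_k = t_k, dt0 = t_k[1])
}

#' Run a named scenario end to end
#'
#' Builds the context (honouring the schedule's calcification, regulation
#' and dysfunction flags) and either solves the coupled equilibrium or walks
#' the slow-time schedule.
#'
#' @param name scenario name (see [make_scenario()])
#' @param config a [default_config()] list
#' @param mesh,basal optional pre-built healthy mesh and basal reference
#'   (reused across paired runs)
#' @return for equilibria: the [solve_coupled_equilibrium()] result; for
#'   schedules: the [slow_time_loop()] result. Both carry the schedule and
#'   basal reference as attributes.
#' @export
run_scenario <- function(name, config = default_config(), mesh = NULL,
                         basal = NULL) {
  sched <- make_scenario(name, config, tau_b = NA)
  ctx <- build_context(config, calcified = isTRUE(sched$calcified),
                       alpha_dys = sched$alpha_dys,
                       regulation = !isFALSE(sched$regulation),
                       mesh = mesh, basal = basal)
  if (identical(sched$kind, "local")) {
    sched <- make_scenario(name, config, tau_b = ctx$kin$tau_b)
  }
  out <- if (identical(sched$kind, "equilibrium"))
    solve_coupled_equilibrium(ctx)
  else slow_time_loop(sched, ctx)
  attr(out, "schedule") <- sched
  attr(out, "basal") <- ctx$basal
  out
}
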