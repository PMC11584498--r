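# Sigmoid pressure-area surrogate A(p) = a / (1 + exp(-b (p/c - 1))) + d
# fitted to finite-element inflation sweeps, and the derived segment
# resistance and compliance.

#' Sweep the cross-section equilibrium over a pressure range
#'
#' Solves the FE equilibrium at `n_p + 1` uniformly spaced pressures in
#' `[0, p_max]`, warm-starting each solve from the previous one.
#'
#' @param mesh a `vessel_mesh`
#' @param materials a [tissue_materials()]
#' @param inelastic an [inelastic_state()]
#' @param p_max maximum pressure (mmHg)
#' @param n_p number of incremental load steps
#' @param keep_states keep the displacement fields (for warm starts and
#'   post-processing)
#' @return data.frame `(p, A, r)` with attribute `states` when requested
#' @export
#' @param warm_u optional list of displacement fields (one per pressure
#'   point, e.g. from a previous sweep) used as initial guesses
sweep_pressure_area <- function(mesh, materials, inelastic, p_max = 250,
                                n_p = 10, keep_states = FALSE,
                                warm_u = NULL) {
  stopifnot(p_max > 0, n_p >= 4)
  ps <- seq(0, p_max, length.out = n_p + 1)
  A <- numeric(length(ps))
  states <- if (keep_states) vector("list", length(ps)) else NULL
  u_list <- vector("list", length(ps))
  u <- NULL
  for (i in seq_along(ps)) {
    u0 <- if (!is.null(warm_u) && length(warm_u) == length(ps))
      warm_u[[i]] else u
    sol <- tryCatch(
      solve_equilibrium(mesh, materials, inelastic, ps[i], u0 = u0),
      error = function(e) NULL)
    if (is.null(sol) && !is.null(u0) && !identical(u0, u))
      sol <- solve_equilibrium(mesh, materials, inelastic, ps[i], u0 = u)
    if (is.null(sol))
      stop("pressure sweep failed at p = ", ps[i], " mmHg", call. = FALSE)
    u <- sol$u
    u_list[[i]] <- u
    A[i] <- sol$A_s
    if (keep_states) states[[i]] <- sol
  }
  out <- data.frame(p = ps, A = A, r = sqrt(A / pi))
  if (keep_states) attr(out, "states") <- states
  attr(out, "u_list") <- u_list
  out
}

surro_eval <- function(p, a, b, c, d) a / (1 + exp(-b * (p / c - 1))) + d

surro_deriv <- function(p, a, b, c, d) {
  s <- 1 / (1 + exp(-b * (p / c - 1)))
  a * b / c * s * (1 - s)
}

#' Fit the sigmoid pressure-area surrogate
#'
#' Constrained least squares (`a, b, c > 0`) with multi-start
#' Levenberg-Marquardt; the fit with the smallest residual is returned.
#'
#' @param pairs data.frame with columns `p` (mmHg) and `A` (mm^2)
#' @param warn_frac residual threshold (fraction of the area range) above
#'   which a surrogate-quality warning is raised
#' @return object of class `surrogate_ap` with `a, b, c, d`, `rms`, `p_range`
#' @export
fit_surrogate <- function(pairs, warn_frac = 0.02) {
  stopifnot(nrow(pairs) >= 4)
  p <- pairs$p; A <- pairs$A
  rngA <- max(A) - min(A)
  prng <- range(p)
  best <- NULL
  starts <- expand.grid(b = c(0.5, 1, 2, 4, 8),
                        c = c(0.2, 0.35, 0.5, 0.75, 1) * max(max(p), 1),
                        a = c(1, 2.5) * max(rngA, 1e-3))
  for (k in seq_len(nrow(starts))) {
    st <- list(a = starts$a[k], b = starts$b[k], c = starts$c[k],
               d = min(A) - 0.5 * rngA)
    fit <- tryCatch(
      minpack.lm::nlsLM(A ~ a / (1 + exp(-b * (p / c - 1))) + d,
                        data = data.frame(p = p, A = A), start = st,
                        lower = c(a = 1e-9, b = 1e-9, c = 1e-9, d = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rms <- sqrt(mean(stats::resid(fit)^2))
    if (is.null(best) || rms < best$rms) {
      cf <- coef(fit)
      best <- list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]], d = cf[["d"]],
                   rms = rms)
    }
  }
  if (is.null(best)) {
    # derivative-free fallback on log-scaled shape parameters
    obj <- function(th) {
      pred <- exp(th[1]) / (1 + exp(-exp(th[2]) * (p / exp(th[3]) - 1))) +
        th[4]
      sum((A - pred)^2)
    }
    o_best <- NULL
    for (k in seq_len(nrow(starts))) {
      th0 <- c(log(starts$a[k]), log(starts$b[k]), log(starts$c[k]),
               min(A) - 0.5 * rngA)
      o <- tryCatch(optim(th0, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(o_best) || o$value < o_best$value))
        o_best <- o
    }
    if (is.null(o_best))
      stop("surrogate fit failed for all starts", call. = FALSE)
    best <- list(a = exp(o_best$par[1]), b = exp(o_best$par[2]),
                 c = exp(o_best$par[3]), d = o_best$par[4],
                 rms = sqrt(o_best$value / length(A)))
  }
  if (best$rms > warn_frac * max(rngA, 1e-12))
    warning(sprintf("surrogate RMS residual %.3g exceeds %.0f%% of area range",
                    best$rms, 100 * warn_frac))
  structure(c(best, list(p_range = prng)), class = "surrogate_ap")
}

#' @exportS3Method base::print
print.surrogate_ap <- function(x, ...) {
  cat(sprintf("surrogate_ap: A(p) = %.3f/(1+exp(-%.3f(p/%.2f - 1))) + %.3f  (RMS %.3g mm^2)\n",
              x$a, x$b, x$c, x$d, x$rms))
  invisible(x)
}

#' Evaluate the surrogate area
#' @param surrogate a `surrogate_ap`
#' @param p pressure (mmHg), vectorized
#' @return area (mm^2)
#' @export
surrogate_area <- function(surrogate, p)
  surro_eval(p, surrogate$a, surrogate$b, surrogate$c, surrogate$d)

#' Segment resistance and compliance from the surrogate
#'
#' Poiseuille resistance `8 pi mu ell / A^2` and compliance
#' `ell dA/dp` using the analytic surrogate derivative.
#'
#' @param surrogate a `surrogate_ap`
#' @param p pressure (mmHg)
#' @param ell_S segment length (mm)
#' @param mu_b dynamic blood viscosity (Pa s)
#' @return list with `R_S` (mmHg s/mL), `C_S` (mL/mmHg), `A` (mm^2)
#' @export
resistance_compliance <- function(surrogate, p, ell_S, mu_b) {
  A <- surrogate_area(surrogate, p)
  if (any(A <= 0)) stop("surrogate area non-positive", call. = FALSE)
  dAdp <- surro_deriv(p, surrogate$a, surrogate$b, surrogate$c, surrogate$d)
  list(R_S = poiseuille_resistance(A, ell_S, mu_b),
       C_S = ell_S * dAdp * 1e-3, A = A)
}
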