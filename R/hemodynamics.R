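# Lumped-parameter (0D) three-segment network: upstream artery, segment of
# interest (surrogate-backed R/C), downstream vasculature. Pressures evolve
# on the fast (heartbeat) time scale and are integrated by backward Euler;
# fictitious pre-beats damp the unknown initial condition before the
# physical window used for averaging.

#' Network parameters of the 0D model
#'
#' @param R1,C1 resistance (mmHg s/mL) and compliance (mL/mmHg) of the
#'   upstream segment
#' @param R3,C3 same for the downstream vasculature
#' @param P_out outflow pressure (mmHg)
#' @param mu_b dynamic blood viscosity (Pa s)
#' @param f_h_b basal heart rate (beats/s)
#' @param V_h stroke volume per beat (mL); 93.33 mL at 60 bpm corresponds to
#'   a cardiac output of 5.6 L/min
#' @param n_h number of physical beats averaged
#' @param steps_per_beat fast-scale resolution
#' @return list of class `network_params`
#' @export
network_params <- function(R1 = 0.1, C1 = 0.5, R3 = 1, C3 = 0.001,
                           P_out = 0, mu_b = 3.5e-3, f_h_b = 1,
                           V_h = 5.6 * 1000 / 60, n_h = 3,
                           steps_per_beat = 200) {
  structure(list(R1 = R1, C1 = C1, R3 = R3, C3 = C3, P_out = P_out,
                 mu_b = mu_b, f_h_b = f_h_b, V_h = V_h, n_h = n_h,
                 steps_per_beat = steps_per_beat), class = "network_params")
}

#' Pulsatile inflow waveform
#'
#' Half-beat raised-cosine ejection of amplitude `Q_a = 4 f_h V_h` followed
#' by a zero-flow filling phase; the per-beat integral equals `V_h`.
#'
#' @param t_h fast time (s), vectorized
#' @param t0 beat-train start (s)
#' @param f_h heart rate (beats/s)
#' @param V_h per-beat ejected volume (mL)
#' @return flow (mL/s)
#' @export
inflow_waveform <- function(t_h, t0 = 0, f_h = 1, V_h = 5.6 * 1000 / 60) {
  stopifnot(f_h > 0)
  Th <- 1 / f_h
  tb <- (t_h - t0) %% Th
  Qa <- 4 * f_h * V_h
  ifelse(tb < Th / 2, Qa / 2 * (1 - cos(4 * pi * f_h * tb)), 0)
}

#' Backward-Euler run of the three-segment network
#'
#' Integrates the pressure ODEs over `n_pre` fictitious pre-beats (from the
#' uniform outflow-pressure state) plus `n_h` physical beats, and returns the
#' physical window. The segment of interest draws its pressure-dependent
#' resistance and compliance from a fitted pressure-area surrogate, or fixed
#' values for verification runs.
#'
#' @param net a [network_params()]
#' @param f_h heart rate for this window (beats/s)
#' @param surrogate a `surrogate_ap` (or `NULL` with `fixed_rc`)
#' @param ell_S segment length (mm)
#' @param n_pre number of pre-beats; default ensures `n_pre / f_h >= 5` s
#' @param fixed_rc optional list `list(R_S=, C_S=)` bypassing the surrogate
#' @param inflow `"pulsatile"` or `"constant"` (constant at `Q_const`)
#' @param Q_const constant inflow (mL/s) when `inflow = "constant"`
#' @param steps_per_beat override of the fast-scale resolution
#' @return data.frame time series over the physical window: `t_h, P1, PS,
#'   P3, Qh, QSp, QSm, pS, qS, A, r, tau`
#' @export
backward_euler_run <- function(net, f_h, surrogate = NULL, ell_S = 300,
                               n_pre = NULL, fixed_rc = NULL,
                               inflow = c("pulsatile", "constant"),
                               Q_const = 0, steps_per_beat = NULL) {
  inflow <- match.arg(inflow)
  stopifnot(f_h > 0)
  if (is.null(n_pre)) n_pre <- max(5L, ceiling(5 * f_h))
  spb <- if (is.null(steps_per_beat)) net$steps_per_beat else steps_per_beat
  fr <- !is.null(fixed_rc)
  if (!fr && is.null(surrogate)) stop("need a surrogate or fixed_rc")
  a <- if (fr) 1 else surrogate$a
  b <- if (fr) 1 else surrogate$b
  cc <- if (fr) 1 else surrogate$c
  d <- if (fr) 0 else surrogate$d
  m <- ode0d_run_cpp(f_h, net$V_h, net$R1, net$C1, net$R3, net$C3, net$P_out,
                     net$mu_b, ell_S, a, b, cc, d, as.integer(n_pre),
                     as.integer(net$n_h), as.integer(spb),
                     if (inflow == "constant") 1L else 0L, Q_const,
                     if (fr) 1L else 0L,
                     if (fr) fixed_rc$R_S else 0,
                     if (fr) fixed_rc$C_S else 0)
  colnames(m) <- c("t_h", "P1", "PS", "P3", "Qh", "QSp", "QSm", "pS", "qS",
                   "A", "r", "tau")
  as.data.frame(m)
}

#' Mean segment pressure and flow series
#' @param series a `backward_euler_run()` data.frame
#' @return data.frame with `t_h`, `p_S`, `q_S`
#' @export
mean_segment_quantities <- function(series) {
  data.frame(t_h = series$t_h,
             p_S = (series$PS + series$P3) / 2,
             q_S = (series$QSp + series$QSm) / 2)
}

#' Poiseuille wall shear stress series
#' @param q_S flow (mL/s)
#' @param r_S lumen radius (mm)
#' @param mu_b dynamic viscosity (Pa s)
#' @return shear stress (Pa)
#' @export
wall_shear_series <- function(q_S, r_S, mu_b) {
  stopifnot(all(r_S > 0))
  4 * mu_b * q_S / (pi * r_S^3) * 1e3
}

#' Time-averaged wall shear stress over the physical window
#'
#' Trapezoidal average of the shear series over the `n_h`-beat window.
#'
#' @param tau shear series (Pa)
#' @param t_h time stamps (s) spanning `n_h / f_h` seconds
#' @return TAWSS (Pa)
#' @export
tawss <- function(tau, t_h) {
  n <- length(tau)
  if (n < 2 || t_h[n] <= t_h[1]) stop("incomplete averaging window")
  dt <- diff(t_h)
  sum(dt * (tau[-1] + tau[-n]) / 2) / (t_h[n] - t_h[1])
}

#' Poiseuille resistance of a cylindrical segment
#' @param A lumen area (mm^2)
#' @param ell length (mm)
#' @param mu_b dynamic viscosity (Pa s)
#' @return resistance (mmHg s/mL)
#' @export
poiseuille_resistance <- function(A, ell, mu_b) {
  8 * pi * mu_b * (ell * 1e-3) / (A * 1e-6)^2 / 133.322e6
}
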