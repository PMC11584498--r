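# Configuration: canonical parameter set with explicit units, YAML loading
# with strict key validation and optional unit-annotated overrides.

#' Default configuration
#'
#' All model parameters with their canonical units: geometry in mm, tissue
#' stiffness in kPa, concentrations in nM, rates in nM/s, network resistances
#' in mmHg s/mL, compliances in mL/mmHg, viscosity in Pa s, times in s.
#'
#' @return nested list of class `vasotone_config`
#' @export
default_config <- function() {
  structure(list(
    geometry = list(R_i0 = 5.55, d_IM = 0.8, d_A = 0.4, eta = 0,
                    ell_S = 300, lambda_z = 1.3),
    mesh = list(n_circ = 48, n_radial_media = 8, n_radial_adventitia = 4,
                seed = 1L),
    ecm = list(mu = 10, k1 = 10, k2 = 2.5, phi_deg = 45, kappa = 1e5),
    smc = list(C_smc = 100, P_smc_max = 100),
    calcified = list(c1 = 302, c2 = -228, c3 = 261, kappa = 1e5,
                     angular_fraction = 1 / 3, radial_extent = 1),
    kinetics = list(D_NO = 848, D_ROS = 848, eta_NO = 1.01, K_RNS = 4,
                    P_NO_b = 80, C_NO_b = 10, R_NO_max = 75, P_O2 = 90,
                    K_m = 5.5),
    tone = list(lambda_minus = 0.59, lambda_b = 0.75, lambda_plus = 1.3,
                k_lambda = 100, xi_c = 0.15),
    network = list(R1 = 0.1, C1 = 0.5, R3 = 1, C3 = 0.001, P_out = 0,
                   mu_b = 3.5e-3, f_h_b = 1, V_h = 5.6 * 1000 / 60,
                   n_h = 3, steps_per_beat = 200),
    coupling = list(p_max = 250, n_p = 10, tol = 1e-3, max_iter = 25,
                    dt_ramp = 10, dt_plateau = 60),
    scenario = list(name = "basal_equilibrium", alpha_dys = 0,
                    duration = 3600),
    output = list(dir = "vasotone_out", stride = 10L)
  ), class = "vasotone_config")
}

unit_factors <- c("kPa" = 1, "MPa" = 1000, "Pa" = 1e-3, "GPa" = 1e6,
                  "mm" = 1, "cm" = 10, "m" = 1000, "um" = 1e-3,
                  "s" = 1, "min" = 60, "h" = 3600,
                  "mmHg" = 1, "nM" = 1, "uM" = 1000,
                  "Pa.s" = 1, "mPa.s" = 1e-3)

resolve_units <- function(x) {
  if (is.list(x) && !is.null(x$value) && !is.null(x$unit)) {
    f <- unit_factors[[x$unit]]
    if (is.null(f)) stop("unknown unit '", x$unit, "'", call. = FALSE)
    return(x$value * f)
  }
  if (is.list(x)) return(lapply(x, resolve_units))
  x
}

check_keys <- function(user, ref, path = "") {
  if (!is.list(user)) return(invisible(TRUE))
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(ref)) {
      sug <- agrep(k, names(ref), max.distance = 0.3, value = TRUE)
      hint <- if (length(sug)) paste0("; did you mean '", sug[1], "'?") else ""
      stop("unknown configuration key '", full, "'", hint, call. = FALSE)
    }
    if (is.list(ref[[k]]) && is.list(user[[k]]) &&
        !(!is.null(user[[k]]$value) && !is.null(user[[k]]$unit)))
      check_keys(user[[k]], ref[[k]], full)
  }
  invisible(TRUE)
}

#' Load a configuration from YAML
#'
#' Unknown keys are rejected (with a spelling suggestion); values may be
#' given either as plain numbers in canonical units or as
#' `{value: ..., unit: ...}` maps that are converted on load.
#'
#' @param path YAML file; an empty file yields the defaults
#' @return a `vasotone_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::yaml.load_file(path)
  ref <- default_config()
  if (is.null(user)) return(ref)
  check_keys(user, ref)
  user <- resolve_units(user)
  out <- modifyList(ref, user)
  class(out) <- "vasotone_config"
  out
}

#' Write a configuration to YAML
#' @param config a `vasotone_config`
#' @param path output file
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
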