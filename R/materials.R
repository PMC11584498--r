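# Constitutive models: fiber-reinforced ECM (neo-Hookean elastin + two
# exponential collagen families with an inelastic straightening stretch),
# active-strain smooth muscle, and a 3-term Yeoh law for calcified tissue.
# The pure-R routines here are the reference implementations used directly in
# tests; the compiled element kernel evaluates the same laws.

#' Extracellular matrix parameters
#'
#' @param mu elastin shear modulus (kPa)
#' @param k1,k2 collagen stiffness constants (kPa, dimensionless), shared by
#'   both fiber families
#' @param phi_deg collagen helix angle from the circumferential direction
#'   (degrees); the two families sit at `+phi` and `-phi`
#' @param kappa bulk modulus (kPa)
#' @return list of class `ecm_params`
#' @export
ecm_params <- function(mu = 10, k1 = 10, k2 = 2.5, phi_deg = 45,
                       kappa = 1e5) {
  stopifnot(mu > 0, k1 > 0, k2 > 0, kappa > 0)
  structure(list(mu = mu, k1 = k1, k2 = k2, phi_deg = phi_deg, kappa = kappa),
            class = "ecm_params")
}

#' Smooth muscle cell parameters
#' @param C_smc SMC elastic stiffness (kPa)
#' @param P_smc_max maximum isometric first Piola-Kirchhoff stress (kPa)
#' @export
smc_params <- function(C_smc = 100, P_smc_max = 100) {
  stopifnot(C_smc > 0, P_smc_max > 0)
  structure(list(C_smc = C_smc, P_smc_max = P_smc_max), class = "smc_params")
}

#' Calcified-tissue Yeoh parameters
#' @param c1,c2,c3 Yeoh coefficients (kPa)
#' @param kappa bulk modulus (kPa)
#' @export
calcified_params <- function(c1 = 302, c2 = -228, c3 = 261, kappa = 1e5) {
  structure(list(c1 = c1, c2 = c2, c3 = c3, kappa = kappa),
            class = "calcified_params")
}

#' Bundle of tissue material parameters
#' @param ecm an [ecm_params()]
#' @param smc an [smc_params()]
#' @param calc a [calcified_params()]
#' @param lambda_z axial pre-stretch
#' @export
tissue_materials <- function(ecm = ecm_params(), smc = smc_params(),
                             calc = calcified_params(), lambda_z = 1.3) {
  structure(list(ecm = ecm, smc = smc, calc = calc, lambda_z = lambda_z),
            class = "tissue_materials")
}

check_spd <- function(C) {
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-10)))
    stop("C must be symmetric", call. = FALSE)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("C must be positive definite", call. = FALSE)
  invisible(TRUE)
}

#' ECM strain energy and stress
#'
#' Isochoric neo-Hookean elastin part plus two exponential collagen families.
#' The inelastic straightening stretch `lambda_cs` rescales the reference
#' metric of the fiber, acting on the squared invariant:
#' `I4e = I4 / lambda_cs^4`. (This invariant-level map is the reading that
#' reproduces the stated vascular-tone calibration; see the methods
#' vignette.) Compressed fibers (`I4e <= 1`) store no energy (Macaulay
#' bracket).
#'
#' @param C 3x3 right Cauchy-Green tensor in the local
#'   (circumferential, axial, radial) frame
#' @param params an [ecm_params()]
#' @param lambda_cs collagen straightening stretch (> 0)
#' @return list with `energy` (kPa, deviatoric part only), `S` (3x3 second
#'   Piola-Kirchhoff deviatoric stress, kPa), and the invariants
#' @export
ecm_energy_and_stress <- function(C, params = ecm_params(), lambda_cs = 1) {
  check_spd(C)
  stopifnot(lambda_cs > 0)
  J <- sqrt(det(C))
  I1 <- sum(diag(C))
  Ib1 <- J^(-2 / 3) * I1
  Ci <- solve(C)
  S <- params$mu * J^(-2 / 3) * (diag(3) - (I1 / 3) * Ci)
  energy <- params$mu / 2 * (Ib1 - 3)
  phi <- params$phi_deg * pi / 180
  I4e <- numeric(2)
  for (s in c(1, 2)) {
    sgn <- if (s == 1) 1 else -1
    a <- c(cos(sgn * phi), sin(sgn * phi), 0) # e_theta, e_z, e_r frame
    I4 <- drop(a %*% C %*% a)
    I4e[s] <- I4 / lambda_cs^4
    E <- I4e[s] - 1
    if (E > 0) {
      energy <- energy + params$k1 / (2 * params$k2) *
        (exp(params$k2 * E^2) - 1)
      dpsi <- params$k1 * E * exp(params$k2 * E^2)
      S <- S + 2 * dpsi / lambda_cs^4 * tcrossprod(a)
    }
  }
  list(energy = energy, S = S, I1_bar = Ib1, I4e = I4e)
}

#' Scalar first Piola-Kirchhoff stress of smooth muscle
#'
#' The sigmoid stress-stretch law `P = P_max (2 s(x) - 1)` with
#' `x = (2 C_smc / P_max)(lambda_e - 1)` and `s` the logistic function; the
#' tangent at `lambda_e = 1` equals `C_smc` and the stress is bounded in
#' `(-P_max, P_max)`.
#'
#' @param lambda_e elastic SMC stretch (> 0)
#' @param params an [smc_params()]
#' @return stress (kPa)
#' @export
smc_stress <- function(lambda_e, params = smc_params()) {
  stopifnot(all(lambda_e > 0))
  x <- 2 * params$C_smc / params$P_smc_max * (lambda_e - 1)
  params$P_smc_max * (2 / (1 + exp(-x)) - 1)
}

#' SMC strain energy density
#' @param lambda_e elastic SMC stretch
#' @param params an [smc_params()]
#' @return energy (kPa)
#' @export
smc_energy <- function(lambda_e, params = smc_params()) {
  Pm <- params$P_smc_max; Cs <- params$C_smc
  Pm / Cs * (Pm * log(1 + exp(2 * Cs / Pm * (lambda_e - 1))) - Cs * lambda_e)
}

#' Multiplicative active-elastic split of the SMC deformation
#'
#' `F_a = lambda_a M + lambda_a^{-1/2} (I - M)` with `M = e_theta x e_theta`;
#' `F_e = F F_a^{-1}` and the elastic stretch along the SMC direction is
#' `lambda_e = sqrt(Tr(C_e M)) = lambda_theta / lambda_a` for shear-free
#' kinematics.
#'
#' @param F 3x3 deformation gradient in the (circumferential, axial, radial)
#'   frame
#' @param lambda_a active stretch (> 0)
#' @return list with `F_e` and `lambda_e`
#' @export
active_elastic_split <- function(F, lambda_a) {
  stopifnot(lambda_a > 0, det(F) > 0)
  M <- diag(c(1, 0, 0))
  Fa <- lambda_a * M + lambda_a^(-1 / 2) * (diag(3) - M)
  Fe <- F %*% solve(Fa)
  Ce <- t(Fe) %*% Fe
  list(F_e = Fe, lambda_e = sqrt(sum(diag(Ce %*% M))))
}

#' Yeoh energy and stress of calcified tissue
#'
#' `Psi = sum_i c_i (I1_bar - 3)^i` with the same perturbed-Lagrangian
#' volumetric treatment as the healthy wall (deviatoric part returned here).
#'
#' @param C 3x3 right Cauchy-Green tensor
#' @param params a [calcified_params()]
#' @return list with `energy` (kPa) and deviatoric `S`
#' @export
calcified_energy_and_stress <- function(C, params = calcified_params()) {
  check_spd(C)
  J <- sqrt(det(C))
  I1 <- sum(diag(C))
  Ib <- J^(-2 / 3) * I1 - 3
  energy <- params$c1 * Ib + params$c2 * Ib^2 + params$c3 * Ib^3
  psip <- params$c1 + 2 * params$c2 * Ib + 3 * params$c3 * Ib^2
  S <- 2 * psip * J^(-2 / 3) * (diag(3) - ((I1 + 0) / 3) * solve(C))
  list(energy = energy, S = S, I1_bar = Ib + 3)
}
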