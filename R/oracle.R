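# Semi-analytic inflation of an incompressible two-layer thick-walled tube
# with the same constitutive laws as the FE model, used as an independent
# verification oracle for axisymmetric, region-wise homogeneous states.
#
# Incompressible kinematics at fixed axial stretch: r(R)^2 = ri^2 +
# (R^2 - Ri^2)/lambda_z, lambda_theta = r/R, lambda_r = 1/(lambda_theta
# lambda_z). The lumen pressure balances the integral of
# (sigma_theta - sigma_r)/r = lambda_theta dPsi/dlambda_theta / r across the
# wall.

oracle_energy <- function(lth, lz, region, materials, lambda_a, lambda_cs) {
  lr <- 1 / (lth * lz)
  e <- materials$ecm
  if (region == "calcified") {
    I1 <- lth^2 + lz^2 + lr^2
    cc <- materials$calc
    Ib <- I1 - 3
    return(cc$c1 * Ib + cc$c2 * Ib^2 + cc$c3 * Ib^3)
  }
  I1 <- lth^2 + lz^2 + lr^2
  psi <- e$mu / 2 * (I1 - 3)
  phi <- e$phi_deg * pi / 180
  I4 <- cos(phi)^2 * lth^2 + sin(phi)^2 * lz^2
  lcs <- if (region == "media") lambda_cs else 1
  E <- I4 / lcs^4 - 1  # invariant-level straightening map
  if (E > 0) psi <- psi + 2 * e$k1 / (2 * e$k2) * (exp(e$k2 * E^2) - 1)
  if (region == "media") {
    le <- lth / lambda_a
    psi <- psi + smc_energy(le, materials$smc)
  }
  psi
}

#' Thick-walled-tube inflation oracle
#'
#' Solves the incompressible axisymmetric inflation of the two-layer tube by
#' radial quadrature of the equilibrium integral, with uniform `lambda_a`
#' (healthy media) and `lambda_cs`. Intended for verification only.
#'
#' @param geom a [cross_section_geometry()]
#' @param materials a [tissue_materials()]
#' @param lambda_a uniform active stretch in the media
#' @param lambda_cs uniform collagen straightening stretch in the media
#' @param p_lumen internal pressure (mmHg)
#' @param n_quad quadrature points per layer
#' @return deformed inner radius (mm)
#' @export
oracle_tube_1d <- function(geom, materials, lambda_a = 1, lambda_cs = 1,
                           p_lumen = 0, n_quad = 200) {
  Ri <- geom$R_i0; Rm <- Ri + geom$d_IM; Ro <- Rm + geom$d_A
  lz <- materials$lambda_z
  dpsi_dlth <- function(lth, region) {
    h <- 1e-6
    (vapply(lth + h, oracle_energy, 0, lz = lz, region = region,
            materials = materials, lambda_a = lambda_a,
            lambda_cs = lambda_cs) -
       vapply(lth - h, oracle_energy, 0, lz = lz, region = region,
              materials = materials, lambda_a = lambda_a,
              lambda_cs = lambda_cs)) / (2 * h)
  }
  p_of_ri <- function(ri) {
    # composite Simpson per layer (the integrand kinks at the interface)
    quad_layer <- function(Ra, Rb, region) {
      n <- if (n_quad %% 2 == 0) n_quad else n_quad + 1
      R <- seq(Ra, Rb, length.out = n + 1)
      r <- sqrt(ri^2 + (R^2 - Ri^2) / lz)
      lth <- r / R
      f <- lth * dpsi_dlth(lth, region) / r
      # dr/dR = R/(lz r); integrate f dr = f (dr/dR) dR
      g <- f * R / (lz * r)
      h <- (Rb - Ra) / n
      w <- rep(c(4, 2), length.out = n - 1)
      h / 3 * (g[1] + g[n + 1] + sum(w * g[2:n]))
    }
    quad_layer(Ri, Rm, "media") + quad_layer(Rm, Ro, "adventitia")
  }
  target <- mmHg_to_kPa(p_lumen)
  f <- function(ri) p_of_ri(ri) - target
  lo <- 0.2 * Ri; hi <- 3 * Ri
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}
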