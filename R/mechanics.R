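# Mixed Q1/P0 finite-element equilibrium of the pressurized cross section.
# Displacements are bilinear, the pressure-like multiplier is element-wise
# constant and statically condensed (p_e = kappa * mean(J - 1), the
# stationarity of the perturbed-Lagrangian energy). The lumen pressure acts
# as a follower load on the deformed intima; out-of-plane kinematics is
# generalized plane strain with a fixed axial pre-stretch.

mech_param_list <- function(materials) {
  list(mu = materials$ecm$mu, k1 = materials$ecm$k1, k2 = materials$ecm$k2,
       phi_rad = materials$ecm$phi_deg * pi / 180,
       kappa = materials$ecm$kappa,
       C_smc = materials$smc$C_smc, P_smc_max = materials$smc$P_smc_max,
       c1 = materials$calc$c1, c2 = materials$calc$c2, c3 = materials$calc$c3,
       kappa_c = materials$calc$kappa, lambda_z = materials$lambda_z)
}

#' Per-element inelastic state
#'
#' @param mesh a `vessel_mesh`
#' @param lambda_a active SMC stretch: scalar (uniform over the healthy
#'   media) or per-element vector
#' @param lambda_cs collagen straightening stretch, same conventions; if
#'   `NULL` it is slaved to `lambda_a` through [collagen_straightening()]
#'   with transfer fraction `xi_c`
#' @param xi_c collagen transfer fraction
#' @return list with per-element `lambda_a`, `lambda_cs` (identity outside
#'   the healthy media)
#' @export
inelastic_state <- function(mesh, lambda_a = 1, lambda_cs = NULL,
                            xi_c = 0.15) {
  ne <- nrow(mesh$elems)
  stopifnot(length(lambda_a) %in% c(1L, ne))
  la <- rep(1, ne)
  la[mesh$region == 0] <- if (length(lambda_a) == 1) lambda_a else
    lambda_a[mesh$region == 0]
  if (is.null(lambda_cs)) {
    lcs <- rep(1, ne)
    lcs[mesh$region == 0] <- collagen_straightening(la[mesh$region == 0], xi_c)
  } else {
    lcs <- rep(1, ne)
    lcs[mesh$region == 0] <- if (length(lambda_cs) == 1) lambda_cs else
      lambda_cs[mesh$region == 0]
  }
  list(lambda_a = la, lambda_cs = lcs)
}

# dofs fixed to remove in-plane rigid-body modes: tangential displacement at
# outer-boundary nodes nearest theta = 0, pi/2 and pi (compatible with
# axisymmetric radial fields)
rigid_body_dofs <- function(mesh) {
  th <- atan2(mesh$coords[mesh$outer_loop, 2], mesh$coords[mesh$outer_loop, 1])
  th[th < 0] <- th[th < 0] + 2 * pi
  pick <- function(t0) mesh$outer_loop[which.min(pmin(abs(th - t0),
                                                      2 * pi - abs(th - t0)))]
  n0 <- pick(0); n90 <- pick(pi / 2); n180 <- pick(pi)
  c(2 * n0, 2 * n90 - 1, 2 * n180) # uy at 0 and pi, ux at pi/2
}

assemble_mech <- function(mesh, materials, inelastic, u, p_kPa,
                          want_tangent = TRUE, want_fields = FALSE) {
  mech_assemble_cpp(mesh$coords, mesh$elems, as.integer(mesh$region),
                    inelastic$lambda_a, inelastic$lambda_cs, u, p_kPa,
                    as.integer(mesh$inner_loop), mech_param_list(materials),
                    want_tangent, want_fields)
}

# Newton driver. A fast nonmonotone pass (full steps, halved only on
# element inversion) handles the common smooth cases, including the
# transient residual growth typical of the volumetric penalty. If it fails,
# a monotone trust-region pass (step-norm cap) takes over; that one copes
# with the nearly-neutral buckling modes of the stiff calcified arc under
# the in-plane compression induced by the axial pre-stretch.
newton_mech <- function(mesh, materials, inelastic, p_kPa, u0, fixed,
                        tol_rel = 1e-8, max_iter = 30) {
  out <- newton_plain(mesh, materials, inelastic, p_kPa, u0, fixed,
                      tol_rel, max_iter)
  if (isTRUE(out$ok)) return(out)
  newton_trust(mesh, materials, inelastic, p_kPa, u0, fixed, tol_rel,
               max_iter = 250)
}

solve_tangent <- function(a, free, ndof, reg = 0) {
  K <- Matrix::sparseMatrix(i = as.integer(a$ti), j = as.integer(a$tj),
                            x = as.numeric(a$tx),
                            dims = c(ndof, ndof))[free, free, drop = FALSE]
  if (reg > 0) {
    dK <- pmax(abs(Matrix::diag(K)), 1e-8 * max(abs(Matrix::diag(K))))
    K <- K + reg * Matrix::Diagonal(x = dK)
  }
  tryCatch(as.numeric(Matrix::solve(K, -a$residual[free])),
           error = function(e) NULL)
}

newton_plain <- function(mesh, materials, inelastic, p_kPa, u0, fixed,
                         tol_rel, max_iter) {
  ndof <- 2 * nrow(mesh$coords)
  free <- setdiff(seq_len(ndof), fixed)
  u <- u0
  a <- assemble_mech(mesh, materials, inelastic, u, p_kPa)
  if (!isTRUE(a$ok)) return(list(ok = FALSE, reason = "inverted start"))
  ref <- NULL
  for (it in seq_len(max_iter)) {
    r <- a$residual[free]
    nr <- sqrt(sum(r^2))
    if (is.null(ref)) ref <- max(nr, 1e-4)
    if (nr < tol_rel * ref || nr < 1e-8)
      return(list(ok = TRUE, u = u, iters = it - 1, resid = nr))
    if (nr > 1e8 * ref)
      return(list(ok = FALSE, reason = "diverged", u = u))
    du <- solve_tangent(a, free, ndof)
    if (is.null(du) || any(!is.finite(du)))
      return(list(ok = FALSE, reason = "singular tangent", u = u))
    step <- 1
    repeat {
      u_try <- u
      u_try[free] <- u[free] + step * du
      a_try <- assemble_mech(mesh, materials, inelastic, u_try, p_kPa)
      if (isTRUE(a_try$ok)) break
      step <- step / 2
      if (step < 1 / 64)
        return(list(ok = FALSE, reason = "inverted element", u = u))
    }
    u <- u_try
    a <- a_try
  }
  list(ok = FALSE, reason = "max iterations", u = u)
}

newton_trust <- function(mesh, materials, inelastic, p_kPa, u0, fixed,
                         tol_rel, max_iter) {
  ndof <- 2 * nrow(mesh$coords)
  free <- setdiff(seq_len(ndof), fixed)
  u <- u0
  a <- assemble_mech(mesh, materials, inelastic, u, p_kPa)
  if (!isTRUE(a$ok)) return(list(ok = FALSE, reason = "inverted start"))
  ref <- NULL
  trust <- 0.2  # cap on the max nodal displacement increment (mm)
  for (it in seq_len(max_iter)) {
    r <- a$residual[free]
    nr <- sqrt(sum(r^2))
    if (is.null(ref)) ref <- max(nr, 1e-4)
    if (nr < tol_rel * ref || nr < 1e-8)
      return(list(ok = TRUE, u = u, iters = it - 1, resid = nr))
    du <- solve_tangent(a, free, ndof)
    if (is.null(du) || any(!is.finite(du)))
      du <- solve_tangent(a, free, ndof, reg = 1e-6)
    if (is.null(du) || any(!is.finite(du)))
      return(list(ok = FALSE, reason = "singular tangent", u = u))
    sc0 <- min(1, trust / max(abs(du)))
    sc <- sc0
    accepted <- FALSE
    for (h in 1:10) {
      u_try <- u
      u_try[free] <- u[free] + sc * du
      a_try <- assemble_mech(mesh, materials, inelastic, u_try, p_kPa)
      nr_try <- if (isTRUE(a_try$ok))
        sqrt(sum(a_try$residual[free]^2)) else Inf
      if (nr_try < nr) { u <- u_try; a <- a_try; accepted <- TRUE; break }
      sc <- sc / 2
    }
    if (!accepted)
      return(list(ok = FALSE, reason = "stagnated line search", u = u))
    trust <- if (sc >= 0.99 * sc0) min(1, trust * 1.5) else
      max(0.01, trust / 2)
  }
  list(ok = FALSE, reason = "max iterations", u = u)
}

#' Solve the cross-section equilibrium at a given lumen pressure
#'
#' Newton iteration with automatic load-step halving (up to 5 levels) on the
#' pressure increment, warm-started from `u0` when given. On failure from a
#' cold start the active stretch is additionally ramped in.
#'
#' @param mesh a `vessel_mesh`
#' @param materials a [tissue_materials()]
#' @param inelastic an [inelastic_state()]
#' @param p_lumen internal pressure (mmHg)
#' @param u0 optional initial displacement guess (length `2 * n_nodes`)
#' @param tol_rel relative residual tolerance of the Newton iteration
#' @return object of class `mechanical_solution`: displacements `u`, element
#'   pressure multiplier `pe` (kPa), mean volume ratio `Jbar`, element field
#'   matrix (`sigma_xx, sigma_yy, sigma_xy, sigma_zz`, von Mises, ...),
#'   deformed lumen area `A_s` (mm^2) and mean internal radius `r_i` (mm)
#' @export
solve_equilibrium <- function(mesh, materials, inelastic, p_lumen,
                              u0 = NULL, tol_rel = 1e-8) {
  stopifnot(p_lumen >= 0)
  ndof <- 2 * nrow(mesh$coords)
  # cold start: isochoric in-plane contraction compensating the axial
  # pre-stretch (J = 1 exactly), which avoids the large volumetric shock of
  # the undeformed guess
  u_iso <- as.numeric(t(mesh$coords)) * (materials$lambda_z^(-1 / 2) - 1)
  if (is.null(u0)) u0 <- u_iso
  fixed <- rigid_body_dofs(mesh)
  p_target <- mmHg_to_kPa(p_lumen)

  # pressure continuation from the warm-start state
  a0 <- assemble_mech(mesh, materials, inelastic, u0, p_target,
                      want_tangent = FALSE)
  u <- u0
  if (isTRUE(a0$ok)) {
    sol <- newton_mech(mesh, materials, inelastic, p_target, u, fixed, tol_rel)
    if (isTRUE(sol$ok)) return(finish_solution(mesh, materials, inelastic,
                                               p_target, sol))
  }
  # halve the load step relative to zero displacement / ramp activation
  n_half <- 0L; n_steps <- 2L
  if (p_target == 0) n_half <- 6L  # nothing to subdivide; go to the ramp
  while (n_half <= 5L) {
    u <- u0; ok_all <- TRUE
    for (s in seq_len(n_steps)) {
      ps <- p_target * s / n_steps
      sol <- newton_mech(mesh, materials, inelastic, ps, u, fixed, tol_rel)
      if (!isTRUE(sol$ok)) { ok_all <- FALSE; break }
      u <- sol$u
    }
    if (ok_all) return(finish_solution(mesh, materials, inelastic, p_target,
                                       sol))
    n_half <- n_half + 1L
    if (n_half > 5L) break
    n_steps <- 2L * n_steps
  }
  # activation ramp fallback from the isochoric cold start
  u <- u_iso
  for (g in seq(0.1, 1, by = 0.1)) {
    inel_g <- list(lambda_a = 1 + g * (inelastic$lambda_a - 1),
                   lambda_cs = 1 + g * (inelastic$lambda_cs - 1))
    sol <- newton_mech(mesh, materials, inel_g, 0, u, fixed, tol_rel)
    if (!isTRUE(sol$ok)) stop("equilibrium solve failed: ", sol$reason,
                              call. = FALSE)
    u <- sol$u
  }
  for (s in seq_len(8L)) {
    ps <- p_target * s / 8L
    sol <- newton_mech(mesh, materials, inelastic, ps, u, fixed, tol_rel)
    if (!isTRUE(sol$ok)) stop("equilibrium solve failed: ", sol$reason,
                              call. = FALSE)
    u <- sol$u
  }
  finish_solution(mesh, materials, inelastic, p_target, sol)
}

finish_solution <- function(mesh, materials, inelastic, p_kPa, sol) {
  a <- assemble_mech(mesh, materials, inelastic, sol$u, p_kPa,
                     want_tangent = FALSE, want_fields = TRUE)
  f <- a$fields
  colnames(f) <- c("pe", "Jbar", "Cinv_xx", "Cinv_yy", "Cinv_xy",
                   "sigma_xx", "sigma_yy", "sigma_xy", "sigma_zz",
                   "von_mises", "lambda_theta", "sigma_tt_smc", "lambda_a",
                   "ref_area")
  A <- deformed_lumen_area(mesh, sol$u)
  structure(list(u = sol$u, pe = a$pe, Jbar = a$Jbar, fields = f,
                 p_lumen_kPa = p_kPa, A_s = A, r_i = sqrt(A / pi),
                 iters = sol$iters, resid = sol$resid),
            class = "mechanical_solution")
}

#' @exportS3Method base::print
print.mechanical_solution <- function(x, ...) {
  cat(sprintf("mechanical_solution: p = %.2f mmHg, A = %.3f mm^2, r_i = %.4f mm (%d Newton its)\n",
              kPa_to_mmHg(x$p_lumen_kPa), x$A_s, x$r_i, x$iters))
  invisible(x)
}

deformed_lumen_area <- function(mesh, u) {
  idx <- mesh$inner_loop
  xy <- mesh$coords[idx, , drop = FALSE] +
    cbind(u[2 * idx - 1], u[2 * idx])
  polygon_area(xy)
}

#' Deformed lumen area of a mechanical solution
#'
#' Signed polygon (shoelace) area of the deformed intima loop.
#'
#' @param solution a `mechanical_solution`
#' @param mesh the `vessel_mesh` it was computed on
#' @return area (mm^2)
#' @export
compute_lumen_area <- function(solution, mesh) {
  A <- deformed_lumen_area(mesh, solution$u)
  if (A <= 0) stop("deformed intima loop has non-positive area", call. = FALSE)
  A
}
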