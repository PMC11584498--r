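# NO-ROS reaction-diffusion in the arterial wall, endothelial shear-dependent
# production, and the maps from NO concentration to smooth muscle active
# stretch and collagen straightening.
#
# Species are material concentrations on the reference mesh; the diffusion
# operator carries the pulled-back metric J C^{-1} of the converged
# mechanical state. Reaction terms are evaluated nodally and weighted by the
# consistent mass matrix (group finite elements), which preserves the uniform
# basal steady state exactly.

#' Kinetic and endothelial parameters of the NO-ROS system
#'
#' Defaults reproduce the basal closure: the ROS basal concentration and
#' production rate are derived from the NO values so that the homogeneous
#' steady state of the mass balances holds identically.
#'
#' @param D_NO,D_ROS diffusion constants (um^2/s)
#' @param eta_NO first-order NO decay rate (1/s)
#' @param K_RNS second-order RNS production rate (1/(nM s))
#' @param P_NO_b NO basal production rate (nM/s)
#' @param C_NO_b NO basal concentration (nM)
#' @param R_NO_max maximum shear-induced NO production rate (nM/s per Pa)
#' @param P_O2 oxygen partial pressure (mmHg)
#' @param K_m Michaelis-Menten constant (mmHg)
#' @param tau_b basal time-averaged wall shear stress (Pa)
#' @return list of class `kinetics_params` with derived `C_ROS_b`, `P_ROS_b`
#' @export
kinetics_params <- function(D_NO = 848, D_ROS = 848, eta_NO = 1.01,
                            K_RNS = 4, P_NO_b = 80, C_NO_b = 10,
                            R_NO_max = 75, P_O2 = 90, K_m = 5.5,
                            tau_b = 1.74) {
  cl <- basal_ros_closure(P_NO_b, C_NO_b, eta_NO, K_RNS)
  structure(list(D_NO = D_NO, D_ROS = D_ROS, eta_NO = eta_NO, K_RNS = K_RNS,
                 P_NO_b = P_NO_b, C_NO_b = C_NO_b,
                 C_ROS_b = cl$C_ROS_b, P_ROS_b = cl$P_ROS_b,
                 R_NO_max = R_NO_max, P_O2 = P_O2, K_m = K_m, tau_b = tau_b),
            class = "kinetics_params")
}

#' Basal ROS closure
#'
#' Inverts the homogeneous steady-state mass balances for the basal ROS
#' concentration and production rate given the NO basal values.
#'
#' @param P_NO_b NO basal production rate (nM/s)
#' @param C_NO_b NO basal concentration (nM)
#' @param eta_NO NO decay rate (1/s)
#' @param K_RNS RNS production rate (1/(nM s))
#' @return list with `C_ROS_b` (nM) and `P_ROS_b` (nM/s)
#' @export
basal_ros_closure <- function(P_NO_b, C_NO_b, eta_NO, K_RNS) {
  if (P_NO_b / C_NO_b <= eta_NO)
    stop("basal closure gives non-positive ROS concentration", call. = FALSE)
  C_ROS_b <- (P_NO_b / C_NO_b - eta_NO) / K_RNS
  list(C_ROS_b = C_ROS_b, P_ROS_b = K_RNS * C_ROS_b * C_NO_b)
}

#' Endothelial NO production rate under shear
#'
#' Michaelis-Menten shear sensitivity around the basal TAWSS, attenuated by
#' the endothelial dysfunction damage variable `alpha_dys`.
#'
#' @param tau_bar time-averaged wall shear stress (Pa)
#' @param params a [kinetics_params()]
#' @param alpha_dys dysfunction damage in `[0, 1]` (0 = responsive)
#' @param floor_frac lower clamp as a fraction of the basal rate; set to
#'   `NULL` to error instead when the computed rate is non-positive
#' @return production rate `P_NO_e` (nM/s)
#' @export
endothelial_NO_production <- function(tau_bar, params, alpha_dys = 0,
                                      floor_frac = 0.01) {
  stopifnot(tau_bar >= 0, alpha_dys >= 0, alpha_dys <= 1)
  sens <- params$R_NO_max * params$P_O2 / (params$K_m + params$P_O2)
  p <- params$P_NO_b + (1 - alpha_dys) * sens * (tau_bar - params$tau_b)
  if (p <= 0) {
    if (is.null(floor_frac))
      stop("shear far below basal: endothelial NO production non-positive",
           call. = FALSE)
    p <- floor_frac * params$P_NO_b
  }
  p
}

#' Endothelial concentrations from the production rates
#'
#' ROS endothelial production scales linearly with the NO one, which makes
#' the endothelial ROS concentration identically equal to its basal value.
#'
#' @param P_NO_e endothelial NO production rate (nM/s)
#' @param params a [kinetics_params()]
#' @return list with `C_NO_e`, `C_ROS_e` (nM) and `P_ROS_e` (nM/s)
#' @export
endothelial_concentrations <- function(P_NO_e, params) {
  P_ROS_e <- params$P_ROS_b * P_NO_e / params$P_NO_b
  if (P_NO_e <= P_ROS_e)
    stop("invalid regime: P_NO_e must exceed P_ROS_e", call. = FALSE)
  C_NO_e <- (P_NO_e - P_ROS_e) / params$eta_NO
  C_ROS_e <- P_ROS_e * params$eta_NO / (params$K_RNS * (P_NO_e - P_ROS_e))
  list(C_NO_e = C_NO_e, C_ROS_e = C_ROS_e, P_ROS_e = P_ROS_e)
}

#' Sigmoid map from NO concentration to SMC active stretch
#'
#' Strictly increasing, bounded in `(lambda_minus, lambda_plus)`, and passing
#' exactly through the basal pair `(C_NO_b, lambda_b)`.
#'
#' @param C_NO NO concentration (nM), vectorized
#' @param tone a [tone_params()]
#' @return active stretch `lambda_a`
#' @export
active_stretch_from_NO <- function(C_NO, tone) {
  stopifnot(all(C_NO >= 0))
  x <- exp(-tone$k_lambda * (C_NO / tone$C_NO_b - 1))
  tone$a_lambda + 2 * tone$b_lambda * (1 / (tone$c_lambda + x) - 1 / 2)
}

#' Vascular tone parameters
#'
#' @param lambda_minus,lambda_b,lambda_plus minimum / basal / maximum SMC
#'   active stretch
#' @param k_lambda NO sensitivity (dimensionless)
#' @param xi_c collagen transfer fraction in `[0, 1]`
#' @param C_NO_b basal NO concentration (nM)
#' @return list of class `tone_params` with the derived sigmoid constants
#' @export
tone_params <- function(lambda_minus = 0.59, lambda_b = 0.75,
                        lambda_plus = 1.3, k_lambda = 100, xi_c = 0.15,
                        C_NO_b = 10) {
  stopifnot(lambda_minus < lambda_b, lambda_b < lambda_plus,
            xi_c >= 0, xi_c <= 1)
  c_l <- (lambda_b - lambda_minus) / (lambda_plus - lambda_b)
  b_l <- (lambda_plus - lambda_minus) * (lambda_b - lambda_minus) /
    (2 * (lambda_plus - lambda_b))
  a_l <- lambda_minus + b_l
  structure(list(lambda_minus = lambda_minus, lambda_b = lambda_b,
                 lambda_plus = lambda_plus, k_lambda = k_lambda, xi_c = xi_c,
                 C_NO_b = C_NO_b, a_lambda = a_l, b_lambda = b_l,
                 c_lambda = c_l), class = "tone_params")
}

#' Collagen straightening stretch slaved to the active stretch
#' @param lambda_a SMC active stretch
#' @param xi_c transfer fraction in `[0, 1]`
#' @return `lambda_cs = 1 + xi_c (lambda_a - 1)`
#' @export
collagen_straightening <- function(lambda_a, xi_c) {
  stopifnot(xi_c >= 0, xi_c <= 1)
  1 + xi_c * (lambda_a - 1)
}

#' Element-average NO concentration
#' @param fields a `species_fields` list (or a nodal vector)
#' @param mesh a `vessel_mesh`
#' @return per-element mean of the 4 corner nodal values (nM)
#' @export
element_average_NO <- function(fields, mesh) {
  v <- if (is.list(fields)) fields$C_NO else fields
  rowMeans(matrix(v[t(mesh$elems)], ncol = 4, byrow = TRUE))
}

#' Species fields container
#' @param mesh a `vessel_mesh`
#' @param kin a [kinetics_params()]
#' @param time slow-scale time stamp (s)
#' @return list of class `species_fields` with uniform basal nodal values
#' @export
basal_species_fields <- function(mesh, kin, time = 0) {
  nn <- nrow(mesh$coords)
  structure(list(C_NO = rep(kin$C_NO_b, nn), C_ROS = rep(kin$C_ROS_b, nn),
                 time = time), class = "species_fields")
}

#' Build the transport operator on a (possibly deformed) configuration
#'
#' Assembles the metric-weighted diffusion matrix and the consistent mass
#' matrix over the healthy (non-calcified) elements; calcified tissue carries
#' neither diffusion nor reaction. Nodes whose support is entirely calcified
#' are frozen at basal values.
#'
#' @param mesh a `vessel_mesh`
#' @param deformation `NULL` (reference metric) or a `mechanical_solution`
#'   whose element fields provide `Jbar` and the inverse in-plane metric
#' @param kin a [kinetics_params()]
#' @return list with sparse `K_NO`, `K_ROS`, `M`, node index sets
#' @export
transport_operator <- function(mesh, deformation = NULL, kin) {
  ne <- nrow(mesh$elems); nn <- nrow(mesh$coords)
  healthy <- which(mesh$region != 2L)
  if (is.null(deformation)) {
    Jbar <- rep(1, ne)
    Cinv <- cbind(rep(1, ne), rep(1, ne), rep(0, ne))
  } else {
    Jbar <- deformation$fields[, "Jbar"]
    Cinv <- deformation$fields[, c("Cinv_xx", "Cinv_yy", "Cinv_xy")]
  }
  tr <- transport_assemble_cpp(mesh$coords, mesh$elems, as.integer(healthy),
                               Jbar, Cinv)
  Kbase <- Matrix::sparseMatrix(i = as.integer(tr$i), j = as.integer(tr$j),
                                x = as.numeric(tr$kx), dims = c(nn, nn))
  Mc <- Matrix::sparseMatrix(i = as.integer(tr$i), j = as.integer(tr$j),
                             x = as.numeric(tr$mx), dims = c(nn, nn))
  # lumped mass: keeps the discrete reaction-diffusion operator monotone,
  # which matters because the NO boundary layer is thinner than an element
  # (consistent-mass weighting produces spurious sub-basal undershoots)
  M <- Matrix::Diagonal(nn, x = Matrix::rowSums(Mc))
  # diffusivities: um^2/s -> mm^2/s
  active <- sort(unique(as.integer(mesh$elems[healthy, ])))
  frozen <- setdiff(seq_len(nn), active)
  dirichlet <- intersect(mesh$inner_loop, active)
  free <- setdiff(active, dirichlet)
  list(K_NO = kin$D_NO * 1e-6 * Kbase, K_ROS = kin$D_ROS * 1e-6 * Kbase,
       M = M, active = active, frozen = frozen, dirichlet = dirichlet,
       free = free, nn = nn)
}

rd_residual <- function(op, kin, C_NO, C_ROS, C_NO_old, C_ROS_old, dt) {
  rno <- kin$eta_NO * C_NO + kin$K_RNS * C_NO * C_ROS - kin$P_NO_b
  rros <- kin$K_RNS * C_NO * C_ROS - kin$P_ROS_b
  Fno <- op$K_NO %*% C_NO + op$M %*% rno
  Fros <- op$K_ROS %*% C_ROS + op$M %*% rros
  if (!is.null(dt)) {
    Fno <- Fno + op$M %*% ((C_NO - C_NO_old) / dt)
    Fros <- Fros + op$M %*% ((C_ROS - C_ROS_old) / dt)
  }
  list(Fno = as.numeric(Fno), Fros = as.numeric(Fros))
}

rd_newton <- function(op, kin, dirichlet_vals, C_NO0, C_ROS0,
                      C_NO_old = NULL, C_ROS_old = NULL, dt = NULL,
                      tol = 1e-11, max_iter = 25) {
  C_NO <- C_NO0; C_ROS <- C_ROS0
  C_NO[op$dirichlet] <- dirichlet_vals$C_NO_e
  C_ROS[op$dirichlet] <- dirichlet_vals$C_ROS_e
  free <- op$free
  nfree <- length(free)
  scale <- kin$C_NO_b
  for (it in seq_len(max_iter)) {
    r <- rd_residual(op, kin, C_NO, C_ROS, C_NO_old, C_ROS_old, dt)
    rr <- c(r$Fno[free], r$Fros[free])
    if (sqrt(sum(rr^2)) < tol * scale * max(1, sqrt(2 * nfree)))
      return(list(C_NO = C_NO, C_ROS = C_ROS, iters = it - 1))
    Dno <- Matrix::Diagonal(op$nn, kin$eta_NO + kin$K_RNS * C_ROS)
    Dx12 <- Matrix::Diagonal(op$nn, kin$K_RNS * C_NO)
    Dx21 <- Matrix::Diagonal(op$nn, kin$K_RNS * C_ROS)
    J11 <- op$K_NO + op$M %*% Dno
    J12 <- op$M %*% Dx12
    J21 <- op$M %*% Dx21
    J22 <- op$K_ROS + op$M %*% Dx12
    if (!is.null(dt)) {
      J11 <- J11 + op$M / dt
      J22 <- J22 + op$M / dt
    }
    J <- rbind(cbind(J11[free, free, drop = FALSE], J12[free, free, drop = FALSE]),
               cbind(J21[free, free, drop = FALSE], J22[free, free, drop = FALSE]))
    dx <- as.numeric(Matrix::solve(J, -rr))
    C_NO[free] <- C_NO[free] + dx[seq_len(nfree)]
    C_ROS[free] <- C_ROS[free] + dx[nfree + seq_len(nfree)]
  }
  stop("reaction-diffusion Newton did not converge", call. = FALSE)
}

#' One implicit step of the NO-ROS reaction-diffusion system
#'
#' Backward-Euler step with Newton resolution of the bilinear scavenging
#' reaction; Dirichlet endothelial values on the intima, zero flux on the
#' outer boundary, fields frozen at basal inside calcifications.
#'
#' @param fields a `species_fields`
#' @param op a [transport_operator()]
#' @param dirichlet list with `C_NO_e`, `C_ROS_e` (nM)
#' @param dt slow-scale time step (s)
#' @param kin a [kinetics_params()]
#' @param n_sub number of implicit sub-steps
#' @return updated `species_fields`
#' @export
step_reaction_diffusion <- function(fields, op, dirichlet, dt, kin,
                                    n_sub = NULL) {
  stopifnot(dt > 0)
  if (is.null(n_sub)) n_sub <- max(1L, ceiling(dt / 30))
  h <- dt / n_sub
  C_NO <- fields$C_NO; C_ROS <- fields$C_ROS
  for (s in seq_len(n_sub)) {
    sol <- rd_newton(op, kin, dirichlet, C_NO, C_ROS,
                     C_NO_old = C_NO, C_ROS_old = C_ROS, dt = h)
    C_NO <- sol$C_NO; C_ROS <- sol$C_ROS
  }
  if (min(C_NO, C_ROS) < -1e-9)
    warning("negative species concentration beyond tolerance")
  structure(list(C_NO = C_NO, C_ROS = C_ROS, time = fields$time + dt),
            class = "species_fields")
}

#' Steady state of the NO-ROS system
#'
#' Direct Newton solve of the time-independent balance; falls back to
#' pseudo-time continuation from the basal state on failure.
#'
#' @inheritParams step_reaction_diffusion
#' @param init optional initial `species_fields`
#' @return `species_fields` at steady state
#' @export
steady_state_fields <- function(op, dirichlet, kin, init = NULL) {
  if (is.null(init)) {
    C_NO0 <- rep(kin$C_NO_b, op$nn); C_ROS0 <- rep(kin$C_ROS_b, op$nn)
  } else {
    C_NO0 <- init$C_NO; C_ROS0 <- init$C_ROS
  }
  sol <- tryCatch(
    rd_newton(op, kin, dirichlet, C_NO0, C_ROS0, dt = NULL),
    error = function(e) NULL)
  if (is.null(sol)) {
    # continuation: large implicit pseudo-time steps from basal
    C_NO <- rep(kin$C_NO_b, op$nn); C_ROS <- rep(kin$C_ROS_b, op$nn)
    for (dt in c(10, 100, 1000, 1e4)) {
      s <- rd_newton(op, kin, dirichlet, C_NO, C_ROS,
                     C_NO_old = C_NO, C_ROS_old = C_ROS, dt = dt)
      C_NO <- s$C_NO; C_ROS <- s$C_ROS
    }
    sol <- rd_newton(op, kin, dirichlet, C_NO, C_ROS, dt = NULL)
  }
  structure(list(C_NO = sol$C_NO, C_ROS = sol$C_ROS, time = Inf),
            class = "species_fields")
}
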