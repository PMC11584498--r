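# Shared fixtures: built once per test run. Geometry and parameters follow
# the package defaults (human abdominal aorta cross section).

fix_unit <- make_fixture("unit")

geom_std <- cross_section_geometry()
mats_std <- tissue_materials()
kin_std <- kinetics_params()
tone_std <- tone_params()
net_std <- network_params()

mesh_small <- build_cross_section_mesh(geom_std, 4, 2, 24)
mesh_med <- build_cross_section_mesh(geom_std, 6, 3, 32)

# nearly pure neo-Hookean material (fibers and muscle switched off) for
# comparisons with the incompressible tube oracle
mats_nh <- tissue_materials(ecm = ecm_params(mu = 10, k1 = 1e-9, k2 = 2.5),
                            smc = smc_params(C_smc = 1e-9, P_smc_max = 1e-9),
                            lambda_z = 1.3)

# fan-triangulation polygon area, an independent check of the shoelace form
tri_area <- function(xy) {
  n <- nrow(xy)
  c0 <- colMeans(xy)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    v1 <- xy[i, ] - c0; v2 <- xy[j, ] - c0
    s <- s + 0.5 * (v1[1] * v2[2] - v1[2] * v2[1])
  }
  s
}

# dense radial finite-difference oracle for the steady coupled NO-ROS
# system on the undeformed annulus (axisymmetric)
radial_rd_oracle <- function(kin, C_NO_e, C_ROS_e, n = 3001,
                             r_in = 5.55, r_out = 6.75) {
  r <- seq(r_in, r_out, length.out = n)
  h <- r[2] - r[1]
  D <- kin$D_NO * 1e-6
  cn <- rep(kin$C_NO_b, n); cr <- rep(kin$C_ROS_b, n)
  for (it in 1:80) {
    idx <- 2:(n - 1)
    res_n <- numeric(n); res_r <- numeric(n)
    res_n[idx] <- D * ((cn[idx + 1] - 2 * cn[idx] + cn[idx - 1]) / h^2 +
                         (cn[idx + 1] - cn[idx - 1]) / (2 * h * r[idx])) -
      kin$eta_NO * cn[idx] - kin$K_RNS * cn[idx] * cr[idx] + kin$P_NO_b
    res_r[idx] <- D * ((cr[idx + 1] - 2 * cr[idx] + cr[idx - 1]) / h^2 +
                         (cr[idx + 1] - cr[idx - 1]) / (2 * h * r[idx])) -
      kin$K_RNS * cn[idx] * cr[idx] + kin$P_ROS_b
    res_n[1] <- cn[1] - C_NO_e; res_r[1] <- cr[1] - C_ROS_e
    res_n[n] <- cn[n] - cn[n - 1]; res_r[n] <- cr[n] - cr[n - 1]
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    add <- function(a, b, v) {
      ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v)
    }
    for (k in idx) {
      add(k, k - 1, D * (1 / h^2 - 1 / (2 * h * r[k])))
      add(k, k + 1, D * (1 / h^2 + 1 / (2 * h * r[k])))
      add(k, k, -2 * D / h^2 - kin$eta_NO - kin$K_RNS * cr[k])
      add(k, n + k, -kin$K_RNS * cn[k])
      add(n + k, n + k - 1, D * (1 / h^2 - 1 / (2 * h * r[k])))
      add(n + k, n + k + 1, D * (1 / h^2 + 1 / (2 * h * r[k])))
      add(n + k, n + k, -2 * D / h^2 - kin$K_RNS * cn[k])
      add(n + k, k, -kin$K_RNS * cr[k])
    }
    add(1, 1, 1); add(n, n, 1); add(n, n - 1, -1)
    add(n + 1, n + 1, 1); add(2 * n, 2 * n, 1); add(2 * n, 2 * n - 1, -1)
    J <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2 * n, 2 * n))
    dx <- as.numeric(Matrix::solve(J, -c(res_n, res_r)))
    cn <- cn + dx[1:n]; cr <- cr + dx[(n + 1):(2 * n)]
    if (max(abs(dx)) < 1e-12) break
  }
  list(r = r, C_NO = cn, C_ROS = cr)
}
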