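# Two-layer quasi-circular annular cross-section meshes.
#
# The mesh is a structured polar-product grid (radial layers x circumferential
# sectors) of bilinear quadrilaterals. Quasi-circularity is realised as a
# low-order Fourier perturbation of the boundary radii with amplitude bounded
# by eta times the minimum layer thickness; eta = 0 gives nominally circular
# boundaries.

#' Cross-section geometry description
#'
#' @param R_i0 mean unloaded internal radius (mm)
#' @param d_IM unloaded intima-media thickness (mm)
#' @param d_A unloaded adventitia thickness (mm)
#' @param eta quasi-circularity perturbation fraction in `[0, 1)`; the boundary
#'   radii are perturbed by a smooth periodic function of amplitude at most
#'   `eta * min(d_IM, d_A)`
#' @param ell_S segment length (mm)
#' @param lambda_z axial pre-stretch (dimensionless)
#' @return an object of class `cross_section_geometry`
#' @export
cross_section_geometry <- function(R_i0 = 5.55, d_IM = 0.8, d_A = 0.4,
                                   eta = 0, ell_S = 300, lambda_z = 1.3) {
  if (R_i0 <= 0 || d_IM <= 0 || d_A <= 0)
    stop("geometry dimensions must be positive", call. = FALSE)
  if (eta < 0 || eta >= 1)
    stop("eta must lie in [0, 1)", call. = FALSE)
  structure(list(R_i0 = R_i0, d_IM = d_IM, d_A = d_A, eta = eta,
                 ell_S = ell_S, lambda_z = lambda_z),
            class = "cross_section_geometry")
}

#' Build the structured annular cross-section mesh
#'
#' Nodes are laid out on `n_radial_media + n_radial_adventitia + 1` rings of
#' `n_circ` sectors each. Element regions are `"media"` for the inner
#' `n_radial_media` rings and `"adventitia"` outside; boundary node sets tag
#' the intima, the media-adventitia interface and the outer surface.
#'
#' @param geom a [cross_section_geometry()]
#' @param n_radial_media,n_radial_adventitia radial element counts per layer
#' @param n_circ circumferential element count
#' @param seed integer seed for the random Fourier phase of the
#'   quasi-circular perturbation (only used when `eta > 0`)
#' @return an object of class `vessel_mesh`
#' @export
build_cross_section_mesh <- function(geom, n_radial_media = 4,
                                     n_radial_adventitia = 2, n_circ = 16,
                                     seed = 1L) {
  stopifnot(inherits(geom, "cross_section_geometry"))
  if (n_radial_media < 2 || n_radial_adventitia < 2 || n_circ < 2)
    stop("element counts must be >= 2", call. = FALSE)
  nrm <- as.integer(n_radial_media); nra <- as.integer(n_radial_adventitia)
  nc <- as.integer(n_circ)
  theta <- 2 * pi * (seq_len(nc) - 1) / nc

  # radial perturbation of all boundaries (thickness-preserving)
  pert <- rep(0, nc)
  if (geom$eta > 0) {
    set.seed(as.integer(seed))
    amp <- runif(3); pha <- runif(3, 0, 2 * pi)
    raw <- amp[1] * cos(2 * theta + pha[1]) + amp[2] * cos(3 * theta + pha[2]) +
      amp[3] * cos(4 * theta + pha[3])
    pert <- geom$eta * min(geom$d_IM, geom$d_A) * raw / max(abs(raw))
  }

  r_rings <- c(geom$R_i0 + geom$d_IM * (0:nrm) / nrm,
               geom$R_i0 + geom$d_IM + geom$d_A * (1:nra) / nra)
  nring <- length(r_rings)            # nrm + nra + 1
  coords <- matrix(0, nring * nc, 2)
  for (i in seq_len(nring)) {
    idx <- (i - 1) * nc + seq_len(nc)
    r <- r_rings[i] + pert
    coords[idx, 1] <- r * cos(theta)
    coords[idx, 2] <- r * sin(theta)
  }

  ne <- (nring - 1) * nc
  elems <- matrix(0L, ne, 4)
  region <- integer(ne)
  e <- 0L
  for (i in seq_len(nring - 1)) {
    for (j in seq_len(nc)) {
      jp <- if (j == nc) 1L else j + 1L
      e <- e + 1L
      elems[e, ] <- c((i - 1L) * nc + j, i * nc + j, i * nc + jp,
                      (i - 1L) * nc + jp)
      region[e] <- if (i <= nrm) 0L else 1L  # 0 media, 1 adventitia, 2 calcified
    }
  }

  mesh <- structure(list(
    coords = coords, elems = elems, region = region,
    inner_loop = seq_len(nc),                       # CCW ordered intima nodes
    interface_nodes = nrm * nc + seq_len(nc),
    outer_loop = (nring - 1) * nc + seq_len(nc),
    n_circ = nc, n_radial_media = nrm, n_radial_adventitia = nra,
    geom = geom), class = "vessel_mesh")
  ja <- element_areas(mesh)
  if (any(ja <= 0)) stop("mesh has inverted elements", call. = FALSE)
  mesh
}

#' @exportS3Method base::print
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("vessel_mesh: %d nodes, %d elements (%d media, %d adventitia, %d calcified)\n",
              nrow(x$coords), nrow(x$elems), sum(x$region == 0),
              sum(x$region == 1), sum(x$region == 2)))
  invisible(x)
}

#' Tag a calcified sector of the media
#'
#' Re-tags a contiguous angular sector of media elements, centred at
#' `theta = 0`, as calcified. The sector spans `angular_fraction` of the full
#' circumference and `radial_extent` of the media thickness measured from the
#' intima.
#'
#' @param mesh a `vessel_mesh`
#' @param angular_fraction fraction of the circumference in `[0, 1]`
#' @param radial_extent fraction of the media thickness in `(0, 1]`
#' @return the mesh with updated region tags
#' @export
tag_calcification <- function(mesh, angular_fraction = 1 / 3,
                              radial_extent = 1) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  if (angular_fraction < 0 || angular_fraction > 1)
    stop("angular_fraction must lie in [0, 1]", call. = FALSE)
  if (angular_fraction == 0) return(mesh)
  nc <- mesh$n_circ
  nsec <- round(angular_fraction * nc)
  # contiguous sector of sectors centred at theta = 0
  half <- nsec / 2
  j_centre <- seq_len(nc)
  th_c <- 2 * pi * (j_centre - 0.5) / nc       # element-centre angles
  th_c <- ifelse(th_c > pi, th_c - 2 * pi, th_c)
  ord <- order(abs(th_c))
  sel_j <- sort(j_centre[ord[seq_len(nsec)]])
  nr_tag <- max(1L, ceiling(radial_extent * mesh$n_radial_media))
  for (i in seq_len(nr_tag)) {
    eids <- (i - 1L) * nc + sel_j
    mesh$region[eids] <- 2L
  }
  mesh
}

#' Element reference areas (shoelace)
#' @param mesh a `vessel_mesh`
#' @return numeric vector of element areas (mm^2)
#' @export
element_areas <- function(mesh) {
  x <- matrix(mesh$coords[t(mesh$elems), 1], ncol = 4, byrow = TRUE)
  y <- matrix(mesh$coords[t(mesh$elems), 2], ncol = 4, byrow = TRUE)
  0.5 * abs((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
              (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
              (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
              (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}

#' Signed area of a closed polygon loop
#' @param xy two-column matrix of vertex coordinates, in order
#' @return signed area (positive for counter-clockwise loops)
#' @export
polygon_area <- function(xy) {
  n <- nrow(xy)
  ip <- c(2:n, 1)
  0.5 * sum(xy[, 1] * xy[ip, 2] - xy[ip, 1] * xy[, 2])
}

#' Reference lumen area of a mesh
#' @param mesh a `vessel_mesh`
#' @return polygon area enclosed by the intima nodes (mm^2)
#' @export
lumen_reference_area <- function(mesh) {
  polygon_area(mesh$coords[mesh$inner_loop, , drop = FALSE])
}
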