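# Programmatic fixtures: coarse meshes and configurations for fast unit
# tests, and the production-resolution mesh used for mesh-sensitivity
# studies.

#' Build a test fixture
#'
#' `unit`: an 8-sector, 4-ring annulus with a coarse solver configuration
#' (few pressure steps, short fast windows) for sub-second tests.
#' `integration`: the production-resolution mesh (about 1500 elements, as
#' used for the reported simulations) with the default configuration.
#'
#' @param level `"unit"` or `"integration"`
#' @return list with `mesh` and `config`
#' @export
make_fixture <- function(level = c("unit", "integration")) {
  level <- match.arg(level)
  config <- default_config()
  if (level == "unit") {
    config$mesh <- list(n_circ = 8, n_radial_media = 2,
                        n_radial_adventitia = 2, seed = 1L)
    config$coupling$n_p <- 5
    config$network$steps_per_beat <- 100
  } else {
    config$mesh <- list(n_circ = 64, n_radial_media = 16,
                        n_radial_adventitia = 8, seed = 1L)
  }
  geom <- do.call(cross_section_geometry, config$geometry)
  mesh <- build_cross_section_mesh(geom, config$mesh$n_radial_media,
                                   config$mesh$n_radial_adventitia,
                                   config$mesh$n_circ, config$mesh$seed)
  list(mesh = mesh, config = config)
}
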