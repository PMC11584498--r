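# Output writers: ASCII VTU field snapshots, CSV time series, JSON run
# summaries.

#' Write a mesh with fields as an ASCII VTU file
#'
#' @param mesh a `vessel_mesh`
#' @param path output file (.vtu)
#' @param point_data named list of per-node numeric vectors
#' @param cell_data named list of per-element numeric vectors (the region
#'   tag is always included)
#' @param u optional nodal displacements to deform the coordinates
#' @return the path, invisibly
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list(),
                      u = NULL) {
  nn <- nrow(mesh$coords); ne <- nrow(mesh$elems)
  xy <- mesh$coords
  if (!is.null(u)) xy <- xy + cbind(u[2 * seq_len(nn) - 1], u[2 * seq_len(nn)])
  cell_data <- c(list(region = as.numeric(mesh$region)), cell_data)
  num <- function(x) paste(formatC(x, format = "g", digits = 9),
                           collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(as.numeric(t(cbind(xy, 0)))))
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(as.integer(t(mesh$elems)) - 1L, collapse = " "))
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(4L * seq_len(ne), collapse = " "))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(9L, ne), collapse = " "))
  w('</DataArray></Cells>')
  w('<PointData>')
  for (nm in names(point_data)) {
    w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
    w(num(point_data[[nm]]))
    w('</DataArray>')
  }
  w('</PointData>')
  w('<CellData>')
  for (nm in names(cell_data)) {
    w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
    w(num(cell_data[[nm]]))
    w('</DataArray>')
  }
  w('</CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Write scenario outputs
#'
#' CSV trajectory (slow scale), CSV fast-scale series of the final state,
#' VTU snapshot of the final fields, and a JSON run summary including the
#' resolved configuration.
#'
#' @param result a [run_scenario()] result
#' @param config the configuration used
#' @param dir output directory (created if missing)
#' @param reference optional paired healthy/basal [run_scenario()] result;
#'   when given, percentage changes vs the reference are included in the
#'   summary
#' @return named list of written paths
#' @export
write_outputs <- function(result, config, dir = config$output$dir,
                          reference = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  basal <- attr(result, "basal")
  sched <- attr(result, "schedule")
  is_eq <- !is.null(result$tau)

  if (!is.null(result$trajectory)) {
    paths$trajectory <- file.path(dir, "trajectory.csv")
    write.csv(result$trajectory, paths$trajectory, row.names = FALSE)
  }
  st <- if (is_eq) result$state else result$ctx$last_state
  ctx <- result$ctx
  if (!is.null(st$series)) {
    paths$fast <- file.path(dir, "fast_series.csv")
    write.csv(st$series, paths$fast, row.names = FALSE)
  }
  if (!is.null(ctx)) {
    paths$vtu <- file.path(dir, "final_state.vtu")
    write_vtu(ctx$mesh, paths$vtu,
              point_data = list(C_NO = ctx$fields$C_NO,
                                C_ROS = ctx$fields$C_ROS),
              cell_data = list(lambda_a = ctx$deformation$fields[, "lambda_a"],
                               von_mises = ctx$deformation$fields[, "von_mises"],
                               Jbar = ctx$deformation$fields[, "Jbar"]),
              u = ctx$deformation$u)
  }
  summary <- list(
    scenario = sched$name,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("vasotone")),
    tau_basal_Pa = basal$tau_b)
  if (is_eq) {
    summary$tau_Pa <- result$tau
    summary$pulse_amplitude_mmHg <- st$amp
    summary$p_mean_mmHg <- st$p_mean
    summary$tawss_change_pct <- 100 * (result$tau / basal$tau_b - 1)
    if (!is.null(reference)) {
      ref_st <- reference$state
      summary$amplitude_change_vs_reference_pct <-
        100 * (st$amp / ref_st$amp - 1)
      summary$tawss_change_vs_reference_pct <-
        100 * (result$tau / reference$tau - 1)
    }
  } else {
    tr <- result$trajectory
    summary$tau_final_Pa <- tr$tau[nrow(tr)]
    summary$tawss_change_pct <- 100 * (tr$tau[nrow(tr)] / basal$tau_b - 1)
  }
  paths$summary <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
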