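# Plain-text serialization: waveforms as 2-column CSV, plane velocity maps
# as a CSV + JSON-sidecar directory, inlet BCs and reports as CSV/JSON,
# meshes and nodal fields as legacy-ASCII VTK unstructured grids.

#' Write / read a flow waveform as 2-column CSV
#'
#' Columns `t_s`, `Q_m3s`; period and systolic markers in a `#`-comment
#' header.
#'
#' @param waveform A `flow_waveform`.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a `flow_waveform` (reader).
#' @export
write_waveform_csv <- function(waveform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# period_s=%.17g", waveform$period), con)
  writeLines(sprintf("# systolic_markers_s=%s",
                     paste(sprintf("%.17g", waveform$systolic_markers),
                           collapse = ";")), con)
  writeLines("t_s,Q_m3s", con)
  utils::write.table(data.frame(waveform$times, waveform$Q), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  period <- as.numeric(sub("# period_s=", "", hdr[1], fixed = TRUE))
  markers <- as.numeric(strsplit(sub("# systolic_markers_s=", "", hdr[2],
                                     fixed = TRUE), ";")[[1]])
  d <- utils::read.csv(path, comment.char = "#")
  flow_waveform(d$t_s, d$Q_m3s, period, markers)
}

#' Write / read a plane velocity map as CSV + JSON sidecar
#'
#' Long-format CSV (`i`, `j`, `phase`, `vel_u`, `vel_v`, `vel_n`, `mask`)
#' plus a JSON sidecar carrying the grid geometry, phases, VENC and
#' provenance.
#'
#' @param map A `plane_velocity_map`.
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @return `path`, invisibly (writer); a `plane_velocity_map` (reader).
#' @export
write_plane_map <- function(map, path) {
  nph <- length(map$phases)
  idx <- expand.grid(i = seq_len(map$n_u), j = seq_len(map$n_v),
                     phase = seq_len(nph))
  d <- data.frame(idx,
                  vel_u = as.vector(map$vel_u),
                  vel_v = as.vector(map$vel_v),
                  vel_n = as.vector(map$vel_n),
                  mask = as.vector(map$lumen_mask)[ (idx$j - 1L) * map$n_u + idx$i ])
  utils::write.csv(d, paste0(path, ".csv"), row.names = FALSE)
  meta <- map[c("n_u", "n_v", "pixel_size_mm", "slab_thickness_mm",
                "u_coords", "v_coords", "phases", "period", "venc",
                "noise_sd", "seed")]
  meta$plane <- map$plane[c("origin", "axis_u", "axis_v", "normal")]
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plane_map
#' @export
read_plane_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- utils::read.csv(paste0(path, ".csv"))
  nph <- length(meta$phases)
  dm <- c(meta$n_u, meta$n_v, nph)
  o <- order(d$phase, d$j, d$i)
  d <- d[o, ]
  mask <- matrix(d$mask[seq_len(meta$n_u * meta$n_v)], meta$n_u, meta$n_v)
  structure(list(
    n_u = meta$n_u, n_v = meta$n_v, pixel_size_mm = meta$pixel_size_mm,
    slab_thickness_mm = meta$slab_thickness_mm,
    u_coords = meta$u_coords, v_coords = meta$v_coords,
    plane = structure(lapply(meta$plane, as.numeric), class = "plane_spec"),
    phases = meta$phases, period = meta$period,
    vel_u = array(d$vel_u, dm), vel_v = array(d$vel_v, dm),
    vel_n = array(d$vel_n, dm),
    lumen_mask = mask, venc = meta$venc, noise_sd = meta$noise_sd,
    seed = meta$seed
  ), class = "plane_velocity_map")
}

#' Write a mesh (with optional nodal fields) as legacy-ASCII VTK
#'
#' Unstructured-grid legacy VTK with hexahedral cells and optional nodal
#' point-data arrays (scalars as one component, vectors as three).
#'
#' @param mesh A `tube_mesh`.
#' @param path Output `.vtk` path.
#' @param point_data Named list of per-node vectors or N x 3 matrices.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$node_positions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tube mesh", "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$node_positions, digits = 12, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  nc <- nrow(mesh$cells)
  writeLines(sprintf("CELLS %d %d", nc, nc * 9L), con)
  utils::write.table(cbind(8L, mesh$cells - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(as.character(rep(12L, nc)), con)
  if (length(point_data) > 0) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.null(dim(v))) {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(v, digits = 12, trim = TRUE), con)
      } else {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(v, digits = 12, trim = TRUE), con,
                           row.names = FALSE, col.names = FALSE,
                           quote = FALSE)
      }
    }
  }
  invisible(path)
}

#' Write a comparison report as a CSV set plus JSON summary
#'
#' Writes `table1.csv`, `inplane_fraction.csv`, `hfi.csv`,
#' `hfi_percent_diff.csv`, `wss_percent_diff.csv`, `pressure.csv` and a
#' `summary.json` with the headline numbers and provenance into `dir`.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$table1, file.path(dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(report$inplane_trace,
                   file.path(dir, "inplane_fraction.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$hfi_table),
                   file.path(dir, "hfi.csv"))
  utils::write.csv(as.data.frame(report$hfi_percent_diff),
                   file.path(dir, "hfi_percent_diff.csv"))
  utils::write.csv(as.data.frame(report$wss_percent_diff),
                   file.path(dir, "wss_percent_diff.csv"))
  utils::write.csv(data.frame(t_s = report$pressure$times,
                              P_Pa = report$pressure$P),
                   file.path(dir, "pressure.csv"), row.names = FALSE)
  summ <- list(
    scenario = report$config$scenario,
    seed = report$provenance$seed,
    package_version = report$provenance$package_version,
    underest_mean_pct = report$table1$underest_mean_pct,
    underest_max_pct = report$table1$underest_max_pct,
    inplane_fraction_avg = report$decomposition$summary$inplane_fraction,
    hfi_avg = as.list(stats::setNames(report$hfi_table[, "Avg"],
                                      rownames(report$hfi_table))),
    hfi_avg_pct_diff = as.list(stats::setNames(
      report$hfi_percent_diff[, "Avg"], rownames(report$hfi_percent_diff))),
    tawss_mean_pct_diff = as.list(stats::setNames(
      report$wss_percent_diff[, "mean_tawss"],
      rownames(report$wss_percent_diff))),
    pressure_range_Pa = range(report$pressure$P))
  jsonlite::write_json(summ, file.path(dir, "summary.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}
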