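# Plain-text interchange: legacy ASCII VTK unstructured grids for meshes and
# deformed shapes, CSV/JSON for profile sequences, YAML for run
# configurations, and a directory of CSV/JSON files for modal bases.
# MatrixMarket export of the sparse system matrices is available for
# debugging.

#' Write a tetrahedral mesh as a legacy ASCII VTK unstructured grid
#'
#' Cell data `layer` (1 = cover, 2 = body) is attached when present; an
#' optional point data field (e.g. displacement magnitude) can be added.
#'
#' @param mesh a `vf_mesh` (or list with `nodes`, `tets`).
#' @param path output file path (`.vtk`).
#' @param X optional node positions overriding `mesh$nodes` (deformed
#'   snapshot).
#' @param point_data optional named list of per-node scalar vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, X = NULL, point_data = NULL) {
  nodes <- if (is.null(X)) mesh$nodes else X
  tets <- mesh$tets
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vfpinn unstructured grid",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nodes))), con)
  utils::write.table(format(nodes, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nrow(tets), 5 * nrow(tets)), con)
  utils::write.table(cbind(4L, tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nrow(tets)), con)
  writeLines(as.character(rep(10L, nrow(tets))), con)
  if (!is.null(mesh$layer)) {
    writeLines(c(sprintf("CELL_DATA %d", nrow(tets)),
                 "SCALARS layer int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(ifelse(mesh$layer == "cover", 1L, 2L)), con)
  }
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nodes)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 17), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid of tetrahedra
#'
#' Parses the subset written by [write_vtk()]: points, tet cells, and the
#' optional `layer` cell field.
#'
#' @param path file path.
#' @return list with `nodes`, `tets`, and `layer` (or `NULL`).
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  vals <- scan(text = ln[(ip + 1):length(ln)], what = double(), n = 3 * np,
               quiet = TRUE)
  nodes <- matrix(vals, np, 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  nc <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  cvals <- scan(text = ln[(ic + 1):length(ln)], what = integer(), n = 5 * nc,
                quiet = TRUE)
  cm <- matrix(cvals, nc, 5, byrow = TRUE)
  stop_if_not(all(cm[, 1] == 4L), "only tetrahedral cells are supported")
  tets <- cm[, 2:5, drop = FALSE] + 1L
  layer <- NULL
  il <- grep("^SCALARS layer", ln)
  if (length(il) == 1) {
    lv <- scan(text = ln[(il + 2):length(ln)], what = integer(), n = nc,
               quiet = TRUE)
    layer <- ifelse(lv == 1L, "cover", "body")
  }
  list(nodes = nodes, tets = tets, layer = layer)
}

#' Write a profile sequence to CSV
#'
#' Long format with columns `t`, `station`, `edge` (all meters/seconds) and
#' a `view` column.
#'
#' @param profiles a `vf_profile_sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- data.frame(t = rep(profiles$times, each = length(profiles$stations)),
                   station = rep(profiles$stations, length(profiles$times)),
                   edge = as.numeric(t(profiles$edges)),
                   view = profiles$view)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a profile sequence from CSV
#'
#' Validates strictly increasing stations and a complete time/station grid.
#'
#' @param path CSV path written by [write_profiles_csv()].
#' @return a `vf_profile_sequence`.
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path)
  stop_if_not(all(c("t", "station", "edge") %in% names(df)),
              "profile CSV must have columns t, station, edge")
  times <- sort(unique(df$t))
  stations <- sort(unique(df$station))
  stop_if_not(nrow(df) == length(times) * length(stations),
              "profile CSV is not a complete time x station grid")
  edges <- matrix(NA_real_, length(times), length(stations))
  ti <- match(df$t, times); si <- match(df$station, stations)
  edges[cbind(ti, si)] <- df$edge
  view <- if ("view" %in% names(df)) as.character(df$view[1]) else "top"
  profile_sequence(times, stations, edges, view = view)
}

#' Write / read a profile sequence as JSON
#'
#' @param profiles a `vf_profile_sequence`.
#' @param path file path.
#' @return `path` (write) or a `vf_profile_sequence` (read).
#' @export
write_profiles_json <- function(profiles, path) {
  jsonlite::write_json(list(times = profiles$times, stations = profiles$stations,
                            edges = profiles$edges, view = profiles$view),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_profiles_json
#' @export
read_profiles_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  profile_sequence(x$times, x$stations, x$edges, view = x$view)
}

#' Read / write a nested run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg nested configuration list.
#' @return the configuration list (read) or `path` (write).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Persist a modal basis to a directory of plain-text files
#'
#' `modes.csv` (3n x J), `frequencies.csv`, and `meta.json` (damping,
#' free-DOF indices, node count).
#'
#' @param basis a `vf_modal_basis`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_modal_basis <- function(basis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(basis$modes, file.path(dir, "modes.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(omega = basis$omega),
                     file.path(dir, "frequencies.csv"), sep = ",",
                     row.names = FALSE)
  jsonlite::write_json(list(alpha = basis$alpha, beta = basis$beta,
                            free_dofs = basis$free_dofs,
                            n_nodes = basis$n_nodes),
                       file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_modal_basis
#' @export
load_modal_basis <- function(dir) {
  modes <- as.matrix(utils::read.table(file.path(dir, "modes.csv"), sep = ","))
  dimnames(modes) <- NULL
  freq <- utils::read.csv(file.path(dir, "frequencies.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  modal_basis(modes, freq$omega, alpha = meta$alpha, beta = meta$beta,
              free_dofs = meta$free_dofs, n_nodes = meta$n_nodes)
}

#' Export system matrices in MatrixMarket format
#'
#' @param sys a `vf_system`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_system_matrices <- function(sys, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(sys$M, "generalMatrix"), file.path(dir, "M.mtx"))
  Matrix::writeMM(methods::as(sys$K, "generalMatrix"), file.path(dir, "K.mtx"))
  invisible(dir)
}
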