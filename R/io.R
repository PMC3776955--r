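#' Write a volume as NIfTI-1
#'
#' @param vol 3-D or 4-D numeric array.
#' @param path output file (`.nii` / `.nii.gz`).
#' @param voxel_size isotropic voxel edge length, mm.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = 1) {
  img <- RNifti::asNifti(vol, pixdim = rep(voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file.
#' @return Numeric array with attribute `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  attr(vol, "voxel_size_mm") <- RNifti::pixdim(img)[1]
  vol
}

#' Export a surface mesh as Wavefront OBJ
#'
#' @param mesh a [extract_surface()] mesh.
#' @param path output `.obj` file.
#' @return The path, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  v <- sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2],
               mesh$vertices[, 3])
  f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
               mesh$faces[, 3])
  writeLines(c(v, f), path)
  invisible(path)
}

#' Export a surface mesh as ascii PLY with per-vertex scalars
#'
#' @param mesh a [extract_surface()] mesh.
#' @param path output `.ply` file.
#' @param scalars optional named list/data frame of per-vertex values
#'   written as extra float properties.
#' @return The path, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, scalars = NULL) {
  nv <- nrow(mesh$vertices)
  props <- c("property float x", "property float y", "property float z")
  cols <- as.data.frame(mesh$vertices)
  names(cols) <- c("x", "y", "z")
  if (!is.null(scalars)) {
    scalars <- as.data.frame(scalars)
    stopifnot(nrow(scalars) == nv)
    props <- c(props, sprintf("property float %s", names(scalars)))
    cols <- cbind(cols, scalars)
  }
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nv), props,
              sprintf("element face %d", nrow(mesh$faces)),
              "property list uchar int vertex_indices", "end_header")
  vlines <- do.call(paste, c(lapply(cols, function(x) sprintf("%.6f", x))))
  flines <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                    mesh$faces[, 3] - 1)
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' Per-vertex results table
#'
#' @param gradients a [map_gradients()] data frame.
#' @param mesh the mesh (for vertex areas).
#' @param path optional CSV output path.
#' @return Data frame with vertex, slope, p, r2, d0, area and overlay
#'   opacity.
#' @export
vertex_results_table <- function(gradients, mesh, path = NULL) {
  tab <- data.frame(vertex = gradients$vertex, g = gradients$g,
                    p = gradients$p, r2 = gradients$r2, d0 = gradients$d0,
                    n_voxels = gradients$n_voxels,
                    area_mm2 = mesh$vertex_area[gradients$vertex],
                    alpha = ifelse(is.na(gradients$p), 0,
                                   alpha_from_p(pmax(gradients$p, 1e-6))))
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  tab
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) file with optional blocks `phantom`, `bootstrap`,
#' `penetration`, and top-level `seed` / `out_dir`, mirroring the
#' arguments of [phantom_spec()], [bootstrap_config()] and
#' [penetration_config()].
#'
#' @param path config file.
#' @return A `pipeline_config` list, see [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config(
    spec = do.call(phantom_spec, as.list(cfg$phantom %||% list())),
    boot = do.call(bootstrap_config, as.list(cfg$bootstrap %||% list())),
    pen = do.call(penetration_config, as.list(cfg$penetration %||% list())),
    seed = cfg$seed %||% 1,
    out_dir = cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
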