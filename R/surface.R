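#' Extract a smooth tissue surface from a binary mask
#'
#' Builds a closed, watertight triangulated isosurface at the 0.5 isolevel
#' of the mask (marching tetrahedra on the voxel-center lattice), then
#' applies volume-preserving Taubin smoothing. Vertices are returned in
#' physical mm via the voxel-size scaling, with voxel centers at
#' `(index - 0.5) * voxel_size`.
#'
#' @param mask binary 3-D array (0 = background, 1 = tissue).
#' @param voxel_size voxel edge length, mm.
#' @param smoothing_iters Taubin smoothing iterations.
#' @param lambda,mu Taubin shrink/inflate factors.
#' @param pre_smooth_fwhm_vox FWHM (in voxels) of a light Gaussian applied
#'   to the binary volume before isosurfacing; positions the 0.5 isolevel
#'   sub-voxel accurately and suppresses staircase facets. 0 disables.
#' @param curvature_smoothing two integers: averaging passes applied to
#'   the normal field and to the curvature estimate (regularization
#'   length should stay below the feature scale of interest).
#' @return An object of class `surface_mesh`: `vertices` (n x 3, mm),
#'   `faces` (m x 3, 1-based, consistently outward oriented),
#'   `normals` (outward unit vectors per vertex; `normals_smooth` is the
#'   regularized field used to orient penetrations), `vertex_area`
#'   (barycentric one-third areas, mm^2), `mean_curvature` (1/mm, positive
#'   where convex), `area` (total, mm^2).
#' @export
extract_surface <- function(mask, voxel_size = attr(mask, "voxel_size_mm"),
                            smoothing_iters = 20, lambda = 0.5,
                            mu = -0.53, pre_smooth_fwhm_vox = 1.2,
                            curvature_smoothing = c(2, 2)) {
  stopifnot(length(dim(mask)) == 3)
  if (is.null(voxel_size)) voxel_size <- 1
  if (!any(mask > 0)) stop("mask is empty: no tissue voxels")
  # Pad with two layers of zeros so surfaces touching the grid edge close
  # and the pre-smoothing kernel has room.
  d <- dim(mask)
  vol <- array(0, d + 4)
  vol[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- as.numeric(mask > 0)
  if (pre_smooth_fwhm_vox > 0)
    vol <- gaussian_blur(vol, pre_smooth_fwhm_vox, 1)
  raw <- .march_tets(as.numeric(vol), dim(vol), 0.5)
  if (nrow(raw$vertices) < 4 || nrow(raw$faces) < 4)
    stop("degenerate mesh: mask too small to carry a surface")
  verts <- (raw$vertices - 2) * voxel_size   # undo padding, scale to mm
  faces <- raw$faces
  verts <- taubin_smooth(verts, faces, iters = smoothing_iters,
                         lambda = lambda, mu = mu)
  mesh <- structure(list(vertices = verts, faces = faces),
                    class = "surface_mesh")
  mesh <- mesh_geometry(mesh, normal_smooth = curvature_smoothing[1],
                        curvature_smooth = curvature_smoothing[2])
  mesh
}

# Taubin lambda/mu smoothing with uniform weights: alternating shrink and
# inflate steps cancel the volume loss of plain Laplacian smoothing.
taubin_smooth <- function(verts, faces, iters, lambda = 0.5, mu = -0.53) {
  if (iters <= 0) return(verts)
  n <- nrow(verts)
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  for (it in seq_len(iters)) {
    for (f in c(lambda, mu)) {
      lap <- as.matrix(A %*% verts) / deg - verts
      verts <- verts + f * lap
    }
  }
  verts
}

# Per-vertex outward normals, barycentric areas and cotangent mean
# curvature; fills the mesh object in place.
mesh_geometry <- function(mesh, normal_smooth = 5, curvature_smooth = 5) {
  V <- mesh$vertices
  F <- mesh$faces
  n <- nrow(V)
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  u <- p2 - p1
  w <- p3 - p1
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  fa <- 0.5 * sqrt(rowSums(fn^2))
  # Area-weighted vertex normals.
  N <- matrix(0, n, 3)
  for (c in 1:3) {
    for (ax in 1:3) {
      N[, ax] <- N[, ax] +
        as.vector(tapply_sum(fn[, ax] / 2, F[, c], n))
    }
  }
  nrm <- sqrt(rowSums(N^2))
  nrm[nrm == 0] <- 1
  N <- N / nrm
  va <- as.vector(tapply_sum(rep(fa / 3, 3), as.vector(F), n))

  # Mean curvature from the directional derivative of the normal field:
  # along an edge (i, j), (n_j - n_i) . (x_j - x_i) / |x_j - x_i|^2 is the
  # normal curvature in that direction (exact on spheres), and averaging
  # over incident edge directions approximates the mean curvature.
  # Marching-tetrahedra meshes have irregular triangle shapes, so both the
  # normal field and the resulting estimate are regularized by
  # area-weighted averaging along the mesh.
  Ns <- N
  for (it in seq_len(max(normal_smooth, 6))) {
    for (ax in 1:3) Ns[, ax] <- smooth_vertex_scalar(Ns[, ax], F, va, 1)
    Ns <- Ns / sqrt(rowSums(Ns^2))
    if (it == normal_smooth) Ncurv <- Ns
  }
  if (normal_smooth == 0) Ncurv <- N
  if (normal_smooth >= max(normal_smooth, 6)) Ncurv <- Ns
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  dx <- V[e[, 2], , drop = FALSE] - V[e[, 1], , drop = FALSE]
  dn <- Ncurv[e[, 2], , drop = FALSE] - Ncurv[e[, 1], , drop = FALSE]
  kap <- rowSums(dn * dx) / rowSums(dx * dx)
  H <- as.vector(tapply_sum(kap, e[, 1], n)) /
    pmax(as.vector(tapply_sum(rep(1, nrow(e)), e[, 1], n)), 1)
  H <- smooth_vertex_scalar(H, F, va, iters = curvature_smooth)

  mesh$normals <- N
  mesh$normals_smooth <- Ns
  mesh$vertex_area <- va
  mesh$mean_curvature <- H
  mesh$area <- sum(fa)
  mesh
}

# Area-weighted neighbor averaging of a per-vertex scalar.
smooth_vertex_scalar <- function(x, faces, vertex_area, iters = 10) {
  n <- length(x)
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = vertex_area[e[, 2]],
                            dims = c(n, n)) +
    Matrix::Diagonal(x = vertex_area)
  w <- Matrix::rowSums(A)
  for (it in seq_len(iters)) x <- as.vector(A %*% x) / w
  x
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Mark the analysis region by surface curvature
#'
#' Flags vertices whose discrete mean curvature exceeds a threshold
#' (convex protrusions), then keeps the largest connected components —
#' the computational analog of outlining the collicular surface by
#' positive tissue curvature.
#'
#' @param mesh a [extract_surface()] mesh.
#' @param curvature_threshold 1/mm; vertices above it are candidates.
#' @param n_components number of connected components to keep.
#' @param min_vertices drop components smaller than this.
#' @param restrict optional logical mask or vertex ids limiting the
#'   candidates (e.g. to the superior protrusions, excluding convex box
#'   edges of a phantom slab).
#' @param close_iters rounds of morphological closing (graph dilation then
#'   erosion) applied to the thresholded set before component selection;
#'   fills pinholes left by curvature-estimate noise.
#' @return Logical per-vertex region mask.
#' @export
curvature_and_region <- function(mesh, curvature_threshold = 0.05,
                                 n_components = 2, min_vertices = 10,
                                 restrict = NULL, close_iters = 2) {
  n <- nrow(mesh$vertices)
  sel <- mesh$mean_curvature > curvature_threshold
  if (!is.null(restrict)) {
    allow <- rep(FALSE, n)
    allow[if (is.logical(restrict)) which(restrict) else restrict] <- TRUE
  } else allow <- rep(TRUE, n)
  sel <- sel & allow
  out <- rep(FALSE, n)
  if (!any(sel)) return(out)
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
  step <- function(s, grow) {
    touched <- as.vector(A %*% s) > 0
    if (grow) (s | touched) else (s & !(as.vector(A %*% !s) > 0))
  }
  for (it in seq_len(close_iters)) sel <- step(sel, TRUE)
  for (it in seq_len(close_iters)) sel <- step(sel, FALSE)
  sel <- sel & allow
  cand <- which(sel)
  if (!length(cand)) return(out)
  g <- mesh_graph(mesh)
  sub <- igraph::induced_subgraph(g, cand)
  comp <- igraph::components(sub)
  keep <- order(comp$csize, decreasing = TRUE)
  keep <- keep[seq_len(min(n_components, length(keep)))]
  keep <- keep[comp$csize[keep] >= min_vertices]
  out[cand[comp$membership %in% keep]] <- TRUE
  out
}

# Edge graph of the mesh, weighted by Euclidean edge length (mm).
mesh_graph <- function(mesh) {
  if (!is.null(mesh$graph)) return(mesh$graph)
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

#' Manifold patch around a vertex
#'
#' Vertices whose shortest along-mesh (edge-path, Dijkstra) distance from
#' the seed is below `radius_mm`. The path distance is an upper bound on
#' the true geodesic distance, so patches are conservative.
#'
#' @param mesh a surface mesh.
#' @param vertex_id seed vertex (1-based).
#' @param radius_mm manifold radius, mm.
#' @param graph optional precomputed [mesh_graph()].
#' @return Integer vertex ids (always includes the seed).
#' @export
manifold_patch <- function(mesh, vertex_id, radius_mm = 0.6,
                           graph = mesh_graph(mesh)) {
  n <- nrow(mesh$vertices)
  if (vertex_id < 1 || vertex_id > n) stop("vertex_id out of range")
  d <- igraph::distances(graph, v = vertex_id, algorithm = "dijkstra")
  sort(unique(c(vertex_id, which(d[1, ] < radius_mm))))
}

#' Nearest-vertex depth map
#'
#' For every in-mask voxel center: the Euclidean distance to the nearest
#' surface vertex (the voxel's depth coordinate) and that vertex's index.
#'
#' @param mask binary array defining the tissue voxels.
#' @param mesh the surface mesh derived from (a compatible) mask.
#' @param voxel_size voxel edge length of `mask`, mm.
#' @return An object of class `depth_map`: data frame `voxels` with
#'   columns `voxel` (linear index into `mask`), `x`, `y`, `z` (mm),
#'   `depth_mm`, `nearest_vertex`; plus `dim` and `voxel_size`.
#' @export
compute_depth_map <- function(mask, mesh,
                              voxel_size = attr(mask, "voxel_size_mm")) {
  if (is.null(voxel_size)) voxel_size <- 1
  idx <- which(mask > 0)
  if (!length(idx)) stop("no tissue voxels in mask")
  pts <- voxel_centers(dim(mask), voxel_size)[idx, , drop = FALSE]
  nn <- .nearest_vertex(pts, mesh$vertices)
  out <- list(voxels = data.frame(voxel = idx, x = pts[, 1], y = pts[, 2],
                                  z = pts[, 3], depth_mm = nn$distance,
                                  nearest_vertex = nn$index),
              dim = dim(mask), voxel_size = voxel_size)
  class(out) <- "depth_map"
  out
}

#' Surface area of a vertex subset
#'
#' Barycentric (one-third-per-vertex) area summed over a subset, mm^2.
#'
#' @param mesh a surface mesh.
#' @param vertex_subset integer ids or logical per-vertex mask; empty
#'   subsets return 0.
#' @return Area in mm^2.
#' @export
region_area <- function(mesh, vertex_subset) {
  if (is.logical(vertex_subset)) vertex_subset <- which(vertex_subset)
  if (!length(vertex_subset)) return(0)
  sum(mesh$vertex_area[vertex_subset])
}
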