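#' Penetration analysis configuration
#'
#' @param radius_mm cylinder radius (the virtual electrode probes a
#'   1.2-mm-diameter column by default).
#' @param depth_range_mm axial extent of the cylinder from the surface, mm.
#' @param patch_radius_mm manifold radius of the surface patch whose mean
#'   normal orients the cylinder, mm.
#' @param d0_grid candidate initial depths (superficial tissue removed
#'   before the linear fit), mm.
#' @param min_points minimum voxels per linear fit.
#' @param value one of "centroid" (preferred frequency, octaves) or
#'   "hl_diff" (high-minus-low amplitude difference, percent signal).
#' @param sig_threshold,trend_threshold p-value thresholds for the area
#'   summary.
#' @param upsample_factor analysis-grid refinement factor relative to the
#'   acquisition grid (response data are resampled onto this finer grid
#'   before depth mapping, mirroring alignment to a finer structural
#'   reference).
#' @param B,seed bootstrap resamples and base seed for slope p values.
#' @return An object of class `penetration_config`.
#' @export
penetration_config <- function(radius_mm = 0.6, depth_range_mm = c(0, 5),
                               patch_radius_mm = 0.6,
                               d0_grid = seq(0, 1.5, by = 0.1),
                               min_points = 4, value = c("centroid", "hl_diff"),
                               sig_threshold = 0.05, trend_threshold = 0.16,
                               upsample_factor = 2, B = 1000, seed = 1) {
  value <- match.arg(value)
  structure(list(radius_mm = radius_mm, depth_range_mm = depth_range_mm,
                 patch_radius_mm = patch_radius_mm, d0_grid = d0_grid,
                 min_points = min_points, value = value,
                 sig_threshold = sig_threshold,
                 trend_threshold = trend_threshold,
                 upsample_factor = upsample_factor, B = B, seed = seed),
            class = "penetration_config")
}

#' Build the fine analysis grid
#'
#' Refines the acquisition grid by an integer factor and constructs the
#' (mask-aware, renormalized) trilinear interpolation operator from the
#' in-mask acquisition voxels to the in-mask fine voxels. Depth maps and
#' cylinder membership are computed on this grid.
#'
#' @param mask acquisition-grid binary mask.
#' @param voxel_size acquisition voxel size, mm.
#' @param factor refinement factor (2 halves the voxel edge).
#' @return List: `mask` (fine binary array), `dim`, `voxel_size`,
#'   `voxel` (linear indices of in-mask fine voxels), `points` (their
#'   centers, mm), `S` (sparse interpolation matrix, fine x coarse
#'   in-mask voxels), `coarse_voxel` (column indexing).
#' @export
analysis_grid <- function(mask, voxel_size = attr(mask, "voxel_size_mm"),
                          factor = 2) {
  stopifnot(length(dim(mask)) == 3, factor >= 1)
  d <- dim(mask)
  fd <- d * factor
  fvs <- voxel_size / factor
  fpts_all <- voxel_centers(fd, fvs)
  inside <- .trilinear(as.numeric(mask > 0), d, fpts_all, voxel_size) >= 0.5
  fmask <- array(as.integer(inside), fd)
  attr(fmask, "voxel_size_mm") <- fvs
  fvox <- which(fmask > 0)
  fpts <- fpts_all[fvox, , drop = FALSE]
  coarse_vox <- which(mask > 0)
  S <- interp_matrix(d, voxel_size, fpts, coarse_vox)
  list(mask = fmask, dim = fd, voxel_size = fvs, voxel = fvox,
       points = fpts, S = S, coarse_voxel = coarse_vox)
}

# Sparse trilinear interpolation matrix from selected coarse voxels to
# arbitrary points; weights on unselected (out-of-mask) voxels are dropped
# and rows renormalized.
interp_matrix <- function(dim, voxel_size, pts, coarse_voxel) {
  n <- nrow(pts)
  g <- sweep(pts, 2, voxel_size, "/") - 0.5
  for (ax in 1:3) g[, ax] <- pmin(pmax(g[, ax], 0), dim[ax] - 1)
  i0 <- pmin(floor(g), matrix(rep(dim - 2, each = n), n, 3))
  i0 <- pmax(i0, 0)
  fr <- g - i0
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- (i0[, 1] + dx) + dim[1] * ((i0[, 2] + dy) +
                                        dim[2] * (i0[, 3] + dz)) + 1
    keep <- w > 0
    ii <- c(ii, which(keep)); jj <- c(jj, lin[keep]); xx <- c(xx, w[keep])
  }
  col_of <- integer(prod(dim))
  col_of[coarse_voxel] <- seq_along(coarse_voxel)
  sel <- col_of[jj] > 0
  S <- Matrix::sparseMatrix(i = ii[sel], j = col_of[jj[sel]], x = xx[sel],
                            dims = c(n, length(coarse_voxel)))
  rs <- Matrix::rowSums(S)
  rs[rs == 0] <- 1
  S / rs
}

#' Build a virtual penetration
#'
#' A cylinder extended along the inward mean surface normal of the
#' manifold patch around a vertex: member voxels are in-mask voxel
#' centers with perpendicular distance to the axis at most `radius_mm`
#' and axial projection inside `depth_range_mm`. Each member carries its
#' nearest-vertex depth from the depth map.
#'
#' @param mesh a [extract_surface()] mesh.
#' @param depthmap a [compute_depth_map()] result (any grid).
#' @param vertex_id origin vertex.
#' @param cfg a [penetration_config()].
#' @param patch optional precomputed manifold patch vertex ids.
#' @return An object of class `penetration`: `vertex`, `origin` (mm),
#'   `direction` (inward unit vector), `rows` (row indices into
#'   `depthmap$voxels`), `depth_mm`, `t_axial`, `usable`.
#' @export
build_penetration <- function(mesh, depthmap, vertex_id, cfg = penetration_config(),
                              patch = NULL) {
  if (is.null(patch))
    patch <- manifold_patch(mesh, vertex_id, cfg$patch_radius_mm)
  N <- if (is.null(mesh$normals_smooth)) mesh$normals else mesh$normals_smooth
  nrm <- colMeans(N[patch, , drop = FALSE])
  nn <- sqrt(sum(nrm^2))
  if (nn == 0) nrm <- mesh$normals[vertex_id, ] else nrm <- nrm / nn
  dir <- unname(-nrm)
  origin <- unname(mesh$vertices[vertex_id, ])
  P <- as.matrix(depthmap$voxels[, c("x", "y", "z")])
  rel <- sweep(P, 2, origin)
  t_ax <- as.vector(rel %*% dir)
  perp2 <- rowSums(rel^2) - t_ax^2
  sel <- which(t_ax >= cfg$depth_range_mm[1] & t_ax <= cfg$depth_range_mm[2] &
                 perp2 <= cfg$radius_mm^2 + 1e-12)
  structure(list(vertex = vertex_id, origin = origin, direction = dir,
                 rows = sel, depth_mm = depthmap$voxels$depth_mm[sel],
                 t_axial = t_ax[sel],
                 usable = length(sel) >= cfg$min_points),
            class = "penetration")
}

# Closed-form least-squares line fit returning slope, intercept and r2.
line_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(c(slope = NA, intercept = NA, r2 = NA))
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
  c(slope = slope, intercept = my - slope * mx, r2 = r2)
}

#' Fit a depth gradient within a penetration
#'
#' Least-squares straight line of value versus depth, re-fit after
#' removing a variable amount of superficial tissue: every candidate
#' initial depth in `d0_grid` keeping at least `min_points` voxels is
#' tried and the one maximizing R^2 is kept (ties broken toward the
#' smaller d0, keeping more data).
#'
#' @param pen a [build_penetration()].
#' @param values value per member voxel (same order as `pen$rows`).
#' @param cfg a [penetration_config()].
#' @return An object of class `depth_fit`: `g` (slope per mm), `intercept`,
#'   `d0`, `r2`, `n_voxels`, `usable`.
#' @export
fit_depth_gradient <- function(pen, values, cfg = penetration_config()) {
  ok <- is.finite(values) & is.finite(pen$depth_mm)
  best <- NULL
  for (d0 in cfg$d0_grid) {
    sel <- ok & pen$depth_mm >= d0
    if (sum(sel) < cfg$min_points) next
    f <- line_fit(pen$depth_mm[sel], values[sel])
    if (is.na(f["slope"])) next
    if (is.null(best) || f["r2"] > best$r2 + 1e-12) {
      best <- list(g = unname(f["slope"]), intercept = unname(f["intercept"]),
                   d0 = d0, r2 = unname(f["r2"]), n_voxels = sum(sel))
    }
  }
  if (is.null(best))
    return(structure(list(g = NA_real_, intercept = NA_real_, d0 = NA_real_,
                          r2 = NA_real_, n_voxels = 0L, usable = FALSE),
                     class = "depth_fit"))
  structure(c(best, list(usable = TRUE)), class = "depth_fit")
}

# Fine-grid per-condition bootstrap means restricted to one penetration:
# resamples the ~55 presentations of each sound condition, averages, and
# interpolates onto the member voxels. Quiet resampling is omitted: the
# quiet reference shifts all conditions equally, and both the centroid
# (offset-invariant by min subtraction) and the high-low difference are
# unaffected by a common offset.
penetration_bootstrap_values <- function(pen, resp, S, cfg, fit) {
  keep <- which(is.finite(pen$depth_mm) & pen$depth_mm >= fit$d0)
  sel <- pen$rows[keep]
  dd <- pen$depth_mm[keep]
  Ssub <- S[sel, , drop = FALSE]
  cols <- which(Matrix::colSums(Ssub) > 0)
  Ssub <- as.matrix(Ssub[, cols, drop = FALSE])
  reps <- dim(resp$samples)[3]
  boot <- vector("list", 5)
  with_seed(cfg$seed + pen$vertex, {
    for (ci in 1:5) {
      W <- bootstrap_weights(reps, cfg$B)
      Xc <- matrix(resp$samples[cols, ci + 1, ], length(cols), reps)
      boot[[ci]] <- (W %*% t(Xc)) %*% t(Ssub)   # B x m
    }
  })
  list(boot = boot, depth = dd)
}

#' Bootstrap p value of a depth-gradient slope
#'
#' Refits the depth line on each of B presentation-level resamples
#' (initial depth held fixed at the point estimate's d0) and reports the
#' fraction of resampled slopes at or below zero, clamped to at least
#' 1/(B+1). One-sided for positive gradients; set `mirror = TRUE` to test
#' reversed (negative) gradients by the fraction of positive slopes.
#'
#' @param pen a [build_penetration()] on the analysis grid.
#' @param resp the acquisition-grid [extract_amplitudes()] object.
#' @param S interpolation matrix of the [analysis_grid()] the penetration
#'   lives on.
#' @param fit the point-estimate [fit_depth_gradient()].
#' @param cfg a [penetration_config()].
#' @param mirror test for negative slopes instead.
#' @return p value in (0, 1].
#' @export
bootstrap_slope_p <- function(pen, resp, S, fit, cfg = penetration_config(),
                              mirror = FALSE) {
  if (!fit$usable) return(NA_real_)
  bv <- penetration_bootstrap_values(pen, resp, S, cfg, fit)
  dd <- bv$depth
  xc <- dd - mean(dd)
  sxx <- sum(xc^2)
  if (cfg$value == "centroid") {
    f <- resp$f_oct
    mn <- bv$boot[[1]]
    for (ci in 2:5) mn <- pmin(mn, bv$boot[[ci]])
    num <- 0; den <- 0
    for (ci in 1:5) {
      w <- bv$boot[[ci]] - mn
      num <- num + w * f[ci]
      den <- den + w
    }
    vals <- num / den
  } else {
    vals <- bv$boot[[5]] - bv$boot[[1]]
  }
  slopes <- as.vector(vals %*% xc) / sxx
  slopes <- slopes[is.finite(slopes)]
  if (!length(slopes)) return(NA_real_)
  frac <- if (mirror) mean(slopes >= 0) else mean(slopes <= 0)
  max(frac, 1 / (cfg$B + 1))
}

#' Map depth gradients over the analysis region
#'
#' One virtual penetration per region vertex: orients the cylinder by the
#' manifold-patch mean normal, fits the depth gradient of the chosen
#' per-voxel value (centroid frequency by default) with the initial-depth
#' search, and assigns a bootstrap slope p value. Unusable penetrations
#' (too few member voxels at every initial depth) are recorded with NA.
#'
#' @param mesh surface mesh with `region` vertices to probe.
#' @param region integer ids or logical mask of region vertices.
#' @param depthmap depth map on the analysis grid.
#' @param grid the [analysis_grid()].
#' @param resp acquisition-grid [extract_amplitudes()] object.
#' @param cfg a [penetration_config()].
#' @param mirror run the mirrored (reversed-gradient) test.
#' @return Data frame, one row per region vertex: `vertex`, `g`, `p`,
#'   `r2`, `d0`, `n_voxels`, `usable`, `nx`, `ny`, `nz` (penetration
#'   direction). Attribute `penetration_rows` holds each penetration's
#'   member rows for downstream ground-truth matching.
#' @export
map_gradients <- function(mesh, region, depthmap, grid, resp,
                          cfg = penetration_config(), mirror = FALSE) {
  if (is.logical(region)) region <- which(region)
  graph <- mesh_graph(mesh)
  dmat <- igraph::distances(graph, v = region, algorithm = "dijkstra")
  fineA <- as.matrix(grid$S %*% resp$A)
  vals_all <- if (cfg$value == "centroid") {
    centroid_frequency(fineA, resp$f_oct)
  } else {
    fineA[, 5] - fineA[, 1]
  }
  rows_list <- vector("list", length(region))
  out <- data.frame(vertex = region, g = NA_real_, p = NA_real_,
                    r2 = NA_real_, d0 = NA_real_, n_voxels = 0L,
                    usable = FALSE, nx = NA_real_, ny = NA_real_,
                    nz = NA_real_)
  for (k in seq_along(region)) {
    v <- region[k]
    patch <- unique(c(v, which(dmat[k, ] < cfg$patch_radius_mm)))
    pen <- build_penetration(mesh, depthmap, v, cfg, patch = patch)
    out$nx[k] <- pen$direction[1]
    out$ny[k] <- pen$direction[2]
    out$nz[k] <- pen$direction[3]
    if (!pen$usable) next
    fit <- fit_depth_gradient(pen, vals_all[pen$rows], cfg)
    if (!fit$usable) next
    p <- bootstrap_slope_p(pen, resp, grid$S, fit, cfg, mirror = mirror)
    out$g[k] <- fit$g
    out$p[k] <- p
    out$r2[k] <- fit$r2
    out$d0[k] <- fit$d0
    out$n_voxels[k] <- fit$n_voxels
    out$usable[k] <- TRUE
    rows_list[[k]] <- pen$rows[pen$depth_mm >= fit$d0]
  }
  attr(out, "penetration_rows") <- rows_list
  out
}

#' Area of significant and trend-level gradients
#'
#' Sums per-vertex barycentric areas over vertices whose p value falls
#' below each threshold.
#'
#' @param mesh surface mesh.
#' @param vertex_ids vertices the p values belong to.
#' @param p p value per vertex (NA = unusable, never counted).
#' @param thresholds p-value thresholds.
#' @return Data frame `threshold`, `area_mm2`.
#' @export
area_summary <- function(mesh, vertex_ids, p, thresholds = c(0.05, 0.16, 1)) {
  data.frame(threshold = thresholds,
             area_mm2 = vapply(thresholds, function(th) {
               sel <- vertex_ids[!is.na(p) & p < th]
               region_area(mesh, sel)
             }, numeric(1)))
}

#' Slope-weighted mean gradient direction
#'
#' The mean tonotopic depth-gradient direction over significant
#' penetrations, weighted by their slopes, normalized to a unit vector,
#' with its sagittal- and axial-plane angles: 0 degrees points anterior
#' (+y), positive sagittal angles rotate superior (+z), positive axial
#' angles rotate to the right (+x).
#'
#' @param directions n x 3 matrix of penetration unit directions.
#' @param g slopes.
#' @param p p values.
#' @param sig_threshold significance cut for inclusion.
#' @return List `n_mean` (unit vector), `sagittal_angle_deg`,
#'   `axial_angle_deg`, `n_used`; all NA when nothing is significant.
#' @export
mean_gradient_direction <- function(directions, g, p, sig_threshold = 0.05) {
  sel <- which(!is.na(p) & p < sig_threshold & is.finite(g))
  if (!length(sel))
    return(list(n_mean = rep(NA_real_, 3), sagittal_angle_deg = NA_real_,
                axial_angle_deg = NA_real_, n_used = 0L))
  w <- g[sel]
  nm <- unname(colSums(directions[sel, , drop = FALSE] * w) / sum(w))
  nm <- nm / sqrt(sum(nm^2))
  list(n_mean = nm,
       sagittal_angle_deg = atan2(nm[3], nm[2]) * 180 / pi,
       axial_angle_deg = atan2(nm[1], nm[2]) * 180 / pi,
       n_used = length(sel))
}

#' Spatial-blurring control
#'
#' Applies a Gaussian kernel of the stated FWHM to every presentation
#' volume of a session, leaving everything else unchanged, so the whole
#' depth analysis can be repeated on spatially smoothed data.
#'
#' @param session a [simulate_session()] object (or any list with a 4-D
#'   `data` array and `spec$voxel_size_mm`).
#' @param fwhm_mm blur kernel FWHM, mm (must exceed the voxel size).
#' @return The session with blurred `data`.
#' @export
blur_control <- function(session, fwhm_mm = 2) {
  vs <- session$spec$voxel_size_mm
  if (fwhm_mm <= vs) stop("fwhm_mm must exceed the voxel size")
  d <- dim(session$data)
  for (pres in seq_len(d[4])) {
    session$data[, , , pres] <-
      gaussian_blur(session$data[, , , pres], fwhm_mm, vs)
  }
  session$blur_fwhm_mm <- fwhm_mm
  session
}

#' Thermal-SNR gain between two effective resolutions
#'
#' Measures the noise-sd ratio between white noise carried to two
#' Gaussian effective resolutions (FWHM), on a grid fine relative to both
#' kernels; for resolutions f1 < f2 the expected gain is the square root
#' of the voxel-volume ratio, (f2/f1)^1.5.
#'
#' @param fwhm_lo_mm,fwhm_hi_mm the two effective resolutions, mm.
#' @param n grid extent per axis.
#' @param spacing_mm grid spacing, mm (keep well below `fwhm_lo_mm`).
#' @param seed RNG seed.
#' @return Measured sd ratio (noise at `fwhm_lo_mm` / noise at
#'   `fwhm_hi_mm`).
#' @export
blur_snr_improvement <- function(fwhm_lo_mm = 1.2, fwhm_hi_mm = 2,
                                 n = 64, spacing_mm = 0.4, seed = 1) {
  noise <- with_seed(seed, array(rnorm(n^3), c(n, n, n)))
  lo <- gaussian_blur(noise, fwhm_lo_mm, spacing_mm)
  hi <- gaussian_blur(noise, fwhm_hi_mm, spacing_mm)
  crop <- ceiling(2 * fwhm_hi_mm / spacing_mm)
  keep <- (crop + 1):(n - crop)
  sd(lo[keep, keep, keep]) / sd(hi[keep, keep, keep])
}

#' Opacity from a p value
#'
#' Overlay transparency convention: opaque below p = 0.05, fully
#' transparent at and above p = 0.5, linear in log(p) between.
#'
#' @param p p value(s) in (0, 1].
#' @return Opacity in [0, 1].
#' @export
alpha_from_p <- function(p) {
  a <- 1 - log(p / 0.05) / log(0.5 / 0.05)
  pmin(pmax(a, 0), 1)
}
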