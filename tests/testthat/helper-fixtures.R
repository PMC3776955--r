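# Shared fixtures, built once per test session and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Digitized sphere, r = 10 mm, 1 mm voxels.
sphere_fixture <- function() {
  cached("sphere", {
    n <- 26
    pts <- voxel_centers(c(n, n, n), 1)
    ctr <- rep(n / 2, 3)
    mask <- array(as.integer(sqrt(rowSums(sweep(pts, 2, ctr)^2)) <= 10),
                  c(n, n, n))
    attr(mask, "voxel_size_mm") <- 1
    # smoothing at twice the voxel scale: converged regime for a large,
    # smooth object
    list(mask = mask, center = ctr, r = 10,
         mesh = extract_surface(mask, pre_smooth_fwhm_vox = 2))
  })
}

# Flat slab block: top face at z = 6 mm, 1 mm voxels.
slab_fixture <- function() {
  cached("slab", {
    d <- c(16, 16, 10)
    pts <- voxel_centers(d, 1)
    mask <- array(as.integer(pts[, 1] > 1 & pts[, 1] < 15 &
                               pts[, 2] > 1 & pts[, 2] < 15 &
                               pts[, 3] > 1 & pts[, 3] < 6), d)
    attr(mask, "voxel_size_mm") <- 1
    list(mask = mask, top = 6, mesh = extract_surface(mask))
  })
}

# Small phantom + session for fast end-to-end tests.
small_spec <- function(...) {
  phantom_spec(grid_shape = c(18, 12, 11), colliculus_radii_mm = c(3.5, 3.5, 3.2),
               cap_separation_mm = 8, slab_top_mm = 6, n_runs = 4, ...)
}

small_session_fixture <- function() {
  cached("small_session", {
    spec <- small_spec()
    mask <- make_phantom_mask(spec)
    truth <- plant_frequency_field(mask, spec)
    session <- simulate_session(truth, spec)
    list(spec = spec, mask = mask, truth = truth, session = session)
  })
}

# Default-condition pipeline run shared by the acceptance tests.
default_pipeline_fixture <- function() {
  cached("default_pipeline", run_pipeline(pipeline_config(seed = 1)))
}

# Recovery experiment at study conditions (three replicate sessions).
recovery_fixture <- function() {
  cached("recovery", run_recovery_experiment(n_sessions = 3, seed = 1))
}

# Hand-built regular planar grid mesh (spacing in mm) for manifold tests.
planar_grid_mesh <- function(n = 7, spacing = 0.5) {
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  verts <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(i, j) (j - 1) * n + i
  faces <- NULL
  for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
    faces <- rbind(faces,
                   c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                   c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  mesh <- structure(list(vertices = verts, faces = faces),
                    class = "surface_mesh")
  tonodepth:::mesh_geometry(mesh)
}
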