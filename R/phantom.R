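#' Specification of the synthetic midbrain phantom
#'
#' Bundles every parameter of the synthetic phantom and its simulated
#' sparse-sampling fMRI session: the geometry (a brainstem slab carrying
#' two superior half-ellipsoid collicular protrusions on a 1.2-mm
#' isotropic grid), the planted tonotopy (a superficial non-tonotopic rind
#' above a linear depth-wise preferred-frequency law inside patchy
#' sub-regions of the caps), and the acquisition model (one response
#' amplitude per 12-s presentation, five log-spaced sound conditions plus
#' quiet, thermal temporal SNR of the images).
#'
#' @param grid_shape voxels per axis (x = right, y = anterior, z = superior).
#' @param voxel_size_mm isotropic voxel edge length, mm.
#' @param colliculus_radii_mm semi-axes (x, y, z) of each collicular cap, mm.
#' @param cap_separation_mm distance between the two cap centers along x, mm.
#' @param slab_top_mm height of the tissue slab's superior face, mm; caps
#'   sit on this plane.
#' @param rind_thickness_mm thickness of the superficial non-tonotopic rind,
#'   mm, in [0, 1.5].
#' @param gradient_oct_per_mm planted depth slope of preferred frequency,
#'   octaves/mm.
#' @param base_freq_oct preferred frequency at the bottom of the rind,
#'   octaves re 1 kHz.
#' @param patch_fraction fraction of the cap surface covered by tonotopic
#'   patches, in (0, 1].
#' @param reversed_patch_fraction fraction of the cap surface whose patches
#'   carry a negated gradient.
#' @param patch_scale_mm characteristic patch diameter, mm.
#' @param snr temporal signal-to-noise ratio of the simulated images.
#' @param n_runs runs per session.
#' @param reps_per_run stimulus-cycle repeats per run (presentations per
#'   condition per run).
#' @param response_amp_pct peak evoked amplitude, percent of baseline.
#' @param untuned_response response of untuned tissue to every sound, as a
#'   fraction of the peak amplitude.
#' @param tuning_width_oct sd of the planted Gaussian (in log2-frequency)
#'   voxel tuning curve, octaves.
#' @param undershoot_frac fraction of the preceding condition's response
#'   subtracted from each presentation (hemodynamic undershoot carry-over);
#'   0 disables it.
#' @param baseline mean image intensity of tissue, arbitrary scanner units.
#' @param gain_amp amplitude of the smooth multiplicative coil-gain field
#'   (0 disables it); exercised by homomorphic normalization.
#' @param f_lo_khz,f_hi_khz extreme stimulus center frequencies, kHz.
#' @param presentation_period_s stimulus presentation period, s.
#' @param seed RNG seed used by field planting and session simulation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24, 16, 15),
                         voxel_size_mm = 1.2,
                         colliculus_radii_mm = c(4.5, 4.5, 4.5),
                         cap_separation_mm = 12,
                         slab_top_mm = 10.8,
                         rind_thickness_mm = 0.7,
                         gradient_oct_per_mm = 0.53,
                         base_freq_oct = -0.5,
                         patch_fraction = 0.7,
                         reversed_patch_fraction = 0,
                         patch_scale_mm = 3,
                         snr = 25,
                         n_runs = 11,
                         reps_per_run = 5,
                         response_amp_pct = 2.5,
                         untuned_response = 0.5,
                         tuning_width_oct = 1,
                         undershoot_frac = 0,
                         baseline = 1000,
                         gain_amp = 0.2,
                         f_lo_khz = 0.25,
                         f_hi_khz = 8,
                         presentation_period_s = 12,
                         seed = 1) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2),
            voxel_size_mm > 0, length(colliculus_radii_mm) == 3,
            all(colliculus_radii_mm >= 0))
  if (rind_thickness_mm < 0 || rind_thickness_mm > 1.5)
    stop("rind_thickness_mm must lie in [0, 1.5]")
  if (snr <= 0) stop("snr must be positive")
  if (patch_fraction < 0 || patch_fraction > 1 ||
      reversed_patch_fraction < 0 || reversed_patch_fraction > 1 ||
      patch_fraction + reversed_patch_fraction > 1)
    stop("patch fractions must lie in [0, 1] and sum to at most 1")
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_mm = voxel_size_mm,
               colliculus_radii_mm = colliculus_radii_mm,
               cap_separation_mm = cap_separation_mm,
               slab_top_mm = slab_top_mm,
               rind_thickness_mm = rind_thickness_mm,
               gradient_oct_per_mm = gradient_oct_per_mm,
               base_freq_oct = base_freq_oct,
               patch_fraction = patch_fraction,
               reversed_patch_fraction = reversed_patch_fraction,
               patch_scale_mm = patch_scale_mm,
               snr = snr, n_runs = n_runs, reps_per_run = reps_per_run,
               response_amp_pct = response_amp_pct,
               untuned_response = untuned_response,
               tuning_width_oct = tuning_width_oct,
               undershoot_frac = undershoot_frac,
               baseline = baseline, gain_amp = gain_amp,
               f_lo_khz = f_lo_khz, f_hi_khz = f_hi_khz,
               presentation_period_s = presentation_period_s,
               seed = seed)
  class(spec) <- "phantom_spec"
  # Geometry derived once: slab box aligned to voxel boundaries, caps
  # centered on the slab top.
  fov <- spec$grid_shape * voxel_size_mm
  margin <- voxel_size_mm
  spec$slab_lo <- c(margin, margin, margin)
  spec$slab_hi <- c(fov[1] - margin, fov[2] - margin, slab_top_mm)
  spec$cap_centers <- rbind(
    c(fov[1] / 2 - cap_separation_mm / 2, fov[2] / 2, slab_top_mm),
    c(fov[1] / 2 + cap_separation_mm / 2, fov[2] / 2, slab_top_mm))
  r <- colliculus_radii_mm
  over <- c(spec$cap_centers[1, 1] - r[1] < spec$slab_lo[1],
            spec$cap_centers[2, 1] + r[1] > spec$slab_hi[1],
            spec$cap_centers[1, 2] - r[2] < spec$slab_lo[2] ||
              spec$cap_centers[1, 2] + r[2] > spec$slab_hi[2],
            slab_top_mm + r[3] > fov[3] - margin)
  if (any(over[c(1, 2)]))
    stop("colliculus_radii_mm exceed the grid along the x axis")
  if (over[3]) stop("colliculus_radii_mm exceed the grid along the y axis")
  if (over[4]) stop("colliculus_radii_mm exceed the grid along the z axis")
  spec
}

#' Logarithmically spaced stimulus center frequencies
#'
#' @param f_lo_khz,f_hi_khz endpoints of the frequency range, kHz.
#' @param n number of center frequencies.
#' @return Geometric progression from `f_lo_khz` to `f_hi_khz`, kHz.
#' @export
stimulus_frequencies <- function(f_lo_khz = 0.25, f_hi_khz = 8, n = 5) {
  if (f_lo_khz <= 0 || f_hi_khz <= 0) stop("frequencies must be positive")
  if (f_lo_khz >= f_hi_khz) stop("f_lo_khz must be below f_hi_khz")
  if (n < 2) stop("need at least two frequencies")
  exp(seq(log(f_lo_khz), log(f_hi_khz), length.out = n))
}

#' Session design table
#'
#' One row per stimulus presentation. Each run repeats the same monotonic
#' cycle of the five sound conditions followed by a quiet reference period
#' (`condition` 0), so one cycle lasts six presentation periods.
#'
#' @param spec a [phantom_spec()].
#' @return A data frame with columns `run`, `presentation` (within run),
#'   `condition` (0 = quiet, 1..5 = sounds low to high) and
#'   `center_freq_khz` (NA for quiet), plus attributes `center_freqs_khz`,
#'   `presentation_period_s` and `cycle_period_s`.
#' @export
session_design <- function(spec) {
  freqs <- stimulus_frequencies(spec$f_lo_khz, spec$f_hi_khz, 5)
  cycle <- c(1:5, 0)
  cond <- rep(rep(cycle, spec$reps_per_run), spec$n_runs)
  n_per_run <- 6 * spec$reps_per_run
  design <- data.frame(
    run = rep(seq_len(spec$n_runs), each = n_per_run),
    presentation = rep(seq_len(n_per_run), spec$n_runs),
    condition = cond,
    center_freq_khz = ifelse(cond == 0, NA_real_, freqs[pmax(cond, 1)]))
  attr(design, "center_freqs_khz") <- freqs
  attr(design, "presentation_period_s") <- spec$presentation_period_s
  attr(design, "cycle_period_s") <- 6 * spec$presentation_period_s
  design
}

#' Binary tissue mask of the phantom
#'
#' Brainstem slab plus two superior half-ellipsoid collicular caps; a voxel
#' is tissue when its center lies inside the slab box or inside a cap
#' (above the slab top plane). Deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return A 3-D 0/1 integer array with attributes `voxel_size_mm` and
#'   `spec`.
#' @export
make_phantom_mask <- function(spec) {
  pts <- voxel_centers(spec$grid_shape, spec$voxel_size_mm)
  in_slab <- pts[, 1] > spec$slab_lo[1] & pts[, 1] < spec$slab_hi[1] &
    pts[, 2] > spec$slab_lo[2] & pts[, 2] < spec$slab_hi[2] &
    pts[, 3] > spec$slab_lo[3] & pts[, 3] < spec$slab_hi[3]
  in_cap <- rep(FALSE, nrow(pts))
  r <- spec$colliculus_radii_mm
  if (all(r > 0)) {
    for (ci in 1:2) {
      d <- sweep(pts, 2, spec$cap_centers[ci, ])
      in_cap <- in_cap |
        (rowSums(sweep(d, 2, r, "/")^2) < 1 & pts[, 3] >= spec$slab_top_mm)
    }
  }
  mask <- array(as.integer(in_slab | in_cap), spec$grid_shape)
  attr(mask, "voxel_size_mm") <- spec$voxel_size_mm
  attr(mask, "spec") <- spec
  mask
}

# Analytic slab + caps volume in mm^3 (caps are half ellipsoids).
phantom_analytic_volume <- function(spec) {
  slab <- prod(spec$slab_hi - spec$slab_lo)
  caps <- 2 * (2 / 3) * pi * prod(spec$colliculus_radii_mm)
  slab + caps
}

# Distance from interior points to an ellipsoid surface (centered,
# semi-axes r), via Newton iteration on the standard projection equation
# x_i = r_i^2 p_i / (r_i^2 + t). Exact for spheres; accurate to ~1e-10
# generally. `pts` are coordinates relative to the ellipsoid center.
ellipsoid_surface_distance <- function(pts, r) {
  pts <- rbind(pts)
  n <- nrow(pts)
  p2 <- sweep(pts^2, 2, r^2, "*")       # r_i^2 p_i^2
  t <- numeric(n)
  for (it in 1:60) {
    den <- outer(t, r^2, "+")           # t + r_i^2
    f <- rowSums(p2 / den^2) - 1
    fp <- -2 * rowSums(p2 / den^3)
    step <- f / fp
    t <- t - step
    t <- pmax(t, -min(r)^2 * 0.999999)
    if (max(abs(step)) < 1e-12) break
  }
  den <- outer(t, r^2, "+")
  proj <- sweep(pts, 2, r^2, "*") / den
  d <- sqrt(rowSums((proj - pts)^2))
  at_center <- rowSums(pts^2) == 0
  d[at_center] <- min(r)
  list(distance = d, surface_point = proj)
}

# Analytic depth (distance to the phantom boundary) plus which boundary
# piece is nearest. Pieces: the two cap surfaces (upper shell or rim), the
# exposed slab top plane, and the slab bottom/side faces. Also returns,
# for every point inside a cap's footprint column, the cap id and a unit
# "tile direction" (scaled outward direction used for patch assignment).
phantom_depth <- function(spec, pts) {
  pts <- rbind(pts)
  n <- nrow(pts)
  r <- spec$colliculus_radii_mm
  cand <- matrix(Inf, n, 6)  # cap1, cap2, top, bottom, x sides, y sides
  cap_domain <- rep(0L, n)
  tile_dir <- matrix(NA_real_, n, 3)
  dz_top <- spec$slab_hi[3] - pts[, 3]
  horiz <- rep(0, n)
  if (all(r > 0)) {
    for (ci in 1:2) {
      rel <- sweep(pts, 2, spec$cap_centers[ci, ])
      relh <- rel[, 1:2, drop = FALSE]
      # Horizontal reach to the footprint edge along the radial direction
      # (exact for circular footprints, close for mild ellipticity).
      hmag <- sqrt(rowSums(relh^2))
      k <- sqrt(rowSums(sweep(relh, 2, r[1:2], "/")^2)) / pmax(hmag, 1e-12)
      k[hmag < 1e-12] <- 1 / min(r[1:2])
      edge_gap <- pmax(1 / k - hmag, 0)
      u <- hmag * k
      in_col <- u < 1 & pts[, 3] <= spec$slab_hi[3] + r[3] &
        pts[, 3] >= spec$slab_lo[3]
      # Distance to the upper shell: ellipsoid projection where it lands
      # on the upper half, else the rim.
      inside <- rowSums(sweep(rel, 2, r, "/")^2) < 1
      es <- ellipsoid_surface_distance(rel, r)
      upper <- es$surface_point[, 3] >= -1e-9
      rim_d <- sqrt(edge_gap^2 + rel[, 3]^2)
      capd <- ifelse(inside & upper, es$distance,
                     ifelse(inside | (u < 1 & rel[, 3] < 0), rim_d, Inf))
      cand[, ci] <- capd
      # Patch coordinate: the scaled azimuth about the cap center. Radial
      # penetrations preserve azimuth at every depth (also below the cap,
      # inside the footprint column), so azimuthal patches stay
      # label-consistent along a penetration.
      sel <- which(in_col & (inside | rel[, 3] <= 0))
      if (length(sel)) {
        cap_domain[sel] <- ci
        tile_dir[sel, 1] <- atan2(rel[sel, 2] / r[2], rel[sel, 1] / r[1])
      }
      under <- u < 1 & dz_top >= 0
      horiz[under] <- pmax(horiz[under], edge_gap[under])
    }
  }
  cand[, 3] <- ifelse(dz_top >= 0, sqrt(dz_top^2 + horiz^2), Inf)
  cand[, 4] <- pts[, 3] - spec$slab_lo[3]
  cand[, 5] <- pmin(pts[, 1] - spec$slab_lo[1], spec$slab_hi[1] - pts[, 1])
  cand[, 6] <- pmin(pts[, 2] - spec$slab_lo[2], spec$slab_hi[2] - pts[, 2])
  piece <- max.col(-cand, ties.method = "first")
  depth <- cand[cbind(seq_len(n), piece)]
  list(depth = depth, piece = piece, cap_domain = cap_domain,
       azimuth = tile_dir[, 1])
}

#' Plant the ground-truth preferred-frequency field
#'
#' Computes each tissue voxel's analytic depth from the phantom geometry
#' (independently of the surface module, to avoid circularity), tiles the
#' cap surfaces into contiguous patches by a seeded surface Voronoi
#' tessellation, labels patches tonotopic / reversed / untuned, and plants
#' the linear preferred-frequency law `base + g * (depth - rind)` (negated
#' in reversed patches) in sub-rind voxels whose nearest boundary is a cap
#' surface.
#'
#' @param mask a mask from [make_phantom_mask()].
#' @param spec the same [phantom_spec()].
#' @return An object of class `ground_truth`: arrays `preferred_freq_oct`
#'   (NA where undefined), `depth_mm`, `patch_label` (0 = untuned tissue,
#'   1 = rind, 2 = tonotopic, 3 = reversed), `cap_domain` (0 outside the
#'   footprint columns, else the cap id), and scalars `g_true`,
#'   `rind_thickness_mm`.
#' @export
plant_frequency_field <- function(mask, spec = attr(mask, "spec")) {
  stopifnot(!is.null(spec))
  if (spec$patch_fraction == 0)
    warning("patch_fraction is 0: no tonotopic voxels will be planted")
  dimm <- dim(mask)
  pts <- voxel_centers(dimm, spec$voxel_size_mm)
  in_mask <- which(mask > 0)
  pd <- phantom_depth(spec, pts[in_mask, , drop = FALSE])
  depth <- array(NA_real_, dimm)
  depth[in_mask] <- pd$depth

  label <- array(0L, dimm)
  label[in_mask] <- 0L
  pref <- array(NA_real_, dimm)
  capdom <- array(0L, dimm)
  capdom[in_mask] <- pd$cap_domain
  r <- spec$colliculus_radii_mm

  with_seed(spec$seed, {
    for (ci in 1:2) {
      sub <- which(pd$cap_domain == ci)
      if (!length(sub)) next
      # Seeded tiling of the cap into contiguous azimuthal wedges; the
      # tonotopic field extends down the whole footprint column, so
      # penetrations reach planted tissue over their full depth range and
      # stay within one wedge (azimuth is depth-invariant along radial
      # penetrations).
      rim_circ <- pi * (r[1] + r[2])
      n_tiles <- max(2L, round(rim_circ / spec$patch_scale_mm))
      seed_az <- sort(runif(n_tiles, -pi, pi))
      n_ton <- round(spec$patch_fraction * n_tiles)
      n_rev <- round(spec$reversed_patch_fraction * n_tiles)
      tile_label <- rep(0L, n_tiles)
      ord <- sample.int(n_tiles)
      if (n_ton > 0) tile_label[ord[seq_len(n_ton)]] <- 2L
      if (n_rev > 0) tile_label[ord[n_ton + seq_len(n_rev)]] <- 3L
      # Nearest seed on the circle.
      dmat <- abs(outer(pd$azimuth[sub], seed_az, "-"))
      dmat <- pmin(dmat, 2 * pi - dmat)
      tile <- max.col(-dmat, ties.method = "first")
      vlab <- tile_label[tile]
      vidx <- in_mask[sub]
      d <- pd$depth[sub]
      is_rind <- d < spec$rind_thickness_mm
      lab <- ifelse(is_rind, 1L, vlab)
      label[vidx] <- lab
      g <- spec$gradient_oct_per_mm
      below <- d - spec$rind_thickness_mm
      pref[vidx[lab == 2L]] <-
        spec$base_freq_oct + g * below[lab == 2L]
      pref[vidx[lab == 3L]] <-
        spec$base_freq_oct - g * below[lab == 3L]
    }
  })
  out <- list(preferred_freq_oct = pref, depth_mm = depth,
              patch_label = label, cap_domain = capdom,
              g_true = spec$gradient_oct_per_mm,
              rind_thickness_mm = spec$rind_thickness_mm, spec = spec)
  class(out) <- "ground_truth"
  out
}

#' Planted voxel tuning curve
#'
#' Gaussian in log2-frequency: response of a voxel preferring
#' `preferred_oct` to a sound at `f_oct`, normalized to a peak of one.
#'
#' @param f_oct stimulus frequency, octaves re 1 kHz.
#' @param preferred_oct preferred frequency, octaves re 1 kHz.
#' @param width_oct tuning sd, octaves.
#' @return Response in [0, 1].
#' @export
tuning_curve <- function(f_oct, preferred_oct, width_oct) {
  exp(-(f_oct - preferred_oct)^2 / (2 * width_oct^2))
}

#' Simulate one sparse-sampling session
#'
#' Produces one response-amplitude volume per stimulus presentation (the
#' flat-top sample of that presentation's evoked response): tissue voxels
#' respond with the planted Gaussian tuning curve scaled to
#' `response_amp_pct` percent of baseline, untuned tissue responds equally
#' to all sounds, the quiet condition is baseline only, and iid Gaussian
#' thermal noise with sd `baseline / snr` is added everywhere. A smooth
#' multiplicative coil-gain field multiplies the baseline when `gain_amp`
#' is nonzero. Optionally a fixed fraction of the preceding condition's
#' response is subtracted (hemodynamic undershoot carry-over).
#'
#' @param ground_truth a [plant_frequency_field()] result.
#' @param spec the [phantom_spec()].
#' @param design a [session_design()] table; defaults to
#'   `session_design(spec)`.
#' @param seed RNG seed; defaults to `spec$seed + 1`.
#' @return An object of class `tono_session`: `data` (4-D array, grid x
#'   presentations, scanner units), `design`, `mask`, `spec`.
#' @export
simulate_session <- function(ground_truth, spec = ground_truth$spec,
                             design = session_design(spec),
                             seed = spec$seed + 1) {
  if (spec$snr <= 0) stop("snr must be positive")
  dimm <- dim(ground_truth$depth_mm)
  nvox <- prod(dimm)
  npres <- nrow(design)
  freqs <- attr(design, "center_freqs_khz")
  f_oct <- log2(freqs)

  mask <- !is.na(ground_truth$depth_mm)
  pts <- voxel_centers(dimm, spec$voxel_size_mm)
  fov <- dimm * spec$voxel_size_mm
  gain <- 1 + spec$gain_amp * cos(pi * pts[, 1] / fov[1]) *
    cos(pi * pts[, 2] / fov[2])
  base_vox <- ifelse(as.vector(mask), spec$baseline * gain, 0)

  # Noise-free fractional response of every voxel to each condition
  # (columns: quiet, five sounds).
  resp <- matrix(0, nvox, 6)
  lab <- as.vector(ground_truth$patch_label)
  tuned <- !is.na(as.vector(ground_truth$preferred_freq_oct))
  untuned_tissue <- as.vector(mask) & !tuned
  for (i in 1:5) {
    resp[tuned, i + 1] <- tuning_curve(
      f_oct[i], ground_truth$preferred_freq_oct[tuned],
      spec$tuning_width_oct)
    resp[untuned_tissue, i + 1] <- spec$untuned_response
  }
  amp <- spec$response_amp_pct / 100

  cond <- design$condition
  prev <- c(NA, cond[-npres])
  prev[design$presentation == 1] <- NA
  data <- with_seed(seed, {
    out <- matrix(0, nvox, npres)
    noise_sd <- spec$baseline / spec$snr
    for (p in seq_len(npres)) {
      frac <- resp[, cond[p] + 1]
      if (spec$undershoot_frac > 0 && !is.na(prev[p]))
        frac <- frac - spec$undershoot_frac * resp[, prev[p] + 1]
      out[, p] <- base_vox * (1 + amp * frac) + rnorm(nvox, 0, noise_sd)
    }
    out
  })
  session <- list(data = array(data, c(dimm, npres)), design = design,
                  mask = array(mask, dimm), spec = spec,
                  f_oct = f_oct, seed = seed)
  class(session) <- "tono_session"
  session
}
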