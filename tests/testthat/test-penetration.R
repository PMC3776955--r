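test_that("cylinder membership equals an exhaustive brute-force scan", {
  fx <- slab_fixture()
  grid <- analysis_grid(fx$mask, 1, 2)
  dm <- compute_depth_map(grid$mask, fx$mesh, grid$voxel_size)
  cfg <- penetration_config(B = 100)
  # top-face vertex near the center
  v <- which.min((fx$mesh$vertices[, 1] - 8)^2 +
                   (fx$mesh$vertices[, 2] - 8)^2 +
                   (fx$mesh$vertices[, 3] - fx$top)^2)
  pen <- build_penetration(fx$mesh, dm, v, cfg)
  expect_true(pen$usable)
  # independent scan over every mapped voxel
  expected <- integer(0)
  for (i in seq_len(nrow(dm$voxels))) {
    rel <- c(dm$voxels$x[i], dm$voxels$y[i], dm$voxels$z[i]) - pen$origin
    t_ax <- sum(rel * pen$direction)
    perp <- sqrt(max(sum(rel^2) - t_ax^2, 0))
    if (perp <= cfg$radius_mm + 1e-9 && t_ax >= 0 && t_ax <= 5)
      expected <- c(expected, i)
  }
  expect_setequal(pen$rows, expected)
  # inward orientation on a flat top face: direction points down
  expect_lt(pen$direction[3], -0.95)
  # zero radius keeps at most the axial voxel column
  cfg0 <- penetration_config(radius_mm = 0)
  pen0 <- build_penetration(fx$mesh, dm, v, cfg0)
  expect_lte(length(pen0$rows), 12)
})

test_that("penetration directions are antiparallel to sphere radii", {
  fx <- sphere_fixture()
  dm <- compute_depth_map(fx$mask, fx$mesh)
  cfg <- penetration_config()
  set.seed(4)
  for (v in sample.int(nrow(fx$mesh$vertices), 10)) {
    pen <- build_penetration(fx$mesh, dm, v, cfg)
    radial <- (fx$mesh$vertices[v, ] - fx$center)
    radial <- radial / sqrt(sum(radial^2))
    angle <- acos(pmin(1, -sum(pen$direction * radial))) * 180 / pi
    expect_lt(angle, 5)
  }
})

test_that("depth-gradient fits recover exact lines and rind breakpoints", {
  pen <- structure(list(vertex = 1L, origin = c(0, 0, 0),
                        direction = c(0, 0, -1), rows = 1:40,
                        depth_mm = seq(0.05, 4, length.out = 40),
                        t_axial = seq(0.05, 4, length.out = 40),
                        usable = TRUE), class = "penetration")
  cfg <- penetration_config()
  # exact line: slope and intercept recovered with r2 = 1
  vals <- -0.4 + 0.53 * pen$depth_mm
  fit <- fit_depth_gradient(pen, vals, cfg)
  expect_equal(fit$g, 0.53)
  expect_equal(fit$r2, 1)
  expect_equal(fit$d0, 0)   # ties broken toward the smaller d0
  # flat rind over 0-1 mm, line beyond: the search removes the rind
  vals2 <- ifelse(pen$depth_mm < 1, 0.1, -0.4 + 0.5 * (pen$depth_mm - 1))
  fit2 <- fit_depth_gradient(pen, vals2, cfg)
  expect_equal(fit2$d0, 1, tolerance = 0.101)
  expect_equal(fit2$g, 0.5, tolerance = 0.05)
  expect_gt(fit2$r2, 0.99)
  # pure noise: poor fits, random slope signs
  set.seed(8)
  fits <- t(vapply(1:40, function(i) {
    f <- fit_depth_gradient(pen, rnorm(40), cfg)
    c(f$g, f$r2)
  }, numeric(2)))
  expect_lt(mean(fits[, 2]), 0.5)
  expect_gt(mean(fits[, 1] > 0), 0.2)
  expect_lt(mean(fits[, 1] > 0), 0.8)
  # too few points at every candidate depth: flagged unusable
  short <- pen
  short$rows <- 1:3
  short$depth_mm <- short$depth_mm[1:3]
  expect_false(fit_depth_gradient(short, vals[1:3], cfg)$usable)
})

test_that("noiseless monotone profiles give the minimal bootstrap p", {
  spec <- small_spec(snr = 1e9, gain_amp = 0, patch_fraction = 1)
  mask <- make_phantom_mask(spec)
  gt <- plant_frequency_field(mask, spec)
  session <- simulate_session(gt, spec)
  mesh <- extract_surface(mask)
  pct <- homomorphic_normalize(session$data, spec$voxel_size_mm)
  resp <- extract_amplitudes(pct, session$design, mask = session$mask)
  grid <- analysis_grid(mask, spec$voxel_size_mm, 2)
  dm <- compute_depth_map(grid$mask, mesh, grid$voxel_size)
  cfg <- penetration_config(B = 200, seed = 5)
  region <- curvature_and_region(mesh,
                                 restrict = mesh$vertices[, 3] > spec$slab_top_mm + 0.5)
  v <- which(region)[which.max(mesh$vertices[which(region), 3])]
  pen <- build_penetration(mesh, dm, v, cfg)
  fineA <- as.matrix(grid$S %*% resp$A)
  vals <- centroid_frequency(fineA, resp$f_oct)
  fit <- fit_depth_gradient(pen, vals[pen$rows], cfg)
  expect_true(fit$usable)
  expect_gt(fit$g, 0.2)
  p <- bootstrap_slope_p(pen, resp, grid$S, fit, cfg)
  expect_equal(p, 1 / (cfg$B + 1))
})

test_that("gradient maps recover planted patches and are deterministic", {
  # favorable noise level isolates the patch-recovery property from the
  # statistical power question
  spec <- small_spec(snr = 100, patch_fraction = 0.6, patch_scale_mm = 4.5,
                     seed = 3)
  mask <- make_phantom_mask(spec)
  gt <- plant_frequency_field(mask, spec)
  session <- simulate_session(gt, spec)
  mesh <- extract_surface(mask)
  region <- curvature_and_region(mesh,
                                 restrict = mesh$vertices[, 3] > spec$slab_top_mm + 0.5)
  pct <- homomorphic_normalize(session$data, spec$voxel_size_mm)
  pct <- highpass(pct, session$design$run, stim_cycles_per_run = spec$reps_per_run)
  resp <- extract_amplitudes(pct, session$design, mask = session$mask)
  grid <- analysis_grid(mask, spec$voxel_size_mm, 2)
  dm <- compute_depth_map(grid$mask, mesh, grid$voxel_size)
  cfg <- penetration_config(B = 300, seed = 11)
  gr <- map_gradients(mesh, region, dm, grid, resp, cfg)
  expect_equal(nrow(gr), sum(region))
  # realized tonotopic tiling covers about the requested surface fraction
  dom <- gt$cap_domain > 0 & gt$patch_label != 1L
  planted <- mean(gt$patch_label[dom] == 2L)
  expect_equal(planted, spec$patch_fraction, tolerance = 0.15)
  # the significant fraction tracks the fraction of penetrations that
  # sample mostly planted tissue
  rows <- attr(gr, "penetration_rows")
  pts <- as.matrix(dm$voxels[, c("x", "y", "z")])
  lab <- tonodepth:::sample_truth(gt$patch_label, pts, spec$voxel_size_mm)
  dep <- tonodepth:::sample_truth(gt$depth_mm, pts, spec$voxel_size_mm)
  fr_ton <- vapply(rows, function(r) {
    if (!length(r)) return(NA_real_)
    deep <- !is.na(dep[r]) & dep[r] >= spec$rind_thickness_mm
    if (!any(deep)) return(NA_real_)
    mean(lab[r][deep] == 2L, na.rm = TRUE)
  }, numeric(1))
  frac_sig <- mean(gr$p < 0.05, na.rm = TRUE)
  # penetrations sampling mostly planted tissue drive the significance;
  # cylinders straddling patch boundaries blur the correspondence, so the
  # match is coarse while the discrimination is strong
  expect_lt(abs(frac_sig - mean(fr_ton > 0.5, na.rm = TRUE)), 0.2)
  sig <- gr$p < 0.05
  expect_gt(mean(fr_ton[sig], na.rm = TRUE),
            mean(fr_ton[!sig], na.rm = TRUE) + 0.2)
  # deterministic under identical seeds
  gr2 <- map_gradients(mesh, region, dm, grid, resp, cfg)
  expect_identical(gr$g, gr2$g)
  expect_identical(gr$p, gr2$p)
})

test_that("reversed patches are caught by the mirrored test", {
  spec <- small_spec(snr = 100, patch_fraction = 0, seed = 6,
                     reversed_patch_fraction = 1)
  mask <- make_phantom_mask(spec)
  gt <- suppressWarnings(plant_frequency_field(mask, spec))
  session <- simulate_session(gt, spec)
  mesh <- extract_surface(mask)
  region <- curvature_and_region(mesh,
                                 restrict = mesh$vertices[, 3] > spec$slab_top_mm + 0.5)
  pct <- homomorphic_normalize(session$data, spec$voxel_size_mm)
  resp <- extract_amplitudes(pct, session$design, mask = session$mask)
  grid <- analysis_grid(mask, spec$voxel_size_mm, 2)
  dm <- compute_depth_map(grid$mask, mesh, grid$voxel_size)
  cfg <- penetration_config(B = 300, seed = 12)
  fwd <- map_gradients(mesh, region, dm, grid, resp, cfg)
  rev <- map_gradients(mesh, region, dm, grid, resp, cfg, mirror = TRUE)
  expect_lt(mean(fwd$p < 0.05, na.rm = TRUE), 0.2)
  expect_gt(mean(rev$p < 0.05, na.rm = TRUE), 0.6)
  expect_lt(median(fwd$g, na.rm = TRUE), 0)
})

test_that("area summaries are monotone in the threshold", {
  fx <- sphere_fixture()
  n <- nrow(fx$mesh$vertices)
  set.seed(13)
  ids <- sample.int(n, 200)
  p <- runif(200)
  a <- area_summary(fx$mesh, ids, p, thresholds = c(0, 0.05, 0.16, 1.01))
  expect_equal(a$area_mm2[1], 0)
  expect_true(all(diff(a$area_mm2) >= 0))
  expect_equal(a$area_mm2[4], region_area(fx$mesh, ids))
  # NA p values (unusable penetrations) never count
  p[1:50] <- NA
  a2 <- area_summary(fx$mesh, ids, p, thresholds = 1.01)
  expect_equal(a2$area_mm2, region_area(fx$mesh, ids[-(1:50)]))
})

test_that("mean gradient direction uses slope weighting and conventions", {
  # single penetration: its own direction
  md <- mean_gradient_direction(rbind(c(0, 0, -1)), 0.5, 0.01)
  expect_equal(md$n_mean, c(0, 0, -1))
  # 3:1 slope weights on anterior/superior unit vectors
  md2 <- mean_gradient_direction(rbind(c(0, 1, 0), c(0, 0, 1)),
                                 g = c(3, 1), p = c(0.01, 0.01))
  expect_equal(md2$sagittal_angle_deg, atan2(1, 3) * 180 / pi,
               tolerance = 1e-8)
  expect_equal(md2$axial_angle_deg, 0)
  # mirror-symmetric directions average onto the symmetry plane
  md3 <- mean_gradient_direction(rbind(c(0.5, 0.5, -0.707),
                                       c(-0.5, 0.5, -0.707)),
                                 g = c(1, 1), p = c(0.01, 0.01))
  expect_equal(md3$n_mean[1], 0, tolerance = 1e-12)
  expect_equal(md3$axial_angle_deg, 0, tolerance = 1e-9)
  # nothing significant: undefined, reported as such
  md4 <- mean_gradient_direction(rbind(c(0, 1, 0)), 1, 0.5)
  expect_true(is.na(md4$sagittal_angle_deg))
  expect_equal(md4$n_used, 0L)
})

test_that("spatial blurring preserves constants and the overlay mapping", {
  fx <- small_session_fixture()
  blurred <- blur_control(fx$session, fwhm_mm = 2)
  expect_equal(dim(blurred$data), dim(fx$session$data))
  # constant volumes are unchanged by the renormalized kernel
  const <- fx$session
  const$data[, , , 1] <- 7
  bc <- blur_control(const, 2)
  expect_equal(bc$data[, , , 1], const$data[, , , 1], tolerance = 1e-9)
  expect_error(blur_control(fx$session, fwhm_mm = 1), "exceed")
  # opacity convention
  expect_equal(alpha_from_p(0.01), 1)
  expect_equal(alpha_from_p(0.05), 1)
  expect_equal(alpha_from_p(0.5), 0)
  expect_equal(alpha_from_p(0.9), 0)
  expect_equal(alpha_from_p(sqrt(0.05 * 0.5)), 0.5)
})

test_that("2-mm blurring preserves the significant-patch layout", {
  res <- default_pipeline_fixture()
  blurred <- blur_control(res$session, fwhm_mm = 2)
  spec <- res$config$spec
  series <- homomorphic_normalize(blurred$data, spec$voxel_size_mm)
  series <- highpass(series, blurred$design$run,
                     stim_cycles_per_run = spec$reps_per_run)
  resp_b <- extract_amplitudes(series, blurred$design, mask = res$session$mask)
  gr_b <- map_gradients(res$mesh, res$region, res$depthmap, res$grid,
                        resp_b, res$config$pen)
  sig0 <- !is.na(res$gradients$p) & res$gradients$p < 0.05
  sigb <- !is.na(gr_b$p) & gr_b$p < 0.05
  jaccard <- sum(sig0 & sigb) / sum(sig0 | sigb)
  expect_gt(jaccard, 0.5)
})

test_that("the mean gradient direction matches the analytic cap normal", {
  res <- default_pipeline_fixture()
  md <- res$summary$direction
  expect_gt(md$n_used, 20)
  expect_equal(sqrt(sum(md$n_mean^2)), 1, tolerance = 1e-9)
  # both caps are symmetric about the mid-sagittal plane, so the
  # slope-weighted average of inward cap normals points straight down
  angle <- acos(sum(md$n_mean * c(0, 0, -1))) * 180 / pi
  expect_lt(angle, 20)
})
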