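test_that("stimulus frequencies form the log-spaced progression", {
  f <- stimulus_frequencies(0.25, 8, 5)
  expect_equal(f[1], 0.25)
  expect_equal(f[5], 8)
  expect_equal(f[2], 0.59, tolerance = 0.01)
  expect_equal(f[3], 1.41, tolerance = 0.01)
  expect_equal(diff(log2(f)), rep(1.25, 4))
  expect_error(stimulus_frequencies(-1, 8, 5), "positive")
  expect_error(stimulus_frequencies(8, 0.25, 5), "below")
  expect_error(stimulus_frequencies(0.25, 8, 1), "two")
})

test_that("session design carries the sparse-sampling structure", {
  spec <- phantom_spec()
  design <- session_design(spec)
  expect_equal(attr(design, "cycle_period_s"),
               6 * attr(design, "presentation_period_s"))
  expect_equal(attr(design, "cycle_period_s"), 72)
  counts <- table(design$condition)
  expect_true(all(counts == 55))
  f <- attr(design, "center_freqs_khz")
  expect_equal(log2(f[5] / f[1]), 5)   # full span, octaves
  # monotonic cycle of the five sounds then quiet
  expect_equal(design$condition[1:6], c(1:5, 0))
})

test_that("phantom mask matches analytic slab + half-ellipsoid volume", {
  spec <- phantom_spec()
  mask <- make_phantom_mask(spec)
  vol <- sum(mask) * spec$voxel_size_mm^3
  expect_equal(vol, tonodepth:::phantom_analytic_volume(spec),
               tolerance = 0.01)
  # zero-size colliculi leave the slab only
  spec0 <- phantom_spec(colliculus_radii_mm = c(0, 0, 0))
  mask0 <- make_phantom_mask(spec0)
  expect_equal(sum(mask0) * spec0$voxel_size_mm^3,
               prod(spec0$slab_hi - spec0$slab_lo), tolerance = 0.001)
  # two disjoint protrusions above the slab
  pts <- voxel_centers(dim(mask), spec$voxel_size_mm)
  above <- which(mask > 0)[pts[mask > 0, 3] > spec$slab_top_mm]
  xs <- pts[above, 1]
  mid <- mean(spec$cap_centers[, 1])
  expect_gt(sum(xs < mid), 10)
  expect_gt(sum(xs > mid), 10)
  gap <- range(xs[xs < mid])[2] < min(xs[xs > mid]) - spec$voxel_size_mm
  expect_true(gap)
  # oversized radii are rejected with the axis named
  expect_error(phantom_spec(colliculus_radii_mm = c(20, 4, 4)), "x axis")
})

test_that("planted field obeys the linear depth law exactly", {
  spec <- phantom_spec(patch_fraction = 0.5, reversed_patch_fraction = 0.3)
  mask <- make_phantom_mask(spec)
  gt <- plant_frequency_field(mask, spec)
  ton <- which(gt$patch_label == 2L)
  expect_gt(length(ton), 20)
  expect_equal(gt$preferred_freq_oct[ton],
               spec$base_freq_oct + spec$gradient_oct_per_mm *
                 (gt$depth_mm[ton] - spec$rind_thickness_mm))
  rev <- which(gt$patch_label == 3L)
  expect_gt(length(rev), 10)
  expect_equal(gt$preferred_freq_oct[rev],
               spec$base_freq_oct - spec$gradient_oct_per_mm *
                 (gt$depth_mm[rev] - spec$rind_thickness_mm))
  # rind voxels are shallower than the rind thickness and carry no field
  rind <- which(gt$patch_label == 1L)
  expect_true(all(gt$depth_mm[rind] < spec$rind_thickness_mm))
  expect_true(all(is.na(gt$preferred_freq_oct[rind])))
  # zero gradient leaves the field constant below the rind
  spec0 <- phantom_spec(gradient_oct_per_mm = 0)
  gt0 <- plant_frequency_field(make_phantom_mask(spec0), spec0)
  ton0 <- !is.na(gt0$preferred_freq_oct)
  expect_true(all(gt0$preferred_freq_oct[ton0] == spec0$base_freq_oct))
})

test_that("slab-face depth equals the distance to the nearest face", {
  spec <- phantom_spec()
  mask <- make_phantom_mask(spec)
  gt <- plant_frequency_field(mask, spec)
  pts <- voxel_centers(dim(mask), spec$voxel_size_mm)
  # voxels far from the caps: depth is the plain box-face distance
  far <- which(mask > 0 &
                 abs(pts[, 1] - spec$cap_centers[1, 1]) > 7 &
                 abs(pts[, 1] - spec$cap_centers[2, 1]) > 7)
  expected <- pmin(pts[far, 3] - spec$slab_lo[3],
                   spec$slab_hi[3] - pts[far, 3],
                   pts[far, 1] - spec$slab_lo[1],
                   spec$slab_hi[1] - pts[far, 1],
                   pts[far, 2] - spec$slab_lo[2],
                   spec$slab_hi[2] - pts[far, 2])
  expect_equal(gt$depth_mm[far], expected)
})

test_that("noise-free sessions reproduce the planted tuning", {
  spec <- small_spec(snr = 1e9, gain_amp = 0, patch_fraction = 1)
  mask <- make_phantom_mask(spec)
  gt <- plant_frequency_field(mask, spec)
  session <- simulate_session(gt, spec)
  design <- session$design
  ton <- which(gt$patch_label == 2L)
  v <- ton[which.max(gt$depth_mm[ton])]
  m <- matrix(session$data, ncol = nrow(design))
  amps <- vapply(1:5, function(ci) mean(m[v, design$condition == ci]),
                 numeric(1))
  f_oct <- session$f_oct
  expect_equal(which.max(amps),
               which.min(abs(f_oct - gt$preferred_freq_oct[v])))
  # tuning is symmetric in log frequency about the preferred value
  expect_equal(tuning_curve(gt$preferred_freq_oct[v] + 0.8,
                            gt$preferred_freq_oct[v], 1),
               tuning_curve(gt$preferred_freq_oct[v] - 0.8,
                            gt$preferred_freq_oct[v], 1))
  # quiet equals baseline exactly when noise and gain are off
  quiet <- session$data[, , , design$condition == 0][, , , 1]
  expect_equal(quiet[mask > 0], rep(spec$baseline, sum(mask)),
               tolerance = 1e-6)
})

test_that("simulated thermal noise matches the configured image SNR", {
  fx <- small_session_fixture()
  session <- fx$session
  design <- session$design
  quiet <- which(design$condition == 0)
  m <- matrix(session$data, ncol = nrow(design))[fx$mask > 0, quiet]
  tsnr <- rowMeans(m) / apply(m, 1, sd)
  expect_equal(mean(tsnr), fx$spec$snr, tolerance = 0.1 * fx$spec$snr)
  # mean over presentations tightens as sqrt(n)
  sem <- apply(m, 1, sd) / sqrt(length(quiet))
  expect_equal(mean(sem) * sqrt(length(quiet)) * fx$spec$snr /
                 mean(rowMeans(m)), 1, tolerance = 0.15)
})

test_that("sessions are reproducible from the seed", {
  spec <- small_spec(seed = 42)
  mask <- make_phantom_mask(spec)
  gt1 <- plant_frequency_field(mask, spec)
  gt2 <- plant_frequency_field(mask, spec)
  expect_identical(gt1$patch_label, gt2$patch_label)
  s1 <- simulate_session(gt1, spec)
  s2 <- simulate_session(gt2, spec)
  expect_identical(s1$data, s2$data)
  s3 <- simulate_session(gt1, spec, seed = 99)
  expect_false(identical(s1$data, s3$data))
})

test_that("phantom input validation rejects bad parameters", {
  expect_error(phantom_spec(rind_thickness_mm = 2), "rind")
  expect_error(phantom_spec(snr = -1), "snr")
  expect_error(phantom_spec(patch_fraction = 1.2), "fraction")
  fx <- small_session_fixture()
  bad <- fx$spec
  bad$snr <- 0
  expect_error(simulate_session(fx$truth, bad), "snr")
  expect_warning(plant_frequency_field(fx$mask,
                                       small_spec(patch_fraction = 0)),
                 "patch_fraction")
})

test_that("undershoot carry-over subtracts part of the preceding response", {
  spec <- small_spec(snr = 1e9, gain_amp = 0, patch_fraction = 1,
                     undershoot_frac = 0.3)
  mask <- make_phantom_mask(spec)
  gt <- plant_frequency_field(mask, spec)
  session <- simulate_session(gt, spec)
  design <- session$design
  v <- which(gt$patch_label == 2L)[1]
  m <- matrix(session$data, ncol = nrow(design))
  f_oct <- session$f_oct
  Tcur <- tuning_curve(f_oct, gt$preferred_freq_oct[v], spec$tuning_width_oct)
  # condition 2 always follows condition 1 within a cycle
  i2 <- which(design$condition == 2 & design$presentation > 1)
  expected <- spec$baseline *
    (1 + spec$response_amp_pct / 100 * (Tcur[2] - 0.3 * Tcur[1]))
  expect_equal(mean(m[v, i2]), expected, tolerance = 1e-6)
  # the first presentation of a run has no predecessor
  spec0 <- small_spec(snr = 1e9, gain_amp = 0, patch_fraction = 1)
  s0 <- simulate_session(gt, spec0)
  m0 <- matrix(s0$data, ncol = nrow(design))
  i1 <- which(design$condition == 1 & design$presentation == 1)
  expect_equal(mean(m[v, i1]), mean(m0[v, i1]), tolerance = 1e-6)
})
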