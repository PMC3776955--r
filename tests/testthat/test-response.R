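make_series <- function(nvox_dim = c(6, 6, 4), nt = 60,
                        baseline = 1000, fun = function(t) 0) {
  d <- c(nvox_dim, nt)
  t <- seq_len(nt)
  mod <- vapply(t, fun, numeric(1))
  array(rep(baseline, prod(nvox_dim)), d) *
    (1 + rep(mod, each = prod(nvox_dim)))
}

test_that("homomorphic normalization removes multiplicative gain", {
  s <- make_series()
  out <- homomorphic_normalize(s, voxel_size = 1)
  expect_equal(as.vector(out), rep(100, length(out)), tolerance = 1e-8)
  # a spatially uniform gain change leaves the output untouched
  s2 <- s * 2
  out2 <- homomorphic_normalize(s2, voxel_size = 1)
  expect_equal(out2[, , , ], out[, , , ], tolerance = 1e-8)
  # a smooth spatial gain field is divided out
  d <- dim(s)
  gain <- array(1 + 0.3 * sin(seq(0, pi, length.out = d[1])), d[1:3])
  s3 <- s * as.vector(gain)
  out3 <- homomorphic_normalize(s3, voxel_size = 1, fwhm_mm = 3)
  expect_equal(mean(out3), 100, tolerance = 0.03)
  # 1% sinusoidal modulation survives with unit amplitude
  s4 <- make_series(nt = 60, fun = function(t) 0.01 * sin(2 * pi * t / 12))
  out4 <- homomorphic_normalize(s4, voxel_size = 1)
  v <- out4[3, 3, 2, ]
  amp <- 2 * abs(fft(v - mean(v)))[6] / length(v)   # 5 cycles over 60
  expect_equal(amp, 1, tolerance = 0.05)
})

test_that("high-pass filtering removes drifts but keeps the stimulus band", {
  nt <- 30
  runs <- rep(1, nt)
  drift <- make_series(nt = nt, fun = function(t) 0.05 * t / nt)
  pct <- homomorphic_normalize(drift, voxel_size = 1)
  hp <- highpass(pct, runs, cutoff_cycles_per_run = 2)
  v <- hp[3, 3, 2, ]
  expect_lt(sd(v), 0.05 * sd(pct[3, 3, 2, ]))
  expect_equal(mean(v), 100, tolerance = 1e-6)
  # 5-cycle stimulus component preserved to at least 95%
  stim <- make_series(nt = nt, fun = function(t) 0.01 * sin(2 * pi * 5 * t / nt))
  hp2 <- highpass(homomorphic_normalize(stim, voxel_size = 1), runs, 2)
  v2 <- hp2[3, 3, 2, ] - 100
  ref <- 100 * (stim[3, 3, 2, ] / 1000 - 1)
  expect_gt(sum(v2 * ref) / sum(ref^2), 0.95)
  expect_error(highpass(pct, runs, cutoff_cycles_per_run = 5), "stimulus")
})

test_that("amplitude extraction references each run's quiet periods", {
  spec <- small_spec(snr = 1e9, gain_amp = 0, patch_fraction = 1)
  mask <- make_phantom_mask(spec)
  gt <- plant_frequency_field(mask, spec)
  session <- simulate_session(gt, spec)
  pct <- homomorphic_normalize(session$data, spec$voxel_size_mm)
  resp <- extract_amplitudes(pct, session$design, mask = session$mask)
  ton <- which(gt$patch_label[resp$voxel] == 2L)
  v <- ton[1]
  planted <- spec$response_amp_pct *
    tuning_curve(resp$f_oct, gt$preferred_freq_oct[resp$voxel[v]],
                 spec$tuning_width_oct)
  # normalization references the temporal mean, which includes the evoked
  # response itself; this rescales amplitudes by a known factor
  scale <- 1 + spec$response_amp_pct / 100 * sum(planted / spec$response_amp_pct) / 6
  expect_equal(unname(resp$A[v, ]), planted / scale, tolerance = 5e-3)
  # constant data give identically zero amplitudes
  flat <- array(500, c(4, 4, 3, nrow(session$design)))
  resp0 <- extract_amplitudes(flat, session$design)
  expect_true(all(abs(resp0$A) < 1e-12))
  # missing quiet presentations are an error
  des <- session$design
  des$condition[des$condition == 0] <- 5
  expect_error(extract_amplitudes(pct, des), "quiet")
})

test_that("centroid frequency matches hand-computed moments", {
  f <- log2(stimulus_frequencies())      # -2 .. 3 octaves re 1 kHz
  expect_equal(centroid_frequency(c(0, 0, 1, 0, 0), f), f[3])
  expect_equal(centroid_frequency(c(0.2, 0.5, 1, 0.5, 0.2), f), f[3])
  # ramp weights: min-subtracted weighted index mean = 3 (0-based)
  expect_equal(centroid_frequency(c(0, 1, 2, 3, 4), f),
               log2(0.25) + 3 * 1.25)
  expect_equal(2^centroid_frequency(c(0, 1, 2, 3, 4), f), 3.36,
               tolerance = 0.01)
  # invariance to additive offsets and positive scaling
  A <- c(0.1, 0.9, 0.4, 0.2, 0.05)
  expect_equal(centroid_frequency(A + 7, f), centroid_frequency(A, f))
  expect_equal(centroid_frequency(A * 3.2, f), centroid_frequency(A, f))
  # bounded by the stimulus band
  expect_true(centroid_frequency(A, f) >= f[1] &&
                centroid_frequency(A, f) <= f[5])
  # constant profiles are undefined
  expect_true(is.na(centroid_frequency(rep(2, 5), f)))
  # matrix form agrees with row-wise evaluation
  M <- rbind(A, c(0, 0, 1, 0, 0))
  expect_equal(centroid_frequency(M, f),
               c(centroid_frequency(A, f), f[3]))
})

test_that("tuning width is the root second central moment", {
  f <- log2(stimulus_frequencies())
  expect_equal(tuning_width(c(0, 0, 1, 0, 0), f), 0)
  # two equal masses at the band edges: half-span of 5 octaves
  expect_equal(tuning_width(c(1, 0, 0, 0, 1), f), 2.5)
  # broad responses are wider than any single peak
  broad <- tuning_width(c(0.8, 1, 0.9, 1, 0.8), f)
  for (k in 1:5) {
    peak <- rep(0, 5); peak[k] <- 1
    expect_gt(broad, tuning_width(peak, f))
  }
  expect_true(is.na(tuning_width(rep(1, 5), f)))
})

test_that("bootstrap means have the classical sampling spread", {
  cfg <- bootstrap_config(B = 1000, seed = 7)
  expect_error(bootstrap_config(B = 50), "100")
  expect_error(bootstrap_distribution(1:3, cfg), "5 samples")
  # constant data: zero-width interval
  bd <- bootstrap_distribution(rep(3.3, 20), cfg)
  expect_equal(diff(bd$ci), 0)
  # Gaussian n = 55: 68% interval half-width ~ sigma/sqrt(n)
  set.seed(11)
  x <- rnorm(55, 10, 2)
  bd2 <- bootstrap_distribution(x, cfg)
  expect_equal(unname(diff(bd2$ci) / 2), sd(x) / sqrt(55), tolerance = 0.2)
  # determinism under the seed
  bd3 <- bootstrap_distribution(x, cfg)
  expect_identical(bd2$means, bd3$means)
})

test_that("sound-versus-quiet p values behave as a one-sided test", {
  cfg <- bootstrap_config(B = 500, seed = 3)
  set.seed(5)
  quiet <- rnorm(55)
  responsive <- list(sound = rnorm(275, 1), quiet = quiet)
  expect_lt(sound_vs_quiet_p(responsive, cfg), 0.05)
  dead <- list(sound = quiet[1:55] - 1000, quiet = quiet)
  expect_equal(sound_vs_quiet_p(dead, cfg), 1)
  # clamp floor
  strong <- list(sound = rnorm(275, 50), quiet = quiet)
  expect_equal(sound_vs_quiet_p(strong, cfg), 1 / (cfg$B + 1))
  # null voxels: p roughly uniform
  ps <- vapply(1:200, function(i) {
    sound_vs_quiet_p(list(sound = rnorm(55), quiet = rnorm(55)),
                     bootstrap_config(B = 200, seed = i))
  }, numeric(1))
  expect_equal(mean(ps), 0.5, tolerance = 0.1)
})

test_that("centroid intervals are zero noise-free and shrink with n", {
  f_oct <- log2(stimulus_frequencies())
  mk_resp <- function(n, sd) {
    A <- tuning_curve(f_oct, 0.5, 1)
    samples <- array(NA_real_, c(1, 6, n))
    set.seed(21)
    samples[1, 1, ] <- rnorm(n, 0, sd)
    for (ci in 1:5) samples[1, ci + 1, ] <- rnorm(n, A[ci], sd)
    structure(list(A = matrix(A, 1), samples = samples, f_oct = f_oct,
                   voxel = 1L, dim = c(1, 1, 1)),
              class = "freq_response")
  }
  cfg <- bootstrap_config(B = 400, seed = 2)
  expect_equal(centroid_ci(mk_resp(20, 0), cfg)$width, 0)
  w14 <- centroid_ci(mk_resp(14, 0.5), cfg)$width
  w55 <- centroid_ci(mk_resp(55, 0.5), cfg)$width
  expect_lt(w55, w14)
})

test_that("frequency maps assemble the per-voxel summaries", {
  fx <- small_session_fixture()
  pct <- homomorphic_normalize(fx$session$data, fx$spec$voxel_size_mm)
  resp <- extract_amplitudes(pct, fx$session$design, mask = fx$session$mask)
  maps <- frequency_maps(resp, bootstrap_config(B = 200, seed = 1))
  tab <- maps$table
  expect_equal(nrow(tab), sum(fx$mask))
  ok <- !is.na(tab$f_cent)
  expect_true(all(tab$f_cent[ok] >= resp$f_oct[1] &
                    tab$f_cent[ok] <= resp$f_oct[5]))
  expect_true(all(tab$f_tune[ok] >= 0))
  expect_true(all(tab$p_sound > 0 & tab$p_sound <= 1))
  expect_equal(tab$hl_diff, resp$A[, 5] - resp$A[, 1])
  vol <- maps_as_volume(maps, "f_cent")
  expect_equal(vol[tab$voxel], tab$f_cent)
  # planted tissue responds more credibly than chance against quiet
  lab <- fx$truth$patch_label[resp$voxel]
  expect_lt(median(tab$p_sound[lab == 2L]), 0.25)
})
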