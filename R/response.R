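#' Bootstrap configuration
#'
#' @param B number of with-replacement resamples.
#' @param seed RNG seed for resampling.
#' @param ci_level central confidence level for percentile intervals.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 1000, seed = 1, ci_level = 0.68) {
  if (B < 100) stop("B must be at least 100")
  structure(list(B = B, seed = seed, ci_level = ci_level),
            class = "bootstrap_config")
}

#' Homomorphic intensity normalization
#'
#' Divides each voxel's series by a spatially smoothed temporal-mean
#' volume and rescales to percent signal, removing smooth multiplicative
#' intensity variations (receiver-coil gain). Smoothing is restricted to
#' the tissue support (normalized convolution), so tissue near the
#' boundary is not dragged toward the empty background. Voxels with
#' near-zero temporal mean are masked out (NA).
#'
#' @param series 4-D array (grid x time/presentations).
#' @param voxel_size voxel edge length, mm.
#' @param fwhm_mm smoothing kernel FWHM for the gain estimate, mm.
#' @param support_frac voxels with temporal mean below this fraction of
#'   the volume maximum are treated as background.
#' @return 4-D array in percent units (tissue mean about 100), background
#'   NA; the smoothed gain volume is attached as attribute `gain`.
#' @export
homomorphic_normalize <- function(series, voxel_size = 1, fwhm_mm = 6,
                                  support_frac = 0.2) {
  d <- dim(series)
  stopifnot(length(d) == 4, d[4] >= 2)
  mvol <- rowMeans(matrix(series, prod(d[1:3]), d[4]))
  mvol <- array(mvol, d[1:3])
  w <- (mvol > support_frac * max(mvol)) * 1
  num <- gaussian_blur(mvol * w, fwhm_mm, voxel_size)
  den <- gaussian_blur(w, fwhm_mm, voxel_size)
  gain <- num / pmax(den, 1e-12)
  bad <- w == 0 | gain <= 0
  gain[bad] <- NA_real_
  out <- 100 * series / as.vector(gain)
  attr(out, "gain") <- gain
  out
}

#' High-pass filtering of presentation series
#'
#' Removes slow intensity drifts run by run: each voxel's within-run
#' series is projected off the DCT components slower than
#' `cutoff_cycles_per_run`, and the mean is re-added as 100 (percent
#' convention). The stimulus component (one cycle per six presentations,
#' i.e. `reps_per_run` cycles per run) must lie above the cutoff.
#'
#' @param series 4-D percent series (grid x presentations).
#' @param runs run index per presentation.
#' @param cutoff_cycles_per_run components slower than this are removed.
#' @param stim_cycles_per_run stimulus frequency in cycles/run, used to
#'   refuse destructive cutoffs.
#' @return Filtered 4-D array, per-voxel run mean re-set to 100.
#' @export
highpass <- function(series, runs, cutoff_cycles_per_run = 2,
                     stim_cycles_per_run = 5) {
  d <- dim(series)
  stopifnot(length(d) == 4, length(runs) == d[4])
  if (cutoff_cycles_per_run >= stim_cycles_per_run)
    stop("cutoff at or above the stimulus frequency would destroy the signal")
  out <- array(NA_real_, d)
  m <- matrix(series, prod(d[1:3]), d[4])
  for (r in unique(runs)) {
    cols <- which(runs == r)
    n <- length(cols)
    B <- dct_basis(n)
    # DCT component k spans k/2 cycles per run; drop 0 < k/2 < cutoff.
    drop <- which((0:(n - 1)) / 2 < cutoff_cycles_per_run &
                    (0:(n - 1)) > 0)
    X <- m[, cols, drop = FALSE]
    co <- X %*% B
    co[, drop] <- 0
    co[, 1] <- 100 * sqrt(n) # DC convention: mean 100
    m[, cols] <- co %*% t(B)
  }
  array(m, d)
}

#' Per-voxel response amplitudes
#'
#' Converts a presentation series plus design into per-voxel frequency
#' responses: each presentation's amplitude is referenced to its run's
#' mean quiet amplitude, and per-condition amplitudes `A(f_i)` are means
#' over the ~55 presentations of each sound.
#'
#' @param series 4-D percent series (grid x presentations), e.g. the
#'   output of [homomorphic_normalize()]/[highpass()], or
#'   `session$data` for raw units (amplitudes are then in raw units).
#' @param design the [session_design()] table matching the series.
#' @param mask optional logical array restricting the voxels.
#' @return An object of class `freq_response`: `A` (voxel x 5 condition
#'   amplitudes), `samples` (voxel x 6 x reps array of quiet-referenced
#'   per-presentation amplitudes; condition 1 of the second dimension is
#'   quiet), `f_oct` (condition frequencies, octaves re 1 kHz), `voxel`
#'   (linear indices), `dim`.
#' @export
extract_amplitudes <- function(series, design, mask = NULL) {
  d <- dim(series)
  stopifnot(length(d) == 4, nrow(design) == d[4])
  if (!any(design$condition == 0)) stop("design has no quiet presentations")
  vox <- if (is.null(mask)) seq_len(prod(d[1:3])) else which(mask > 0)
  m <- matrix(series, prod(d[1:3]), d[4])[vox, , drop = FALSE]
  freqs <- attr(design, "center_freqs_khz")
  if (is.null(freqs))
    freqs <- sort(unique(design$center_freq_khz[design$condition > 0]))
  # Reference every presentation to its run's mean quiet amplitude.
  for (r in unique(design$run)) {
    rc <- design$run == r
    qm <- rowMeans(m[, rc & design$condition == 0, drop = FALSE])
    m[, rc] <- m[, rc] - qm
  }
  reps <- min(table(design$condition))
  samples <- array(NA_real_, c(length(vox), 6, reps))
  for (ci in 0:5) {
    cols <- which(design$condition == ci)[seq_len(reps)]
    samples[, ci + 1, ] <- m[, cols]
  }
  A <- apply(samples[, 2:6, , drop = FALSE], c(1, 2), mean)
  structure(list(A = A, samples = samples, f_oct = log2(freqs),
                 voxel = vox, dim = d[1:3]),
            class = "freq_response")
}

# Min-subtracted positive weights; rows that are entirely constant are
# flagged NA (the subtraction zeroes all weights).
minsub_weights <- function(A) {
  A <- rbind(A)
  w <- A - apply(A, 1, min)
  w[rowSums(w) <= 0, ] <- NA_real_
  w
}

#' Centroid (first-moment) preferred frequency
#'
#' Amplitude-weighted mean stimulus frequency, computed in log2-frequency
#' (octaves re 1 kHz) after making the amplitudes positive definite by
#' subtracting the row minimum. Constant response profiles are undefined
#' and return NA.
#'
#' @param A amplitude vector (5) or matrix (voxels x 5).
#' @param f_oct condition frequencies, octaves re 1 kHz.
#' @return Centroid frequency in octaves re 1 kHz, within the stimulus
#'   band.
#' @export
centroid_frequency <- function(A, f_oct) {
  w <- minsub_weights(A)
  out <- unname(as.vector(w %*% f_oct) / rowSums(w))
  if (is.vector(A)) out[1] else out
}

#' Tuning width (second-moment spread)
#'
#' Square root of the min-subtracted second central moment of the
#' amplitude response about the centroid, in octaves.
#'
#' @inheritParams centroid_frequency
#' @return Tuning width, octaves (>= 0); NA for constant profiles.
#' @export
tuning_width <- function(A, f_oct) {
  w <- minsub_weights(A)
  fc <- as.vector(w %*% f_oct) / rowSums(w)
  m2 <- rowSums(w * (matrix(f_oct, nrow(w), 5, byrow = TRUE) - fc)^2) /
    rowSums(w)
  out <- unname(sqrt(pmax(m2, 0)))
  if (is.vector(A)) out[1] else out
}

# B x n matrix of bootstrap resampling weights (counts / n); each row is
# one with-replacement resample of n items.
bootstrap_weights <- function(n, B) {
  t(rmultinom(B, n, rep(1, n))) / n
}

#' Bootstrap distribution of a sample mean
#'
#' Resamples the observations with replacement `B` times, averaging each
#' resample; the central `ci_level` percentile interval of the resampled
#' means is the confidence interval.
#'
#' @param samples numeric vector of observations (n >= 5).
#' @param cfg a [bootstrap_config()].
#' @return List with `means` (length B), `ci` (lower, upper) and
#'   `level`.
#' @export
bootstrap_distribution <- function(samples, cfg = bootstrap_config()) {
  n <- length(samples)
  if (n < 5) stop("need at least 5 samples to bootstrap")
  means <- with_seed(cfg$seed,
                     as.vector(bootstrap_weights(n, cfg$B) %*% samples))
  a <- (1 - cfg$ci_level) / 2
  list(means = means,
       ci = unname(quantile(means, c(a, 1 - a), type = 7)),
       level = cfg$ci_level)
}

#' Bootstrap p value for sound versus quiet
#'
#' One-sided bootstrap test that the mean response over all sound
#' presentations exceeds the mean over quiet periods: the p value is the
#' fraction of resampled (mean sound - mean quiet) differences at or
#' below zero, clamped to at least `1/(B+1)`.
#'
#' @param resp a [extract_amplitudes()] object, or a list with elements
#'   `sound` and `quiet` (sample vectors) for a single voxel.
#' @param cfg a [bootstrap_config()].
#' @return p value(s) in (0, 1]; one per voxel for a `freq_response`.
#' @export
sound_vs_quiet_p <- function(resp, cfg = bootstrap_config()) {
  if (inherits(resp, "freq_response")) {
    nv <- nrow(resp$A)
    reps <- dim(resp$samples)[3]
    Xs <- matrix(aperm(resp$samples[, 2:6, , drop = FALSE], c(1, 3, 2)),
                 nv, 5 * reps)
    Xq <- matrix(resp$samples[, 1, ], nv, reps)
    with_seed(cfg$seed, {
      Ws <- bootstrap_weights(5 * reps, cfg$B)
      Wq <- bootstrap_weights(reps, cfg$B)
      diff <- Ws %*% t(Xs) - Wq %*% t(Xq)   # B x nv
      pmax(colMeans(diff <= 0), 1 / (cfg$B + 1))
    })
  } else {
    stopifnot(is.list(resp), !is.null(resp$sound), !is.null(resp$quiet))
    if (length(resp$sound) < 5 || length(resp$quiet) < 5)
      stop("need at least 5 samples to bootstrap")
    with_seed(cfg$seed, {
      Ws <- bootstrap_weights(length(resp$sound), cfg$B)
      Wq <- bootstrap_weights(length(resp$quiet), cfg$B)
      diff <- as.vector(Ws %*% resp$sound) - as.vector(Wq %*% resp$quiet)
      max(mean(diff <= 0), 1 / (cfg$B + 1))
    })
  }
}

# Per-condition bootstrap mean amplitudes for every voxel: resamples the
# presentations of each sound condition (shared resampling across voxels,
# which preserves spatial correlation) and returns a B x nvox x 5 array of
# quiet-referenced amplitude means.
bootstrap_condition_means <- function(resp, cfg) {
  nv <- nrow(resp$A)
  reps <- dim(resp$samples)[3]
  out <- array(NA_real_, c(cfg$B, nv, 5))
  with_seed(cfg$seed, {
    for (ci in 1:5) {
      W <- bootstrap_weights(reps, cfg$B)
      out[, , ci] <- W %*% t(matrix(resp$samples[, ci + 1, ], nv, reps))
    }
  })
  out
}

#' Bootstrap confidence interval of the centroid frequency
#'
#' Recomputes the centroid inside every bootstrap resample (the min
#' subtraction is applied per resample) and returns the percentile
#' interval per voxel.
#'
#' @param resp a [extract_amplitudes()] object.
#' @param cfg a [bootstrap_config()].
#' @return Data frame with `lower`, `upper` and `width` (octaves) per
#'   voxel.
#' @export
centroid_ci <- function(resp, cfg = bootstrap_config()) {
  bm <- bootstrap_condition_means(resp, cfg)
  nv <- dim(bm)[2]
  cent <- matrix(NA_real_, cfg$B, nv)
  for (b in seq_len(cfg$B)) {
    cent[b, ] <- centroid_frequency(matrix(bm[b, , ], nv, 5), resp$f_oct)
  }
  a <- (1 - cfg$ci_level) / 2
  qs <- apply(cent, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE,
              type = 7)
  data.frame(lower = qs[1, ], upper = qs[2, ], width = qs[2, ] - qs[1, ])
}

#' Per-voxel frequency maps
#'
#' Assembles the standard per-voxel summaries: centroid frequency, tuning
#' width, high-minus-low amplitude difference, sound-versus-quiet
#' bootstrap p, and (optionally) the centroid confidence interval.
#'
#' @param resp a [extract_amplitudes()] object.
#' @param cfg a [bootstrap_config()].
#' @param ci compute the per-voxel centroid interval (the costliest map).
#' @return An object of class `frequency_maps`: data frame `table` (one
#'   row per voxel) plus `f_oct`, `dim`, `voxel`. Use [maps_as_volume()]
#'   to reshape a column into a grid volume.
#' @export
frequency_maps <- function(resp, cfg = bootstrap_config(), ci = FALSE) {
  tab <- data.frame(voxel = resp$voxel,
                    f_cent = centroid_frequency(resp$A, resp$f_oct),
                    f_tune = tuning_width(resp$A, resp$f_oct),
                    hl_diff = resp$A[, 5] - resp$A[, 1],
                    p_sound = sound_vs_quiet_p(resp, cfg))
  if (ci) {
    cw <- centroid_ci(resp, cfg)
    tab$ci_lower <- cw$lower
    tab$ci_upper <- cw$upper
    tab$ci_width <- cw$width
  }
  structure(list(table = tab, f_oct = resp$f_oct, dim = resp$dim,
                 voxel = resp$voxel),
            class = "frequency_maps")
}

#' Reshape a per-voxel map column into a grid volume
#'
#' @param maps a [frequency_maps()] object.
#' @param column column of `maps$table` to reshape.
#' @return 3-D array (NA outside the mapped voxels).
#' @export
maps_as_volume <- function(maps, column = "f_cent") {
  vol <- array(NA_real_, maps$dim)
  vol[maps$table$voxel] <- maps$table[[column]]
  vol
}
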