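#!/usr/bin/env Rscript
# Stage 6: spatial-smoothing control analysis.
#
# Blurs every presentation volume with a 2-mm FWHM Gaussian kernel and
# repeats the identical depth analysis: if the patchy layout of
# significant gradients were thermal noise, it would not survive the
# blur. Also measures the thermal-SNR gain between 1.2-mm and 2-mm
# effective resolutions on white noise.

suppressPackageStartupMessages(library(tonodepth))
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

res <- run_pipeline(pipeline_config(seed = 1))
blurred <- blur_control(res$session, fwhm_mm = 2)
spec <- res$config$spec
series <- homomorphic_normalize(blurred$data, spec$voxel_size_mm)
series <- highpass(series, blurred$design$run,
                   stim_cycles_per_run = spec$reps_per_run)
resp_b <- extract_amplitudes(series, blurred$design,
                             mask = res$session$mask)
gr_b <- map_gradients(res$mesh, res$region, res$depthmap, res$grid,
                      resp_b, res$config$pen)

sig0 <- !is.na(res$gradients$p) & res$gradients$p < 0.05
sigb <- !is.na(gr_b$p) & gr_b$p < 0.05
jac <- sum(sig0 & sigb) / sum(sig0 | sigb)
cat("significant vertices: original", sum(sig0), "| blurred", sum(sigb),
    "| Jaccard overlap", round(jac, 2), "\n")
cat("mean slope, significant: original",
    round(mean(res$gradients$g[sig0]), 2), "| blurred",
    round(mean(gr_b$g[sigb]), 2), "oct/mm",
    "(blurring attenuates gradient magnitude)\n")
gainf <- blur_snr_improvement(1.2, 2, n = 64, spacing_mm = 0.4, seed = 1)
cat("thermal-SNR gain, 1.2 mm -> 2 mm resolution:", round(gainf, 2),
    "(voxel-volume heuristic:", round((2 / 1.2)^1.5, 2), ")\n")
write.csv(data.frame(vertex = gr_b$vertex, g_blur = gr_b$g,
                     p_blur = gr_b$p),
          file.path(out, "vertex_gradients_blurred.csv"),
          row.names = FALSE)
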