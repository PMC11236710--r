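#!/usr/bin/env Rscript
# Growth-rate slope analysis: puncta born near the front of a migrating
# cell sweep backwards through the normalized coordinate; the averaged
# signal-versus-position curve is fitted piecewise to recover the
# configured threefold back/front growth-rate ratio.

suppressPackageStartupMessages(library(mcsgrad))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

gr <- experiment_growth_slopes(n_cells = 8, seed = 505, growth_ratio = 3)
utils::write.csv(gr$curve, "results/analysis/05_growth_curve.csv",
                 row.names = FALSE)
utils::write.csv(
  data.frame(n_obs = gr$n_obs, slope_front = gr$slope_front,
             slope_back = gr$slope_back, slope_ratio = gr$slope_ratio,
             p_argmax = gr$p_argmax, configured_ratio = gr$configured_ratio),
  "results/analysis/05_growth_summary.csv", row.names = FALSE)

cat(sprintf(
  "Growth curve from %d punctum observations: front slope %.1f, back slope
%.1f (ratio units per unit position), back/front ratio %.2f against the
configured %.0f. Signal peaks at p = %.2f.\n",
  gr$n_obs, gr$slope_front, gr$slope_back, gr$slope_ratio,
  gr$configured_ratio, gr$p_argmax))
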