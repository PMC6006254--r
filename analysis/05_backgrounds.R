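#!/usr/bin/env Rscript
# Six-sample background comparison: TTD amplitude vs spectrally unmixed dye
# concentration across dye/blood/ink/gold-nanoparticle compositions, with
# two dye-free controls and per-sample t-tests against the dye-only sample.

suppressPackageStartupMessages(library(ttdpa))

cfg <- run_config(seed = 5, repeats = 5, output_dir = "results/backgrounds")
res <- run_experiment(cfg, "backgrounds")

cat("TTD amplitudes (t-test vs dye-only sample):\n")
print(res$ttd_ttests, row.names = FALSE)
cat("\nspectrally unmixed relative dye concentration:\n")
print(res$su_ttests, row.names = FALSE)
cat("\nTTD is flat across the four dye samples and ~0 for both controls;\n")
cat("unmixing inflates the blue-ink sample (spectrum collinear with the dye).\n")
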