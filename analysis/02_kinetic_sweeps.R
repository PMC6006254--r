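#!/usr/bin/env Rscript
# Kinetics of the TTD amplitude: delay sweep with exponential decay fit,
# oxygen-level comparison of fitted lifetimes (Stern-Volmer quenching), and
# the concentration linearity sweep.

suppressPackageStartupMessages(library(ttdpa))

cfg <- run_config(seed = 2, repeats = 5, noise_sd = 0.12,
                  output_dir = "results/kinetics")
res <- run_experiment(cfg, "kinetic_sweeps")

cat(sprintf("delay sweep: fitted tau_eff = %.3f us (r^2 = %.4f)\n",
            res$delay_sweep$tau_fit[1], res$delay_sweep$r_squared[1]))
oxy <- unique(res$oxygen_sweep[, c("oxygen_percent", "tau_fit")])
for (i in seq_len(nrow(oxy)))
  cat(sprintf("oxygen %4.1f%%: tau_eff = %.3f us\n",
              oxy$oxygen_percent[i], oxy$tau_fit[i]))
cs <- res$concentration_sweep
r <- cor(cs$concentration, cs$mean_amplitude)
cat(sprintf("concentration sweep: linearity r = %.5f over %g-%g mg/mL\n",
            r, min(cs$concentration), max(cs$concentration)))
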