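#!/usr/bin/env Rscript
# Step 5: Monte-Carlo calibration of the per-segment ANCOVA interaction test.
# Under the null preset the rejection rate should sit at the nominal 5% level;
# under the withdrawal-delay preset the test should fire in the two segments
# overlapping the delay window (DIV55-78, DIV78-95) and stay near the nominal
# level outside it. 300 replicates per preset keep this step to ~1 minute;
# the acceptance script runs the larger calibrated versions (1000 and 500).

suppressPackageStartupMessages(library(devindexr))

n_sims <- 300L
mc_null <- mc_interaction_rates("null", n_sims = n_sims, seed = 7)
mc_delay <- mc_interaction_rates("withdrawal_delay", n_sims = n_sims,
                                 seed = 8)

rate_by_seg <- function(mc) tapply(mc$interaction_p < 0.05, mc$segment, mean)
rates <- data.frame(
  segment = names(rate_by_seg(mc_null)),
  null_rejection = as.vector(rate_by_seg(mc_null)),
  delay_rejection = as.vector(rate_by_seg(mc_delay))
)

dir.create("results/calibration", recursive = TRUE, showWarnings = FALSE)
write_table_csv(tibble::as_tibble(rates),
                "results/calibration/interaction_rates.csv")

cat(sprintf("interaction-test rejection rates at alpha = 0.05 (%d sims):\n",
            n_sims))
print(rates, row.names = FALSE, digits = 3)
cat(sprintf("\npooled null rate: %.3f (nominal 0.05)\n",
            mean(mc_null$interaction_p < 0.05)))
cat("delay window in the generator: DIV67-DIV95; the two overlapping",
    "segments carry the power, as expected.\n")
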