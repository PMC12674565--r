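#!/usr/bin/env Rscript
# Sampling-effort calibration: how fast do local accuracy (held-out RMSE)
# and precision (mean quantile-forest SD) improve as 0-100% of the dense
# province's campaign is added to a baseline that never sampled it?
# 11 fractions, 10 random repeats each; fraction 1.0 evaluated once
# in-sample.

library(srisoscape)

cal <- experiment_calibration(seed = 6)
readr::write_csv(cal$curve, "results/calibration_curve.csv")
readr::write_csv(cal$summary, "results/calibration_summary.csv")

print(cal$summary, n = 12)
message(sprintf(
  "held-out RMSE %.4g (0%%) -> %.4g (+10%%) -> %.4g (100%%, in-sample)",
  cal$rmse_f0, cal$rmse_f10, cal$rmse_f100))
message(sprintf(
  "mean predicted SD %.4g (0%%) -> %.4g (+10%%) -> %.4g (100%%)",
  cal$sd_f0, cal$sd_f10, cal$sd_f100))
message(sprintf("Spearman rho (mean RMSE vs fraction, f < 1): %.2f",
                cal$spearman_rho))
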