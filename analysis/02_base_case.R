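#!/usr/bin/env Rscript
# Deterministic base case: both arms' discounted cost breakdown, QALYs, life
# years and the ICER, plus the one-off calibration of the donafenib
# patient-assistance multiplier against the published arm total.

suppressPackageStartupMessages(library(psmcea))
dir.create("results", recursive = TRUE, showWarnings = FALSE)

cfg <- base_config()

# The assistance-program design is undocumented; this is the single
# calibrated value (stored in the packaged config) and how it was obtained.
cal <- calibrate_pap(cfg, target_cost = 22330.23, scheme = "price_multiplier")
cat(sprintf("calibrated PAP price multiplier: %.7f (achieves US$%.2f)\n",
            cal$value, cal$achieved_cost))
calk <- calibrate_pap(cfg, target_cost = 22330.23, scheme = "pay_first_k")
cat(sprintf("nearest pay-first-k alternative: k = %d (achieves US$%.2f)\n",
            calk$value, calk$achieved_cost))

ev <- evaluate_model(cfg)
tab <- results_table(ev)
print(tab, digits = 6)
write.csv(tab, "results/base_case.csv", row.names = FALSE)

cmp <- ev$comparison
cat(sprintf("\nincremental: dCost US$%.2f, dQALY %.4f, ICER US$%.2f/QALY\n",
            cmp$delta_cost, cmp$delta_qaly, cmp$icer))
cat(sprintf("NMB at 3x GDP (US$%.2f/QALY): US$%.2f -> %s\n",
            cmp$wtp, cmp$nmb,
            if (cmp$nmb > 0) "cost-effective" else "not cost-effective"))
cat("wrote results/base_case.csv\n")
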