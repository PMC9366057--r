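#!/usr/bin/env Rscript
# Stage 6 — what-if imputation among the Scale-278 triplet.
#
# Clamps each of D (Scale 2), Pt (Scale 7) and Sc (Scale 8) at 1,000
# values drawn from the patient network's marginal and imputes the other
# two scales' conditional means under both fitted group networks (a
# paired design: both networks see identical draws). The mean paired
# difference (healthy minus schizophrenia) shows how the same observed
# scale propagates differently through the two dependence structures.

library(mmpibn)

seed <- 20260926
net_h <- load_network("results/network_healthy.json")
net_s <- load_network("results/network_schizophrenia.json")

wt <- whatif_difference_table(net_h, net_s, n = 1000, seed = seed)
print(wt)

write.csv(round(wt$mean_diff, 3), "results/whatif_mean_difference.csv")
write.csv(round(wt$sd_diff, 3), "results/whatif_sd_difference.csv")
write.csv(signif(wt$p_value, 3), "results/whatif_p_values.csv")

cat("\nReading the Sc row: a patient-typical Schizophrenia-scale score",
    "implies visibly higher Depression and Psychasthenia under the healthy",
    "network than under the patient network - the low-2 / low-7 / high-8",
    "signature emerges from the patients' attenuated D-Pt-Sc coupling.\n")
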