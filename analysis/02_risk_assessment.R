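#!/usr/bin/env Rscript
# Step 2 — multi-route cancer and non-cancer risk for adult and child
# receptors, driven by the published summed mean soil concentration.
#
# Writes results/risk_table.csv (full precision) and prints the table at
# reporting precision (ILCR to 2 significant figures, HQ to 2 decimals).

suppressPackageStartupMessages(library(pahsoilrisk))
dir.create("results", showWarnings = FALSE)

c_total <- reference_total()
factors <- slope_factors()

risk <- lapply(c(adult = "adult", child = "child"), function(rc) {
  assess_risk(c_total, exposure_profile(rc), factors)
})

bundle <- structure(list(risk = risk), class = "report_bundle_lite")
rt <- do.call(rbind, lapply(risk, function(r) {
  data.frame(receptor = r$receptor,
             ilcr_ingestion = r$ilcr_ingestion,
             ilcr_inhalation = r$ilcr_inhalation,
             ilcr_dermal = r$ilcr_dermal,
             ilcr_total = r$ilcr_total,
             edi = r$edi, hq = r$hq,
             cancer_exceeds = r$cancer_exceeds,
             noncancer_exceeds = r$noncancer_exceeds)
}))
rownames(rt) <- NULL
utils::write.csv(rt, "results/risk_table.csv", row.names = FALSE)

cat(sprintf("Exposure concentration: %.2f mg/kg (summed compound means)\n\n",
            c_total))
print(format_risk_table(rt))
cat("\nFindings:\n")
cat("- Ingestion and dermal contact dominate; both exceed the 1e-6\n")
cat("  screening risk by more than two orders of magnitude for both receptors.\n")
cat("- Inhalation risk is ~4 orders of magnitude smaller (PEF = 1.36e9 m3/kg).\n")
cat(sprintf("- Hazard quotients (RfD = %.1e, CF = 1): adult %.2f, child %.2f —\n",
            factors$rfd, rt$hq[1], rt$hq[2]))
cat("  far above the non-cancer threshold of 1.\n")
cat("Full-precision table written to results/risk_table.csv\n")
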