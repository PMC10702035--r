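#!/usr/bin/env Rscript
# Step 4 — the synthetic case-study analysis.
#
# Builds the synthetic fixture matching the motivating cohort's marginal
# counts (786 records, 61 cases, subset of 325; exposure missing by
# design for 414 and by chance for 79), tabulates the descriptive table,
# and applies all five analysis approaches with the known design weight
# (0.30)^-1 and m = 50 imputations. Writes results/case_table1.csv and
# results/case_study.csv.

library(ccmisim)

dir.create("results", showWarnings = FALSE)
fixture <- make_fixture(fixture_spec(seed = 20240904))
write_cohort_csv(fixture, "results/case_fixture.csv")

t1 <- summarize_table1(fixture)
write.csv(t1, "results/case_table1.csv", row.names = FALSE)
cat("Descriptive table (synthetic fixture):\n")
print(t1, row.names = FALSE)

res <- run_case_study(fixture, m = 50, cycles = 10, seed = 20240905)
write.csv(res, "results/case_study.csv", row.names = FALSE)
cat("\nRisk ratio for food allergy given vitamin D insufficiency:\n")
for (i in seq_len(nrow(res))) {
  cat(sprintf(
    "  %-11s RR %.2f (95%% CI %.2f-%.2f)\n",
    res$approach[i], res$RR[i], res$ci_lower[i], res$ci_upper[i]
  ))
}
cat("
The fixture's joint distribution is synthetic (margins only), so the
point estimates are not those of the real cohort; the structural pattern
— every MI-based interval narrower than the CCA and IPW-only intervals —
is the comparison of interest.
")
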