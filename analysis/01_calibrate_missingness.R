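#!/usr/bin/env Rscript
# Step 1 — calibrate the unintended-missingness mechanisms.
#
# For each mechanism (independent / dependent), level (low / high) and
# association setting (observed / enhanced) this solves for the free
# intercept-like parameters so the target proportions hold: at the low
# level, 20% of records with >= 1 confounder missing, 10% with the
# exposure missing, 25% with any of the three incomplete; at the high
# level the component percentages double. Calibrated configurations
# (with achieved proportions) are written to results/calibration/.

library(ccmisim)

out_dir <- "results/calibration"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (setting in c("observed", "enhanced")) {
  params <- default_generation_params(setting)
  for (mechanism in c("independent", "dependent")) {
    for (level in c("low", "high")) {
      cfg <- calibrate_intercepts(
        params, missingness_config(mechanism, level, setting),
        seed = 20240901
      )
      nm <- paste(mechanism, level, setting, sep = "_")
      write_missingness_config(cfg, file.path(out_dir, paste0(nm, ".yaml")))
      rows[[nm]] <- data.frame(
        mechanism = mechanism, level = level, setting = setting,
        p_conf_any = cfg$achieved$p_conf_any,
        p_exposure = cfg$achieved$p_exposure,
        p_any = cfg$achieved$p_any
      )
      cat(sprintf(
        "%-28s conf-any %.4f  exposure %.4f  any %.4f\n",
        nm, cfg$achieved$p_conf_any, cfg$achieved$p_exposure, cfg$achieved$p_any
      ))
    }
  }
}
summary <- do.call(rbind, rows)
write.csv(summary, file.path(out_dir, "achieved_proportions.csv"), row.names = FALSE)
cat("\nAll mechanisms calibrated; configs under", out_dir, "\n")
cat("At the high level only the component targets are doubled; the\n")
cat("any-incomplete proportion is emergent (about 46%, not 50%).\n")
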