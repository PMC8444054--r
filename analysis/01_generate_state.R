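#!/usr/bin/env Rscript
# Generate the synthetic ten-catchment state and its observed historical
# series, and write them in the package's interchange formats. Everything
# downstream (02-06) reads nothing but these files and the package itself.

suppressPackageStartupMessages(library(phnsim))

seed <- 20211
out_dir <- "results/synthetic_state"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

state <- generate_state(seed = seed, n_catchments = 10)

for (p in state) {
  write_catchment_config(p, file.path(out_dir, paste0(p$name, ".yaml")))
  obs <- generate_observed_series(p, 2011:2020, noise_cv = 0.05, seed = seed)
  write_observed_series(obs, file.path(out_dir, paste0(p$name, "_observed.csv")))
}

profiles <- do.call(rbind, lapply(state, function(p) {
  pr <- attr(p, "profile")
  data.frame(catchment = p$name, class = pr$density_class,
             population = round(pr$population),
             target_suicide_rate = pr$target_suicide_rate,
             ed_presentation_multiplier = pr$ed_presentation_multiplier,
             capacity_slack = pr$capacity_slack,
             specialist_slack = pr$specialist_slack)
}))
write.csv(profiles, file.path(out_dir, "profiles.csv"), row.names = FALSE)
write_manifest(file.path(out_dir, "manifest.yaml"),
               step = "01_generate_state", seed = seed, n_catchments = 10,
               noise_cv = 0.05)

cat("Synthetic state written to", out_dir, "\n")
print(profiles, row.names = FALSE)
cat("\nPopulations span", format(min(profiles$population), big.mark = ","),
    "to", format(max(profiles$population), big.mark = ","),
    "; target suicide rates span",
    sprintf("%.2f-%.2f per 100,000/year.\n",
            min(profiles$target_suicide_rate),
            max(profiles$target_suicide_rate)))
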