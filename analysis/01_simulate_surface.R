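#!/usr/bin/env Rscript
# Step 1: generate the synthetic study surface.
#
# The default scenario emulates a national male population observed over
# ages 0..89 and 20 calendar years: a one-term Lee-Carter truth with an
# infant-mortality/Gompertz age schedule, loadings concentrated at young
# ages, a period index following a random walk with drift (-0.8 logit
# units/year on the summed-loading scale), exposure 100000 persons per
# cell and binomial death counts.  Writes the exposure and death-count
# matrices in the standard CSV schema.

suppressPackageStartupMessages(library(mortboot))

seed <- 2024
dir.create("results", showWarnings = FALSE)

params <- make_params(A = 90, T = 20, family = "LC1", seed = seed)
surface <- simulate_deaths(params, exposure = 1e5, dispersion = 1,
                           seed = seed + 1)

write_surface(surface, "results/surface_E.csv", "results/surface_d.csv")
write_params_json(params, "results/true_params.json")

message(sprintf("Simulated surface: %d ages x %d years, %.0f deaths in total.",
                length(surface$ages), length(surface$years), sum(surface$d)))
message(sprintf("Crude q ranges from %.2g (young adult) to %.2g (oldest age).",
                min(surface$q), max(surface$q)))
message("Wrote results/surface_E.csv, results/surface_d.csv, results/true_params.json")
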