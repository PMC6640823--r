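#!/usr/bin/env Rscript
# Step 2: fit every TCSPC histogram and aggregate to animal level.
#
# Re-generates the seed-42 cohort (deterministic), fits all histograms with
# the per-channel reconvolution policy (single-exponential channel 1,
# double-exponential channels 2-4), computes spectral intensity fractions
# and normalized absorbance, aggregates the 9 measurements per animal and
# region, and runs the AMC-vs-MI comparisons. Large per-measurement tables
# go to scratch/pipeline; animal-level tables to results/.

suppressMessages(library(cardiofluor))

cohort <- generate_cohort(default_cohort_spec(), config = sim_config(),
                          seed = 42L)
t0 <- Sys.time()
res <- run_pipeline(cohort)
cat(sprintf("fitted %d histograms in %.1f min (%d non-converged, excluded)\n",
            res$n_fits, as.numeric(difftime(Sys.time(), t0, units = "mins")),
            res$n_excluded))

write_results(res, "scratch/pipeline")
dir.create("results", showWarnings = FALSE)
utils::write.csv(res$animals, "results/animals.csv", row.names = FALSE)

# quick look: fitted channel-4 short lifetime in the infarct region
an <- res$animals
t1 <- an[an$parameter == "tau1_ch4" & an$roi == "LVA", ]
summ <- stats::aggregate(value ~ group + week, data = t1,
                         FUN = function(v) c(mean = mean(v), sd = sd(v)))
cat("fitted channel-4 tau1 (ns) in LVA, mean (sd) per group and week:\n")
print(do.call(data.frame, summ))
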