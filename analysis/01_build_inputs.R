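#!/usr/bin/env Rscript
# Build the annual index-procedure volume series that seed the forecast:
# the observed US TAVR series linearly extrapolated back to 2007 and forward
# to 2035 (unsaturated market), and bioprosthetic SAVR from literature-scale
# pre-2012 values, 80% of total surgical AVR for 2012-2020, and a constant
# 50,000 cases from 2021. Writes both series to results/volume_series.csv.

suppressPackageStartupMessages(library(vivforecast))

tavr <- build_tavr_series(tavr_observed_us(), back_to = 2007,
                          forward_to = 2035)
savr <- build_savr_series(savr_total_surgical_us(),
                          bioprosthetic_fraction = 0.8,
                          pre_period = savr_bioprosthetic_pre2012_us(),
                          constant_from = 2021, constant_value = 50000,
                          end_year = 2035)

dir.create("results", showWarnings = FALSE)
both <- rbind(cbind(proc = "TAVR", as.data.frame(tavr)),
              cbind(proc = "SAVR", as.data.frame(savr)))
write.csv(both, "results/volume_series.csv", row.names = FALSE, quote = FALSE)

cat("TAVR series:", min(tavr$year), "-", max(tavr$year), "\n")
cat("  observed years:", paste(range(tavr$year[tavr$provenance == "observed"]),
                               collapse = "-"), "\n")
cat("  extrapolated 2035 native TAVR:",
    format(volume_at(tavr, 2035), big.mark = ","), "\n")
cat("SAVR series:", min(savr$year), "-", max(savr$year),
    "| plateau 2021-2035 at", format(volume_at(savr, 2030), big.mark = ","),
    "\n")

# consistency note: a ~15% ViV share of all TAVR at a ~42k ViV volume implies
# roughly 280k all-TAVR in 2035; the native series plus the forecast ViV
# should be the same order of magnitude
cat("implied all-TAVR 2035 at 15% share of 42k ViV:  ~280,000\n")
cat("native 2035 + forecast ViV will be checked by analysis/02_run_forecast.R\n")
cat("wrote results/volume_series.csv\n")
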