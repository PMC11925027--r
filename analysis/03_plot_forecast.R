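#!/usr/bin/env Rscript
# Plot the forecast curves (total ViV and its TAVR-in-SAVR / TAVR-in-TAVR
# components with ensemble-SD ribbons) from the table written by
# analysis/02_run_forecast.R.

suppressPackageStartupMessages({
  library(ggplot2)
})

fc <- read.csv("results/forecast/forecast.csv")
if (!nrow(fc)) stop("run analysis/02_run_forecast.R first")

long <- rbind(
  data.frame(year = fc$year, series = "TAVR-in-SAVR", mean = fc$tinS_mean,
             sd = fc$tinS_sd),
  data.frame(year = fc$year, series = "TAVR-in-TAVR", mean = fc$tinT_mean,
             sd = fc$tinT_sd),
  data.frame(year = fc$year, series = "Total ViV", mean = fc$total_mean,
             sd = fc$total_sd))
long <- long[long$year >= 2010, ]

p <- ggplot(long, aes(year, mean, colour = series, fill = series)) +
  geom_ribbon(aes(ymin = mean - 2 * sd, ymax = mean + 2 * sd),
              alpha = 0.2, colour = NA) +
  geom_line(linewidth = 0.9) +
  scale_y_continuous(labels = scales::comma) +
  labs(x = NULL, y = "Annual procedures",
       title = "Forecast US transcatheter valve-in-valve volumes",
       subtitle = "Ensemble means ± 2 SD over 20 replicates",
       colour = NULL, fill = NULL) +
  theme_minimal(base_size = 11) +
  theme(legend.position = "bottom")

dir.create("results", showWarnings = FALSE)
ggsave("results/forecast_curves.pdf", p, width = 7, height = 4.5)
cat("wrote results/forecast_curves.pdf\n")
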