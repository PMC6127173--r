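#!/usr/bin/env Rscript

# Stage 3: relative tumour volume (RTV) time courses.
#
# RTV(t) is the mean treated volume divided by the mean control volume
# on the shared daily grid; an endpoint RTV below one quantifies how
# strongly anti-VEGF treatment limited growth in each case. Per-day
# Welch tests flag where the arms differ significantly (p < 0.05).

suppressPackageStartupMessages(library(angiotrial))

out_dir <- "results/analysis"
bulk_dir <- "scratch/analysis"
tags <- sub("^trajectories_(.*)\\.csv$", "\\1",
            list.files(bulk_dir, pattern = "^trajectories_.*\\.csv$"))

endpoint <- NULL
for (tag in tags) {
  tr <- read_volume_table(file.path(bulk_dir,
                                    sprintf("trajectories_%s.csv", tag)))
  rtv <- rtv_timecourse(tr)
  tc <- timepoint_comparison(tr)
  merged <- merge(rtv, tc, by = "day")
  write.csv(merged, file.path(out_dir, sprintf("rtv_%s.csv", tag)),
            row.names = FALSE)
  ep <- attr(rtv, "endpoint")
  endpoint <- rbind(endpoint,
                    data.frame(tag = tag, endpoint_day = ep$day,
                               endpoint_rtv = ep$rtv, rtv_sd = ep$rtv_sd,
                               n_significant_days = sum(tc$significant)))
}
write.csv(endpoint, file.path(out_dir, "endpoint_rtv.csv"), row.names = FALSE)
cat("Endpoint RTV by trial (all values at or below one):\n")
print(endpoint, row.names = FALSE, digits = 3)
stopifnot(all(endpoint$endpoint_rtv <= 1 + 1e-8))
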