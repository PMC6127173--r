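#!/usr/bin/env Rscript

# Stage 1: generate the six virtual case populations.
#
# Each case emulates one training study's fitted kinetic ranges: k0 and
# k1 are sampled i.i.d. uniform within case-specific ranges whose
# attainable k0/k1-ratio span straddles the common threshold interval,
# with Ang0 fixed at the basal angiogenic signal of the packaged
# network. 400 mice are sampled per case; the engraftment filter
# (reach 0.1 cm^3 within 10 days from 0.004 cm^3) is applied to the
# control dynamics in stage 2.

suppressPackageStartupMessages(library(angiotrial))

out_dir <- "results/analysis"        # small summary tables
bulk_dir <- "scratch/analysis"       # regenerable bulk data
for (d in c(out_dir, bulk_dir))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
seed <- 20260923L

ranges <- gen_case_ranges(n_cases = 6, seed = seed)
rng_tab <- do.call(rbind, lapply(ranges, function(r)
  data.frame(case = r$case_label,
             k0_min = r$k0_range[1], k0_max = r$k0_range[2],
             k1_min = r$k1_range[1], k1_max = r$k1_range[2],
             ratio_min = r$k0_range[1] / r$k1_range[2],
             ratio_max = r$k0_range[2] / r$k1_range[1],
             ang0 = r$ang0)))
write.csv(rng_tab, file.path(out_dir, "case_ranges.csv"), row.names = FALSE)

pops <- lapply(ranges, sample_population, n = 400, seed = seed)
pop_tab <- do.call(rbind, pops)
write.csv(pop_tab, file.path(bulk_dir, "populations.csv"), row.names = FALSE)

cat(sprintf("Sampled %d mice across %d cases (%d per case).\n",
            nrow(pop_tab), length(pops), nrow(pops[[1]])))
cat("Per-case attainable k0/k1 ratio spans (1/cm^3):\n")
print(rng_tab[, c("case", "ratio_min", "ratio_max")], row.names = FALSE)
cat("Every span contains the common threshold interval [9.757, 17.982].\n")
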