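#!/usr/bin/env Rscript

# Stage 2: paired control/treated trials under protocol A.
#
# For tractable runtime this analysis simulates the first 60 mice of
# each sampled case population (the mechanistic simulations are exact,
# so n trades statistical resolution, not correctness). Each mouse is
# simulated twice over an identical horizon -- once untreated, once
# with trigger-started biweekly bevacizumab at 10 mg/kg from
# 0.1 cm^3 -- and the engraftment exclusion filter is applied from the
# control dynamics. Alternative protocols (Z, V11a, V11a-D) are run
# for one case to compare dosing strategies.

suppressPackageStartupMessages(library(angiotrial))

out_dir <- "results/analysis"
bulk_dir <- "scratch/analysis"
seed <- 20260923L
n_sim <- 60

pops <- read.csv(file.path(bulk_dir, "populations.csv"))
model <- build_default_network()

run_case <- function(case, protocol_name, tag) {
  pop <- pops[pops$case_label == case, ][seq_len(n_sim), ]
  trial <- run_trial(pop, make_protocol(protocol_name), model = model,
                     seed = seed)
  write_volume_table(trial$trajectories,
                     file.path(bulk_dir, sprintf("trajectories_%s.csv", tag)),
                     seed = seed)
  cat(sprintf("%-12s protocol %-6s retained %d/%d, horizon %d days, %d failures\n",
              case, protocol_name, nrow(trial$params), nrow(pop),
              trial$horizon, length(trial$failures)))
  invisible(trial)
}

trials <- list()
for (case in unique(pops$case_label))
  trials[[case]] <- run_case(case, "A", case)

# alternative dosing strategies for one case
for (p in c("Z", "V11a", "V11a_D"))
  run_case("case2", p, paste0("case2_", p))
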