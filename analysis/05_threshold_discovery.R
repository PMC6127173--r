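#!/usr/bin/env Rscript

# Stage 5: threshold biomarker discovery.
#
# For every protocol-A case, each observed k0/k1 ratio (and each k1) in
# the treated arm is tested as a split point with the log-rank test;
# contiguous significant candidates with a consistent direction of
# benefit form the case's valid threshold interval. The intersection
# across cases is the common range; its midpoint is the working median
# threshold used for the six-group stratified comparison.

suppressPackageStartupMessages(library(angiotrial))

out_dir <- "results/analysis"
bulk_dir <- "scratch/analysis"
pops <- read.csv(file.path(bulk_dir, "populations.csv"))
cases <- unique(pops$case_label)

sweep_one <- function(tag, selector) {
  tr <- read_volume_table(file.path(bulk_dir,
                                    sprintf("trajectories_%s.csv", tag)))
  recs <- derive_survival(tr, cutoff = 2)
  recs <- merge(recs, pops[pops$case_label == tag,
                           c("mouse_id", "k0", "k1")], by = "mouse_id")
  scan <- threshold_scan(recs, selector, min_group_size = 8)
  write.csv(as.data.frame(scan),
            file.path(bulk_dir, sprintf("scan_%s_%s.csv", selector, tag)),
            row.names = FALSE)
  valid_range(scan)
}

for (selector in c("ratio", "k1", "k0")) {
  ranges <- lapply(cases, sweep_one, selector = selector)
  names(ranges) <- cases
  tab <- do.call(rbind, lapply(cases, function(cs) {
    r <- ranges[[cs]]
    if (!nrow(r)) return(data.frame(case = cs, low = NA, high = NA))
    p <- r[which(r$primary), ]
    data.frame(case = cs, low = p$low, high = p$high)
  }))
  write.csv(tab, file.path(out_dir, sprintf("ranges_%s.csv", selector)),
            row.names = FALSE)
  cr <- common_range(ranges)
  cat(sprintf("\n%s sweep: per-case primary intervals\n", selector))
  print(tab, row.names = FALSE, digits = 4)
  if (cr$empty) {
    cat(sprintf("%s: no common interval across the six cases\n", selector))
  } else {
    cat(sprintf("common %s_thresh range: [%.4g, %.4g], median %.4g\n",
                selector, cr$low, cr$high, cr$median))
  }
  if (selector == "ratio" && !cr$empty) {
    # six-group stratification of each case at the common median
    strat <- NULL
    for (cs in cases) {
      tr <- read_volume_table(file.path(bulk_dir,
                                        sprintf("trajectories_%s.csv", cs)))
      recs <- derive_survival(tr, cutoff = 2)
      recs <- merge(recs, pops[pops$case_label == cs,
                               c("mouse_id", "k0", "k1")], by = "mouse_id")
      sac <- stratify_and_compare(recs, cr$median, "ratio")
      strat <- rbind(strat, cbind(case = cs, sac$comparisons))
      write.csv(sac$medians,
                file.path(out_dir, sprintf("medians_sixgroup_%s.csv", cs)),
                row.names = FALSE)
    }
    write.csv(strat, file.path(out_dir, "sixgroup_comparisons.csv"),
              row.names = FALSE)
  }
}
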