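#!/usr/bin/env Rscript
# Step 1: assemble the study inputs.
#
# The analysis runs entirely on synthetic stand-ins generated by the package
# (regenerable via scripts/make_extdata.R): a two-guild fossil occurrence
# table with the study's bookkeeping (279 occurrences, 88 species, 9 extant)
# and five dated proxy tables. This step validates them and writes the
# bookkeeping summary.

suppressMessages(library(paleocarn))
dir.create("results", showWarnings = FALSE)
extdata <- function(f) system.file("extdata", f, package = "paleocarn")

occ <- read_occurrences(extdata("synthetic_occurrences.tsv"))
s <- attr(occ, "summary")
cat(sprintf(
  "occurrence table: %d occurrences, %d species (%d large / %d small),\n",
  s$n_occurrences, s$n_species, s$n_large, s$n_small))
cat(sprintf("  %d extant, %d extinct\n", s$n_extant, s$n_extinct))

summary_df <- data.frame(quantity = names(s), value = unlist(s))
utils::write.table(summary_df, "results/01_dataset_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (p in c("brain", "forest", "temperature", "precipitation",
            "water_deficit")) {
  m <- read_proxy(extdata(paste0("synthetic_proxy_", p, ".tsv")))
  cat(sprintf("proxy %-14s %3d measurements, ages %.2f-%.2f Ma\n",
              p, nrow(m), min(m$age_min), max(m$age_max)))
}
cat("wrote results/01_dataset_summary.tsv\n")
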