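#!/usr/bin/env Rscript
# Stage 2: reduce to C-alpha atoms, split each system into single-subunit
# trajectories, and concatenate everything (systems in configuration
# order, subunits in chain-id order) into one combined trajectory with
# per-frame provenance tags.

suppressPackageStartupMessages(library(dynsel))

src <- "results/data"
tags <- c("sysA", "sysB", "sysC", "sysD")

subunits <- list()
for (tag in tags) {
  tr <- read_trajectory(file.path(src, paste0(tag, ".pdb")), system = tag)
  ca <- select_calpha(tr)
  parts <- split_chains(ca)
  cat(sprintf("%s: %d frames, %d CA atoms -> %d subunit trajectories\n",
              tag, n_frames(ca), n_atoms(ca), length(parts)))
  subunits <- c(subunits, parts)
}

combined <- concatenate_trajectories(subunits)
cat(sprintf("combined: %d frames x %d atoms from %d subunit trajectories\n",
            n_frames(combined), n_atoms(combined), length(subunits)))
write_trajectory(combined, file.path(src, "combined.pdb"))
writeLines(combined$system, file.path(src, "combined_systems.txt"))
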