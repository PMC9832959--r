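#!/usr/bin/env Rscript
# Generate the synthetic compound screen: 438-compound kinase-inhibitor
# library, 80 compounds/plate in technical quadruplets + 32 DMSO controls
# per 384-well plate, one assay plate per sex per library plate, 6 days of
# sex-dimorphic growth with planted hyper/hypo effects.
library(gtscreen)

out <- file.path("results", "screen")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- screen_config(seed = 1)
layout <- generate_plate_layout(cfg$n_compounds, cfg$compounds_per_plate,
                                cfg$replicates, cfg$controls_per_plate,
                                cfg$plate_format, seed = cfg$seed)
effects <- plant_effects(sort(unique(layout$compound_id[layout$role == "compound"])),
                         n_hypo = cfg$n_hypo, n_hyper = cfg$n_hyper,
                         effect_hypo = cfg$effect_hypo,
                         effect_hyper = cfg$effect_hyper, seed = cfg$seed)
meas <- simulate_screen_counts(layout, effects, cfg$growth, cfg$days,
                               seed = cfg$seed)

write_layout_csv(layout, file.path(out, "layout.csv"))
write.csv(effects, file.path(out, "planted_effects.csv"), row.names = FALSE)
write.csv(meas, file.path(out, "measurements.csv"), row.names = FALSE)

cat("Plates per sex:", length(unique(layout$plate_id)), "\n")
cat("Wells measured:", nrow(meas), "(compound:",
    sum(meas$role == "compound"), "; control:", sum(meas$role == "control"), ")\n")
cat("Planted truth:", cfg$n_hypo, "hypo x", cfg$effect_hypo, ";",
    cfg$n_hyper, "hyper x", cfg$effect_hyper, "\n")
cat("Median day-6 count (male):",
    median(meas$cell_count[meas$sex == "male"]), "cells/well\n")
cat("Wrote", out, "\n")
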