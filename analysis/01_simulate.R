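#!/usr/bin/env Rscript
# Stage 1 — simulate the study dataset.
#
# Generates the multiclass expression dataset with known ground truth and
# writes it in the standard matrix + labels TSV layout. The ground-truth
# gene sets are kept alongside so later stages can score their recovery.

source("analysis/00_config.R")

gen <- generate_dataset(study_spec())
write_expression(gen$dataset, study_path("matrix.tsv"),
                 study_path("labels.tsv"))
writeLines(jsonlite::toJSON(gen$truth, pretty = TRUE),
           study_path("ground_truth.json"))

cat("Simulated study dataset:\n")
print(gen$dataset)
cat("\nGround truth:", length(gen$truth$informative), "informative,",
    length(gen$truth$redundant), "redundant,",
    length(gen$truth$noise), "noise genes\n")
cat("Written to", STUDY_DIR, "\n")
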