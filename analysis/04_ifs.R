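#!/usr/bin/env Rscript
# Stage 4 — incremental feature selection with both classifiers.
#
# Evaluates nested top-k prefixes of the mRMR list (step 10) under 10-fold
# stratified cross-validation with fold-internal SMOTE balancing, scoring
# each prefix by multiclass MCC, then selects the optimal (highest-MCC)
# and compact (smallest k within tolerance 0.025 of the optimum)
# classifiers from each curve.

source("analysis/00_config.R")

dataset <- read_expression(study_path("matrix.tsv"), study_path("labels.tsv"),
                           min_class_size = 10, scale = "log2")
ranked <- read_ranked_list(study_path("ranked_genes.tsv"))

selection <- list()
for (kind in c("tree", "margin")) {
  cur <- run_ifs(dataset, ranked, classifier_spec(kind, seed = STUDY_SEED),
                 step = 10, max_k = 100, K_folds = 10,
                 seed = stage_seed(STUDY_SEED, paste0("ifs_", kind)))
  write_ifs_curve(cur, study_path(sprintf("ifs_curve_%s.tsv", kind)))
  opt <- select_optimal(cur)
  cmp <- select_compact(cur, tolerance = 0.025)
  selection[[kind]] <- list(
    optimal = list(k = opt$k, mcc = opt$mcc,
                   overall_accuracy = opt$overall_accuracy),
    compact = list(k = cmp$k, mcc = cmp$mcc,
                   overall_accuracy = cmp$overall_accuracy))
  cat(sprintf("\n%s classifier IFS curve (k : MCC):\n  %s\n", kind,
              paste(sprintf("%d: %.3f", cur$records$k, cur$records$mcc),
                    collapse = "  ")))
  cat(sprintf("  optimal: k = %d, MCC = %.3f, accuracy = %.3f\n",
              opt$k, opt$mcc, opt$overall_accuracy))
  cat(sprintf("  compact: k = %d, MCC = %.3f, accuracy = %.3f\n",
              cmp$k, cmp$mcc, cmp$overall_accuracy))
}
writeLines(jsonlite::toJSON(selection, auto_unbox = TRUE, digits = I(10),
                            pretty = TRUE),
           study_path("selection.json"))
cat("\nCurves and selection written to", STUDY_DIR, "\n")
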