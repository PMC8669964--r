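#!/usr/bin/env Rscript
# Stage 3 — mRMR ranking of the Boruta-retained genes.
#
# Orders the retained genes by max-relevance/min-redundancy (MID criterion,
# 3-bin discretization at mean +/- sd) and writes the ranked list that the
# incremental feature selection stage consumes.

source("analysis/00_config.R")

dataset <- read_expression(study_path("matrix.tsv"), study_path("labels.tsv"),
                           min_class_size = 10, scale = "log2")
ret <- utils::read.table(study_path("boruta_retained.tsv"), header = TRUE,
                         sep = "\t", comment.char = "#")
confirmed <- ret$gene_id[ret$status == "confirmed"]
cat("Ranking", length(confirmed), "Boruta-retained genes by mRMR (MID)\n")

ranked <- rank_mrmr(dataset, candidate_genes = confirmed, criterion = "MID")
write_ranked_list(ranked, study_path("ranked_genes.tsv"))

truth <- jsonlite::fromJSON(file.path(STUDY_DIR, "ground_truth.json"))
top <- utils::head(ranked, 10)
cat("\nTop 10 genes (score = selection criterion at that step):\n")
print(data.frame(top, informative = top$gene_id %in% truth$informative),
      row.names = FALSE)
cat(sprintf("\nInformative genes in the top %d: %d of %d\n",
            length(truth$informative),
            sum(ranked$gene_id[seq_along(truth$informative)] %in%
                  truth$informative),
            length(truth$informative)))
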