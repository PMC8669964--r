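#!/usr/bin/env Rscript
# Stage 5 — decision-rule extraction from the compact gene panel.
#
# Trains a CART tree on all samples using the compact panel chosen by the
# tree-classifier IFS curve, extracts one IF-THEN rule per leaf, verifies
# that the rules reproduce the tree exactly, and summarizes rules, criteria
# and distinct genes per class.

source("analysis/00_config.R")

dataset <- read_expression(study_path("matrix.tsv"), study_path("labels.tsv"),
                           min_class_size = 10, scale = "log2")
ranked <- read_ranked_list(study_path("ranked_genes.tsv"))
selection <- jsonlite::fromJSON(file.path(STUDY_DIR, "selection.json"))

k <- selection$tree$compact$k
panel <- ranked$gene_id[seq_len(k)]
cat(sprintf("Training the rule tree on all %d samples with the compact %d-gene panel\n",
            nrow(dataset$values), k))

x <- dataset$values[, panel, drop = FALSE]
tree <- train_tree(x, dataset$labels,
                   seed = stage_seed(STUDY_SEED, "rules"))
rules <- extract_rules(tree)
write_rules(rules, study_path("rules.jsonl"), study_path("rules.txt"))

fidelity <- mean(predict_rules(rules, x) == predict(tree, x))
cat(sprintf("%d rules extracted; rule/tree agreement on training samples: %.0f%%\n",
            length(rules$rules), 100 * fidelity))

summ <- summarize_rules(rules)
writeLines(c("# per-class decision-rule summary",
             "class\tn_rules\tn_criteria\tn_genes",
             paste(summ$class, summ$n_rules, summ$n_criteria, summ$n_genes,
                   sep = "\t")),
           study_path("rule_summary.tsv"))
cat("\nPer-class summary (rules / criteria / distinct genes):\n")
print(summ, row.names = FALSE)
cat("\nFirst rule:\n")
r1 <- rules$rules[[1]]
cat(sprintf("  IF %s THEN class = %s (support %d)\n",
            paste(sprintf("%s %s %.2f", r1$criteria$gene_id,
                          r1$criteria$comparator, r1$criteria$threshold),
                  collapse = " AND "),
            r1$class, r1$support))
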