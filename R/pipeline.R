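# Orchestration of the full chain (simulate/load -> Boruta -> mRMR -> IFS
# per classifier -> optimal/compact selection -> decision rules) from one
# config, with stage logging and resumable on-disk artifacts.

#' Build and validate a pipeline configuration
#'
#' The config is a nested list (or a YAML file of the same shape) with:
#' \describe{
#'   \item{input}{either `list(matrix = path, labels = path)` or
#'     `list(synthetic = <synthetic_spec fields>)` — exactly one.}
#'   \item{min_class_size}{classes smaller than this are dropped on load
#'     (default 10; also applied to synthetic data for symmetry).}
#'   \item{boruta}{`max_iter`, `alpha`, `num_trees`.}
#'   \item{mrmr}{`criterion` ("MID"/"MIQ"), `sigma`, `n_select`.}
#'   \item{ifs}{`classifiers` (subset of "tree","margin"), `step`, `max_k`,
#'     `folds`, `tolerance`, `smote` (`apply`, `k_neighbors`, `scope`).}
#'   \item{rules}{`from` — which classifier's compact panel the rule tree
#'     uses (default "tree"); `balance` — train the rule tree on
#'     SMOTE-balanced samples (default FALSE).}
#'   \item{seed}{global seed; per-stage seeds are derived from it.}
#'   \item{out_dir}{artifact directory.}
#' }
#'
#' @param config a list as above, or the path to a YAML file.
#' @return a validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  err <- function(path, msg) stop(sprintf("config$%s: %s", path, msg),
                                  call. = FALSE)
  inp <- config$input
  if (is.null(inp)) err("input", "missing")
  has_files <- !is.null(inp$matrix) || !is.null(inp$labels)
  has_synth <- !is.null(inp$synthetic)
  if (has_files == has_synth)
    err("input", "exactly one of {matrix+labels, synthetic} must be given")
  if (has_files && (is.null(inp$matrix) || is.null(inp$labels)))
    err("input", "both matrix and labels paths are required")
  if (has_synth)
    do.call(synthetic_spec, inp$synthetic)  # validates, errors name fields
  if (is.null(config$out_dir)) err("out_dir", "missing")
  if (is.null(config$seed)) config$seed <- 1L
  assert_scalar_number(config$seed, "seed", lower = 0)

  config$min_class_size <- config$min_class_size %||% 10L
  config$boruta <- utils::modifyList(
    list(max_iter = 100L, alpha = 0.05, num_trees = 500L),
    config$boruta %||% list())
  config$mrmr <- utils::modifyList(
    list(criterion = "MID", sigma = 1, n_select = NULL),
    config$mrmr %||% list())
  if (!config$mrmr$criterion %in% c("MID", "MIQ"))
    err("mrmr$criterion", "must be 'MID' or 'MIQ'")
  config$ifs <- utils::modifyList(
    list(classifiers = c("tree", "margin"), step = 10L, max_k = NULL,
         folds = 10L, tolerance = 0.025,
         smote = list(apply = TRUE, k_neighbors = 5L, scope = "fold")),
    config$ifs %||% list())
  bad <- setdiff(config$ifs$classifiers, c("tree", "margin"))
  if (length(bad)) err("ifs$classifiers",
                       paste("unknown classifier:", paste(bad, collapse = ", ")))
  config$rules <- utils::modifyList(
    list(from = "tree", balance = FALSE), config$rules %||% list())
  if (!config$rules$from %in% config$ifs$classifiers)
    err("rules$from", "must name one of the IFS classifiers")
  structure(config, class = "pipeline_config")
}

#' Run the full biomarker-discovery pipeline
#'
#' Stages run in order: dataset (simulate or load), Boruta screening, mRMR
#' ranking of the retained genes, IFS per classifier, optimal/compact
#' selection, and rule extraction from a CART tree trained on all samples
#' with the compact gene panel. Every stage writes its artifact into
#' `out_dir` and is skipped on rerun when its artifact already exists
#' (unless `force = TRUE`), so interrupted runs resume.
#'
#' @param config a [pipeline_config()] (or a list/YAML path coercible to
#'   one).
#' @param force rerun all stages even when artifacts exist.
#' @return invisibly, a list with the in-memory stage results (`dataset`,
#'   `truth` (synthetic only), `boruta`, `ranked`, `curves`, `selection`,
#'   `rules`, `rule_summary`) and `paths` to the written artifacts.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    matrix = file.path(config$out_dir, "dataset_matrix.tsv"),
    labels = file.path(config$out_dir, "dataset_labels.tsv"),
    truth = file.path(config$out_dir, "ground_truth.json"),
    retained = file.path(config$out_dir, "boruta_retained.tsv"),
    ranked = file.path(config$out_dir, "ranked_genes.tsv"),
    selection = file.path(config$out_dir, "selection.json"),
    rules = file.path(config$out_dir, "rules.jsonl"),
    rules_txt = file.path(config$out_dir, "rules.txt"),
    rule_summary = file.path(config$out_dir, "rule_summary.tsv"),
    log = file.path(config$out_dir, "run.log"),
    meta = file.path(config$out_dir, "run_meta.json"))
  for (cl in config$ifs$classifiers)
    paths[[paste0("curve_", cl)]] <-
      file.path(config$out_dir, sprintf("ifs_curve_%s.tsv", cl))

  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   sprintf(...))
    message(msg)
    cat(msg, "\n", file = paths$log, append = TRUE)
  }
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_line("stage %-9s done in %.1fs", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  res <- list(paths = paths)

  ## dataset -----------------------------------------------------------
  synth <- !is.null(config$input$synthetic)
  res$dataset <- stage("dataset", {
    if (!force && file.exists(paths$matrix) && file.exists(paths$labels)) {
      read_expression(paths$matrix, paths$labels,
                      min_class_size = config$min_class_size,
                      scale = if (synth) "log2" else "raw")
    } else if (synth) {
      spec <- do.call(synthetic_spec, config$input$synthetic)
      gen <- generate_dataset(spec)
      res$truth <- gen$truth
      write_expression(gen$dataset, paths$matrix, paths$labels)
      writeLines(jsonlite::toJSON(gen$truth, auto_unbox = FALSE,
                                  pretty = TRUE), paths$truth)
      gen$dataset
    } else {
      d <- read_expression(config$input$matrix, config$input$labels,
                           min_class_size = config$min_class_size)
      write_expression(d, paths$matrix, paths$labels)
      d
    }
  })
  if (synth && is.null(res$truth) && file.exists(paths$truth))
    res$truth <- jsonlite::fromJSON(paths$truth)

  ## boruta -------------------------------------------------------------
  res$boruta <- stage("boruta", {
    if (!force && file.exists(paths$retained)) {
      d <- utils::read.table(paths$retained, header = TRUE, sep = "\t",
                             comment.char = "#")
      structure(list(confirmed = d$gene_id[d$status == "confirmed"],
                     rejected = d$gene_id[d$status == "rejected"],
                     tentative = character(0),
                     hit_counts = stats::setNames(d$hits, d$gene_id),
                     n_iterations = NA_integer_),
                class = "boruta_result")
    } else {
      b <- run_boruta(res$dataset, max_iter = config$boruta$max_iter,
                      alpha = config$boruta$alpha,
                      num_trees = config$boruta$num_trees,
                      seed = stage_seed(config$seed, "boruta"))
      st <- stats::setNames(rep("rejected", length(b$hit_counts)),
                            names(b$hit_counts))
      st[b$confirmed] <- "confirmed"
      writeLines(c("# Boruta screening result",
                   "gene_id\tstatus\thits",
                   paste(names(b$hit_counts), st[names(b$hit_counts)],
                         b$hit_counts, sep = "\t")), paths$retained)
      b
    }
  })
  if (length(res$boruta$confirmed) == 0L)
    stop("stage 'boruta' failed: no gene was confirmed", call. = FALSE)

  ## mrmr ---------------------------------------------------------------
  res$ranked <- stage("mrmr", {
    if (!force && file.exists(paths$ranked)) read_ranked_list(paths$ranked)
    else {
      r <- rank_mrmr(res$dataset, candidate_genes = res$boruta$confirmed,
                     n_select = config$mrmr$n_select,
                     criterion = config$mrmr$criterion,
                     sigma = config$mrmr$sigma)
      write_ranked_list(r, paths$ranked)
      r
    }
  })

  ## ifs ----------------------------------------------------------------
  res$curves <- list()
  for (cl in config$ifs$classifiers) {
    pth <- paths[[paste0("curve_", cl)]]
    res$curves[[cl]] <- stage(paste0("ifs_", cl), {
      if (!force && file.exists(pth)) read_ifs_curve(pth)
      else {
        cur <- run_ifs(res$dataset, res$ranked,
                       classifier = classifier_spec(cl, seed = config$seed),
                       step = config$ifs$step, max_k = config$ifs$max_k,
                       K_folds = config$ifs$folds,
                       seed = stage_seed(config$seed, paste0("ifs_", cl)),
                       smote = config$ifs$smote)
        write_ifs_curve(cur, pth)
        cur
      }
    })
  }

  ## selection ----------------------------------------------------------
  res$selection <- stage("selection", {
    sel <- lapply(res$curves, function(cur) {
      opt <- select_optimal(cur)
      cmp <- select_compact(cur, tolerance = config$ifs$tolerance)
      list(optimal = list(k = opt$k, mcc = opt$mcc,
                          overall_accuracy = opt$overall_accuracy),
           compact = list(k = cmp$k, mcc = cmp$mcc,
                          overall_accuracy = cmp$overall_accuracy))
    })
    writeLines(jsonlite::toJSON(sel, auto_unbox = TRUE, digits = I(10),
                                pretty = TRUE), paths$selection)
    sel
  })

  ## rules --------------------------------------------------------------
  res$rules <- stage("rules", {
    if (!force && file.exists(paths$rules)) read_rules(paths$rules)
    else {
      k <- res$selection[[config$rules$from]]$compact$k
      genes <- res$ranked$gene_id[seq_len(k)]
      x <- classifier_matrix(res$dataset)[, genes, drop = FALSE]
      y <- res$dataset$labels
      if (isTRUE(config$rules$balance)) {
        bal <- smote_balance(x, y,
                             k_neighbors = config$ifs$smote$k_neighbors %||% 5L,
                             seed = stage_seed(config$seed, "rules_smote"))
        x <- bal$values
        y <- bal$labels
      }
      tree <- train_tree(x, y, seed = stage_seed(config$seed, "rules"))
      rl <- extract_rules(tree)
      write_rules(rl, paths$rules, paths$rules_txt)
      rl
    }
  })
  res$rule_summary <- stage("summary", {
    s <- summarize_rules(res$rules)
    writeLines(c("# per-class decision-rule summary",
                 "class\tn_rules\tn_criteria\tn_genes",
                 paste(s$class, s$n_rules, s$n_criteria, s$n_genes,
                       sep = "\t")), paths$rule_summary)
    s
  })

  ## provenance ---------------------------------------------------------
  meta <- list(
    seed = config$seed,
    stage_seeds = list(boruta = stage_seed(config$seed, "boruta"),
                       rules = stage_seed(config$seed, "rules")),
    input_checksums = as.list(tools::md5sum(c(paths$matrix, paths$labels))),
    n_samples = nrow(res$dataset$values),
    n_genes = ncol(res$dataset$values),
    n_retained = length(res$boruta$confirmed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             paths$meta)
  log_line("pipeline complete: %d retained genes, %d ranked, %d rules",
           length(res$boruta$confirmed), nrow(res$ranked),
           length(res$rules$rules))
  invisible(res)
}
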