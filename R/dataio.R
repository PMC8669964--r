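# Readers/writers for the pipeline's text artifacts. Everything is plain
# TSV/JSON-lines (UTF-8, "." decimal, gzip accepted transparently by fread)
# and every writer/reader pair is a lossless round trip.

#' Read an expression matrix and its sample labels
#'
#' The matrix TSV must have a header row and a first column of identifiers;
#' orientation (samples as rows vs genes as rows) is auto-detected by
#' matching identifiers against the label file, and genes-as-rows input is
#' transposed. Classes with fewer than `min_class_size` samples are dropped
#' together with their samples — small classes cannot support stratified
#' cross-validation.
#'
#' @param matrix_path path to the expression TSV (optionally gzipped).
#' @param labels_path path to a two-column TSV mapping sample id to class
#'   name (header row required).
#' @param min_class_size classes with fewer samples than this are dropped
#'   (default 10).
#' @param scale scale of the stored values, `"raw"` (default) or `"log2"`.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path, min_class_size = 10L,
                            scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  lab <- data.table::fread(labels_path, header = TRUE, sep = "\t",
                           colClasses = "character", data.table = FALSE)
  if (ncol(lab) < 2L)
    stop("labels file must have two columns: sample id, class name",
         call. = FALSE)
  lab_ids <- lab[[1L]]
  lab_cls <- lab[[2L]]
  if (anyDuplicated(lab_ids))
    stop("duplicate sample ids in labels file: ",
         paste(unique(lab_ids[duplicated(lab_ids)]), collapse = ", "),
         call. = FALSE)

  mat <- data.table::fread(matrix_path, header = TRUE, sep = "\t",
                           data.table = FALSE)
  row_ids <- as.character(mat[[1L]])
  col_ids <- colnames(mat)[-1L]
  num <- mat[, -1L, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    j <- which(bad)[1L]
    i <- which(is.na(suppressWarnings(as.numeric(num[[j]]))))[1L]
    stop(sprintf("non-numeric expression value at row '%s', column '%s'",
                 row_ids[min(i, length(row_ids))], col_ids[j]), call. = FALSE)
  }
  values <- as.matrix(num)
  rownames(values) <- row_ids

  # orientation: whichever axis overlaps the label ids more holds samples
  if (sum(col_ids %in% lab_ids) > sum(row_ids %in% lab_ids))
    values <- t(values)
  missing <- setdiff(rownames(values), lab_ids)
  if (length(missing))
    stop("samples present in matrix but absent from labels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)

  cls <- stats::setNames(lab_cls, lab_ids)[rownames(values)]
  keep_classes <- names(which(table(cls) >= min_class_size))
  if (length(keep_classes) == 0L)
    stop("all classes have fewer than min_class_size = ", min_class_size,
         " samples", call. = FALSE)
  keep <- cls %in% keep_classes
  expression_dataset(values[keep, , drop = FALSE], cls[keep], scale = scale)
}

#' Write an expression dataset as matrix + label TSVs
#'
#' @param dataset an [expression_dataset()].
#' @param matrix_path,labels_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(dataset, matrix_path, labels_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  header <- paste(c("sample_id", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], fmt_num(v[i, ])), collapse = "\t"), character(1))
  writeLines(c(header, rows), matrix_path)
  writeLines(c("sample_id\tclass",
               paste(rownames(v), as.character(dataset$labels), sep = "\t")),
             labels_path)
  invisible(c(matrix_path, labels_path))
}

#' Construct a ranked feature list
#'
#' @param gene_ids character vector, best-ranked gene first.
#' @param scores per-rank value of the selection criterion.
#' @return an object of class `ranked_features` (a data.frame with columns
#'   `rank`, `gene_id`, `score`).
#' @export
ranked_features <- function(gene_ids, scores) {
  stopifnot(is.character(gene_ids), length(gene_ids) == length(scores))
  if (anyDuplicated(gene_ids))
    stop("ranked feature list contains duplicate gene ids", call. = FALSE)
  structure(data.frame(rank = seq_along(gene_ids), gene_id = gene_ids,
                       score = as.numeric(scores)),
            class = c("ranked_features", "data.frame"))
}

#' Write/read a ranked feature list
#'
#' @param ranked a [ranked_features()] object.
#' @param path output TSV path.
#' @return `write_ranked_list` invisibly returns `path`; `read_ranked_list`
#'   returns the [ranked_features()] object.
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_features"))
  writeLines(c("# ranked gene list: rank 1 = most important",
               "# columns: rank, gene_id, selection-criterion score",
               "rank\tgene_id\tscore",
               paste(ranked$rank, ranked$gene_id, fmt_num(ranked$score),
                     sep = "\t")), path)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         colClasses = c("integer", "character", "numeric"))
  ranked_features(d$gene_id, d$score)
}

#' Write/read an IFS curve
#'
#' The TSV carries one row per evaluated subset size with columns `k`,
#' `overall_accuracy`, `mcc`, then one per-class accuracy column per class.
#'
#' @param curve an `ifs_curve` (see [run_ifs()]).
#' @param path output TSV path.
#' @return `write_ifs_curve` invisibly returns `path`; `read_ifs_curve`
#'   returns the `ifs_curve`.
#' @export
write_ifs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  rec <- curve$records
  acc_cols <- paste0("acc.", curve$class_names)
  header <- c(
    "# incremental feature selection curve",
    sprintf("# classifier: %s; cv_seed: %d; smote: %s",
            curve$classifier$kind, curve$seed, curve$smote_scope),
    "# columns: k (subset size), overall_accuracy, mcc, then per-class accuracy",
    paste(c("k", "overall_accuracy", "mcc", acc_cols), collapse = "\t"))
  rows <- vapply(seq_len(nrow(rec)), function(i)
    paste(c(rec$k[i], fmt_num(rec$overall_accuracy[i]), fmt_num(rec$mcc[i]),
            fmt_num(unlist(rec[i, acc_cols]))), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ifs_curve
#' @export
read_ifs_curve <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# classifier:", lines, value = TRUE)
  kind <- sub("^# classifier: ([a-z]+);.*$", "\\1", meta)
  seed <- as.integer(sub("^.*cv_seed: ([0-9]+);.*$", "\\1", meta))
  scope <- sub("^.*smote: ", "", meta)
  d <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                         sep = "\t")
  class_names <- sub("^acc\\.", "", grep("^acc\\.", colnames(d), value = TRUE))
  structure(list(records = d, class_names = class_names,
                 classifier = list(kind = kind), seed = seed,
                 smote_scope = scope),
            class = "ifs_curve")
}

#' Write/read a decision-rule set
#'
#' Rules are written twice: a machine-readable JSON-lines file (one rule per
#' line) and a human-readable indented IF-THEN text file.
#'
#' @param rules a `rule_set` (see [extract_rules()]).
#' @param path path of the JSON-lines file.
#' @param text_path optional path of the IF-THEN text rendering; default
#'   `path` with extension replaced by `.txt`.
#' @return `write_rules` invisibly returns the paths written; `read_rules`
#'   reconstructs the `rule_set` from the JSON-lines file.
#' @export
write_rules <- function(rules, path, text_path = NULL) {
  stopifnot(inherits(rules, "rule_set"))
  if (is.null(text_path)) text_path <- sub("\\.[A-Za-z]+$", ".txt", path)
  if (identical(text_path, path)) text_path <- paste0(path, ".txt")
  hdr <- sprintf(
    "{\"header\":{\"n_rules\":%d,\"classes\":[%s]}}",
    length(rules$rules),
    paste(sprintf("\"%s\"", rules$class_names), collapse = ","))
  lines <- vapply(rules$rules, function(r) {
    crit <- if (nrow(r$criteria) == 0L) "[]" else paste0(
      "[", paste(sprintf("{\"gene_id\":\"%s\",\"comparator\":\"%s\",\"threshold\":%s}",
                         r$criteria$gene_id, r$criteria$comparator,
                         fmt_num(r$criteria$threshold)), collapse = ","), "]")
    sprintf("{\"class\":\"%s\",\"support\":%d,\"criteria\":%s}",
            r$class, r$support, crit)
  }, character(1))
  writeLines(c(hdr, lines), path)

  txt <- unlist(lapply(seq_along(rules$rules), function(i) {
    r <- rules$rules[[i]]
    cond <- if (nrow(r$criteria) == 0L) "    TRUE" else
      sprintf("    %s %s %s", r$criteria$gene_id, r$criteria$comparator,
              fmt_num(r$criteria$threshold))
    c(sprintf("Rule %d (support %d):", i, r$support), "  IF",
      paste(cond, collapse = " AND\n"),
      sprintf("  THEN class = %s", r$class), "")
  }))
  writeLines(c(sprintf("# %d decision rules", length(rules$rules)), txt),
             text_path)
  invisible(c(path, text_path))
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1L])
  rules <- lapply(lines[-1L], function(l) {
    r <- jsonlite::fromJSON(l)
    crit <- if (length(r$criteria) == 0L)
      data.frame(gene_id = character(0), comparator = character(0),
                 threshold = numeric(0))
    else data.frame(gene_id = r$criteria$gene_id,
                    comparator = r$criteria$comparator,
                    threshold = r$criteria$threshold)
    list(class = r$class, support = as.integer(r$support), criteria = crit)
  })
  structure(list(rules = rules,
                 class_names = as.character(hdr$header$classes)),
            class = "rule_set")
}
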