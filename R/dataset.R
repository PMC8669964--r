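#' Construct a labeled expression dataset
#'
#' The universal container of the pipeline: a samples x genes numeric matrix
#' with a class label per sample. Class names are always mapped to factor
#' levels in lexicographic order so the encoding is deterministic across
#' runs and file orderings.
#'
#' @param values numeric matrix, samples as rows, genes as columns; dimnames
#'   give sample and gene identifiers.
#' @param labels character or factor of per-sample class names.
#' @param scale `"raw"` for non-negative expression values (e.g. TPM) or
#'   `"log2"` for values already on a log2 scale. Classifiers transform raw
#'   values by `log2(x + 1)` before fitting; log2 data is used as-is.
#' @return an object of class `expression_dataset`: a list with elements
#'   `values`, `labels` (factor), `scale`.
#' @export
expression_dataset <- function(values, labels, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x genes)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry sample ids (rownames) and gene ids (colnames)",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  if (length(labels) != nrow(values))
    stop("length(labels) must equal the number of samples", call. = FALSE)
  if (scale == "raw" && any(values < 0))
    stop("raw-scale expression values must be non-negative", call. = FALSE)
  labels <- factor(as.character(labels),
                   levels = sort(unique(as.character(labels))))
  structure(list(values = values, labels = labels, scale = scale),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d samples x %d genes (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("classes:",
      paste(sprintf("%s (%d)", levels(x$labels), tabulate(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

n_classes <- function(dataset) nlevels(dataset$labels)

# Matrix the classifiers actually see: raw data goes through log2(x + 1).
classifier_matrix <- function(dataset) {
  if (dataset$scale == "raw") log2(dataset$values + 1) else dataset$values
}
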