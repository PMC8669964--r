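# Max-relevance/min-redundancy feature ranking. Continuous expression is
# discretized into three bins around the mean, relevance and redundancy are
# empirical mutual information (bits), and genes are selected greedily by
# the MID (difference) or MIQ (quotient) criterion.

#' Discretize a continuous variable into three bins
#'
#' Bin boundaries are `mean - sigma * sd` and `mean + sigma * sd` with the
#' population standard deviation: code 0 below the lower boundary, 2 above
#' the upper, 1 otherwise. A constant vector collapses to all-1 codes.
#'
#' @param values numeric vector.
#' @param sigma boundary width in standard deviations (default 1).
#' @return an object of class `discretized_variable`: list with `codes`
#'   (integers in `0..n_bins-1`) and `n_bins`.
#' @export
discretize <- function(values, sigma = 1) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  assert_scalar_number(sigma, "sigma")
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  codes <- 1L + as.integer(values > m + sigma * s) -
    as.integer(values < m - sigma * s)
  as_discretized(codes, 3L)
}

#' @rdname discretize
#' @param codes integer codes in `0..n_bins-1`.
#' @param n_bins number of levels.
#' @export
as_discretized <- function(codes, n_bins) {
  codes <- as.integer(codes)
  n_bins <- as.integer(n_bins)
  if (anyNA(codes) || any(codes < 0L) || any(codes >= n_bins))
    stop("codes must lie in 0..n_bins-1", call. = FALSE)
  structure(list(codes = codes, n_bins = n_bins),
            class = "discretized_variable")
}

#' Empirical mutual information of two discretized variables
#'
#' Computed from the empirical joint frequency table in bits (log base 2),
#' with the convention `0 * log 0 = 0`. Always non-negative and symmetric.
#'
#' @param a,b `discretized_variable` objects of equal length.
#' @return mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  stopifnot(inherits(a, "discretized_variable"),
            inherits(b, "discretized_variable"))
  if (length(a$codes) != length(b$codes))
    stop("variables have different lengths", call. = FALSE)
  mi_codes(a$codes, a$n_bins, b$codes, b$n_bins)
}

# MI on bare integer code vectors (0-based); hot path of rank_mrmr.
mi_codes <- function(ca, Ba, cb, Bb) {
  n <- length(ca)
  joint <- tabulate(ca * Bb + cb + 1L, Ba * Bb) / n
  pa <- tabulate(ca + 1L, Ba) / n
  pb <- tabulate(cb + 1L, Bb) / n
  # joint index i*Bb + j + 1: b-level varies fastest, so transpose the outer
  pp <- as.vector(t(outer(pa, pb)))
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / pp[nz]))
}

#' Rank genes by max-relevance/min-redundancy
#'
#' Greedy mRMR: the first gene maximizes mutual information with the class
#' label; each subsequent gene maximizes relevance minus mean redundancy
#' with the already-selected genes (`MID`) or relevance divided by mean
#' redundancy (`MIQ`). Ties are broken by candidate order (stable), so the
#' ranking is fully deterministic.
#'
#' @param dataset an [expression_dataset()].
#' @param candidate_genes character vector of gene ids to rank (default all
#'   genes); typically the Boruta-retained set.
#' @param n_select number of genes to rank (default: all candidates; clamped
#'   to the candidate count).
#' @param criterion `"MID"` (difference form, default) or `"MIQ"` (quotient).
#' @param sigma discretization boundary width (see [discretize()]).
#' @return a [ranked_features()] object; `score` holds the criterion value
#'   at each selection step (pure relevance for rank 1).
#' @export
rank_mrmr <- function(dataset, candidate_genes = NULL, n_select = NULL,
                      criterion = c("MID", "MIQ"), sigma = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  criterion <- match.arg(criterion)
  genes <- colnames(dataset$values)
  candidate_genes <- candidate_genes %||% genes
  if (length(candidate_genes) == 0L)
    stop("candidate gene set is empty", call. = FALSE)
  if (!all(candidate_genes %in% genes))
    stop("unknown candidate genes: ",
         paste(setdiff(candidate_genes, genes), collapse = ", "),
         call. = FALSE)
  p <- length(candidate_genes)
  n_select <- min(n_select %||% p, p)
  if (n_select < 1L) stop("n_select must be >= 1", call. = FALSE)

  codes <- vapply(candidate_genes,
                  function(g) discretize(dataset$values[, g], sigma)$codes,
                  integer(nrow(dataset$values)))
  ycodes <- as.integer(dataset$labels) - 1L
  C <- nlevels(dataset$labels)
  relevance <- vapply(seq_len(p),
                      function(j) mi_codes(codes[, j], 3L, ycodes, C),
                      numeric(1))

  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)
  remaining <- rep(TRUE, p)
  for (step in seq_len(n_select)) {
    if (step == 1L) {
      crit <- relevance
    } else {
      mean_red <- red_sum / length(selected)
      crit <- if (criterion == "MID") relevance - mean_red
              else relevance / pmax(mean_red, .Machine$double.eps)
    }
    crit[!remaining] <- -Inf
    pick <- which.max(crit)  # first maximum = stable candidate-order tie-break
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    remaining[pick] <- FALSE
    if (step < n_select) {
      upd <- which(remaining)
      red_sum[upd] <- red_sum[upd] + vapply(
        upd, function(j) mi_codes(codes[, j], 3L, codes[, pick], 3L),
        numeric(1))
    }
  }
  ranked_features(candidate_genes[selected], scores)
}
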