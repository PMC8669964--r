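#' Specify a synthetic multiclass expression dataset
#'
#' Describes a generative model that mimics the structure of multiclass
#' tumor-typing expression data: a handful of class-informative genes, a set
#' of redundant genes that are noisy copies of informative ones, and a large
#' majority of class-independent noise genes, all on a heavy-tailed
#' non-negative expression scale (log-normal).
#'
#' Each informative gene is "on" (its log2 mean shifted up by `effect_size`)
#' in a random nonempty proper subset of classes, so no single gene can
#' separate all classes and multi-gene panels/rules are required — the
#' structure that makes downstream recovery tests meaningful.
#'
#' @param n_classes number of classes (>= 2).
#' @param class_sizes integer vector of per-class sample counts (each >= 2);
#'   may be unbalanced.
#' @param n_informative number of genes carrying class signal.
#' @param n_redundant number of genes that are noisy copies of randomly
#'   chosen informative genes.
#' @param n_noise number of class-independent genes.
#' @param effect_size mean log2-scale shift of an informative gene in its
#'   signal classes.
#' @param noise_sd within-class log2-scale standard deviation.
#' @param redundancy_sd sd of the log2-scale noise added to redundant copies.
#' @param seed integer RNG seed; identical specs (seed included) generate
#'   bit-identical datasets.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes, class_sizes, n_informative,
                           n_redundant = 0L, n_noise = 0L,
                           effect_size = 2, noise_sd = 0.5,
                           redundancy_sd = 0.25, seed = 1L) {
  chk_count <- function(x, name, lower) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < lower)
      stop(sprintf("invalid synthetic_spec field '%s': must be an integer >= %d",
                   name, lower), call. = FALSE)
    as.integer(x)
  }
  n_classes <- chk_count(n_classes, "n_classes", 2L)
  if (!is.numeric(class_sizes) || length(class_sizes) != n_classes ||
      anyNA(class_sizes) || any(class_sizes != round(class_sizes)) ||
      any(class_sizes < 2))
    stop("invalid synthetic_spec field 'class_sizes': must be ",
         n_classes, " integers, each >= 2", call. = FALSE)
  n_informative <- chk_count(n_informative, "n_informative", 0L)
  n_redundant <- chk_count(n_redundant, "n_redundant", 0L)
  n_noise <- chk_count(n_noise, "n_noise", 0L)
  if (n_informative + n_redundant + n_noise < 1L)
    stop("invalid synthetic_spec field 'n_informative': total gene count is zero",
         call. = FALSE)
  if (n_redundant > 0L && n_informative < 1L)
    stop("invalid synthetic_spec field 'n_redundant': redundant genes need ",
         "at least one informative parent", call. = FALSE)
  assert_scalar_number(effect_size, "effect_size")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(redundancy_sd, "redundancy_sd", lower = 0)
  seed <- chk_count(seed, "seed", 0L)
  structure(list(n_classes = n_classes,
                 class_sizes = as.integer(class_sizes),
                 n_informative = n_informative, n_redundant = n_redundant,
                 n_noise = n_noise, effect_size = effect_size,
                 noise_sd = noise_sd, redundancy_sd = redundancy_sd,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Draws log2 expression as Normal(baseline + class shift, `noise_sd`) with a
#' per-gene baseline Uniform(1, 8); `scale = "raw"` exponentiates to the
#' non-negative TPM-like scale, `scale = "log2"` (default) returns the log2
#' values directly.
#'
#' @param spec a [synthetic_spec()].
#' @param scale output scale, `"log2"` (default) or `"raw"`.
#' @return a list with elements `dataset` (an [expression_dataset()]) and
#'   `truth`, a list with `informative`, `redundant`, `noise` gene-id sets,
#'   `redundant_parent` (named character: redundant gene -> its informative
#'   source), and `signal_classes` (per informative gene, the class names in
#'   which it is shifted).
#' @export
generate_dataset <- function(spec, scale = c("log2", "raw")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  scale <- match.arg(scale)
  C <- spec$n_classes
  n <- sum(spec$class_sizes)
  m <- spec$n_informative + spec$n_redundant + spec$n_noise
  gene_ids <- sprintf("G%06d", seq_len(m))
  info_ids <- gene_ids[seq_len(spec$n_informative)]
  red_ids <- gene_ids[spec$n_informative + seq_len(spec$n_redundant)]
  noise_ids <- gene_ids[spec$n_informative + spec$n_redundant + seq_len(spec$n_noise)]
  class_names <- sprintf("class%02d", seq_len(C))
  labels <- rep(class_names, spec$class_sizes)
  sample_ids <- sprintf("S%04d", seq_len(n))
  lab_idx <- rep(seq_len(C), spec$class_sizes)

  with_seed(spec$seed, {
    baseline <- stats::runif(m, 1, 8)
    # signal-class subsets: each informative gene is on in 1..C-1 classes
    signal_classes <- lapply(seq_len(spec$n_informative), function(i) {
      k <- sample.int(C - 1L, 1L)
      sort(sample.int(C, k))
    })
    mu <- matrix(rep(baseline, each = n), nrow = n, ncol = m,
                 dimnames = list(sample_ids, gene_ids))
    for (i in seq_len(spec$n_informative)) {
      on_rows <- lab_idx %in% signal_classes[[i]]
      mu[on_rows, i] <- mu[on_rows, i] + spec$effect_size
    }
    logx <- mu + matrix(stats::rnorm(n * m, 0, spec$noise_sd), nrow = n)
    parent_of <- character(0)
    if (spec$n_redundant > 0L) {
      parents <- sample.int(spec$n_informative, spec$n_redundant, replace = TRUE)
      parent_of <- stats::setNames(info_ids[parents], red_ids)
      for (j in seq_len(spec$n_redundant)) {
        col <- spec$n_informative + j
        logx[, col] <- logx[, parents[j]] +
          stats::rnorm(n, 0, spec$redundancy_sd)
      }
    }
  })

  values <- if (scale == "raw") 2^logx else logx
  dataset <- expression_dataset(values, labels, scale = scale)
  truth <- list(informative = info_ids, redundant = red_ids,
                noise = noise_ids, redundant_parent = parent_of,
                signal_classes = stats::setNames(
                  lapply(signal_classes, function(s) class_names[s]),
                  info_ids))
  list(dataset = dataset, truth = truth)
}
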