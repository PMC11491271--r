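#' Load gene sets from a GMT file
#'
#' GMT lines are tab-separated: set name, description, then member genes.
#' Members are deduplicated; an empty set or a duplicate set name is an
#' error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (a gene-set collection).
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short)) {
    stop("GMT line(s) without members in ", path, ": line(s) ",
         paste(which(short), collapse = ", "))
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty)) stop("empty gene set(s): ", paste(names_[empty],
                                                    collapse = ", "))
  setNames(sets, names_)
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Per-sample gene-set activity scores (rank-based GSVA-style walk)
#'
#' Computes a signed enrichment score for each gene set in each sample from
#' gene-level back-splicing. The procedure is the deterministic rank/ECDF
#' form of single-sample gene-set variation scoring:
#' \enumerate{
#'   \item per gene, the expression-level statistic is the empirical CDF of
#'     the gene across samples (average ranks for ties, divided by the
#'     number of samples);
#'   \item per sample, genes are ordered by decreasing statistic (ties broken
#'     by row name for reproducibility); the rank weight is `|z|` with `z`
#'     the centred rank `(N + 1)/2 - position`;
#'   \item a Kuiper-like random walk steps through the ordering: genes in the
#'     set add `|z|^tau / sum_set |z|^tau`, genes outside subtract
#'     `1 / (N - set size)`;
#'   \item the score is the maximum positive deviation plus the minimum
#'     negative deviation of the walk (the signed `max_diff` convention), so
#'     it always lies in `[-1, 1]`. A positive score means the set's genes
#'     concentrate at the top of the sample's back-splicing ranking.
#' }
#'
#' @param mat Gene x sample matrix (at least 3 samples).
#' @param sets Gene-set collection from [load_gmt()]. Sets are intersected
#'   with the matrix rows; a set with fewer than 2 matrix genes is skipped
#'   with a warning.
#' @param tau Rank-weight exponent (default 1).
#' @return Matrix of scores, sets x samples.
#' @export
gsva_scores <- function(mat, sets, tau = 1) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3) stop("need at least 3 samples for activity scoring")
  if (is.null(rownames(mat))) stop("matrix must have gene row names")
  n <- ncol(mat); N <- nrow(mat)
  ecdf_stat <- t(apply(mat, 1, rank)) / n  # ties -> average ranks

  keep <- vapply(sets, function(s) sum(s %in% rownames(mat)) >= 2, logical(1))
  if (any(!keep)) {
    warning("skipping set(s) with < 2 matrix genes: ",
            paste(names(sets)[!keep], collapse = ", "))
  }
  sets <- lapply(sets[keep], intersect, rownames(mat))
  if (!length(sets)) stop("no usable gene set")

  scores <- matrix(NA_real_, length(sets), n,
                   dimnames = list(names(sets), colnames(mat)))
  z_abs <- abs((N + 1) / 2 - seq_len(N))
  for (s in seq_len(n)) {
    ord <- order(-ecdf_stat[, s], rownames(mat))
    genes_ordered <- rownames(mat)[ord]
    w <- z_abs^tau
    for (k in seq_along(sets)) {
      in_set <- genes_ordered %in% sets[[k]]
      m <- sum(in_set)
      step <- ifelse(in_set, w / sum(w[in_set]), -1 / (N - m))
      walk <- cumsum(step)
      scores[k, s] <- max(c(0, walk[walk > 0])) + min(c(0, walk[walk < 0]))
    }
  }
  scores
}

#' Summarise hallmark back-splicing activity
#'
#' For each hallmark, the fraction of tumour samples with a positive
#' activity score; a hallmark is "active" when at least half the tumour
#' samples score positive. With a `categories` mapping, also reports the
#' count and percentage of active hallmarks per category (1-decimal
#' percentages).
#'
#' @param scores Score matrix from [gsva_scores()].
#' @param tumour_samples Column names to summarise over (e.g. the tumour
#'   group); defaults to all columns.
#' @param categories Optional named character vector mapping hallmark name
#'   to category.
#' @return `list(hallmarks, categories)`: per-hallmark `data.frame`
#'   (`hallmark`, `frac_positive`, `active`) and, when requested, the
#'   per-category `data.frame` (`category`, `n_active`, `n_total`,
#'   `percent`).
#' @export
hallmark_activity_summary <- function(scores, tumour_samples = NULL,
                                      categories = NULL) {
  if (is.null(tumour_samples)) tumour_samples <- colnames(scores)
  sub <- scores[, tumour_samples, drop = FALSE]
  frac <- rowMeans(sub > 0)
  hallmarks <- data.frame(hallmark = rownames(scores),
                          frac_positive = as.numeric(frac),
                          active = as.numeric(frac) >= 0.5,
                          stringsAsFactors = FALSE, row.names = NULL)
  cat_df <- NULL
  if (!is.null(categories)) {
    cats <- categories[hallmarks$hallmark]
    split_active <- split(hallmarks$active, cats)
    cat_df <- data.frame(
      category = names(split_active),
      n_active = vapply(split_active, sum, numeric(1)),
      n_total = vapply(split_active, length, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    cat_df$percent <- round(100 * cat_df$n_active / cat_df$n_total, 1)
  }
  list(hallmarks = hallmarks, categories = cat_df)
}

#' Hypergeometric over-representation of gene sets
#'
#' For each set, tests whether the hit genes over-represent the set within
#' the universe: with `N = |universe|`, `K = |set ∩ universe|`,
#' `n = |hits|`, `k = |set ∩ hits|`, the p-value is the upper tail
#' `P(X >= k)` of the hypergeometric distribution. q-values are BH-adjusted
#' across the sets tested.
#'
#' @param hits Character vector of hit genes (must be a subset of
#'   `universe`).
#' @param universe Character vector, the gene universe.
#' @param sets Gene-set collection.
#' @param top_n Optionally keep only the `top_n` smallest p-values.
#' @return `data.frame`: `set`, `k`, `K`, `n`, `N`, `fold`, `pvalue`,
#'   `qvalue`, ordered by p-value.
#' @export
hypergeom_enrichment <- function(hits, universe, sets, top_n = NULL) {
  hits <- unique(hits); universe <- unique(universe)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  N <- length(universe); n <- length(hits)
  K <- vapply(sets, function(s) length(intersect(s, universe)), integer(1))
  k <- vapply(sets, function(s) length(intersect(s, hits)), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  res <- data.frame(set = names(sets), k = k, K = K, n = n, N = N,
                    fold = ifelse(expected > 0, k / expected, NA_real_),
                    pvalue = p, qvalue = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$pvalue, res$set), ]
  rownames(res) <- NULL
  if (!is.null(top_n)) res <- head(res, top_n)
  res
}
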