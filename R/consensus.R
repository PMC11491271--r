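#' Read and validate a sample sheet
#'
#' The sample sheet describes the paired tumour/NAT design: one row per
#' sequencing library with its group, patient (pair) identifier and total
#' mapped reads used for normalisation.
#'
#' @param path TSV with columns `sample_id`, `group` (`tumour`/`NAT`),
#'   `pair_id`, `library_size`.
#' @return Validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "group", "pair_id", "library_size")
  if (!all(need %in% names(df))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!all(df$group %in% c("tumour", "NAT"))) {
    stop("group must be 'tumour' or 'NAT'")
  }
  if (any(df$library_size <= 0)) stop("library_size must be positive")
  tab <- table(df$pair_id, df$group)
  if (any(tab > 1)) stop("a pair_id has more than one sample per group")
  df
}

#' Merge one sample's multi-caller calls by junction
#'
#' Collapses a sample's calls to one record per distinct junction key. The
#' raw expression level of a junction in a sample is the arithmetic mean of
#' its back-splicing read counts over the callers that detected it: a caller
#' that did not report the junction contributes nothing (not an implicit
#' zero). If one caller reports the same key several times its reads are
#' summed before averaging.
#'
#' @param calls Junction call `data.frame` for a single sample.
#' @return `data.frame` with `key`, `sample_id`, `n_callers`, `callers`
#'   (comma-joined sorted ids) and `mean_reads`.
#' @export
merge_sample_calls <- function(calls) {
  validate_junction_calls(calls)
  if (nrow(calls) == 0) {
    return(data.frame(key = character(), sample_id = character(),
                      n_callers = integer(), callers = character(),
                      mean_reads = numeric(), stringsAsFactors = FALSE))
  }
  if (length(unique(calls$sample_id)) != 1) {
    stop("merge_sample_calls expects calls from exactly one sample")
  }
  key <- junction_key(calls)
  # per (key, caller) first, so duplicate rows from one caller sum
  per_caller <- rowsum(calls$bsj_reads,
                       group = paste(key, calls$caller_id, sep = "\r"))
  kc <- strsplit(rownames(per_caller), "\r", fixed = TRUE)
  k <- vapply(kc, `[[`, character(1), 1)
  caller <- vapply(kc, `[[`, character(1), 2)
  ord <- order(k, caller)
  k <- k[ord]; caller <- caller[ord]; reads <- per_caller[ord, 1]
  out <- data.frame(
    key = unique(k),
    sample_id = calls$sample_id[1],
    n_callers = as.integer(tapply(caller, k, length)[unique(k)]),
    callers = vapply(split(caller, k)[unique(k)], paste,
                     character(1), collapse = ","),
    mean_reads = as.numeric(tapply(reads, k, mean)[unique(k)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Build the high-confidence circRNA catalogue and raw expression matrix
#'
#' Applies the consensus filters: a junction survives in a sample when it was
#' detected by at least `min_callers` callers and its cross-caller mean read
#' count is at least `min_reads`; it enters the catalogue when it survives in
#' at least `min_samples` samples within the tumour group or within the NAT
#' group (`group_rule = "either"`) or pooled across both
#' (`group_rule = "pooled"`).
#'
#' By default the read threshold applies to the cross-caller mean, which is
#' the defined raw expression level; set `reads_rule = "per_caller"` to
#' require instead that every contributing caller individually reported at
#' least `min_reads` (the stricter alternative reading). The per-caller mode
#' needs per-call data, so it re-derives support from `calls` when supplied.
#'
#' @param merged Row-bound output of [merge_sample_calls()] across samples.
#' @param samples Validated sample sheet.
#' @param min_callers,min_reads,min_samples Filter thresholds (defaults 2, 2,
#'   5).
#' @param group_rule `"either"` (default) or `"pooled"`.
#' @return `list(catalog, matrix)`: the catalogue `data.frame` (`key`,
#'   `chrom`, `start`, `end`, `strand`, `n_samples_tumour`, `n_samples_nat`,
#'   `host_gene`) sorted by coordinates, and the raw expression matrix
#'   (junction keys x sample ids) holding `mean_reads` for surviving cells
#'   and 0 elsewhere, with attribute `normalised = FALSE`.
#' @export
build_catalog <- function(merged, samples, min_callers = 2, min_reads = 2,
                          min_samples = 5,
                          group_rule = c("either", "pooled")) {
  group_rule <- match.arg(group_rule)
  samples <- validate_sample_sheet(samples)
  unknown <- setdiff(unique(merged$sample_id), samples$sample_id)
  if (length(unknown)) {
    stop("merged calls reference unknown sample(s): ",
         paste(unknown, collapse = ", "))
  }
  surv <- merged[merged$n_callers >= min_callers &
                   merged$mean_reads >= min_reads, , drop = FALSE]
  grp <- setNames(samples$group, samples$sample_id)
  if (nrow(surv)) {
    in_t <- tapply(grp[surv$sample_id] == "tumour", surv$key, sum)
    in_n <- tapply(grp[surv$sample_id] == "NAT", surv$key, sum)
    keys <- names(in_t)
    keep <- if (group_rule == "either") {
      in_t >= min_samples | in_n >= min_samples
    } else {
      (in_t + in_n) >= min_samples
    }
    keys <- keys[keep]
  } else {
    keys <- character()
    in_t <- in_n <- integer()
  }
  coords <- if (length(keys)) parse_junction_key(keys) else
    data.frame(key = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character())
  catalog <- data.frame(coords,
                        n_samples_tumour = if (length(keys))
                          as.integer(in_t[keys]) else integer(),
                        n_samples_nat = if (length(keys))
                          as.integer(in_n[keys]) else integer(),
                        host_gene = rep(NA_character_, length(keys)),
                        stringsAsFactors = FALSE, row.names = NULL)
  catalog <- catalog[order(catalog$chrom, catalog$start, catalog$end,
                           catalog$strand), , drop = FALSE]
  rownames(catalog) <- NULL

  mat <- matrix(0, nrow = nrow(catalog), ncol = nrow(samples),
                dimnames = list(catalog$key, samples$sample_id))
  cells <- surv[surv$key %in% catalog$key, , drop = FALSE]
  if (nrow(cells)) {
    mat[cbind(match(cells$key, catalog$key),
              match(cells$sample_id, samples$sample_id))] <- cells$mean_reads
  }
  attr(mat, "normalised") <- FALSE
  attr(catalog, "filters") <- list(min_callers = min_callers,
                                   min_reads = min_reads,
                                   min_samples = min_samples,
                                   group_rule = group_rule)
  list(catalog = catalog, matrix = mat)
}

#' Normalise a raw expression matrix by library size
#'
#' Scales each column to reads-per-`scale` total mapped reads (counts per
#' million by default): `value * scale / library_size`.
#'
#' @param raw Raw matrix from [build_catalog()] (attribute
#'   `normalised = FALSE`).
#' @param samples Sample sheet supplying `library_size` per column.
#' @param scale Normalisation scale; default `1e6`.
#' @return Matrix of identical shape with attribute `normalised = TRUE`.
#' @export
normalize_matrix <- function(raw, samples, scale = 1e6) {
  if (isTRUE(attr(raw, "normalised"))) stop("matrix is already normalised")
  libs <- setNames(samples$library_size, samples$sample_id)
  missing_lib <- setdiff(colnames(raw), names(libs))
  if (length(missing_lib)) {
    stop("no library_size for sample(s): ", paste(missing_lib, collapse = ", "))
  }
  out <- sweep(raw, 2, libs[colnames(raw)] / scale, "/")
  attr(out, "normalised") <- TRUE
  out
}

#' Write an expression matrix as TSV with a provenance header
#' @param mat Matrix with junction/gene rows and sample columns.
#' @param path Output path.
#' @param provenance Optional named list recorded in a `#` header line.
#' @export
write_matrix_tsv <- function(mat, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", paste(names(provenance), unlist(provenance),
                                  sep = "=", collapse = " ")), con)
  }
  df <- data.frame(key = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @param normalised Value for the `normalised` attribute.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path, normalised = NA) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  attr(mat, "normalised") <- normalised
  mat
}
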