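#' Read a pan-cancer reference circRNA catalogue
#'
#' TSV with columns `key` (canonical circRNA key, same display convention as
#' [junction_key()]) and `types` (comma-separated cancer-type codes the key
#' was detected in). Matching downstream is exact on the key: no coordinate
#' slop is applied.
#'
#' @param path TSV path.
#' @return Named list mapping key to character vector of type codes.
#' @export
read_reference_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("key", "types") %in% names(df))) {
    stop("reference catalogue needs 'key' and 'types' columns")
  }
  if (anyDuplicated(df$key)) stop("duplicate keys in reference catalogue")
  types <- strsplit(df$types, ",", fixed = TRUE)
  empty <- vapply(types, length, integer(1)) == 0
  if (any(empty)) stop("reference entry with no cancer types")
  setNames(types, df$key)
}

#' Write a reference catalogue
#' @param reference Named list (key -> type codes).
#' @param path Output path.
#' @export
write_reference_catalog <- function(reference, path) {
  df <- data.frame(key = names(reference),
                   types = vapply(reference, paste, character(1),
                                  collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap of a catalogue with a pan-cancer reference
#'
#' Reports the overlap count and percentage (1 decimal, over the catalogue),
#' the per-type detection fraction (share of catalogue keys found in each
#' reference type), the distribution of the number of *other* cancer types
#' per overlapping key (the key's type count, excluding `own_type` when
#' given), and the fraction of overlapping keys found in more than
#' `many_types_cut` types.
#'
#' @param keys Character vector of catalogue keys (nonempty).
#' @param reference Reference catalogue from [read_reference_catalog()].
#' @param own_type Optional code of the study's own cancer type, excluded
#'   from type counts.
#' @param many_types_cut Threshold for the "ubiquitous" fraction
#'   (default 15).
#' @return `list(n_catalog, n_overlap, percent_overlap, per_type,
#'   type_count_distribution, frac_many_types)`.
#' @export
overlap_stats <- function(keys, reference, own_type = NULL,
                          many_types_cut = 15) {
  keys <- unique(keys)
  if (!length(keys)) stop("empty catalogue")
  hit <- keys %in% names(reference)
  n_overlap <- sum(hit)
  type_sets <- reference[keys[hit]]
  if (!is.null(own_type)) {
    type_sets <- lapply(type_sets, setdiff, own_type)
  }
  counts <- vapply(type_sets, length, integer(1))
  all_types <- sort(unique(unlist(reference)))
  per_type <- vapply(all_types, function(tp) {
    mean(vapply(reference[keys[hit]], function(s) tp %in% s, logical(1))) *
      n_overlap / length(keys)
  }, numeric(1))
  dist <- if (n_overlap) table(counts) else table(integer())
  list(
    n_catalog = length(keys),
    n_overlap = n_overlap,
    percent_overlap = round(100 * n_overlap / length(keys), 1),
    per_type = setNames(per_type, all_types),
    type_count_distribution = dist,
    frac_many_types = if (n_overlap) mean(counts > many_types_cut)
      else NA_real_
  )
}

#' Identify study-specific circRNAs
#'
#' A catalogue key is specific to the study's cancer type when the reference
#' records it nowhere else: its type set minus `own_type` is empty, or it is
#' absent from the reference altogether.
#'
#' @param keys Catalogue keys.
#' @param reference Reference catalogue.
#' @param own_type The study's own cancer-type code.
#' @return `list(specific_keys, n_specific, fraction)` with `fraction`
#'   rendered to 2 decimals of the percentage-free proportion.
#' @export
call_specific <- function(keys, reference, own_type) {
  keys <- unique(keys)
  is_specific <- vapply(keys, function(k) {
    if (!k %in% names(reference)) return(TRUE)
    length(setdiff(reference[[k]], own_type)) == 0
  }, logical(1))
  list(specific_keys = keys[is_specific],
       n_specific = sum(is_specific),
       fraction = round(sum(is_specific) / length(keys), 4),
       percent = round(100 * sum(is_specific) / length(keys), 2))
}
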