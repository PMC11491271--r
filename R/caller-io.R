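#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rnorm rpois rnbinom runif rexp rbinom setNames
#'   pnorm pchisq pt phyper qnorm cor complete.cases quantile sd var aggregate
#' @importFrom utils read.delim write.table head combn
NULL

CALLER_IDS <- c("find_circ", "circrna_finder", "ciri2", "circexplorer2")
STRANDS <- c("+", "-", ".")

#' Construct a table of harmonised back-splice junction calls
#'
#' A junction call records one back-splice junction (BSJ) observed by one
#' caller in one sample. Coordinates are kept in an internal 0-based
#' half-open frame: `start` is the 0-based left boundary of the back-splice,
#' `end` the exclusive right boundary, so `end - start` is the genomic span
#' of the circRNA.
#'
#' @param chrom Chromosome names (non-empty strings).
#' @param start 0-based inclusive junction starts.
#' @param end 0-based exclusive junction ends; must exceed `start`.
#' @param strand One of `"+"`, `"-"`, `"."` per call. `"."` (unstranded) is
#'   kept distinct from the two stranded values; it is never merged with them.
#' @param bsj_reads Non-negative back-splicing read counts. Zero is allowed:
#'   read-count filtering happens at the consensus stage, not at parse time.
#' @param caller_id One of `find_circ`, `circrna_finder`, `ciri2`,
#'   `circexplorer2` (recycled if length 1).
#' @param sample_id Sample identifier (recycled if length 1).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `bsj_reads`, `caller_id`, `sample_id`.
#' @export
junction_calls <- function(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           bsj_reads = integer(),
                           caller_id = character(), sample_id = character()) {
  n <- length(chrom)
  if (length(caller_id) == 1) caller_id <- rep(caller_id, n)
  if (length(sample_id) == 1) sample_id <- rep(sample_id, n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   bsj_reads = as.numeric(bsj_reads),
                   caller_id = as.character(caller_id),
                   sample_id = as.character(sample_id),
                   stringsAsFactors = FALSE)
  validate_junction_calls(df)
  df
}

validate_junction_calls <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end", "strand", "bsj_reads",
            "caller_id", "sample_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("junction call table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(!nzchar(df$chrom))) stop("empty chromosome name in junction calls")
  if (any(df$start >= df$end)) stop("junction with start >= end")
  if (any(df$bsj_reads < 0)) stop("negative bsj_reads")
  if (any(!df$strand %in% STRANDS)) stop("strand must be one of +, -, .")
  bad <- setdiff(unique(df$caller_id), CALLER_IDS)
  if (length(bad)) stop("unknown caller_id: ", paste(bad, collapse = ", "))
  invisible(df)
}

#' Parse one caller output file into harmonised junction calls
#'
#' Supported dialects (tab-separated, frozen fixture formats):
#' \describe{
#'   \item{find_circ, circrna_finder}{BED6: chrom, start (0-based),
#'     end (exclusive), name, score = BSJ reads, strand.}
#'   \item{circexplorer2}{BED-like, 7 columns: chrom, start (0-based), end
#'     (exclusive), name, score, strand, readNumber = BSJ reads.}
#'   \item{ciri2}{Headered TSV: circRNA_ID, chr, circRNA_start (1-based),
#'     circRNA_end (inclusive), strand, junction_reads. One is subtracted
#'     from the start to reach the internal 0-based half-open frame.}
#' }
#'
#' @param path Path to the caller output file.
#' @param caller_id Which dialect to parse; one of the four supported ids.
#' @param sample_id Sample identifier attached to every parsed call.
#' @param strict If `TRUE` (default) a malformed row aborts with an error
#'   naming the file and line; if `FALSE` malformed rows are skipped with a
#'   warning.
#' @return A junction call `data.frame` (see [junction_calls()]); rows with
#'   zero reads are retained.
#' @export
parse_caller_output <- function(path, caller_id, sample_id = "sample",
                                strict = TRUE) {
  if (!caller_id %in% CALLER_IDS) {
    stop("unknown caller_id '", caller_id, "'; expected one of ",
         paste(CALLER_IDS, collapse = ", "))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  has_header <- caller_id == "ciri2"
  lines <- readLines(path)
  if (has_header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(junction_calls())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- switch(caller_id, circexplorer2 = 7, ciri2 = 6, 6)
  line_no <- seq_along(lines) + as.integer(has_header)

  parse_row <- function(f) {
    if (length(f) < min_cols) return(NULL)
    if (caller_id == "ciri2") {
      out <- list(chrom = f[2], start = suppressWarnings(as.numeric(f[3])) - 1,
                  end = suppressWarnings(as.numeric(f[4])), strand = f[5],
                  bsj = suppressWarnings(as.numeric(f[6])))
    } else {
      reads_col <- if (caller_id == "circexplorer2") 7 else 5
      out <- list(chrom = f[1], start = suppressWarnings(as.numeric(f[2])),
                  end = suppressWarnings(as.numeric(f[3])), strand = f[6],
                  bsj = suppressWarnings(as.numeric(f[reads_col])))
    }
    ok <- nzchar(out$chrom) && !is.na(out$start) && !is.na(out$end) &&
      out$start < out$end && out$strand %in% STRANDS &&
      !is.na(out$bsj) && out$bsj >= 0
    if (!ok) NULL else out
  }

  rows <- lapply(fields, parse_row)
  bad <- vapply(rows, is.null, logical(1))
  if (any(bad)) {
    msg <- sprintf("malformed %s row(s) in %s at line(s) %s", caller_id,
                   path, paste(line_no[bad], collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; skipped")
    rows <- rows[!bad]
  }
  if (!length(rows)) return(junction_calls())
  junction_calls(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    bsj_reads = vapply(rows, `[[`, numeric(1), "bsj"),
    caller_id = caller_id, sample_id = sample_id
  )
}

#' Canonical circRNA key
#'
#' Renders a junction as `"chrom:display_start|display_end:strand"` where
#' the displayed coordinates are 1-based inclusive (`display_start =
#' start + 1`, `display_end = end`). Identical junctions observed by
#' different callers collide to one key; the key round-trips losslessly via
#' [parse_junction_key()].
#'
#' @param chrom Chromosome names, or a junction-call / catalogue `data.frame`
#'   with `chrom`, `start`, `end`, `strand` columns.
#' @param start,end,strand Internal-frame coordinates (ignored when `chrom`
#'   is a data.frame).
#' @return Character vector of keys.
#' @export
junction_key <- function(chrom, start = NULL, end = NULL, strand = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    chrom <- df$chrom; start <- df$start; end <- df$end; strand <- df$strand
  }
  sprintf("%s:%d|%d:%s", chrom, as.integer(start) + 1L, as.integer(end),
          strand)
}

#' Parse canonical circRNA keys back to internal coordinates
#'
#' @param keys Character vector of keys produced by [junction_key()].
#' @return `data.frame` with `key`, `chrom`, `start`, `end`, `strand`
#'   (internal 0-based half-open frame).
#' @export
parse_junction_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+)\\|([0-9]+):([+.-])$", keys))
  bad <- vapply(m, length, integer(1)) != 5
  if (any(bad)) stop("unparseable key(s): ", paste(keys[bad], collapse = ", "))
  data.frame(
    key = keys,
    chrom = vapply(m, `[[`, character(1), 2),
    start = as.numeric(vapply(m, `[[`, character(1), 3)) - 1,
    end = as.numeric(vapply(m, `[[`, character(1), 4)),
    strand = vapply(m, `[[`, character(1), 5),
    stringsAsFactors = FALSE
  )
}

#' Write a circRNA catalogue as BED6
#'
#' Emits 0-based half-open BED with the canonical key in the name column and
#' the rounded mean normalised read count (capped at 1000) as score. Rows are
#' sorted by (chrom, start, end).
#'
#' @param catalog Catalogue `data.frame` with `chrom`, `start`, `end`,
#'   `strand` and optionally `mean_norm_reads`.
#' @param path Output path.
#' @export
write_catalog_bed <- function(catalog, path) {
  score <- if ("mean_norm_reads" %in% names(catalog)) {
    pmin(1000, round(catalog$mean_norm_reads))
  } else rep(0, nrow(catalog))
  bed <- data.frame(chrom = catalog$chrom, start = as.integer(catalog$start),
                    end = as.integer(catalog$end),
                    name = junction_key(catalog), score = score,
                    strand = catalog$strand, stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start, bed$end), ]
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Emit junction calls in a caller's native dialect
#'
#' The inverse of [parse_caller_output()]; used by the synthetic-data
#' generator and by dialect round-trip tests.
#'
#' @param calls Junction call `data.frame` (internal frame).
#' @param path Output path.
#' @param caller_id Target dialect.
#' @export
write_caller_output <- function(calls, path, caller_id) {
  if (!caller_id %in% CALLER_IDS) stop("unknown caller_id: ", caller_id)
  if (caller_id == "ciri2") {
    df <- data.frame(circRNA_ID = sprintf("circ_%d", seq_len(nrow(calls))),
                     chr = calls$chrom,
                     circRNA_start = as.integer(calls$start) + 1L,
                     circRNA_end = as.integer(calls$end),
                     strand = calls$strand,
                     junction_reads = as.integer(calls$bsj_reads))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  } else {
    df <- data.frame(chrom = calls$chrom, start = as.integer(calls$start),
                     end = as.integer(calls$end),
                     name = sprintf("j%d", seq_len(nrow(calls))),
                     score = as.integer(calls$bsj_reads),
                     strand = calls$strand)
    if (caller_id == "circexplorer2") {
      df$score <- rep(0L, nrow(df))
      df$readNumber <- as.integer(calls$bsj_reads)
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Write the harmonised junction table
#'
#' @param calls Junction call `data.frame`.
#' @param path Output TSV path.
#' @export
write_junction_table <- function(calls, path) {
  out <- data.frame(key = junction_key(calls), calls,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "caller_id"] <- "caller"
  names(out)[names(out) == "sample_id"] <- "sample"
  out <- out[c("key", "chrom", "start", "end", "strand", "sample", "caller",
               "bsj_reads")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
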