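#' Load a gene model from GTF
#'
#' Consumes gene-level records (feature type `gene`) and their `gene_id`,
#' `gene_name` and `gene_type`/`gene_biotype` attributes. Only gene spans are
#' kept; exon structure is not used for host assignment.
#'
#' @param path GTF file path.
#' @return A list of class `gene_model` with `genes` (a `data.frame`:
#'   `gene_id`, `gene_name`, `biotype`, `chrom`, `strand`, `start` (0-based),
#'   `end`) and `gr` (a `GRanges` index for overlap queries).
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) {
    gr <- gr[gr$type == "gene"]
  }
  md <- S4Vectors::mcols(gr)
  biotype <- if ("gene_type" %in% names(md)) md$gene_type
    else if ("gene_biotype" %in% names(md)) md$gene_biotype
    else rep(NA_character_, length(gr))
  genes <- data.frame(
    gene_id = md$gene_id,
    gene_name = if ("gene_name" %in% names(md)) md$gene_name else md$gene_id,
    biotype = as.character(biotype),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1,  # internal 0-based frame
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene model")
  if (any(genes$start >= genes$end)) stop("invalid gene interval in model")
  structure(list(genes = genes, gr = gr), class = "gene_model")
}

#' Assign host (parental) genes to catalogue entries
#'
#' Intersects each circRNA span with gene spans. When several genes overlap
#' a circRNA the winner is chosen deterministically: same-strand genes first
#' (back-splicing is strand-specific; an unstranded `.` circRNA matches no
#' strand preferentially), then the largest overlap length, then the
#' lexicographically smallest `gene_id`. Entries overlapping no gene — or on
#' a chromosome absent from the model — are labelled `"intergenic"`.
#'
#' @param catalog Catalogue `data.frame` from [build_catalog()].
#' @param model A `gene_model` from [read_gene_model()].
#' @param prefer_strand Set `FALSE` to rank purely by overlap length.
#' @return The catalogue with `host_gene`, `host_biotype` and `circ_name`
#'   (`"circ<GENE_NAME>"`, `NA` for intergenic) columns filled in.
#' @export
assign_host_genes <- function(catalog, model, prefer_strand = TRUE) {
  stopifnot(inherits(model, "gene_model"))
  if (nrow(catalog) == 0) {
    catalog$host_gene <- character(0)
    catalog$host_biotype <- character(0)
    catalog$circ_name <- character(0)
    return(catalog)
  }
  missing_chr <- setdiff(unique(catalog$chrom), unique(model$genes$chrom))
  if (length(missing_chr)) {
    warning("chromosome(s) absent from gene model, entries left intergenic: ",
            paste(missing_chr, collapse = ", "))
  }
  circ_gr <- GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(start = catalog$start + 1, end = catalog$end),
    strand = sub("\\.", "*", catalog$strand)  # "." never strand-matches
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(circ_gr, model$gr, ignore.strand = TRUE)
  )
  host <- rep("intergenic", nrow(catalog))
  biotype <- rep(NA_character_, nrow(catalog))
  cname <- rep(NA_character_, nrow(catalog))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(circ_gr)[qi], IRanges::ranges(model$gr)[si]))
    same <- catalog$strand[qi] == model$genes$strand[si]
    gid <- model$genes$gene_id[si]
    ord <- order(qi, if (prefer_strand) !same else rep(FALSE, length(qi)),
                 -ov, gid)
    first <- !duplicated(qi[ord])
    sel_q <- qi[ord][first]
    sel_s <- si[ord][first]
    host[sel_q] <- model$genes$gene_id[sel_s]
    biotype[sel_q] <- model$genes$biotype[sel_s]
    cname[sel_q] <- paste0("circ", model$genes$gene_name[sel_s])
  }
  catalog$host_gene <- host
  catalog$host_biotype <- biotype
  catalog$circ_name <- cname
  catalog
}

#' Aggregate back-splicing to gene level
#'
#' Sums normalised BSJ reads of all circRNAs assigned to each host gene,
#' per sample (exact additivity; intergenic entries are excluded). Also
#' reports per-gene circRNA counts and total reads for genomic summaries.
#'
#' @param mat Normalised expression matrix (junction keys x samples).
#' @param catalog Annotated catalogue ([assign_host_genes()]).
#' @return `list(matrix, gene_summary)`: the gene x sample matrix and a
#'   `data.frame` with `gene_id`, `n_circ`, `total_reads`.
#' @export
aggregate_gene_bsj <- function(mat, catalog) {
  if (!isTRUE(attr(mat, "normalised"))) {
    stop("aggregate_gene_bsj expects a normalised matrix")
  }
  if (!"host_gene" %in% names(catalog) || all(is.na(catalog$host_gene))) {
    stop("catalogue is not annotated; run assign_host_genes first")
  }
  keep <- !is.na(catalog$host_gene) & catalog$host_gene != "intergenic" &
    catalog$key %in% rownames(mat)
  sub <- catalog[keep, , drop = FALSE]
  if (!nrow(sub)) {
    gm <- matrix(0, 0, ncol(mat), dimnames = list(NULL, colnames(mat)))
    attr(gm, "normalised") <- TRUE
    return(list(matrix = gm,
                gene_summary = data.frame(gene_id = character(),
                                          n_circ = integer(),
                                          total_reads = numeric())))
  }
  gm <- rowsum(mat[sub$key, , drop = FALSE], group = sub$host_gene)
  gm <- gm[order(rownames(gm)), , drop = FALSE]
  attr(gm, "normalised") <- TRUE
  summary <- data.frame(
    gene_id = rownames(gm),
    n_circ = as.integer(table(sub$host_gene)[rownames(gm)]),
    total_reads = rowSums(gm),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(matrix = gm, gene_summary = summary)
}

#' Per-window normalised back-splicing density
#'
#' Tiles each chromosome with half-open windows of `window_size` bases,
#' assigns every junction to the window containing its start, normalises
#' reads per million within each sample, and sums across the requested
#' samples. Conservation holds: the window totals sum to the total
#' normalised reads.
#'
#' @param junctions `data.frame` with `chrom`, `start`, `sample_id`,
#'   `reads` (raw read counts).
#' @param samples Sample sheet (supplies `library_size`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_size Window width in bp (default 1e6).
#' @return `data.frame` with `chrom`, `win_start`, `win_end`, `reads`
#'   covering every window of every chromosome in `chrom_lengths`.
#' @export
window_density <- function(junctions, samples, chrom_lengths,
                           window_size = 1e6) {
  if (window_size <= 0) stop("window_size must be positive")
  libs <- setNames(samples$library_size, samples$sample_id)
  track <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[[ch]] - 1, by = window_size)
    data.frame(chrom = ch, win_start = starts,
               win_end = pmin(starts + window_size, chrom_lengths[[ch]]),
               reads = 0, stringsAsFactors = FALSE)
  }))
  if (nrow(junctions)) {
    unknown <- setdiff(unique(junctions$chrom), names(chrom_lengths))
    if (length(unknown)) {
      stop("junction chromosome(s) missing from chrom_lengths: ",
           paste(unknown, collapse = ", "))
    }
    norm <- junctions$reads * 1e6 / libs[junctions$sample_id]
    win <- floor(junctions$start / window_size) * window_size
    idx <- match(paste(junctions$chrom, win),
                 paste(track$chrom, track$win_start))
    add <- rowsum(norm, group = idx)
    track$reads[as.integer(rownames(add))] <-
      track$reads[as.integer(rownames(add))] + add[, 1]
  }
  track
}

#' Write a window-density track as bedGraph
#' @param track Output of [window_density()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track[c("chrom", "win_start", "win_end", "reads")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tally host genes by biotype
#'
#' Each distinct host gene counts once regardless of how many circRNAs it
#' expresses; fractions are percentages of circRNA-expressing genes.
#'
#' @param catalog Annotated catalogue.
#' @return `data.frame` with `biotype`, `n_genes`, `percent` (1 decimal).
#' @export
biotype_summary <- function(catalog) {
  keep <- !is.na(catalog$host_gene) & catalog$host_gene != "intergenic"
  hosts <- unique(catalog[keep, c("host_gene", "host_biotype")])
  if (!nrow(hosts)) {
    return(data.frame(biotype = character(), n_genes = integer(),
                      percent = numeric()))
  }
  tab <- sort(table(hosts$host_biotype), decreasing = TRUE)
  data.frame(biotype = names(tab), n_genes = as.integer(tab),
             percent = round(100 * as.integer(tab) / nrow(hosts), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
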