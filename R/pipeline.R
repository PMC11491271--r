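#' Assemble and validate a pipeline run configuration
#'
#' Collects input paths and stage parameters, checking that every
#' referenced file exists and that parameters are within range before any
#' stage runs.
#'
#' @param outdir Output directory (created).
#' @param caller_manifest TSV with columns `path`, `sample_id`, `caller_id`
#'   listing every caller output file.
#' @param sample_sheet Sample sheet TSV.
#' @param gtf Gene model GTF.
#' @param gmt Hallmark GMT (optional; activity stage skipped without it).
#' @param categories Optional hallmark-category TSV (`hallmark`,
#'   `category`).
#' @param reference Optional pan-cancer reference catalogue TSV.
#' @param expression Optional host-gene expression TSV (genes x samples).
#' @param immune Optional immune-abundance TSV (samples x cell types).
#' @param clinical Optional clinical TSV (`subject`, `expression`, `group`,
#'   `time`, `event`, `adverse_feature`).
#' @param min_callers,min_reads,min_samples Consensus filter thresholds.
#' @param group_rule `"either"` or `"pooled"` sample-frequency rule.
#' @param fc_threshold,alpha Differential-expression call thresholds.
#' @param tau GSVA-style rank-weight exponent.
#' @param own_type Study cancer-type code for the pan-cancer stage.
#' @param strict Strict caller parsing (default) or lenient skip-with-log.
#' @param seed Seed recorded in the run report (the pipeline itself is
#'   deterministic).
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(outdir, caller_manifest, sample_sheet, gtf,
                            gmt = NULL, categories = NULL, reference = NULL,
                            expression = NULL, immune = NULL,
                            clinical = NULL, min_callers = 2, min_reads = 2,
                            min_samples = 5,
                            group_rule = "either", fc_threshold = 1.5,
                            alpha = 0.05, tau = 1, own_type = "GBC",
                            strict = TRUE, seed = 1) {
  required <- list(caller_manifest = caller_manifest,
                   sample_sheet = sample_sheet, gtf = gtf)
  optional <- list(gmt = gmt, categories = categories, reference = reference,
                   expression = expression, immune = immune,
                   clinical = clinical)
  for (nm in names(required)) {
    if (!file.exists(required[[nm]])) {
      stop("configuration error: ", nm, " file not found: ", required[[nm]])
    }
  }
  for (nm in names(optional)) {
    if (!is.null(optional[[nm]]) && !file.exists(optional[[nm]])) {
      stop("configuration error: ", nm, " file not found: ", optional[[nm]])
    }
  }
  stopifnot(min_callers >= 1, min_reads >= 0, min_samples >= 1,
            fc_threshold > 1, alpha > 0, alpha < 1, tau > 0)
  manifest <- read.delim(caller_manifest, stringsAsFactors = FALSE)
  if (!all(c("path", "sample_id", "caller_id") %in% names(manifest))) {
    stop("caller manifest needs path, sample_id, caller_id columns")
  }
  manifest$path <- resolve_manifest_paths(manifest$path, caller_manifest)
  missing_files <- manifest$path[!file.exists(manifest$path)]
  if (length(missing_files)) {
    stop("configuration error: caller file(s) not found: ",
         paste(head(missing_files, 5), collapse = ", "))
  }
  structure(c(list(outdir = outdir), required, optional,
              list(min_callers = min_callers, min_reads = min_reads,
                   min_samples = min_samples, group_rule = group_rule,
                   fc_threshold = fc_threshold, alpha = alpha, tau = tau,
                   own_type = own_type, strict = strict, seed = seed)),
            class = "run_config")
}

out_path <- function(cfg, name) file.path(cfg$outdir, name)

# manifest paths may be relative to the manifest's own directory
resolve_manifest_paths <- function(paths, manifest_file) {
  ifelse(file.exists(paths), paths,
         file.path(dirname(manifest_file), paths))
}

read_junction_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  junction_calls(chrom = df$chrom, start = df$start, end = df$end,
                 strand = df$strand, bsj_reads = df$bsj_reads,
                 caller_id = df$caller, sample_id = df$sample)
}

stage_parse <- function(cfg) {
  manifest <- read.delim(cfg$caller_manifest, stringsAsFactors = FALSE)
  manifest$path <- resolve_manifest_paths(manifest$path, cfg$caller_manifest)
  calls <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    parse_caller_output(manifest$path[i], manifest$caller_id[i],
                        manifest$sample_id[i], strict = cfg$strict)
  }))
  write_junction_table(calls, out_path(cfg, "junctions.tsv"))
  c(n_calls = nrow(calls))
}

stage_consensus <- function(cfg) {
  calls <- read_junction_table(out_path(cfg, "junctions.tsv"))
  samples <- read_sample_sheet(cfg$sample_sheet)
  merged <- do.call(rbind, lapply(split(calls, calls$sample_id),
                                  merge_sample_calls))
  built <- build_catalog(merged, samples, min_callers = cfg$min_callers,
                         min_reads = cfg$min_reads,
                         min_samples = cfg$min_samples,
                         group_rule = cfg$group_rule)
  norm <- normalize_matrix(built$matrix, samples)
  prov <- attr(built$catalog, "filters")
  write.table(built$catalog, out_path(cfg, "catalog.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(built$matrix, out_path(cfg, "raw_matrix.tsv"), prov)
  write_matrix_tsv(norm, out_path(cfg, "norm_matrix.tsv"), prov)
  c(n_circ = nrow(built$catalog))
}

stage_annotate <- function(cfg) {
  catalog <- read.delim(out_path(cfg, "catalog.tsv"),
                        stringsAsFactors = FALSE)
  model <- read_gene_model(cfg$gtf)
  samples <- read_sample_sheet(cfg$sample_sheet)
  catalog <- assign_host_genes(catalog, model)
  norm <- read_matrix_tsv(out_path(cfg, "norm_matrix.tsv"),
                          normalised = TRUE)
  agg <- aggregate_gene_bsj(norm, catalog)
  raw <- read_matrix_tsv(out_path(cfg, "raw_matrix.tsv"), normalised = FALSE)
  junctions <- do.call(rbind, lapply(colnames(raw), function(s) {
    nz <- raw[, s] > 0
    data.frame(chrom = catalog$chrom[nz], start = catalog$start[nz],
               sample_id = s, reads = raw[nz, s], stringsAsFactors = FALSE)
  }))
  chrom_lengths <- chrom_lengths_from_model(model, junctions)
  track <- window_density(junctions, samples, chrom_lengths)
  write.table(catalog, out_path(cfg, "catalog_annotated.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_catalog_bed(catalog, out_path(cfg, "catalog.bed"))
  write_matrix_tsv(agg$matrix, out_path(cfg, "gene_matrix.tsv"))
  write.table(agg$gene_summary, out_path(cfg, "gene_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_bedgraph(track, out_path(cfg, "windows.bedgraph"))
  write.table(biotype_summary(catalog), out_path(cfg, "biotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  c(n_genes = nrow(agg$matrix))
}

chrom_lengths_from_model <- function(model, junctions = NULL) {
  lens <- tapply(model$genes$end, model$genes$chrom, max)
  lens <- setNames(as.numeric(lens), names(lens))
  if (!is.null(junctions) && nrow(junctions)) {
    jl <- tapply(junctions$start + 1, junctions$chrom, max)
    for (ch in names(jl)) {
      lens[ch] <- max(lens[ch], jl[[ch]], na.rm = TRUE)
    }
  }
  # round up to whole Mb so windows tile past the last feature
  ceiling(lens / 1e6) * 1e6
}

stage_de <- function(cfg) {
  raw <- read_matrix_tsv(out_path(cfg, "raw_matrix.tsv"), normalised = FALSE)
  samples <- read_sample_sheet(cfg$sample_sheet)
  de <- run_diffexp(raw, samples, fc_threshold = cfg$fc_threshold,
                    alpha = cfg$alpha)
  write.table(de, out_path(cfg, "differential.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  volcano <- data.frame(key = de$key, log2fc = de$log2fc,
                        neg_log10_q = -log10(pmax(de$qvalue, 1e-300)),
                        call = de$call)
  write.table(volcano, out_path(cfg, "volcano.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  c(n_up = attr(de, "n_up"), n_down = attr(de, "n_down"))
}

stage_activity <- function(cfg) {
  if (is.null(cfg$gmt)) return(c(skipped = 1))
  gm <- read_matrix_tsv(out_path(cfg, "gene_matrix.tsv"), normalised = TRUE)
  sets <- load_gmt(cfg$gmt)
  scores <- suppressWarnings(gsva_scores(gm, sets, tau = cfg$tau))
  samples <- read_sample_sheet(cfg$sample_sheet)
  categories <- NULL
  if (!is.null(cfg$categories)) {
    cat_df <- read.delim(cfg$categories, stringsAsFactors = FALSE)
    categories <- setNames(cat_df$category, cat_df$hallmark)
  }
  tum <- intersect(colnames(scores),
                   samples$sample_id[samples$group == "tumour"])
  act <- hallmark_activity_summary(scores, tum, categories)
  write_matrix_tsv(scores, out_path(cfg, "activity_scores.tsv"))
  write.table(act$hallmarks, out_path(cfg, "activity_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(act$categories)) {
    write.table(act$categories, out_path(cfg, "activity_categories.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  c(n_hallmarks = nrow(scores))
}

# differential calls for a continuous expression matrix: per-row Wilcoxon
# tumour-vs-NAT with BH and median fold change
expression_calls <- function(expr, samples, fc_threshold = 1.5,
                             alpha = 0.05) {
  groups <- samples$group[match(colnames(expr), samples$sample_id)]
  res <- t(apply(expr, 1, function(v) {
    w <- wilcoxon_rank_sum(v[groups == "tumour"], v[groups == "NAT"])
    c(p = w$pvalue, fc = w$fold_change)
  }))
  q <- bh_adjust(res[, "p"])
  call <- rep("none", nrow(expr))
  call[!is.na(res[, "fc"]) & res[, "fc"] >= fc_threshold & q < alpha] <- "up"
  call[!is.na(res[, "fc"]) & res[, "fc"] <= 1 / fc_threshold &
         q < alpha] <- "down"
  data.frame(key = rownames(expr), pvalue = res[, "p"], qvalue = q,
             fold_change = res[, "fc"], call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

stage_associate <- function(cfg) {
  de <- read.delim(out_path(cfg, "differential.tsv"),
                   stringsAsFactors = FALSE)
  catalog <- read.delim(out_path(cfg, "catalog_annotated.tsv"),
                        stringsAsFactors = FALSE)
  samples <- read_sample_sheet(cfg$sample_sheet)
  counts <- c()

  if (!is.null(cfg$expression)) {
    expr <- read_matrix_tsv(cfg$expression)
    host_de <- expression_calls(expr, samples, cfg$fc_threshold, cfg$alpha)
    in_expr <- catalog$host_gene %in% rownames(expr)
    sub <- catalog[in_expr & catalog$host_gene != "intergenic", ]
    if (nrow(sub)) {
      circ_calls <- de[match(sub$key, de$key), c("key", "call")]
      hc <- data.frame(key = sub$key,
                       call = host_de$call[match(sub$host_gene,
                                                 host_de$key)])
      oct <- classify_change_octants(circ_calls, hc)
      write.table(oct$pairs, out_path(cfg, "octants.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(oct$summary, out_path(cfg, "concordance_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      # circRNA-host Spearman for the differential circRNAs
      norm <- read_matrix_tsv(out_path(cfg, "norm_matrix.tsv"),
                              normalised = TRUE)
      tested <- sub[de$call[match(sub$key, de$key)] != "none", ]
      if (nrow(tested)) {
        shared <- intersect(colnames(norm), colnames(expr))
        assoc <- spearman_fdr(norm[, shared, drop = FALSE],
                              expr[, shared, drop = FALSE],
                              data.frame(x_id = tested$key,
                                         y_id = tested$host_gene))
        write.table(assoc, out_path(cfg, "circ_host_correlation.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        counts <- c(counts, n_correlated = nrow(assoc))
      }
    }
  }
  if (!is.null(cfg$immune)) {
    imm <- read.delim(cfg$immune, stringsAsFactors = FALSE,
                      check.names = FALSE)
    imat <- t(as.matrix(imm[, -1, drop = FALSE]))
    colnames(imat) <- imm[[1]]
    norm <- read_matrix_tsv(out_path(cfg, "norm_matrix.tsv"),
                            normalised = TRUE)
    shared <- intersect(colnames(norm), colnames(imat))
    de_keys <- de$key[de$call != "none"]
    if (length(de_keys) && length(shared) >= 4) {
      pairs <- expand.grid(x_id = de_keys, y_id = rownames(imat),
                           stringsAsFactors = FALSE)
      assoc <- suppressWarnings(
        spearman_fdr(norm[, shared, drop = FALSE],
                     imat[, shared, drop = FALSE], pairs))
      write.table(assoc, out_path(cfg, "circ_immune_correlation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      counts <- c(counts, n_immune_pairs = nrow(assoc))
    }
  }
  if (!is.null(cfg$clinical)) {
    clin <- read.delim(cfg$clinical, stringsAsFactors = FALSE)
    grp <- if ("group" %in% names(clin)) clin$group
      else median_split(clin$expression)
    tab <- table(factor(clin$adverse_feature, c(0, 1)),
                 factor(grp, c("low", "high")))
    chis <- pearson_chisq(as.matrix(tab))
    lr <- logrank_test(clin$time, clin$event, grp)
    clin_out <- data.frame(
      statistic = c("pearson_chi2", "logrank_chi2"),
      value = c(chis$chi2, lr$chi2),
      pvalue = c(chis$pvalue, lr$pvalue))
    write.table(clin_out, out_path(cfg, "clinical_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    km <- data.frame(subject = clin$subject, time = clin$time,
                     event = clin$event, group = grp)
    write.table(km, out_path(cfg, "survival_groups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts <- c(counts, n_subjects = nrow(clin))
  }
  if (!length(counts)) counts <- c(skipped = 1)
  counts
}

stage_pancancer <- function(cfg) {
  if (is.null(cfg$reference)) return(c(skipped = 1))
  catalog <- read.delim(out_path(cfg, "catalog.tsv"),
                        stringsAsFactors = FALSE)
  reference <- read_reference_catalog(cfg$reference)
  ov <- overlap_stats(catalog$key, reference, own_type = cfg$own_type)
  sp <- call_specific(catalog$key, reference, cfg$own_type)
  report <- data.frame(
    metric = c("n_catalog", "n_overlap", "percent_overlap",
               "frac_many_types", "n_specific", "percent_specific"),
    value = c(ov$n_catalog, ov$n_overlap, ov$percent_overlap,
              ov$frac_many_types, sp$n_specific, sp$percent))
  write.table(report, out_path(cfg, "pancancer_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sp$specific_keys, out_path(cfg, "specific_keys.txt"))
  c(n_overlap = ov$n_overlap, n_specific = sp$n_specific)
}

PIPELINE_STAGES <- c("parse", "consensus", "annotate", "de", "activity",
                     "associate", "pancancer")

#' Run the pipeline end-to-end (or selected stages)
#'
#' Executes parse, consensus, annotation, differential expression, hallmark
#' activity, association and pan-cancer stages in order. Every stage writes
#' its TSV outputs into `outdir`; a JSON run report records parameters, row
#' counts and wall time. Stages communicate through their TSV outputs, so
#' any suffix of the stage list can be rerun individually. Reruns with
#' identical inputs produce identical TSVs.
#'
#' @param cfg A validated [pipeline_config()].
#' @param stages Subset of stages to run, in pipeline order.
#' @return Invisibly, the run report list.
#' @export
run_pipeline <- function(cfg, stages = PIPELINE_STAGES) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  runners <- list(parse = stage_parse, consensus = stage_consensus,
                  annotate = stage_annotate, de = stage_de,
                  activity = stage_activity, associate = stage_associate,
                  pancancer = stage_pancancer)
  report <- list(package = "circensus",
                 version = as.character(utils::packageVersion("circensus")),
                 parameters = cfg[!names(cfg) %in% "outdir"],
                 stages = list())
  t0 <- Sys.time()
  for (st in stages) {
    res <- tryCatch(runners[[st]](cfg), error = function(e) {
      report$stages[[st]] <- list(status = "failed",
                                  error = conditionMessage(e))
      report$wall_time_s <-
        as.numeric(difftime(Sys.time(), t0, units = "secs"))
      jsonlite::write_json(report, out_path(cfg, "run_report.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop("pipeline stage '", st, "' failed: ", conditionMessage(e))
    })
    report$stages[[st]] <- list(status = "ok", counts = as.list(res))
  }
  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, out_path(cfg, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(report)
}
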