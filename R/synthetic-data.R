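#' Simulation configuration for synthetic fixture bundles
#'
#' Returns the stated world the generator emulates: a paired tumour/NAT
#' design with negative-binomial back-splice-junction counts, a spiked
#' differential fraction, four callers with distinct sensitivities, false
#' positives and coordinate dialects, hallmark-style gene sets, a
#' pan-cancer reference catalogue with a known overlap fraction, and
#' immune/clinical tables tied to a designated circRNA.
#'
#' @param preset `"full"` (20 pairs, 2000 circRNAs) or `"reduced"` (6 pairs,
#'   300 circRNAs, the desk-scale default for tests).
#' @param ... Named overrides for any configuration field.
#' @return A `list` of class `sim_config`.
#' @export
sim_config <- function(preset = c("reduced", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_pairs = if (preset == "full") 20L else 6L,
    n_circ = if (preset == "full") 2000L else 300L,
    n_genes = 600L,
    n_chroms = 3L,
    chrom_length = 1e7,
    gene_fraction_of_chrom = 0.9,  # genes live in the first 90%
    gene_width_min = 5e3, gene_width_max = 4e4,
    overlap_gene_fraction = 0.05,   # extra genes overlapping existing ones
    intergenic_fraction = 0.05,     # circRNAs placed outside any gene
    biotype_probs = c(protein_coding = 0.91, lncRNA = 0.09),
    base_meanlog = log(5), base_sdlog = 1,
    spike_meanlog = log(20), spike_sdlog = 0.5,
    de_frac_up = 0.04, de_frac_down = 0.027,
    de_log2fc = 2,                  # 4-fold spikes
    dispersion = 0.2,
    libsize_min = 2e7, libsize_max = 4e7,
    read_jitter = TRUE,   # Poisson jitter on reported caller read counts
    caller_profiles = list(
      find_circ      = list(sensitivity = 0.90, fp_rate = 0.02),
      circrna_finder = list(sensitivity = 0.85, fp_rate = 0.02),
      ciri2          = list(sensitivity = 0.95, fp_rate = 0.02),
      circexplorer2  = list(sensitivity = 0.90, fp_rate = 0.02)
    ),
    set_categories = c(cancer_signalling = 8L, immune = 5L,
                       proliferation = 4L, metabolism = 3L),
    set_size_min = 10L, set_size_max = 40L,
    ref_overlap_fraction = 0.912,
    ref_n_types = 45L,
    ref_own_type = "GBC",
    ref_frac_many_types = 0.803,    # of overlapping keys, in >15 other types
    n_cell_types = 8L,
    immune_rho = 0.4,
    host_rho = 0.46,
    n_subjects = 50L,
    hazard_ratio = 2.5,
    baseline_hazard = 1 / 40,       # events per month in the low group
    censor_time = 60,               # months of follow-up
    feature_p_low = 0.3,            # P(adverse feature | low expression)
    feature_or = 9                  # odds ratio for the high group
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$de_frac_up >= 0, cfg$de_frac_down >= 0,
            cfg$de_frac_up + cfg$de_frac_down <= 1,
            cfg$intergenic_fraction >= 0, cfg$intergenic_fraction <= 1,
            cfg$ref_overlap_fraction >= 0, cfg$ref_overlap_fraction <= 1)
  structure(cfg, class = "sim_config")
}

# independent per-stage substreams off one master seed, so adding a stage
# never perturbs earlier draws
stage_seed <- function(seed, stage) {
  offsets <- c(genome = 1, counts = 2, callers = 3, sets = 4,
               reference = 5, clinical = 6)
  as.integer((as.numeric(seed) * 7919 + 104729 * offsets[[stage]]) %%
               2147483587)
}

#' Simulate the planted truth: genome, genes, circRNAs and counts
#'
#' Places genes without overlap on a synthetic genome (plus a configurable
#' fraction of overlapping genes to exercise host-assignment tie-breaking),
#' plants circRNAs inside host genes (plus an intergenic fraction in
#' gene-free territory), and draws NB-distributed BSJ counts with
#' tumour/NAT mean shifts for the differential rows. Differential spikes
#' are planted at moderately expressed junctions (their base mean is drawn
#' from a higher lognormal), emulating the validated, high-sample-frequency
#' candidates a study would follow up. Fully deterministic under the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return List of class `sim_truth`: `config`, `seed`, `chrom_lengths`,
#'   `genes` (data.frame), `truth` (per-circRNA data.frame with key,
#'   coordinates, host gene, status and group means), `counts` (latent
#'   true BSJ count matrix, circRNAs x samples) and `samples` (sample
#'   sheet).
#' @export
simulate_truth <- function(config = sim_config(), seed = 1) {
  set.seed(stage_seed(seed, "genome"))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_lengths <- setNames(rep(config$chrom_length, config$n_chroms), chroms)

  # non-overlapping genes: one gene per equal-width slot in the gene zone
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  gene_rows <- list()
  gid <- 0
  for (ch in chroms) {
    zone <- config$chrom_length * config$gene_fraction_of_chrom
    slot <- floor(zone / per_chrom)
    width_cap <- min(config$gene_width_max, floor(slot * 0.8))
    if (width_cap <= config$gene_width_min) {
      stop("infeasible gene placement: slots too small for gene widths")
    }
    n_here <- min(per_chrom, config$n_genes - gid)
    if (n_here <= 0) break
    w <- round(runif(n_here, config$gene_width_min, width_cap))
    s <- (seq_len(n_here) - 1) * slot +
      floor(runif(n_here, 0, slot - w))
    gene_rows[[ch]] <- data.frame(
      gene_id = sprintf("G%04d", gid + seq_len(n_here)),
      gene_name = sprintf("GENE%04d", gid + seq_len(n_here)),
      biotype = sample(names(config$biotype_probs), n_here, replace = TRUE,
                       prob = config$biotype_probs),
      chrom = ch,
      strand = sample(c("+", "-"), n_here, replace = TRUE),
      start = s, end = s + w, stringsAsFactors = FALSE)
    gid <- gid + n_here
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  # extra genes overlapping existing ones (tie-break exercise)
  n_extra <- round(config$overlap_gene_fraction * nrow(genes))
  if (n_extra > 0) {
    host_idx <- sample(nrow(genes), n_extra)
    w <- round(runif(n_extra, config$gene_width_min,
                     pmax(config$gene_width_min + 1,
                          (genes$end - genes$start)[host_idx])))
    s <- genes$start[host_idx] +
      floor(runif(n_extra, 0, pmax(1, (genes$end - genes$start)[host_idx] / 2)))
    extra <- data.frame(
      gene_id = sprintf("G%04d", nrow(genes) + seq_len(n_extra)),
      gene_name = sprintf("GENE%04d", nrow(genes) + seq_len(n_extra)),
      biotype = sample(names(config$biotype_probs), n_extra, replace = TRUE,
                       prob = config$biotype_probs),
      chrom = genes$chrom[host_idx],
      strand = sample(c("+", "-"), n_extra, replace = TRUE),
      start = s, end = s + w, stringsAsFactors = FALSE)
    genes <- rbind(genes, extra)
  }

  # circRNAs: most inside a (non-overlapping) host gene, some intergenic
  n_intergenic <- round(config$intergenic_fraction * config$n_circ)
  n_genic <- config$n_circ - n_intergenic
  main_genes <- genes[seq_len(gid), ]
  host_of <- sample(gid, n_genic, replace = TRUE)
  g <- main_genes[host_of, ]
  gw <- g$end - g$start
  c_start <- g$start + floor(runif(n_genic, 0, gw * 0.5))
  c_end <- pmin(g$end, c_start + 100 + floor(runif(n_genic, 0, gw * 0.5)))
  genic <- data.frame(chrom = g$chrom, start = c_start, end = c_end,
                      strand = g$strand, host_gene = g$gene_id,
                      stringsAsFactors = FALSE)
  # intergenic zone: [92%, 96%) of each chromosome (gene-free; the last 4%
  # is reserved for caller-specific false positives)
  ig_zone_start <- config$chrom_length * 0.92
  ig_zone_end <- config$chrom_length * 0.96
  ig_start <- floor(runif(n_intergenic, ig_zone_start, ig_zone_end - 2000))
  intergenic <- data.frame(
    chrom = sample(chroms, n_intergenic, replace = TRUE),
    start = ig_start,
    end = ig_start + 200 + floor(runif(n_intergenic, 0, 1500)),
    strand = sample(c("+", "-"), n_intergenic, replace = TRUE),
    host_gene = "intergenic", stringsAsFactors = FALSE)
  truth <- rbind(genic, intergenic)
  truth$key <- junction_key(truth)
  dup <- duplicated(truth$key)
  while (any(dup)) {  # nudge duplicated placements to keep keys unique
    truth$start[dup] <- truth$start[dup] + 1
    truth$key <- junction_key(truth)
    dup <- duplicated(truth$key)
  }

  # expression truth
  set.seed(stage_seed(seed, "counts"))
  n <- nrow(truth)
  status <- rep("none", n)
  n_up <- round(config$de_frac_up * n)
  n_down <- round(config$de_frac_down * n)
  de_pool <- which(truth$host_gene != "intergenic")
  de_idx <- sample(de_pool, n_up + n_down)
  status[de_idx[seq_len(n_up)]] <- "up"
  status[de_idx[n_up + seq_len(n_down)]] <- "down"
  base_mean <- exp(rnorm(n, config$base_meanlog, config$base_sdlog))
  base_mean[status != "none"] <-
    exp(rnorm(n_up + n_down, config$spike_meanlog, config$spike_sdlog))
  shift <- 2^(config$de_log2fc * (status == "up") -
                config$de_log2fc * (status == "down"))
  truth$status <- status
  truth$base_mean <- base_mean
  truth$tumour_mean <- base_mean * shift
  truth$nat_mean <- base_mean

  pair_id <- sprintf("P%02d", seq_len(config$n_pairs))
  samples <- data.frame(
    sample_id = c(sprintf("T%02d", seq_len(config$n_pairs)),
                  sprintf("N%02d", seq_len(config$n_pairs))),
    group = rep(c("tumour", "NAT"), each = config$n_pairs),
    pair_id = c(pair_id, pair_id),
    library_size = round(runif(2 * config$n_pairs, config$libsize_min,
                               config$libsize_max)),
    stringsAsFactors = FALSE)

  depth <- samples$library_size / mean(samples$library_size)
  mu <- outer(truth$nat_mean, depth)
  tum <- samples$group == "tumour"
  mu[, tum] <- outer(truth$tumour_mean, depth[tum])
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   nrow = n, dimnames = list(truth$key, samples$sample_id))

  structure(list(config = config, seed = seed,
                 chrom_lengths = chrom_lengths, genes = genes,
                 truth = truth, counts = counts, samples = samples),
            class = "sim_truth")
}

#' Emit per-sample caller files in the four dialects
#'
#' Each caller independently detects each expressed junction with its
#' configured sensitivity, reports Poisson-jittered read counts
#' (`observed ~ Poisson(true count)`, zero retained), writes
#' dialect-correct coordinates (CIRI2 1-based inclusive, the BED dialects
#' 0-based half-open), and plants caller-unique false positives at its
#' false-positive rate. False positives live in the last 4% of each
#' chromosome — territory the truth generator never uses — at start
#' positions congruent to the caller's index modulo 4, so no two callers
#' can ever emit the same false junction and the consensus filter must
#' remove all of them.
#'
#' @param sim A `sim_truth` bundle.
#' @param dir Output directory (created if needed).
#' @return `list(manifest, fp_truth)`: the file manifest (`path`,
#'   `sample_id`, `caller_id`) and the planted-false-positive table.
#' @export
emulate_callers <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim$config
  manifest <- list()
  fp_rows <- list()
  callers <- names(cfg$caller_profiles)
  fp_zone_start <- cfg$chrom_length * 0.96
  for (si in seq_len(nrow(sim$samples))) {
    sid <- sim$samples$sample_id[si]
    for (ci in seq_along(callers)) {
      caller <- callers[ci]
      prof <- cfg$caller_profiles[[caller]]
      set.seed(as.integer((stage_seed(sim$seed, "callers") +
                             si * 3571 + ci * 101) %% 2147483587))
      expressed <- sim$counts[, sid] > 0
      detected <- expressed & runif(nrow(sim$truth)) < prof$sensitivity
      obs <- if (cfg$read_jitter) {
        rpois(sum(detected), lambda = sim$counts[detected, sid])
      } else {
        sim$counts[detected, sid]
      }
      calls <- junction_calls(
        chrom = sim$truth$chrom[detected],
        start = sim$truth$start[detected], end = sim$truth$end[detected],
        strand = sim$truth$strand[detected], bsj_reads = obs,
        caller_id = caller, sample_id = sid)
      n_fp <- rpois(1, prof$fp_rate * sum(expressed))
      if (n_fp > 0) {
        fp_start <- floor(runif(n_fp, fp_zone_start,
                                cfg$chrom_length - 5000))
        fp_start <- fp_start - (fp_start %% 4) + (ci - 1)  # caller-unique
        fp <- junction_calls(
          chrom = sample(names(sim$chrom_lengths), n_fp, replace = TRUE),
          start = fp_start, end = fp_start + 300 +
            floor(runif(n_fp, 0, 2000)),
          strand = sample(c("+", "-"), n_fp, replace = TRUE),
          bsj_reads = sample(2:10, n_fp, replace = TRUE),
          caller_id = caller, sample_id = sid)
        fp <- fp[!duplicated(junction_key(fp)), , drop = FALSE]
        calls <- rbind(calls, fp)
        fp_rows[[paste(sid, caller)]] <-
          data.frame(key = junction_key(fp), sample_id = sid,
                     caller_id = caller, stringsAsFactors = FALSE)
      }
      ext <- if (caller == "ciri2") "tsv" else "bed"
      path <- file.path(dir, sprintf("%s.%s.%s", sid, caller, ext))
      write_caller_output(calls, path, caller)
      manifest[[paste(sid, caller)]] <-
        data.frame(path = path, sample_id = sid, caller_id = caller,
                   stringsAsFactors = FALSE)
    }
  }
  list(manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
       fp_truth = if (length(fp_rows))
         do.call(rbind, c(fp_rows, list(make.row.names = FALSE)))
       else data.frame(key = character(), sample_id = character(),
                       caller_id = character()))
}

#' Generate hallmark-style gene sets over the synthetic gene model
#'
#' @param sim A `sim_truth` bundle.
#' @return `list(sets, categories)`: named list of gene-id sets and the
#'   hallmark-to-category mapping.
#' @export
simulate_gene_sets <- function(sim) {
  cfg <- sim$config
  set.seed(stage_seed(sim$seed, "sets"))
  gene_ids <- sim$genes$gene_id
  sets <- list()
  categories <- character()
  for (cat in names(cfg$set_categories)) {
    for (i in seq_len(cfg$set_categories[[cat]])) {
      nm <- sprintf("HALLMARK_%s_%d", toupper(cat), i)
      size <- sample(cfg$set_size_min:cfg$set_size_max, 1)
      sets[[nm]] <- sort(sample(gene_ids, size))
      categories[nm] <- cat
    }
  }
  list(sets = sets, categories = categories)
}

#' Generate a pan-cancer reference catalogue with planted overlap
#'
#' Each truth key is absent from the reference with probability
#' `1 - ref_overlap_fraction` (those keys are study-specific by
#' construction); otherwise it is recorded under the study's own type plus
#' a number of other types drawn so that `ref_frac_many_types` of
#' overlapping keys sit in more than 15 other types.
#'
#' @param sim A `sim_truth` bundle.
#' @return Named list mapping key to type codes.
#' @export
simulate_reference <- function(sim) {
  cfg <- sim$config
  set.seed(stage_seed(sim$seed, "reference"))
  other_types <- setdiff(
    c(cfg$ref_own_type,
      sprintf("CT%02d", seq_len(cfg$ref_n_types - 1))), cfg$ref_own_type)
  keys <- sim$truth$key
  present <- runif(length(keys)) < cfg$ref_overlap_fraction
  reference <- lapply(which(present), function(i) {
    many <- runif(1) < cfg$ref_frac_many_types
    k <- if (many) sample(16:length(other_types), 1) else sample(1:15, 1)
    c(cfg$ref_own_type, sample(other_types, k))
  })
  setNames(reference, keys[present])
}

#' Simulate immune-abundance, gene-expression and clinical tables
#'
#' The designated cell-type column (`"T cells CD4 memory activated"`) is
#' tied to the target circRNA's CPM across tumour samples through a
#' Gaussian copula calibrated for the configured Spearman correlation
#' (`rho_z = 2 sin(pi rho / 6)`); the target host gene's expression is tied
#' the same way across all samples. Survival times are exponential with the
#' hazard scaled by the configured hazard ratio for subjects in the `high`
#' median-split group, censored at the follow-up horizon; the binary
#' adverse feature is drawn with the configured odds ratio between groups.
#'
#' @param sim A `sim_truth` bundle.
#' @param target Key of the designated circRNA; default picks the planted
#'   up-spike with the largest tumour mean (deterministic).
#' @return `list(target, immune, expression, clinical)`: the immune table
#'   (tumour samples x cell types), a host-gene expression matrix (genes x
#'   all samples) and the subject-level clinical table (`subject`,
#'   `expression`, `group`, `time`, `event`, `adverse_feature`).
#' @export
simulate_clinical <- function(sim, target = NULL) {
  cfg <- sim$config
  set.seed(stage_seed(sim$seed, "clinical"))
  if (is.null(target)) {
    ups <- sim$truth[sim$truth$status == "up", ]
    if (!nrow(ups)) stop("no planted up-regulated circRNA to target")
    target <- ups$key[which.max(ups$tumour_mean)]
  }
  if (!target %in% sim$truth$key) stop("unknown target circRNA: ", target)

  tum <- sim$samples$group == "tumour"
  tum_ids <- sim$samples$sample_id[tum]
  cpm_t <- sim$counts[target, tum_ids] * 1e6 /
    sim$samples$library_size[match(tum_ids, sim$samples$sample_id)]

  copula_partner <- function(values, rho_s) {
    rho_z <- 2 * sin(pi * rho_s / 6)
    n <- length(values)
    z1 <- qnorm((rank(values, ties.method = "average") - 0.5) / n)
    z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * rnorm(n)
    pnorm(z2)
  }

  cell_types <- c("T cells CD4 memory activated", "T cells CD4 naive",
                  "T cells CD8", "Eosinophils", "Macrophages M1",
                  "Macrophages M2", "NK cells", "B cells")
  cell_types <- cell_types[seq_len(min(cfg$n_cell_types, length(cell_types)))]
  immune <- sapply(cell_types, function(ct) {
    if (ct == "T cells CD4 memory activated") {
      0.3 * copula_partner(cpm_t, cfg$immune_rho)
    } else if (ct == "T cells CD4 naive") {
      0.3 * copula_partner(cpm_t, -cfg$immune_rho / 2)
    } else {
      0.3 * runif(length(cpm_t))
    }
  })
  rownames(immune) <- tum_ids

  # host-gene expression: hosts of every planted differential circRNA are
  # tied to their circRNA's CPM (so circ/host concordance is non-trivial),
  # plus background genes with independent noise
  all_ids <- sim$samples$sample_id
  de_rows <- which(sim$truth$status != "none" &
                     sim$truth$host_gene != "intergenic")
  de_hosts <- unique(sim$truth$host_gene[de_rows])
  host <- sim$truth$host_gene[sim$truth$key == target]
  de_hosts <- union(de_hosts, host)
  bg_genes <- setdiff(sim$genes$gene_id, de_hosts)[seq_len(40)]
  expression <- matrix(exp(rnorm(40 * length(all_ids), 3, 1)),
                       nrow = 40, dimnames = list(bg_genes, all_ids))
  for (g in de_hosts) {
    circ <- sim$truth$key[sim$truth$host_gene == g &
                            sim$truth$status != "none"][1]
    if (is.na(circ)) circ <- target
    cpm_g <- sim$counts[circ, all_ids] * 1e6 / sim$samples$library_size
    expression <- rbind(expression,
                        matrix(100 * copula_partner(cpm_g, cfg$host_rho),
                               nrow = 1, dimnames = list(g, all_ids)))
  }

  subj_expr <- exp(rnorm(cfg$n_subjects, cfg$spike_meanlog, 1))
  grp <- median_split(subj_expr)
  hazard <- cfg$baseline_hazard * ifelse(grp == "high", cfg$hazard_ratio, 1)
  t_raw <- rexp(cfg$n_subjects, rate = hazard)
  event <- as.integer(t_raw <= cfg$censor_time)
  time <- pmax(0.1, pmin(t_raw, cfg$censor_time))
  odds_low <- cfg$feature_p_low / (1 - cfg$feature_p_low)
  p_high <- odds_low * cfg$feature_or / (1 + odds_low * cfg$feature_or)
  feature <- rbinom(cfg$n_subjects, 1,
                    ifelse(grp == "high", p_high, cfg$feature_p_low))
  clinical <- data.frame(subject = sprintf("S%03d", seq_len(cfg$n_subjects)),
                         expression = subj_expr, group = unname(grp),
                         time = round(time, 2), event = event,
                         adverse_feature = feature, stringsAsFactors = FALSE)
  list(target = target, immune = immune, expression = expression,
       clinical = clinical)
}

write_gtf <- function(genes, path) {
  attrs <- sprintf(
    'gene_id "%s"; gene_name "%s"; gene_type "%s";',
    genes$gene_id, genes$gene_name, genes$biotype)
  lines <- sprintf("%s\tcircensus_sim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$chrom, genes$start + 1, genes$end, genes$strand,
                   attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a complete fixture bundle on disk
#'
#' Writes the sample sheet, four caller-dialect files per sample, a GTF
#' gene model, a hallmark GMT (plus a category map), the reference
#' pan-cancer catalogue, immune-abundance / gene-expression / clinical
#' tables, the planted-truth tables and a config echo. Byte-identical for a
#' fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @param dir Output directory.
#' @return Invisibly, a list with the in-memory simulation (`sim`,
#'   `callers`, `sets`, `reference`, `clinical`) and all file `paths`.
#' @export
simulate_bundle <- function(config = sim_config(), seed = 1, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_truth(config, seed)
  callers <- emulate_callers(sim, file.path(dir, "callers"))
  gs <- simulate_gene_sets(sim)
  reference <- simulate_reference(sim)
  clin <- simulate_clinical(sim)

  paths <- list(
    sample_sheet = file.path(dir, "samples.tsv"),
    gtf = file.path(dir, "genes.gtf"),
    gmt = file.path(dir, "hallmarks.gmt"),
    categories = file.path(dir, "hallmark_categories.tsv"),
    reference = file.path(dir, "reference_catalog.tsv"),
    immune = file.path(dir, "immune_abundance.tsv"),
    expression = file.path(dir, "gene_expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    caller_manifest = file.path(dir, "caller_manifest.tsv"),
    truth = file.path(dir, "truth_circ.tsv"),
    fp_truth = file.path(dir, "truth_false_positives.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write.table(sim$samples, paths$sample_sheet, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gtf(sim$genes, paths$gtf)
  write_gmt(gs$sets, paths$gmt)
  write.table(data.frame(hallmark = names(gs$categories),
                         category = unname(gs$categories)),
              paths$categories, sep = "\t", quote = FALSE, row.names = FALSE)
  write_reference_catalog(reference, paths$reference)
  # paths relative to the bundle dir, so bundles are location-independent
  rel_manifest <- callers$manifest
  rel_manifest$path <- file.path("callers", basename(rel_manifest$path))
  write.table(rel_manifest, paths$caller_manifest, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = rownames(clin$immune), clin$immune,
                         check.names = FALSE),
              paths$immune, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = rownames(clin$expression),
                         clin$expression, check.names = FALSE),
              paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(clin$clinical, paths$clinical, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(callers$fp_truth, paths$fp_truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  flat <- unlist(config)
  writeLines(c("# circensus synthetic bundle configuration",
               sprintf("seed: %s", seed),
               sprintf("%s: %s", names(flat), flat)), paths$config)
  invisible(list(sim = sim, callers = callers, sets = gs,
                 reference = reference, clinical = clin, paths = paths))
}
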