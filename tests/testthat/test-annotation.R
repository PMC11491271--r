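genes_fixture <- function() {
  data.frame(
    gene_id = c("AATF", "BIG", "SMALL", "OPP"),
    gene_name = c("AATF", "BIG", "SMALL", "OPP"),
    biotype = c("protein_coding", "protein_coding", "lncRNA",
                "protein_coding"),
    chrom = c("chr17", "chr1", "chr1", "chr1"),
    strand = c("+", "+", "+", "-"),
    start = c(36950000, 1000, 1450, 900),
    end = c(36960000, 2000, 1650, 2500),
    stringsAsFactors = FALSE)
}

test_that("host genes follow strand, overlap-length and id tie-breaking", {
  model <- make_gene_model(genes_fixture())
  catalog <- data.frame(
    chrom = c("chr17", "chr9", "chr1", "chr1"),
    start = c(36952885, 100, 1100, 1200),
    end = c(36953907, 500, 1600, 1600),
    strand = c("+", "+", "+", "-"),
    stringsAsFactors = FALSE)
  catalog$key <- junction_key(catalog)
  expect_warning(ann <- assign_host_genes(catalog, model), "chr9")
  # wholly inside a same-strand gene
  expect_equal(ann$host_gene[1], "AATF")
  expect_equal(ann$circ_name[1], "circAATF")
  # no overlapping gene (chromosome absent from the model)
  expect_equal(ann$host_gene[2], "intergenic")
  expect_true(is.na(ann$circ_name[2]))
  # same-strand candidates BIG (overlap 500) vs SMALL (overlap 150)
  expect_equal(ann$host_gene[3], "BIG")
  # same-strand OPP wins over larger-overlap opposite-strand genes
  expect_equal(ann$host_gene[4], "OPP")
  # without strand preference the largest overlap wins
  expect_warning(flat <- assign_host_genes(catalog, model,
                                           prefer_strand = FALSE))
  expect_equal(flat$host_gene[4], "BIG")
})

test_that("interval assignment agrees with the all-pairs scan oracle", {
  set.seed(5)
  n_genes <- 150
  gstart <- sample(0:90000, n_genes)
  genes <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n_genes)),
    gene_name = sprintf("G%03d", seq_len(n_genes)),
    biotype = "protein_coding",
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = gstart, end = gstart + sample(500:8000, n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  model <- make_gene_model(genes)
  cstart <- sample(0:95000, 300)
  catalog <- data.frame(
    chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
    start = cstart, end = cstart + sample(100:4000, 300, replace = TRUE),
    strand = sample(c("+", "-", "."), 300, replace = TRUE),
    stringsAsFactors = FALSE)
  catalog$key <- junction_key(catalog)
  ann <- assign_host_genes(catalog, model)
  expect_equal(ann$host_gene, oracle_assign_hosts(catalog, genes))
  ann2 <- assign_host_genes(catalog, model, prefer_strand = FALSE)
  expect_equal(ann2$host_gene,
               oracle_assign_hosts(catalog, genes, prefer_strand = FALSE))
})

test_that("gene-level aggregation is exactly additive and conservative", {
  model <- make_gene_model(genes_fixture())
  catalog <- data.frame(
    chrom = c("chr17", "chr17", "chr1", "chr1"),
    start = c(36952000, 36955000, 1100, 5000),
    end = c(36953000, 36956000, 1400, 5500),
    strand = c("+", "+", "+", "+"), stringsAsFactors = FALSE)
  catalog$key <- junction_key(catalog)
  ann <- assign_host_genes(catalog, model)
  expect_equal(ann$host_gene, c("AATF", "AATF", "BIG", "intergenic"))
  mat <- matrix(c(3, 2, 7, 1, 0, 5, 4, 9), nrow = 4,
                dimnames = list(catalog$key, c("T01", "N01")))
  attr(mat, "normalised") <- TRUE
  agg <- aggregate_gene_bsj(mat, ann)
  expect_equal(unname(agg$matrix["AATF", "T01"]), 5.0)     # 3 + 2
  expect_false("SMALL" %in% rownames(agg$matrix))          # no circRNAs
  # conservation: totals over genes equal totals over genic circRNAs
  expect_equal(sum(agg$matrix), sum(mat[1:3, ]))
  expect_equal(agg$gene_summary$n_circ[agg$gene_summary$gene_id == "AATF"],
               2L)
  raw <- mat
  attr(raw, "normalised") <- FALSE
  expect_error(aggregate_gene_bsj(raw, ann), "normalised")
})

test_that("window density bins by start and conserves totals", {
  samples <- make_samples(1)
  lengths <- c(chr1 = 3e6)
  empty <- window_density(
    data.frame(chrom = character(), start = numeric(),
               sample_id = character(), reads = numeric()),
    samples, lengths)
  expect_equal(nrow(empty), 3)
  expect_true(all(empty$reads == 0))

  junctions <- data.frame(chrom = "chr1", start = 1500000,
                          sample_id = "T01", reads = 4,
                          stringsAsFactors = FALSE)
  track <- window_density(junctions, samples, lengths)  # library 1e6: CPM=raw
  expect_equal(track$reads[track$win_start == 1e6], 4.0)
  expect_equal(sum(track$reads), 4.0)

  set.seed(3)
  many <- data.frame(chrom = "chr1", start = sample(0:(3e6 - 1), 200),
                     sample_id = sample(samples$sample_id, 200,
                                        replace = TRUE),
                     reads = sample(1:20, 200, replace = TRUE),
                     stringsAsFactors = FALSE)
  track2 <- window_density(many, samples, lengths)
  expect_equal(sum(track2$reads), sum(many$reads * 1e6 / 1e6))
  expect_error(window_density(many, samples, lengths, window_size = 0),
               "positive")
})

test_that("biotype summary counts each host gene once", {
  ann <- data.frame(
    key = sprintf("k%d", 1:5),
    host_gene = c("A", "A", "B", "C", "X"),
    host_biotype = c("protein_coding", "protein_coding", "protein_coding",
                     "lncRNA", NA),
    stringsAsFactors = FALSE)
  ann$host_gene[5] <- "intergenic"
  out <- biotype_summary(ann)
  expect_equal(out$n_genes[out$biotype == "protein_coding"], 2L)
  expect_equal(out$percent[out$biotype == "protein_coding"], 66.7)
  expect_equal(nrow(biotype_summary(ann[0, ])), 0L)
  all_coding <- biotype_summary(ann[1:3, ])
  expect_equal(all_coding$percent, 100.0)
})
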