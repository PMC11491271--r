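small_cfg <- function(...) {
  sim_config("reduced", n_circ = 80L, n_genes = 120L, ...)
}

test_that("bundles are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_bundle(small_cfg(), seed = 3, dir = d1)
  simulate_bundle(small_cfg(), seed = 3, dir = d2)
  simulate_bundle(small_cfg(), seed = 4, dir = d3)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  expect_equal(files, list.files(d2, recursive = TRUE))
  same <- vapply(files, function(f) {
    identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }, logical(1))
  expect_true(all(same))
  differs <- vapply(setdiff(files, "config.yaml"), function(f) {
    !identical(readLines(file.path(d1, f)), readLines(file.path(d3, f)))
  }, logical(1))
  expect_true(any(differs))
})

test_that("truth respects configured fractions and effect sizes", {
  no_de <- simulate_truth(small_cfg(de_frac_up = 0, de_frac_down = 0),
                          seed = 2)
  expect_true(all(no_de$truth$status == "none"))

  cfg <- sim_config("full", n_circ = 400L)
  sim <- simulate_truth(cfg, seed = 6)
  expect_equal(sum(sim$truth$status == "up"), round(0.04 * 400))
  # planted log2fc = 2: group mean ratios concentrate near 4
  depth <- sim$samples$library_size / mean(sim$samples$library_size)
  scaled <- sweep(sim$counts, 2, depth, "/")
  up <- sim$truth$status == "up"
  ratio <- rowMeans(scaled[up, sim$samples$group == "tumour"]) /
    rowMeans(scaled[up, sim$samples$group == "NAT"])
  # each ratio has CV ~ sqrt(2 * (1/mu + disp) / n); 3-SE band on the mean
  se <- sd(ratio) / sqrt(sum(up))
  expect_lt(abs(mean(ratio) - 4), 3 * se + 0.2)

  # intergenic circRNAs never fall inside a gene span
  ig <- sim$truth[sim$truth$host_gene == "intergenic", ]
  for (i in seq_len(nrow(ig))) {
    g <- sim$genes[sim$genes$chrom == ig$chrom[i], ]
    expect_false(any(pmin(ig$end[i], g$end) > pmax(ig$start[i], g$start)))
  }
})

test_that("the noiseless caller limit recovers filter-passing truth exactly", {
  cfg <- small_cfg(read_jitter = FALSE,
                   caller_profiles = list(
                     find_circ = list(sensitivity = 1, fp_rate = 0),
                     circrna_finder = list(sensitivity = 1, fp_rate = 0),
                     ciri2 = list(sensitivity = 1, fp_rate = 0),
                     circexplorer2 = list(sensitivity = 1, fp_rate = 0)))
  dir <- withr::local_tempdir()
  sim <- simulate_truth(cfg, seed = 8)
  em <- emulate_callers(sim, dir)
  expect_equal(nrow(em$fp_truth), 0L)
  calls <- do.call(rbind, lapply(seq_len(nrow(em$manifest)), function(i) {
    parse_caller_output(em$manifest$path[i], em$manifest$caller_id[i],
                        em$manifest$sample_id[i])
  }))
  merged <- do.call(rbind, lapply(split(calls, calls$sample_id),
                                  merge_sample_calls))
  built <- build_catalog(merged, sim$samples)
  # expectation: thresholds applied directly to the true counts
  grp <- sim$samples$group
  pass <- sim$counts >= 2
  expected <- rownames(sim$counts)[
    rowSums(pass[, grp == "tumour"]) >= 5 | rowSums(pass[, grp == "NAT"]) >= 5]
  expect_setequal(built$catalog$key, expected)
})

test_that("a single sensitive caller cannot reach the consensus filter", {
  cfg <- small_cfg(caller_profiles = list(
    find_circ = list(sensitivity = 1, fp_rate = 0),
    circrna_finder = list(sensitivity = 0, fp_rate = 0),
    ciri2 = list(sensitivity = 0, fp_rate = 0),
    circexplorer2 = list(sensitivity = 0, fp_rate = 0)))
  dir <- withr::local_tempdir()
  sim <- simulate_truth(cfg, seed = 9)
  em <- emulate_callers(sim, dir)
  calls <- do.call(rbind, lapply(seq_len(nrow(em$manifest)), function(i) {
    parse_caller_output(em$manifest$path[i], em$manifest$caller_id[i],
                        em$manifest$sample_id[i])
  }))
  merged <- do.call(rbind, lapply(split(calls, calls$sample_id),
                                  merge_sample_calls))
  expect_equal(nrow(build_catalog(merged, sim$samples)$catalog), 0L)
})

test_that("default caller profiles exclude every planted false positive", {
  for (s in 1:2) {
    dir <- withr::local_tempdir()
    sim <- simulate_truth(small_cfg(), seed = s)
    em <- emulate_callers(sim, dir)
    calls <- do.call(rbind, lapply(seq_len(nrow(em$manifest)), function(i) {
      parse_caller_output(em$manifest$path[i], em$manifest$caller_id[i],
                          em$manifest$sample_id[i])
    }))
    merged <- do.call(rbind, lapply(split(calls, calls$sample_id),
                                    merge_sample_calls))
    built <- build_catalog(merged, sim$samples)
    expect_gt(nrow(em$fp_truth), 0)
    expect_equal(sum(unique(em$fp_truth$key) %in% built$catalog$key), 0L)
    # every catalogue key traces back to planted truth
    expect_true(all(built$catalog$key %in% sim$truth$key))
  }
})

test_that("clinical simulation honours correlation and hazard parameters", {
  # null correlation: |rho| below the 3/sqrt(n) sampling bound
  sim0 <- simulate_truth(sim_config("reduced", n_circ = 60L,
                                    immune_rho = 0, host_rho = 0), seed = 12)
  clin0 <- simulate_clinical(sim0)
  tum <- sim0$samples$sample_id[sim0$samples$group == "tumour"]
  cpm <- sim0$counts[clin0$target, tum] * 1e6 /
    sim0$samples$library_size[match(tum, sim0$samples$sample_id)]
  rho0 <- cor(cpm, clin0$immune[tum, "T cells CD4 memory activated"],
              method = "spearman")
  expect_lt(abs(rho0), 3 / sqrt(length(tum)))

  # strong correlation at n = 40 tumour samples
  sim9 <- simulate_truth(sim_config("full", n_pairs = 40L, n_circ = 60L,
                                    immune_rho = 0.9), seed = 13)
  clin9 <- simulate_clinical(sim9)
  tum9 <- sim9$samples$sample_id[sim9$samples$group == "tumour"]
  cpm9 <- sim9$counts[clin9$target, tum9] * 1e6 /
    sim9$samples$library_size[match(tum9, sim9$samples$sample_id)]
  rho9 <- cor(cpm9, clin9$immune[tum9, "T cells CD4 memory activated"],
              method = "spearman")
  expect_gt(rho9, 0.75)
  expect_lt(rho9, 0.98)

  # hazard ratio 1: log-rank p roughly uniform across replicate seeds
  pvals <- vapply(1:30, function(s) {
    sim <- simulate_truth(sim_config("reduced", n_pairs = 3L, n_circ = 40L,
                                     hazard_ratio = 1), seed = 100 + s)
    clin <- simulate_clinical(sim)$clinical
    logrank_test(clin$time, clin$event, clin$group)$pvalue
  }, numeric(1))
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)

  expect_error(simulate_clinical(sim0, target = "chrZ:1|2:+"), "unknown")
})
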