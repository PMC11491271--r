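# Independent oracle implementations used across test files. These are
# deliberately naive re-derivations of the contracts (loops, enumeration),
# kept free of any code path they are used to check.

# random harmonised junction calls on a small genome
random_calls <- function(n, seed, samples = c("s1", "s2"),
                         callers = c("find_circ", "ciri2")) {
  set.seed(seed)
  start <- sample(0:99999, n, replace = TRUE)
  junction_calls(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start,
    end = start + sample(100:5000, n, replace = TRUE),
    strand = sample(c("+", "-", "."), n, replace = TRUE),
    bsj_reads = sample(0:50, n, replace = TRUE),
    caller_id = sample(callers, n, replace = TRUE),
    sample_id = sample(samples, n, replace = TRUE)
  )
}

make_samples <- function(n_pairs, libsize = 1e6) {
  data.frame(
    sample_id = c(sprintf("T%02d", seq_len(n_pairs)),
                  sprintf("N%02d", seq_len(n_pairs))),
    group = rep(c("tumour", "NAT"), each = n_pairs),
    pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2),
    library_size = libsize,
    stringsAsFactors = FALSE
  )
}

# writes a gene table as GTF and loads it through the package reader
make_gene_model <- function(genes) {
  path <- tempfile(fileext = ".gtf")
  lines <- sprintf(
    "%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\"; gene_type \"%s\";",
    genes$chrom, genes$start + 1, genes$end, genes$strand, genes$gene_id,
    genes$gene_name, genes$biotype)
  writeLines(lines, path)
  read_gene_model(path)
}

# literal re-evaluation of the three consensus rules over per-call records
oracle_consensus_filter <- function(calls, samples, min_callers = 2,
                                    min_reads = 2, min_samples = 5) {
  key <- junction_key(calls)
  surviving <- list()
  for (s in unique(calls$sample_id)) {
    in_s <- calls$sample_id == s
    for (k in unique(key[in_s])) {
      rows <- which(in_s & key == k)
      per_caller <- tapply(calls$bsj_reads[rows], calls$caller_id[rows], sum)
      if (length(per_caller) >= min_callers &&
          mean(per_caller) >= min_reads) {
        surviving[[length(surviving) + 1]] <-
          data.frame(key = k, sample_id = s, mean_reads = mean(per_caller))
      }
    }
  }
  surv <- if (length(surviving)) do.call(rbind, surviving) else
    data.frame(key = character(), sample_id = character(),
               mean_reads = numeric())
  grp <- setNames(samples$group, samples$sample_id)
  kept <- character()
  for (k in unique(surv$key)) {
    ss <- surv$sample_id[surv$key == k]
    if (sum(grp[ss] == "tumour") >= min_samples ||
        sum(grp[ss] == "NAT") >= min_samples) kept <- c(kept, k)
  }
  list(keys = sort(kept), survivors = surv)
}

# brute-force BH by the literal step-up definition, double loop
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    candidates <- vapply(seq_len(n), function(j) {
      if (r[j] >= r[i]) n * p[j] / r[j] else Inf
    }, numeric(1))
    min(1, min(candidates))
  }, numeric(1))
}

# step-enumerated GSVA-style walk for one sample and one set
oracle_gsva_walk <- function(mat, set, sample, tau = 1) {
  n <- ncol(mat)
  N <- nrow(mat)
  # ecdf statistic by explicit tie-averaged rank counting
  stat <- vapply(rownames(mat), function(g) {
    v <- mat[g, ]
    x <- mat[g, sample]
    (sum(v < x) + (sum(v == x) + 1) / 2) / n
  }, numeric(1))
  ord <- order(-stat, rownames(mat))
  genes <- rownames(mat)[ord]
  w <- abs((N + 1) / 2 - seq_len(N))^tau
  inset <- genes %in% set
  denom_in <- sum(w[inset])
  denom_out <- N - sum(inset)
  level <- 0
  walk <- numeric(N)
  for (i in seq_len(N)) {
    level <- level + if (inset[i]) w[i] / denom_in else -1 / denom_out
    walk[i] <- level
  }
  max(c(0, walk)) + min(c(0, walk))
}

# exhaustive hypergeometric upper tail by enumerating draws
oracle_hypergeom_enum <- function(N, K, n, k) {
  universe <- seq_len(N)
  successes <- seq_len(K)
  draws <- combn(N, n)
  overlaps <- apply(draws, 2, function(d) sum(d %in% successes))
  mean(overlaps >= k)
}

# log-rank by explicit at-risk table evaluation
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  obs <- exp <- v <- 0
  for (tj in sort(unique(time[event == 1]))) {
    n1 <- sum(time >= tj & g1); n2 <- sum(time >= tj & !g1)
    d <- sum(time == tj & event == 1)
    d1 <- sum(time == tj & event == 1 & g1)
    nn <- n1 + n2
    obs <- obs + d1
    exp <- exp + d * n1 / nn
    if (nn > 1) v <- v + d * n1 * n2 * (nn - d) / (nn^2 * (nn - 1))
  }
  (obs - exp)^2 / v
}

# exact two-sided rank-sum p by enumeration of group assignments
oracle_wilcoxon_enum <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  na <- length(a)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  us <- apply(combn(n, na), 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# naive all-pairs host assignment with the documented preference order
oracle_assign_hosts <- function(catalog, genes, prefer_strand = TRUE) {
  vapply(seq_len(nrow(catalog)), function(i) {
    ov <- pmin(catalog$end[i], genes$end) - pmax(catalog$start[i], genes$start)
    cand <- which(genes$chrom == catalog$chrom[i] & ov > 0)
    if (!length(cand)) return("intergenic")
    same <- genes$strand[cand] == catalog$strand[i]
    ord <- order(if (prefer_strand) !same else rep(FALSE, length(cand)),
                 -ov[cand], genes$gene_id[cand])
    genes$gene_id[cand[ord[1]]]
  }, character(1))
}
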