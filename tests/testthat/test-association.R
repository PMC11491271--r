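test_that("Spearman correlations follow rank arithmetic and rank invariance", {
  x <- matrix(c(1, 2, 3, 4, 5,
                1, 2, 3, 4, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("x1", "x2"), paste0("s", 1:5)))
  y <- matrix(c(2, 4, 6, 8, 100,      # monotone transform of x1
                5, 4, 3, 2, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("y1", "y2"), paste0("s", 1:5)))
  res <- spearman_fdr(x, y, data.frame(x_id = c("x1", "x1"),
                                       y_id = c("y1", "y2")))
  expect_equal(res$rho, c(1, -1))
  expect_equal(res$pvalue, c(0, 0))

  # hand rank arithmetic on n = 5 (t approximation needs n >= 4)
  x5 <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list("a", paste0("s", 1:5)))
  y5 <- matrix(c(3, 1, 2, 5, 4), 1, dimnames = list("b", paste0("s", 1:5)))
  r5 <- spearman_fdr(x5, y5, data.frame(x_id = "a", y_id = "b"))
  expect_equal(r5$rho, cor(1:5, c(3, 1, 2, 5, 4), method = "spearman"))
  expect_equal(r5$pvalue,
               cor.test(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4),
                        method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-10)

  # invariance under strictly increasing transforms
  set.seed(9)
  xv <- matrix(rnorm(12), 1, dimnames = list("a", paste0("s", 1:12)))
  yv <- matrix(rnorm(12), 1, dimnames = list("b", paste0("s", 1:12)))
  base <- spearman_fdr(xv, yv, data.frame(x_id = "a", y_id = "b"))
  trans <- spearman_fdr(exp(xv), yv^3 + 10 * yv,
                        data.frame(x_id = "a", y_id = "b"))
  expect_equal(trans$rho, base$rho)
  expect_equal(trans$pvalue, base$pvalue)

  flat <- matrix(1, 1, 12, dimnames = list("a", paste0("s", 1:12)))
  expect_warning(cc <- spearman_fdr(flat, yv,
                                    data.frame(x_id = "a", y_id = "b")),
                 "constant")
  expect_true(is.na(cc$rho))
  expect_error(spearman_fdr(xv[, 1:3, drop = FALSE],
                            yv[, 1:3, drop = FALSE],
                            data.frame(x_id = "a", y_id = "b")),
               "at least 4")
})

test_that("octant classification partitions and reproduces percentages", {
  circ <- data.frame(key = c("a", "b", "c", "d"),
                     call = c("up", "up", "down", "none"))
  host <- data.frame(key = c("a", "b", "c", "d"),
                     call = c("up", "down", "none", "none"))
  out <- classify_change_octants(circ, host)
  expect_equal(out$pairs$region, c("up/up", "up/down", "down/none",
                                   "unchanged"))
  expect_equal(out$pairs$consistent, c(TRUE, FALSE, FALSE, FALSE))

  set.seed(21)
  calls <- c("up", "down", "none")
  rnd_circ <- data.frame(key = sprintf("k%03d", 1:200),
                         call = sample(calls, 200, replace = TRUE))
  rnd_host <- data.frame(key = sprintf("k%03d", 1:200),
                         call = sample(calls, 200, replace = TRUE))
  rnd <- classify_change_octants(rnd_circ, rnd_host)
  # every pair in exactly one region; eight octants + unchanged only
  expect_equal(nrow(rnd$pairs), 200L)
  expect_true(all(rnd$pairs$region %in%
                    c(paste(rep(calls, each = 3), rep(calls, 3), sep = "/")
                      [-9], "unchanged")))
  expect_equal(sum(rnd$pairs$consistent) +
                 sum(!rnd$pairs$consistent & rnd$pairs$region != "unchanged") +
                 sum(rnd$pairs$region == "unchanged"), 200L)

  # cohort-scale worked percentages
  expect_equal(concordance_percent(47, 959), 4.9)
  expect_equal(concordance_percent(34, 466), 7.3)
  expect_error(classify_change_octants(
    data.frame(key = "z", call = "up"), host), "host-gene call")
})

test_that("median split sends ties to low", {
  expect_equal(unname(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(unname(median_split(c(7, 7, 7))), rep("low", 3))
  expect_error(median_split(5), "at least 2")
  set.seed(2)
  v <- rlnorm(50)
  split <- median_split(v)
  expect_equal(sum(split == "low") + sum(split == "high"), 50L)
  expect_true(all(v[split == "high"] > median(v)))
})

test_that("Pearson chi-squared reproduces the six clinicopathological rows", {
  # 2x2 tables (rows = categories, cols = low/high) with published statistics
  tables <- list(
    gender      = list(m = rbind(c(15, 17), c(8, 10)), chi2 = 0.0274),
    age         = list(m = rbind(c(8, 8), c(15, 19)), chi2 = 0.1516),
    tnm         = list(m = rbind(c(9, 3), c(14, 24)), chi2 = 5.3461),
    tumour_size = list(m = rbind(c(12, 5), c(11, 22)), chi2 = 6.2691),
    lymph_node  = list(m = rbind(c(10, 2), c(13, 25)), chi2 = 8.8601),
    stage       = list(m = rbind(c(15, 4), c(8, 23)), chi2 = 13.3910)
  )
  for (nm in names(tables)) {
    res <- pearson_chisq(tables[[nm]]$m)
    expect_equal(res$chi2, tables[[nm]]$chi2, tolerance = 1e-3,
                 info = nm)
    expect_equal(res$pvalue,
                 chisq.test(tables[[nm]]$m, correct = FALSE)$p.value,
                 tolerance = 1e-10, info = nm)
  }
  expect_equal(pearson_chisq(rbind(c(10, 10), c(20, 20)))$chi2, 0)
  expect_error(pearson_chisq(rbind(c(0, 0), c(5, 5))), "margins")
  expect_error(pearson_chisq(matrix(1, 3, 2)), "2x2")
})

test_that("log-rank agrees with oracles on small instances", {
  ident <- logrank_test(time = c(1, 2, 3, 1, 2, 3),
                        event = c(1, 1, 1, 1, 1, 1),
                        group = rep(c("a", "b"), each = 3))
  expect_equal(ident$chi2, 0)
  expect_equal(ident$pvalue, 1)

  toy <- logrank_test(time = c(1, 2, 3, 4), event = rep(1, 4),
                      group = c("A", "A", "B", "B"))
  expect_equal(toy$chi2,
               oracle_logrank(c(1, 2, 3, 4), rep(1, 4),
                              c("A", "A", "B", "B")))

  set.seed(31)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    time <- sample(1:20, n, replace = TRUE)
    event <- rbinom(n, 1, 0.8)
    group <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    ours <- logrank_test(time, event, group)
    expect_equal(ours$chi2, oracle_logrank(time, event, group),
                 tolerance = 1e-12)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(ours$chi2, sd$chisq, tolerance = 1e-9)
  }
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "two groups")
  expect_error(logrank_test(c(0, 2), c(1, 1), c("a", "b")), "positive")
})

test_that("rank-sum test matches enumeration and the reference oracle", {
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$pvalue, 1)

  small <- wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(small$pvalue, 1 / 6, tolerance = 1e-12)

  set.seed(41)
  for (rep in 1:10) {
    a <- round(rnorm(sample(3:6, 1)), 4)   # continuous: no ties
    b <- round(rnorm(sample(3:6, 1)) + 0.3, 4)
    ours <- wilcoxon_rank_sum(a, b)
    expect_equal(ours$pvalue, oracle_wilcoxon_enum(a, b), tolerance = 1e-12)
    expect_equal(ours$pvalue,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  # large-sample branch against the reference with continuity correction
  set.seed(43)
  a <- rnorm(25); b <- rnorm(30) + 0.5
  ours <- wilcoxon_rank_sum(a, b)
  expect_equal(ours$pvalue,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  # rank invariance under common monotone transform
  expect_equal(wilcoxon_rank_sum(exp(a), exp(b))$pvalue, ours$pvalue)

  fold <- wilcoxon_rank_sum(c(10, 20, 30), c(2, 4, 6))
  expect_equal(fold$fold_change, 5)
  expect_true(is.na(wilcoxon_rank_sum(c(1, 2), c(-1, 1))$fold_change))
})
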