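#' Spearman correlations for a family of requested pairs
#'
#' For each requested (row of `x`, row of `y`) pair, computes Spearman's rho
#' with average ranks for ties and a p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' FDR is BH-adjusted across exactly the requested family (not all-vs-all).
#' A constant vector leaves rho undefined; the pair is reported with `NA`
#' and a warning.
#'
#' @param x,y Numeric matrices with identical, aligned sample columns.
#' @param pairs `data.frame` with columns `x_id`, `y_id` naming rows of `x`
#'   and `y`.
#' @return `data.frame`: `x_id`, `y_id`, `rho`, `pvalue`, `qvalue`.
#' @export
spearman_fdr <- function(x, y, pairs) {
  if (!identical(colnames(x), colnames(y))) {
    stop("x and y must share identical sample columns")
  }
  n <- ncol(x)
  if (n < 4) stop("need at least 4 paired samples")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    xv <- x[pairs$x_id[i], ]
    yv <- y[pairs$y_id[i], ]
    if (sd(xv) == 0 || sd(yv) == 0) {
      warning("constant vector for pair ", pairs$x_id[i], " / ",
              pairs$y_id[i], "; rho undefined")
      return(c(rho = NA_real_, p = NA_real_))
    }
    rho <- cor(rank(xv), rank(yv))
    if (abs(rho) >= 1) return(c(rho = rho, p = 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    c(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
  })
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_adjust(p[ok])
  data.frame(x_id = pairs$x_id, y_id = pairs$y_id, rho = rho, pvalue = p,
             qvalue = q, stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify circRNA/host-gene expression-change concordance
#'
#' Crosses each circRNA's differential call with its host gene's call into
#' one of eight change regions (`"up/up"`, `"up/none"`, ..., `"down/down"`,
#' circRNA status first) or `"unchanged"` for none/none. A pair is
#' *consistent* when both move in the same direction (`up/up` or
#' `down/down`). The summary reports, separately for circ-up and circ-down
#' entries, the count and 1-decimal percentage of consistent pairs.
#'
#' @param circ_calls `data.frame` with `key`, `call` for circRNAs.
#' @param host_calls `data.frame` with `key`, `call` for the matched host
#'   genes (same keys; intergenic circRNAs must be excluded beforehand).
#' @return `list(pairs, summary)`: per-pair regions and the concordance
#'   summary `data.frame` (`direction`, `n`, `k_consistent`, `percent`).
#' @export
classify_change_octants <- function(circ_calls, host_calls) {
  m <- match(circ_calls$key, host_calls$key)
  if (anyNA(m)) stop("every circRNA needs a host-gene call")
  circ <- circ_calls$call
  host <- host_calls$call[m]
  ok <- c("up", "down", "none")
  if (!all(circ %in% ok) || !all(host %in% ok)) {
    stop("calls must be 'up', 'down' or 'none'")
  }
  region <- ifelse(circ == "none" & host == "none", "unchanged",
                   paste(circ, host, sep = "/"))
  pairs <- data.frame(key = circ_calls$key, circ_status = circ,
                      host_status = host, region = region,
                      consistent = region %in% c("up/up", "down/down"),
                      stringsAsFactors = FALSE, row.names = NULL)
  summary <- do.call(rbind, lapply(c("up", "down"), function(d) {
    sub <- pairs[pairs$circ_status == d, ]
    n <- nrow(sub); k <- sum(sub$consistent)
    data.frame(direction = d, n = n, k_consistent = k,
               percent = if (n > 0) round(100 * k / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, summary = summary)
}

#' Concordance percentage for given counts
#'
#' The rendering rule used in the concordance summary: `100 * k / n`
#' rounded to 1 decimal.
#'
#' @param k Number of consistent pairs.
#' @param n Number of pairs in the direction.
#' @return Percentage, 1 decimal.
#' @export
concordance_percent <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  round(100 * k / n, 1)
}

#' Median split into high/low expression groups
#'
#' Subjects at or below the median are labelled `low`; above the median,
#' `high` (ties go to `low`).
#'
#' @param values Numeric vector (length >= 2), optionally named.
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  labels <- ifelse(values <= median(values), "low", "high")
  names(labels) <- names(values)
  labels
}

#' Pearson chi-squared test on a 2x2 table
#'
#' `chi2 = sum (O - E)^2 / E` with expected counts from the margins; no
#' continuity correction. The p-value is the 1-df upper chi-squared tail.
#'
#' @param tab 2x2 matrix of nonnegative counts with positive margins.
#' @return `list(table, chi2, pvalue)`.
#' @export
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins must be positive")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  list(table = tab, chi2 = chi2,
       pvalue = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in the first
#' group is compared with its hypergeometric expectation given the at-risk
#' counts; the statistic is `(sum O - sum E)^2 / sum V` with the
#' hypergeometric variance, and the p-value is the 1-df chi-squared upper
#' tail.
#'
#' @param time Positive follow-up times.
#' @param event Logical/0-1 event indicators (1 = event, 0 = censored).
#' @param group Two-level group labels.
#' @return `list(chi2, pvalue, observed, expected)` with per-group observed
#'   and expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  if (any(time <= 0)) stop("times must be positive")
  group <- as.character(group)
  levels_ <- sort(unique(group))
  if (length(levels_) != 2) stop("need exactly two groups")
  if (min(table(group)) == 0) stop("a group is empty")
  event <- as.integer(event)
  if (sum(event) < 1) stop("need at least one event")
  g1 <- group == levels_[1]
  times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (tj in times) {
    at_risk <- time >= tj
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(time == tj & event == 1)
    d1_j <- sum(time == tj & event == 1 & g1)
    o1 <- o1 + d1_j
    e1 <- e1 + d_j * n1_j / n_j
    if (n_j > 1) {
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  total <- sum(event)
  list(chi2 = chi2, pvalue = pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = setNames(c(o1, total - o1), levels_),
       expected = setNames(c(e1, total - e1), levels_))
}

#' Wilcoxon rank-sum test with median fold change
#'
#' Ranks are averaged over ties. For a pooled size of at most 20 the
#' two-sided p-value is computed by exhaustive enumeration of group
#' assignments (a permutation null, exact under ties too); for larger
#' samples the normal approximation with continuity correction and the
#' tie-corrected variance is used. Also reports `median(a) / median(b)`
#' (reported as `NA` when `median(b)` is zero).
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   referring to the location of `a` relative to `b`.
#' @return `list(statistic, pvalue, fold_change)` where `statistic` is the
#'   Mann-Whitney U of `a`.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (n <= 20) {
    combos <- combn(n, na)
    us <- apply(combos, 2, function(idx) {
      sum(r[idx]) - na * (na + 1) / 2
    })
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(us - mu) >= abs(u - mu) - eps),
      greater = mean(us >= u - eps),
      less = mean(us <= u + eps))
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    correction <- switch(alternative, two.sided = sign(u - mu) * 0.5,
                         greater = 0.5, less = -0.5)
    z <- (u - mu - correction) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z))
  }
  fold <- if (median(b) == 0) NA_real_ else median(a) / median(b)
  list(statistic = u, pvalue = min(1, p), fold_change = fold)
}
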