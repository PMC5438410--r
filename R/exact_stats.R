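#' Exact and asymptotic tests for small-sample contingency and rank data
#'
#' These are the workhorse tests behind the validation-assay and
#' cross-sectional analyses: a two-sided Fisher exact test on 2x2 tables
#' (minimum-likelihood definition), the Pearson chi-square test on r x c
#' tables, and an exact Mann-Whitney U test whose null distribution is the
#' complete permutation distribution of group labelings. All tests are
#' two-sided.
#'
#' @name exact_stats
NULL

#' Construct a validated 2x2 contingency table
#'
#' @param a,b,c,d Non-negative integer cell counts; `a`,`b` form the first
#'   row and `c`,`d` the second.
#' @return An object of class `contingency_2x2` (a 2x2 integer matrix).
#' @examples
#' contingency_2x2(13, 0, 9, 11)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("all cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) {
    stop("table is all zero: test undefined", call. = FALSE)
  }
  m <- matrix(as.integer(round(cells)), nrow = 2, byrow = TRUE)
  class(m) <- c("contingency_2x2", class(m))
  m
}

new_test_result <- function(method, statistic, p_value, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(method = method, statistic = statistic,
         p_value = min(p_value, 1), sidedness = "two-sided", ...),
    class = "pnet_test_result"
  )
}

#' @export
print.pnet_test_result <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic) && !is.na(x$statistic)) {
    cat("  statistic:", format(x$statistic), "\n")
  }
  cat("  two-sided p:", format(x$p_value), "\n")
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Computes point probabilities of every table compatible with the observed
#' margins from the hypergeometric distribution and sums those no more
#' probable than the observed table (the minimum-likelihood two-sided
#' definition, as in standard statistical software). The alternative
#' "double the smaller tail" definition is available via `method`.
#'
#' @param table A `contingency_2x2` (or any 2x2 matrix of non-negative
#'   integer counts).
#' @param method `"minimum_likelihood"` (default) or `"double_tail"`.
#' @return A `pnet_test_result` with the sample odds ratio as statistic
#'   (`Inf`/0 flagged via `or_degenerate`) and the two-sided p-value.
#' @examples
#' fisher_exact_2x2(contingency_2x2(13, 0, 9, 11))  # p ~ 0.0016
#' @export
fisher_exact_2x2 <- function(table,
                             method = c("minimum_likelihood", "double_tail")) {
  method <- match.arg(method)
  if (!is.matrix(table) || !all(dim(table) == 2)) {
    table <- contingency_2x2(table[1], table[2], table[3], table[4])
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)
  n <- a + b + c + d
  if (n < 1) stop("table is all zero: test undefined", call. = FALSE)
  r1 <- a + b; c1 <- a + c
  # support of the (1,1) cell under fixed margins
  lo <- max(0L, r1 - (n - c1)); hi <- min(r1, c1)
  support <- lo:hi
  dens <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  if (method == "minimum_likelihood") {
    # relative tolerance guards against ties lost to floating point
    p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(dens[support <= a])
    upper <- sum(dens[support >= a])
    p <- min(1, 2 * min(lower, upper))
  }
  or <- (a * d) / (b * c)
  new_test_result(
    method = paste0("Fisher exact test (", gsub("_", "-", method), ")"),
    statistic = or, p_value = p,
    odds_ratio = or, or_degenerate = (b == 0 || c == 0 || a == 0 || d == 0)
  )
}

#' Pearson chi-square test on an r x c contingency table
#'
#' Classical Pearson statistic with expected counts from the margins and a
#' chi-square reference distribution on (r-1)(c-1) degrees of freedom. No
#' continuity correction is applied.
#'
#' @param table An r x c matrix of non-negative integer counts, r,c >= 2.
#' @return A `pnet_test_result` with the chi-square statistic, degrees of
#'   freedom and p-value.
#' @examples
#' chi_square_rxc(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
#' @export
chi_square_rxc <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  n <- sum(table)
  if (n < 1) stop("table is all zero: test undefined", call. = FALSE)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate margin: a row or column is all zero", call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  new_test_result(
    method = "Pearson chi-square test", statistic = stat,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE), df = df
  )
}

# Exact two-sided Mann-Whitney p by counting subsets of the midrank
# multiset. Doubled midranks are integers, so the subset-sum distribution
# over all choose(n, n1) labelings is computed exactly by dynamic
# programming; this is identical to full enumeration, including under ties.
mw_exact_p <- function(ranks2, n1, u2_obs) {
  n <- length(ranks2)
  n2 <- n - n1
  smax <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  # counts[k][s+1] = number of k-subsets with doubled-rank sum s
  counts <- vector("list", n1 + 1)
  counts[[1]] <- c(1, numeric(smax))
  for (k in seq_len(n1)) counts[[k + 1]] <- numeric(smax + 1)
  for (r in ranks2) {
    for (k in n1:1) {
      prev <- counts[[k]]
      shifted <- c(numeric(r), prev[seq_len(smax + 1 - r)])
      counts[[k + 1]] <- counts[[k + 1]] + shifted
    }
  }
  tab <- counts[[n1 + 1]]
  sums <- which(tab > 0) - 1
  freq <- tab[tab > 0]
  # doubled U = doubled rank sum of group 1 minus n1(n1+1)
  u2 <- sums - n1 * (n1 + 1)
  center2 <- n1 * n2  # doubled null mean of U
  keep <- abs(u2 - center2) >= abs(u2_obs - center2)
  sum(freq[keep]) / sum(freq)
}

#' Mann-Whitney U test with an exact permutation branch
#'
#' U is computed with midrank tie handling. When the combined sample size
#' is at most `max_exact_n` the two-sided p-value is the proportion, over
#' all `choose(n1+n2, n1)` labelings of the observed values, of labelings
#' whose U deviates from its null mean `n1*n2/2` at least as much as the
#' observed U (computed exactly by subset-sum counting over doubled
#' midranks, which is equivalent to full enumeration). Larger samples use
#' the normal approximation with tie-corrected variance and a continuity
#' correction.
#'
#' @param group1,group2 Non-empty numeric vectors.
#' @param max_exact_n Combined-size threshold for the exact branch.
#' @return A `pnet_test_result` with the U statistic (for `group1`) and
#'   two-sided p-value; `exact` records which branch was used.
#' @examples
#' mann_whitney_exact(c(1.18, 1.07, 0.79, 0.81, 0.13, 0.34),
#'                    c(0.04, 0, 0, 0))  # p = 2/210
#' @export
mann_whitney_exact <- function(group1, group2, max_exact_n = 20) {
  group1 <- as.numeric(group1); group2 <- as.numeric(group2)
  if (length(group1) == 0 || length(group2) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(group1) || anyNA(group2)) stop("missing values not allowed",
                                           call. = FALSE)
  n1 <- length(group1); n2 <- length(group2); n <- n1 + n2
  r <- rank(c(group1, group2))  # midranks
  ranks2 <- as.integer(round(2 * r))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact <- n <= max_exact_n
  if (exact) {
    u2_obs <- as.integer(round(2 * u))
    p <- mw_exact_p(ranks2, n1, u2_obs)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence against the null
    } else {
      # continuity-corrected, mirroring the discreteness of U
      z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-z)
    }
  }
  new_test_result(method = "Mann-Whitney U test", statistic = u,
                  p_value = p, exact = exact, n1 = n1, n2 = n2)
}

#' Median and range summary
#'
#' The even-length median is the mean of the two central order statistics,
#' matching how ratio summaries are conventionally reported alongside the
#' Mann-Whitney test.
#'
#' @param values Non-empty numeric vector.
#' @return A list with `median`, `min` and `max`.
#' @export
summarize_median_range <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    stop("values must be non-empty and complete", call. = FALSE)
  }
  list(median = stats::median(values), min = min(values), max = max(values))
}
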