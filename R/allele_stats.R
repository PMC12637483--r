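#' Expected close-allele distribution under allele independence
#'
#' If alleles of the same cell loop independently, the number of close
#' alleles per cell is binomial: the expected fraction of cells with exactly
#' `c` close alleles is
#' \deqn{f(c) = \binom{n}{c} p_c^c (1 - p_c)^{n - c}, \quad c = 0 \dots n,}
#' where `p_c` is the population frequency of close alleles and `n` the
#' ploidy. Deviations of the observed distribution from this null reveal
#' cell-to-cell heterogeneity (alleles of one cell behaving more similarly
#' than alleles of different cells).
#'
#' @param p_c population frequency of close alleles, in \[0, 1\].
#' @param n ploidy (alleles per cell), >= 1.
#' @return object of class `"binomial_null"`: list with `p_c`, `n` and
#'   `expected_fractions` (named numeric, `c0` ... `cn`, summing to 1).
#' @export
#' @examples
#' binomial_expected(0.5, 2)$expected_fractions  # 0.25 0.50 0.25
binomial_expected <- function(p_c, n) {
  check_prob(p_c, "p_c")
  n <- check_count(n, "n")
  c_ <- 0:n
  f <- choose(n, c_) * p_c^c_ * (1 - p_c)^(n - c_)
  structure(list(p_c = p_c, n = n,
                 expected_fractions = setNames(f, paste0("c", c_))),
            class = "binomial_null")
}

#' Observed distribution of cells by number of close alleles
#'
#' Counts cells with exactly 0, 1, ..., n alleles in contact and pools the
#' population close-allele frequency `p_c = sum(contacts) / (N * n)` used to
#' parameterize the independence null. Input is either a cell-summary table
#' (every cell must carry exactly `n` retained pairs, as guaranteed by
#' [ploidy_filter()]) or a bare integer vector of per-cell contact counts.
#'
#' @param x [summarize_cells()] output, or an integer vector in `0:n`.
#' @param n ploidy.
#' @param condition label stored on the result.
#' @return object of class `"close_allele_distribution"`: list with
#'   `condition`, `counts` (named `c0` ... `cn`), `N`, `n`, `p_c`.
#' @export
observed_distribution <- function(x, n, condition = NA_character_) {
  n <- check_count(n, "n")
  if (is.data.frame(x)) {
    check_cols(x, c("n_pairs", "n_contacts"), "x")
    if (any(x$n_pairs != n)) {
      stop(sprintf("%d cell(s) have n_pairs != %d; apply ploidy_filter first",
                   sum(x$n_pairs != n), n), call. = FALSE)
    }
    k <- x$n_contacts
  } else {
    k <- as.integer(x)
  }
  if (!length(k)) stop("no cells to tabulate", call. = FALSE)
  if (any(k < 0 | k > n)) {
    stop("contact counts must lie in 0..n", call. = FALSE)
  }
  counts <- as.integer(tabulate(k + 1L, nbins = n + 1L))
  structure(list(condition = condition,
                 counts = setNames(counts, paste0("c", 0:n)),
                 N = length(k), n = n,
                 p_c = sum(k) / (length(k) * n)),
            class = "close_allele_distribution")
}

#' Chi-square test of allele independence
#'
#' Pearson chi-square comparison of the observed distribution of cells with
#' 0..n close alleles against the binomial expectation at the pooled `p_c`:
#' \eqn{\chi^2 = \sum_c (O_c - E_c)^2 / E_c}. Categories with expected count
#' below `expected_floor` are pooled with their inner neighbour (from the
#' tails inward) for validity, reducing the degrees of freedom accordingly.
#'
#' Because `p_c` is estimated from the same cells, the statistic is
#' asymptotically chi-square with `categories - 2` degrees of freedom; that
#' is the default. `df_estimated = FALSE` uses the plain goodness-of-fit
#' `categories - 1` instead (same statistic, larger p-values).
#'
#' @param dist a `close_allele_distribution`.
#' @param df_estimated account for the estimated `p_c` in the degrees of
#'   freedom (default TRUE).
#' @param expected_floor minimum expected count per category before pooling.
#' @return an object of class `"htest"` with `statistic`, `parameter` (df),
#'   `p.value`, `observed` and `expected` counts. When `p_c` is 0 or 1 all
#'   mass sits in one category and the test is undefined: statistic and
#'   p-value are `NA` and the method string is flagged.
#' @export
independence_test <- function(dist, df_estimated = TRUE, expected_floor = 1) {
  stopifnot(inherits(dist, "close_allele_distribution"))
  O <- as.numeric(dist$counts)
  N <- dist$N
  null <- binomial_expected(dist$p_c, dist$n)
  E <- N * as.numeric(null$expected_fractions)
  if (dist$p_c %in% c(0, 1)) {
    out <- list(statistic = c(`X-squared` = NA_real_),
                parameter = c(df = NA_real_), p.value = NA_real_,
                method = paste("Chi-square test of allele independence",
                               "(undefined: all alleles in one category)"),
                data.name = as.character(dist$condition),
                observed = O, expected = E)
    class(out) <- "htest"
    return(out)
  }
  # pool sparse tail categories inward
  while (length(E) > 2L && E[1] < expected_floor) {
    E[2] <- E[2] + E[1]; O[2] <- O[2] + O[1]
    E <- E[-1]; O <- O[-1]
  }
  while (length(E) > 2L && E[length(E)] < expected_floor) {
    k <- length(E)
    E[k - 1] <- E[k - 1] + E[k]; O[k - 1] <- O[k - 1] + O[k]
    E <- E[-k]; O <- O[-k]
  }
  stat <- sum((O - E)^2 / E)
  df <- length(E) - 1L - as.integer(df_estimated)
  df <- max(df, 1L)
  out <- list(statistic = c(`X-squared` = stat),
              parameter = c(df = df),
              p.value = pchisq(stat, df, lower.tail = FALSE),
              method = "Chi-square test of allele independence vs binomial null",
              data.name = as.character(dist$condition),
              observed = O, expected = E)
  class(out) <- "htest"
  out
}

#' Marascuilo procedure for multiple comparisons of proportions
#'
#' Simultaneous pairwise comparison of k proportions (e.g. fractions of
#' close alleles across conditions). The difference \eqn{|p_i - p_j|} is
#' significant when it exceeds the critical range
#' \deqn{r_{ij} = \sqrt{\chi^2_{1-\alpha, k-1}}
#'   \sqrt{p_i(1-p_i)/n_i + p_j(1-p_j)/n_j}.}
#'
#' @param p proportions in \[0, 1\] (length k >= 2).
#' @param n group sizes (>= 1), recycled to length k.
#' @param labels group labels (defaults to names of `p` or indices).
#' @param alpha family-wise significance level.
#' @return data.frame with one row per unordered pair: `group_i`,
#'   `group_j`, `p_i`, `p_j`, `abs_diff`, `critical_range`, `significant`.
#' @export
marascuilo <- function(p, n, labels = NULL, alpha = 0.05) {
  if (length(p) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("`p` must be proportions in [0, 1]", call. = FALSE)
  }
  n <- rep_len(n, length(p))
  if (any(!is.finite(n) | n < 1)) {
    stop("`n` must be group sizes >= 1", call. = FALSE)
  }
  check_prob(alpha, "alpha")
  if (is.null(labels)) {
    labels <- if (!is.null(names(p))) names(p) else
      paste0("group_", seq_along(p))
  }
  k <- length(p)
  crit <- sqrt(qchisq(1 - alpha, df = k - 1))
  pairs <- utils::combn(k, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  r <- crit * sqrt(p[i] * (1 - p[i]) / n[i] + p[j] * (1 - p[j]) / n[j])
  data.frame(group_i = labels[i], group_j = labels[j],
             p_i = p[i], p_j = p[j],
             abs_diff = abs(p[i] - p[j]),
             critical_range = r,
             significant = abs(p[i] - p[j]) > r,
             stringsAsFactors = FALSE)
}

#' @export
print.binomial_null <- function(x, ...) {
  cat(sprintf("Binomial null (p_c = %.4f, ploidy %d):\n", x$p_c, x$n))
  print(round(x$expected_fractions, 4))
  invisible(x)
}

#' @export
print.close_allele_distribution <- function(x, ...) {
  cat(sprintf("Close-allele distribution [%s]: N = %d cells, p_c = %.4f\n",
              x$condition, x$N, x$p_c))
  print(x$counts)
  invisible(x)
}
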