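# Exact Wilcoxon signed-rank test of paired differences against zero.
#
# Exactness is preserved under ties: the null distribution is built for the
# *realized* (possibly tied, average) rank vector, i.e. over all 2^n equally
# likely sign assignments of those ranks. The distribution is accumulated by
# convolution over the doubled ranks (average ranks are multiples of 1/2, so
# doubling puts them on an integer grid); this is algebraically identical to
# enumerating the 2^n assignments but costs O(n * sum(ranks)).

# Counts of sign assignments by doubled rank-sum: counts[w + 1] is the number
# of assignments with 2 * W+ == w.
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test against zero
#'
#' Tests whether paired differences (here: per-species log fold-changes) are
#' symmetric about zero. Zeros are removed before ranking; tied absolute
#' differences receive average ranks. For `n <= exact_n_max` usable
#' differences the p-value is exact, computed from the full null distribution
#' of the rank-sum statistic over all `2^n` sign assignments of the realized
#' rank vector, so exactness holds under ties. For larger `n` a normal
#' approximation with tie-corrected variance and continuity correction is
#' used and flagged in the result.
#'
#' The default two-sided p-value follows the doubling rule,
#' `min(1, 2 * min(P(W+ <= w), P(W+ >= w)))`, which yields the dyadic values
#' (0.0625, 0.25, ...) familiar from small exact tests. The alternative
#' minimum-likelihood convention (sum of probabilities of outcomes no more
#' likely than the observed one) is available via `p_convention`.
#'
#' @param diffs Numeric vector of differences (log fold-changes).
#' @param exact_n_max Largest `n` for exact computation (default 25).
#' @param p_convention `"doubling"` (default) or `"min-likelihood"`.
#' @return An object of class `signed_rank`: a list with elements `n_used`
#'   (count after zero removal), `w_plus`, `w_minus` (rank sums),
#'   `p_value` (two-sided; `NA` when `n_used` is 0) and `method`
#'   (`"exact"`, `"approximate"` or `"not_testable"`).
#' @export
#' @examples
#' # five differences, all positive: smallest attainable two-sided p
#' exact_signed_rank(c(0.2, 0.5, 0.1, 0.9, 0.4))$p_value  # 0.0625
#' tidy(exact_signed_rank(rnorm(8)))
exact_signed_rank <- function(diffs, exact_n_max = 25,
                              p_convention = c("doubling", "min-likelihood")) {
  p_convention <- match.arg(p_convention)
  if (!is.numeric(diffs)) abort_schema("`diffs` must be numeric")
  assert_count(exact_n_max, "exact_n_max", lower = 1)
  diffs <- diffs[!is.na(diffs)]
  x <- diffs[diffs != 0]
  n <- length(x)
  if (n == 0) {
    return(new_signed_rank(0L, NA_real_, NA_real_, NA_real_, "not_testable",
                           p_convention))
  }
  r <- rank(abs(x))
  w_plus <- sum(r[x > 0])
  w_minus <- sum(r[x < 0])

  if (n <= exact_n_max) {
    ranks2 <- as.integer(round(2 * r))
    counts <- signed_rank_counts(ranks2)
    total <- 2^n
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[seq.int(w2 + 1, length(counts))]) / total
    p <- if (p_convention == "doubling") {
      min(1, 2 * min(p_le, p_ge))
    } else {
      obs <- counts[w2 + 1]
      sum(counts[counts <= obs]) / total
    }
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- w_plus - mu
    p <- min(1, 2 * stats::pnorm(-(abs(z) - 0.5) / sqrt(sigma2)))
    method <- "approximate"
  }
  new_signed_rank(as.integer(n), w_plus, w_minus, p, method, p_convention)
}

new_signed_rank <- function(n_used, w_plus, w_minus, p_value, method,
                            p_convention) {
  structure(
    list(n_used = n_used, w_plus = w_plus, w_minus = w_minus,
         p_value = p_value, method = method, p_convention = p_convention),
    class = "signed_rank"
  )
}

#' @export
print.signed_rank <- function(x, ...) {
  cat("Exact Wilcoxon signed-rank test against zero\n")
  if (x$method == "not_testable") {
    cat("  not testable: no nonzero differences\n")
    return(invisible(x))
  }
  cat(sprintf("  n used (zeros removed): %d\n", x$n_used))
  cat(sprintf("  rank sums: W+ = %g, W- = %g\n", x$w_plus, x$w_minus))
  cat(sprintf("  two-sided p = %.4f (%s, %s rule)\n",
              x$p_value, x$method, x$p_convention))
  invisible(x)
}

#' Tidy a signed-rank test result
#'
#' @param x A [exact_signed_rank()] result.
#' @param ... Unused.
#' @return A one-row tibble with columns `n_used`, `w_plus`, `w_minus`,
#'   `p_value`, `method`.
#' @method tidy signed_rank
#' @export
tidy.signed_rank <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, w_plus = x$w_plus, w_minus = x$w_minus,
                 p_value = x$p_value, method = x$method)
}

#' @rdname tidy.signed_rank
#' @method glance signed_rank
#' @export
glance.signed_rank <- function(x, ...) tidy.signed_rank(x)
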