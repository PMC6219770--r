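## Wilcoxon signed-rank and Mann-Whitney rank-sum tests with exact
## small-sample p-values.
##
## Both tests enumerate their full permutation space exactly for small
## samples -- including tied data, where midranks are used and the exact
## distribution is obtained by dynamic programming over the (doubled, hence
## integer) rank weights.  Larger samples fall back to the tie-corrected
## normal approximation with continuity correction.  Counts stay below 2^53
## for every n the exact path accepts, so the dynamic program is exact in
## double precision.

## Distribution of the sum of a random subset of `weights` where each
## element is included independently (signed-rank null).  Returns counts
## indexed by sum 0..sum(weights).
subset_sum_counts <- function(weights) {
  total <- sum(weights)
  f <- numeric(total + 1L)
  f[1L] <- 1
  upto <- 0L
  for (w in weights) {
    idx <- seq_len(upto + 1L)
    f[idx + w] <- f[idx + w] + f[idx]
    upto <- upto + w
  }
  f
}

## Distribution of the rank sum of a size-m subset drawn without replacement
## from `weights` (rank-sum null).  Returns counts indexed by sum 0..total.
fixed_size_subset_sum_counts <- function(weights, m) {
  total <- sum(weights)
  g <- matrix(0, nrow = m + 1L, ncol = total + 1L)
  g[1L, 1L] <- 1
  for (w in weights) {
    for (j in rev(seq_len(m))) {
      row <- g[j, ]
      nz <- which(row != 0)
      if (length(nz))
        g[j + 1L, nz + w] <- g[j + 1L, nz + w] + row[nz]
    }
  }
  g[m + 1L, ]
}

two_sided_from_counts <- function(counts, w2) {
  total_count <- sum(counts)
  idx <- seq_along(counts) - 1L
  p_lo <- sum(counts[idx <= w2]) / total_count
  p_hi <- sum(counts[idx >= w2]) / total_count
  min(1, 2 * min(p_lo, p_hi))
}

new_test_result <- function(test, statistic, p, n, paired, exact, note = NULL) {
  structure(list(test = test, statistic = statistic, p = p, n = n,
                 paired = paired, exact = exact, note = note),
            class = "lcd_test")
}

#' @export
print.lcd_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.5g (%s, %s)\n", x$test,
              x$statistic, x$p, paste("n =", paste(x$n, collapse = ", ")),
              if (x$exact) "exact" else "normal approximation"))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Paired test on `x - y` (or directly on a vector of differences).  Zero
#' differences are discarded (classic Wilcoxon treatment).  For `n <=
#' exact_limit` non-zero differences the two-sided p-value is computed from
#' the exact permutation distribution over all 2^n sign assignments --
#' tied magnitudes included, via midranks -- otherwise the tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x numeric vector: first member of each pair, or the differences.
#' @param y optional second member of each pair.
#' @param exact_limit largest n handled exactly (default 25).
#' @return An object of class `lcd_test` with fields `statistic` (V, the sum
#'   of the positive-difference ranks), `p`, `n` (non-zero pairs), `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("no non-missing pairs")
  d0 <- d[d != 0]
  n <- length(d0)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(new_test_result("wilcoxon-signed-rank", 0, 1, 0L, TRUE, TRUE,
                           "all differences zero"))
  }
  r <- rank(abs(d0))
  W <- sum(r[d0 > 0])
  if (n <= exact_limit) {
    counts <- subset_sum_counts(as.integer(round(2 * r)))
    p <- two_sided_from_counts(counts, round(2 * W))
    return(new_test_result("wilcoxon-signed-rank", W, p, n, TRUE, TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(abs(d0))
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
  num <- W - mu
  num <- num - sign(num) * 0.5  # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(num) / sigma))
  new_test_result("wilcoxon-signed-rank", W, p, n, TRUE, FALSE)
}

#' Mann-Whitney rank-sum test (two-sided)
#'
#' Unpaired two-group comparison.  For `n1 + n2 <= exact_limit` the
#' two-sided p-value is computed from the exact distribution of the
#' first-group rank sum over all `choose(n1 + n2, n1)` group assignments
#' (midranks under ties), otherwise the tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param a,b numeric vectors, the two groups.
#' @param exact_limit largest `n1 + n2` handled exactly (default 20).
#' @return An object of class `lcd_test`; `statistic` is the Mann-Whitney U
#'   of the first group, `n = c(n1, n2)`.
#' @export
mann_whitney <- function(a, b, exact_limit = 20L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (n <= exact_limit) {
    counts <- fixed_size_subset_sum_counts(as.integer(round(2 * r)), n1)
    p <- two_sided_from_counts(counts, round(2 * W))
    return(new_test_result("mann-whitney", U, p, c(n1, n2), FALSE, TRUE))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma <- sqrt(n1 * n2 / 12 *
                  ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  num <- U - mu
  num <- num - sign(num) * 0.5
  p <- min(1, 2 * stats::pnorm(-abs(num) / sigma))
  new_test_result("mann-whitney", U, p, c(n1, n2), FALSE, FALSE)
}
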