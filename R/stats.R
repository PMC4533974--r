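#' Nonparametric test results
#'
#' Lightweight container for the package's self-contained nonparametric tests:
#' the statistic (`U` for Mann-Whitney, `r` for Spearman), a two-sided p-value,
#' the sample sizes and the method name.
#'
#' @param statistic Numeric test statistic.
#' @param p_value Two-sided p-value in \[0, 1\].
#' @param n1,n2 Sample sizes (`n2 = NA` for one-sample quantities such as a
#'   correlation).
#' @param method Character label.
#' @return A list of class `evo_test`.
#' @keywords internal
#' @export
new_test_result <- function(statistic, p_value, n1, n2 = NA_integer_, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n1 = as.integer(n1), n2 = as.integer(n2), method = method),
            class = "evo_test")
}

#' @export
print.evo_test <- function(x, ...) {
  ns <- if (is.na(x$n2)) sprintf("n = %d", x$n1) else sprintf("n1 = %d, n2 = %d", x$n1, x$n2)
  cat(sprintf("<evo_test> %s: statistic = %.6g, p = %.4g (%s)\n",
              x$method, x$statistic, x$p_value, ns))
  invisible(x)
}

#' @rdname new_test_result
#' @param x An `evo_test`.
#' @param ... Unused.
#' @export
tidy.evo_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p.value = x$p_value, n1 = x$n1, n2 = x$n2)
}

#' @rdname new_test_result
#' @export
glance.evo_test <- function(x, ...) tidy(x)

#' Spearman rank correlation
#'
#' Rank correlation computed from scratch: both series are converted to
#' mid-ranks (ties share the average of the ranks they cover) and the Pearson
#' correlation of the ranks is computed explicitly. The two-sided p-value uses
#' the t approximation with `n - 2` degrees of freedom, adequate at the sample
#' sizes of the pooled-population analyses (thousands of organisms).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return An `evo_test` with `statistic` = Spearman's r.
#' @examples
#' spearman_correlation(1:10, (1:10)^2)$statistic # exactly 1
#' @export
spearman_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) {
    abort("`x` and `y` must have equal length.", class = "extinctsim_stat_error")
  }
  if (n < 3L) {
    abort("Spearman correlation needs at least 3 observations.",
          class = "extinctsim_stat_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    abort("Spearman correlation is undefined when a series has zero rank variance.",
          class = "extinctsim_stat_error")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  new_test_result(r, p, n1 = n, method = "Spearman rank correlation")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test computed from scratch. The statistic is
#' `U = R1 - n1 (n1 + 1) / 2` where `R1` is the rank sum of the first sample
#' (mid-ranks under ties). For small tie-free samples (`n1 + n2 <= 12`) the
#' p-value is exact, by enumeration of all `choose(n1 + n2, n1)` labelings of
#' the pooled sample; otherwise a normal approximation with tie correction and
#' a 0.5 continuity correction is used.
#'
#' @param a,b Non-empty numeric vectors.
#' @return An `evo_test` with `statistic` = U for sample `a`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$p_value # exact: 0.1
#' @export
mann_whitney_u <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0L || n2 == 0L) {
    abort("Both samples must be non-empty.", class = "extinctsim_stat_error")
  }
  pooled <- c(a, b)
  rks <- rank(pooled)
  u1 <- sum(rks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n1 + n2 <= 12L) {
    # exact: U distribution over all assignments of ranks to sample a
    combos <- utils::combn(n1 + n2, n1)
    uall <- colSums(matrix(rks[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    umin <- min(u1, u2)
    p <- mean(uall <= umin | uall >= n1 * n2 - umin)
  } else {
    m <- n1 * n2 / 2
    n <- n1 + n2
    tie_sizes <- table(pooled)
    tie_term <- sum(tie_sizes^3 - tie_sizes) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u1 - m) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
  }
  new_test_result(u1, p, n1 = n1, n2 = n2, method = "Mann-Whitney U")
}

#' Write a test result as JSON
#'
#' Serialises an `evo_test` as a JSON object with fields `method`,
#' `statistic`, `p_value`, `n1`, `n2`.
#'
#' @param test An `evo_test`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_test_json <- function(test, path) {
  jsonlite::write_json(
    list(method = test$method, statistic = test$statistic,
         p_value = test$p_value, n1 = test$n1, n2 = test$n2),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
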