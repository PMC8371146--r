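# Nonparametric cohort statistics. Both tests are implemented directly so
# that small-sample behaviour is fully specified: the Mann-Whitney U null
# distribution is enumerated exactly for small groups, and the chi-square
# statistic is the plain Pearson sum without continuity correction unless
# requested.

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided throughout. When both groups have at most `exact_max`
#' observations the permutation null distribution of U is enumerated in
#' full (all `choose(n1 + n2, n1)` group assignments, ties handled by
#' midranks), and the p-value is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#' Otherwise the tie-corrected normal approximation with a 0.5 continuity
#' correction is used.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_max largest per-group size for exact enumeration, default 8.
#' @param alpha significance level recorded in the result, default 0.05.
#' @return object of class `test_result`: `statistic` (U, the smaller of
#'   U1/U2, SPSS convention), `p_value`, `method`, `n` (per-group sizes),
#'   `alpha`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(c(a, b))))
    stop("samples must be finite", call. = FALSE)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks for ties
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  exact <- n1 <= exact_max && n2 <= exact_max
  if (exact) {
    combs <- utils::combn(N, n1)
    u_null <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_null <= u1), mean(u_null >= u1)))
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "Mann-Whitney U (normal approximation, tie- and continuity-corrected)"
  }
  structure(list(statistic = u, p_value = p, method = method,
                 n = c(n1 = n1, n2 = n2), alpha = alpha),
            class = "test_result")
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` on an r x c count table,
#' `df = (r - 1)(c - 1)`, p-value from the chi-square distribution. No
#' continuity correction by default; `yates = TRUE` applies the Yates
#' correction (2 x 2 tables only).
#'
#' @param table numeric matrix of non-negative counts; all row and column
#'   margins must be positive.
#' @param yates apply Yates continuity correction (2 x 2 only).
#' @param alpha significance level recorded in the result, default 0.05.
#' @return object of class `test_result` with `statistic`, `df`, `p_value`,
#'   `method`, `n` (grand total), `alpha`.
#' @export
pearson_chi_square <- function(table, yates = FALSE, alpha = 0.05) {
  O <- as.matrix(table)
  if (any(!is.finite(O)) || any(O < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (nrow(O) < 2L || ncol(O) < 2L)
    stop("table must be at least 2 x 2", call. = FALSE)
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row/column margin", call. = FALSE)
  E <- outer(rs, cs) / sum(O)
  if (yates && !(nrow(O) == 2L && ncol(O) == 2L))
    stop("Yates correction applies to 2 x 2 tables only", call. = FALSE)
  dev <- abs(O - E)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = if (yates) "Pearson chi-square (Yates-corrected)"
                          else "Pearson chi-square",
                 n = sum(O), alpha = alpha),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g%s, p = %.4g (alpha = %g)\n",
              x$method, x$statistic,
              if (!is.null(x$df)) sprintf(", df = %d", x$df) else "",
              x$p_value, x$alpha))
  invisible(x)
}
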