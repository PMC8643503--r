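## Nonparametric statistical engine with explicitly stated conventions so
## results are reproducible bit for bit: exact null enumeration at small
## sample sizes (midranks for ties, which base R's exact paths refuse),
## normal approximation with continuity and tie corrections otherwise, and
## the point-probability two-sided rule for Fisher's exact test. All tests
## are two-sided.

new_stat_result <- function(method, statistic, p_value, effect, n,
                            note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(method = method, statistic = statistic,
                 p_value = min(p_value, 1), effect = effect, n = n,
                 note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  stat <- paste(names(x$statistic), signif(unname(x$statistic), 5),
                sep = " = ", collapse = ", ")
  cat(sprintf("<stat_result> %s: %s, p = %.4g (n = %s)\n", x$method, stat,
              x$p_value, paste(x$n, collapse = "+")))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of symmetric paired differences about zero. Zero
#' differences are dropped; absolute differences are midranked. For n <= 15
#' retained pairs the null distribution is enumerated exactly over all 2^n
#' sign assignments (valid under ties); otherwise a normal approximation
#' with tie correction and continuity correction is used. The two-sided
#' exact p doubles the smaller tail, capped at 1.
#'
#' @param x,y Paired numeric vectors, or differences in `x` with `y = NULL`.
#' @param exact_max Largest n for the exact enumeration path.
#' @return A `stat_result` with the signed-rank statistic `V` (sum of ranks
#'   of positive differences), the p value, and as effect summary the
#'   rank-biserial correlation, the approximate Z and the median difference.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 15L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (anyNA(d)) stop("missing values in paired differences")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(new_stat_result("Wilcoxon signed-rank", c(V = NA_real_), 1,
                           list(rank_biserial = 0, z = 0, median_diff = 0), 0))
  }
  if (n < 5) stop("need at least 5 non-zero differences, got ", n)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  s <- n * (n + 1) / 2
  if (n <= exact_max) {
    ## exact: distribution of V over all sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vdist <- as.vector(signs %*% r)
    p_lo <- mean(vdist <= v + 1e-9)
    p_hi <- mean(vdist >= v - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    z <- NA_real_
  } else {
    mu <- s / 2
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(v - mu) * 0.5
    z <- (v - mu - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  rb <- (2 * v - s) / s   # rank-biserial correlation
  new_stat_result("Wilcoxon signed-rank", c(V = v), p,
                  list(rank_biserial = rb, z = z,
                       median_diff = stats::median(d)),
                  n)
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided rank-sum test. U counts pairs where a value of `a` exceeds one
#' of `b`, with half-counts for ties (midranks). For m + n <= 20 the exact
#' permutation distribution of U is enumerated over all C(m+n, m) group
#' assignments of the pooled midranks; that distribution is symmetric about
#' mn/2, and p sums the probability of outcomes at least as far from mn/2
#' as observed. Larger samples use the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b Numeric vectors.
#' @param exact_max Largest m + n for the exact path.
#' @return A `stat_result` with statistic `U` (for group `a`), the p value
#'   and the common-language effect size `U / (mn)`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 20L) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (anyNA(c(a, b))) stop("missing values")
  m <- length(a)
  n <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mid <- m * n / 2
  if (m + n <= exact_max) {
    sel <- utils::combn(m + n, m)
    ranksum <- colSums(matrix(r[sel], nrow = m))
    udist <- ranksum - m * (m + 1) / 2
    p <- mean(abs(udist - mid) >= abs(u - mid) - 1e-9)
  } else {
    N <- m + n
    ties <- table(r)
    sigma2 <- m * n / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    cc <- sign(u - mid) * 0.5
    z <- (u - mid - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_stat_result("Mann-Whitney U", c(U = u), p,
                  list(cles = u / (m * n),
                       median_a = stats::median(a),
                       median_b = stats::median(b)),
                  c(m = m, n = n))
}

## All permutations of 1..n (matrix n! x n); recursion is fine for n <= 8.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks. For n <= 8 the two-sided p
#' is exact by enumeration of all n! rank permutations; otherwise the
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))` on n - 2 degrees of
#' freedom is used.
#'
#' @param x,y Numeric vectors of equal length (n >= 5).
#' @param exact_max Largest n for the exact path.
#' @return A `stat_result` with `rho` and the p value.
#' @export
spearman_rho <- function(x, y, exact_max = 8L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (anyNA(x) || anyNA(y)) stop("missing values")
  n <- length(x)
  if (n < 5) stop("need n >= 5, got ", n)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("a variable is constant; rho is undefined")
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rhod <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhod) >= abs(rho) - 1e-9)
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  new_stat_result("Spearman rank correlation", c(rho = rho), p,
                  list(rho = rho), n)
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the first cell is hypergeometric under
#' independence. The two-sided p value follows the point-probability rule:
#' the sum of probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table, with a 1e-7
#' relative slack absorbing floating-point ties. A table with a zero margin
#' carries no information and returns p = 1.
#'
#' @param table 2x2 matrix (or object coercible to one) of non-negative
#'   counts. Rows: exposure stratum; columns: outcome.
#' @return A `stat_result` with the observed table probability as
#'   statistic, the p value and the sample odds ratio.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("cells must be non-negative integers")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) {
    return(new_stat_result("Fisher exact (2x2)", c(p_obs = 1), 1,
                           list(odds_ratio = NA_real_), sum(tab),
                           note = "zero margin"))
  }
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  new_stat_result("Fisher exact (2x2)", c(p_obs = p_obs), min(p, 1),
                  list(odds_ratio = or,
                       prop_row1 = tab[1, 1] / r1,
                       prop_row2 = tab[2, 1] / r2),
                  sum(tab))
}

#' Elevated-neurofilament threshold from control data
#'
#' The abnormality cut-off for plasma neurofilament light chain: more than
#' 3 standard deviations above the healthy-control mean (sample SD, n - 1
#' denominator).
#'
#' @param control_nfl Numeric vector of control NfL values, pg/ml.
#' @param n_sd Number of SDs above the mean (default 3).
#' @return Threshold in pg/ml.
#' @export
elevated_nfl_threshold <- function(control_nfl, n_sd = 3) {
  control_nfl <- as.numeric(control_nfl)
  if (anyNA(control_nfl) || length(control_nfl) == 0) {
    stop("control NfL values must be non-missing")
  }
  if (length(control_nfl) < 10) {
    warning("fewer than 10 controls; the normal range is poorly estimated")
  }
  sd_c <- if (length(control_nfl) > 1) stats::sd(control_nfl) else 0
  mean(control_nfl) + n_sd * sd_c
}
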