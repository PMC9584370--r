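#' Median and interquartile range
#'
#' Quartiles by inclusive linear interpolation between order statistics
#' (R's default type-7 rule); the method is fixed so cohort summaries are
#' reproducible and reconcilable.
#'
#' @param values Numeric vector with at least one finite value.
#' @return List `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0)
    .stop2("median_iqr needs at least one finite value", class = "bq_input")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Two-sided Mann-Whitney test
#'
#' Exact p by enumeration when the pooled sample has at most 20 observations
#' and no ties; tie-corrected normal approximation with continuity correction
#' otherwise.  `U` is reported in the conventional min(U1, U2) form, so
#' complete separation of the groups gives U = 0 regardless of direction.
#' Identical samples in both groups degenerate to p = 1 with a warning.
#'
#' @param a,b Numeric vectors.
#' @return List `U`, `p`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    .stop2("both groups must be non-empty", class = "bq_input")
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(U = length(a) * length(b) / 2, p = 1,
                method = "degenerate"))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided"))
  u1 <- unname(wt$statistic)
  list(U = min(u1, length(a) * length(b) - u1), p = wt$p.value,
       method = if (exact) "exact" else "normal_tie_corrected")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' p is the sum of hypergeometric probabilities of all tables (with the
#' observed margins) no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List `odds_ratio` (conditional MLE), `p`, `method`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    .stop2("table must be 2x2", class = "bq_input")
  if (any(table < 0) || any(table != round(table)))
    .stop2("counts must be non-negative integers", class = "bq_input")
  ft <- fisher.test(table, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value,
       method = "hypergeometric_two_sided")
}

#' Unpaired two-sample t-test
#'
#' Pooled-variance by default (the study reported plain unpaired t-tests);
#' Welch's unequal-variance form by flag.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param welch Use the Welch correction.
#' @return List `t`, `p`, `df`, `method`.
#' @export
unpaired_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    .stop2("each group needs >= 2 values", class = "bq_input")
  if (var(a) == 0 && var(b) == 0)
    .stop2("zero variance in both groups; t undefined", class = "bq_degenerate")
  tt <- t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       method = if (welch) "welch" else "pooled")
}

# all permutations of 1..n as an (n!) x n matrix
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Spearman rank correlation
#'
#' Average ranks for ties; `rho` is the Pearson correlation of the ranks.
#' For n <= 9 the p-value is exact, from full enumeration of all n!
#' permutations (valid under ties, unlike the classical no-tie null
#' distribution); otherwise the usual t-approximation is used.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List `rho`, `p`, `method`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y))
    .stop2("x and y must have equal length", class = "bq_input")
  n <- length(x)
  if (n < 3)
    .stop2("need at least 3 pairs", class = "bq_input")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    .stop2("correlation undefined for constant input", class = "bq_degenerate")
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- .permutations(n)
    ryp <- matrix(ry[perms], nrow(perms), n)
    rs <- as.vector(cor(rx, t(ryp)))
    p <- mean(abs(rs) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p = p, method = method, n = n)
}
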