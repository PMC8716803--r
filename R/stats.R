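#' Spearman correlation of per-vial rates with concentration
#'
#' Rank correlation of the per-vial median relaxation rates against the
#' vial concentrations, with average ranks for ties and the p-value from
#' the standard t approximation.
#'
#' @param stats A `vial_stats` data frame (see [summarize_vials()]) or
#'   any data frame with `concentration` and `median_rate` columns.
#' @return List with `rho` and `p_value`.
#' @export
spearman_vs_concentration <- function(stats) {
  if (nrow(stats) < 4L)
    abort_validation("need at least 4 vials for a rank correlation")
  x <- stats$concentration
  y <- stats$median_rate
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    abort_o17("rank correlation undefined for a constant vector",
              "o17_undefined_correlation_error")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Shapiro-Wilk normality test
#'
#' @param sample Numeric vector with 3 to 5000 observations.
#' @return List with the `W` statistic and `p_value`.
#' @export
normality_test <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 3L || n > 5000L)
    abort_validation(sprintf(
      "Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n))
  sw <- stats::shapiro.test(sample)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' Games-Howell pairwise post hoc test
#'
#' Pairwise comparisons of group means under unequal variances and
#' sizes: for groups i, j the Welch standard error is
#' `sqrt(s_i^2/n_i + s_j^2/n_j)`, the degrees of freedom follow
#' Welch-Satterthwaite, and the statistic
#' `q = |mean_i - mean_j| * sqrt(2) / SE` is referred to the studentized
#' range distribution with `k` groups, which supplies the built-in
#' family-wise adjustment.
#'
#' Degenerate pairs with zero variance in both groups get `p = 1` when
#' the means are equal and `p = 0` otherwise, by convention.
#'
#' @param groups Named list of numeric vectors (each `n >= 2`), or a
#'   data frame with columns `group` and `value`. Names (or group
#'   labels) identify the concentrations being compared.
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `mean_diff`, `se`, `df`, `q`, `p_adj`.
#' @export
games_howell_pairwise <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  k <- length(groups)
  if (k < 2L) abort_validation("need at least 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) abort_validation("every group needs n >= 2")
  labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    diff <- m[i] - m[j]
    if (se2 == 0) {
      p <- if (abs(diff) < .Machine$double.eps^0.5) 1 else 0
      return(data.frame(group1 = labels[i], group2 = labels[j],
                        mean_diff = diff, se = 0, df = NA_real_,
                        q = if (p == 1) 0 else Inf, p_adj = p))
    }
    se <- sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                     (v[j] / n[j])^2 / (n[j] - 1))
    q <- abs(diff) * sqrt(2) / se
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group1 = labels[i], group2 = labels[j],
               mean_diff = diff, se = se, df = df, q = q, p_adj = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
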