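# Group statistics: pooled two-sample t test and two-way cell-means ANOVA
# with Tukey-Kramer post hoc comparisons. Degrees of freedom are tracked
# explicitly because published test statistics are reported as t(df) and
# q(df).

#' Pooled-variance two-sample Student t test
#'
#' Classical Student t with the pooled variance estimate and
#' `df = n_x + n_y - 2`; two-sided p value. When the pooled variance is
#' zero (all observations in both groups identical) the statistic is
#' undefined and reported as degenerate: `statistic = 0` if the means are
#' also equal, otherwise `Inf` with sign of the mean difference, with
#' `degenerate = TRUE` either way.
#'
#' @param x,y Numeric vectors of per-animal measurements (each `n >= 2`).
#' @param labels Length-2 character vector naming the two groups.
#' @return One-row data frame (`comparison`, `statistic`, `df`, `p`,
#'   `degenerate`).
#' @export
t_test_two_sample <- function(x, y, labels = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 values",
                             call. = FALSE)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    stat <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
    degen <- TRUE
  } else {
    stat <- dm / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * stats::pt(-abs(stat), df)
    degen <- FALSE
  }
  data.frame(comparison = paste(labels, collapse = " vs "),
             statistic = stat, df = df, p = p, degenerate = degen)
}

#' Two-way ANOVA (cell-means error term) with Tukey-Kramer post hoc
#'
#' Fits the cell-means model over the crossing of two factors: the error
#' mean square is pooled within cells with `df = N - k` for `k` non-empty
#' cells (every cell of the crossing must be occupied). Each pair of cells
#' is then compared with the Tukey-Kramer studentized-range statistic
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, referred to the
#' studentized range distribution with `k` means and `N - k` error df --
#' the construction that reproduces published q(df) values for unbalanced
#' group sizes. No correction beyond Tukey is applied.
#'
#' @param values Numeric vector of measurements.
#' @param factor_a,factor_b Factor labels, same length as `values` (each
#'   with >= 2 levels).
#' @return Data frame with one row per cell pair: `comparison`,
#'   `statistic` (q), `df`, `p`.
#' @export
two_way_anova_tukey <- function(values, factor_a, factor_b) {
  values <- as.numeric(values)
  stopifnot(length(factor_a) == length(values),
            length(factor_b) == length(values))
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("both factors need at least 2 levels", call. = FALSE)
  cell <- interaction(fa, fb, sep = ":", lex.order = TRUE)
  tab <- table(cell)
  if (any(tab == 0))
    stop("empty cell(s) in the two-way design: ",
         paste(names(tab)[tab == 0], collapse = ", "), call. = FALSE)
  k <- nlevels(cell)
  n <- length(values)
  if (n <= k) stop("need total N > number of cells", call. = FALSE)
  df <- n - k
  means <- tapply(values, cell, mean)
  ns <- as.integer(tab)
  sse <- sum(tapply(values, cell, function(v) sum((v - mean(v))^2)))
  mse <- sse / df
  pairs <- utils::combn(k, 2)
  lv <- levels(cell)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- if (se == 0) {
      if (means[i] == means[j]) 0 else Inf
    } else abs(means[i] - means[j]) / se
    c(q = unname(q))
  })
  p <- ifelse(is.finite(res), stats::ptukey(res, nmeans = k, df = df,
                                            lower.tail = FALSE),
              ifelse(res == 0, 1, 0))
  data.frame(comparison = paste(lv[pairs[1, ]], "vs", lv[pairs[2, ]]),
             statistic = as.numeric(res), df = df, p = as.numeric(p))
}
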