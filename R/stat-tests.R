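#' Statistical tests used by the pipeline
#'
#' Closed-form implementations of the procedures the analysis relies on:
#' Welch's unequal-variance t-test, chi-square goodness of fit,
#' Benjamini-Hochberg step-up adjustment, and one-/two-way ANOVA. All
#' p-values are two-sided. Each test returns an `edit_test` list with
#' elements `statistic`, `df`, `p`, `test_name`.
#'
#' @name stat_tests
NULL

edit_test <- function(statistic, df, p, test_name) {
  structure(list(statistic = statistic, df = df, p = p, test_name = test_name),
            class = "edit_test")
}

#' @export
print.edit_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %.6g, p = %.6g\n",
              x$test_name, x$statistic, x$df, x$p))
  invisible(x)
}

#' Welch's unpaired t-test
#'
#' t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny), with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @param x,y numeric vectors, each of length >= 2; at least one group must
#'   have nonzero variance.
#' @return An `edit_test`.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) fail("welch_t: need >= 2 observations per group")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) fail("welch_t: both groups have zero variance")
  se2x <- vx / nx; se2y <- vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  edit_test(t, df, p, "Welch two-sample t-test")
}

#' Chi-square goodness-of-fit test
#'
#' sum((observed - expected)^2 / expected) on df = k - 1.
#'
#' @param observed non-negative counts.
#' @param expected positive expected counts, same length; defaults to equal
#'   expectation at the observed total.
#' @return An `edit_test`.
#' @export
chi2_gof <- function(observed, expected = NULL) {
  if (is.null(expected)) expected <- rep(sum(observed) / length(observed), length(observed))
  if (length(observed) != length(expected)) fail("chi2_gof: length mismatch")
  if (length(observed) < 2) fail("chi2_gof: need >= 2 cells")
  if (any(expected <= 0)) fail("chi2_gof: expected counts must be positive")
  if (any(observed < 0)) fail("chi2_gof: observed counts must be non-negative")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  edit_test(stat, df, p, "chi-square goodness of fit")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns FDR-adjusted p-values in the input order. Monotone step-up:
#' adjusted p(i) = min over j >= i of p(j) * m / j on the sorted scale,
#' capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\]. NAs are propagated.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) fail("bh_adjust: p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    out[ok] <- pmin(1, cummin(pv[o] * m / seq(m, 1)))[ro]
  }
  out
}

#' One-way ANOVA
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   nonempty, total N > number of groups).
#' @return An `edit_test` (F statistic, numerator df stored in `df` as a
#'   two-element vector c(df1, df2)).
#' @export
anova_one_way <- function(groups) {
  if (length(groups) < 2) fail("anova_one_way: need >= 2 groups")
  n <- lengths(groups)
  if (any(n < 1)) fail("anova_one_way: empty group")
  all <- unlist(groups)
  N <- length(all); k <- length(groups)
  if (N <= k) fail("anova_one_way: no residual degrees of freedom")
  grand <- mean(all)
  means <- vapply(groups, mean, 0)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - means[i])^2), 0))
  df1 <- k - 1; df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  edit_test(f, c(df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE),
            "one-way ANOVA")
}

#' Two-way ANOVA (balanced designs)
#'
#' Fixed-effects two-way ANOVA with interaction for balanced designs (equal
#' replication in every cell). With one observation per cell the interaction
#' is not estimable and the additive model is fitted (interaction used as
#' error). Unbalanced designs are rejected.
#'
#' @param response numeric vector.
#' @param factor_a,factor_b factors (or coercible), same length as response.
#' @return A list of `edit_test` results named `factor_a`, `factor_b`, and
#'   (when estimable) `interaction`.
#' @export
anova_two_way <- function(response, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (length(response) != length(fa) || length(response) != length(fb)) {
    fail("anova_two_way: length mismatch")
  }
  counts <- table(fa, fb)
  if (any(counts == 0)) fail("anova_two_way: empty cell")
  if (length(unique(as.vector(counts))) != 1) {
    fail("anova_two_way: design is unbalanced; equal cell counts required")
  }
  r <- as.vector(counts)[1]
  a <- nlevels(fa); b <- nlevels(fb); N <- length(response)
  grand <- mean(response)
  mean_a <- tapply(response, fa, mean)
  mean_b <- tapply(response, fb, mean)
  cell <- tapply(response, list(fa, fb), mean)
  ss_a <- r * b * sum((mean_a - grand)^2)
  ss_b <- r * a * sum((mean_b - grand)^2)
  ss_cells <- r * sum((cell - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((response - grand)^2)
  ss_err <- ss_tot - ss_cells
  df_a <- a - 1; df_b <- b - 1; df_ab <- (a - 1) * (b - 1)
  if (r > 1) {
    df_err <- N - a * b
  } else {
    # additive model: interaction absorbs the error
    ss_err <- ss_ab
    df_err <- df_ab
  }
  mk <- function(ss, df1, name) {
    f <- (ss / df1) / (ss_err / df_err)
    edit_test(f, c(df1, df_err), stats::pf(f, df1, df_err, lower.tail = FALSE),
              name)
  }
  out <- list(factor_a = mk(ss_a, df_a, "two-way ANOVA: factor A"),
              factor_b = mk(ss_b, df_b, "two-way ANOVA: factor B"))
  if (r > 1) out$interaction <- mk(ss_ab, df_ab, "two-way ANOVA: interaction")
  out
}

#' Kruskal-Wallis rank-sum test (wrapper)
#'
#' Thin wrapper over [stats::kruskal.test()], provided for completeness; no
#' reported quantity in this pipeline depends on it.
#'
#' @param groups list of numeric vectors.
#' @return An `edit_test`.
#' @export
kruskal_wallis <- function(groups) {
  kt <- stats::kruskal.test(groups)
  edit_test(unname(kt$statistic), unname(kt$parameter), kt$p.value,
            "Kruskal-Wallis rank sum test")
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics from mean ranks with the tie correction, BH-adjusted.
#' Provided for completeness; no reported quantity depends on it.
#'
#' @param groups named list of numeric vectors.
#' @return Data frame with columns group1, group2, z, p, p_adj.
#' @export
dunn_test <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  rk <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rk <- tapply(rk, g, mean)
  n <- tapply(rk, g, length)
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[pr[1]] + 1 / n[pr[2]]))
    z <- (mean_rk[pr[1]] - mean_rk[pr[2]]) / se
    c(z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = res["z", ], p = res["p", ], p_adj = bh_adjust(res["p", ]),
             row.names = NULL)
}
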