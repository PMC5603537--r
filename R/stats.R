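.check_groups <- function(values, groups, min_per_group = 2) {
  stopifnot(length(values) == length(groups))
  if (anyNA(values) || anyNA(groups)) stop("values/groups contain NA")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < min_per_group))
    stop("every group needs at least ", min_per_group, " values")
  g
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition for grouped measurements such as
#' per-treatment conversion efficiencies or coal heating values, via
#' [stats::aov()].
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length as `values`.
#' @return A list of class `"anova_groups"`: `F` statistic, `df` (between,
#'   within), `p_value`, `ms_within`, per-group `means` and `n`.
#' @examples
#' one_way_anova(c(1, 2, 5, 6, 9, 10), rep(c("a", "b", "c"), each = 2))
#' @export
one_way_anova <- function(values, groups) {
  g <- .check_groups(values, groups)
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1L]]
  Fval <- tab[1L, "F value"]
  pval <- tab[1L, "Pr(>F)"]
  if (stats::var(values) == 0 || tab[1L, "Sum Sq"] == 0) {
    # no between-group variation at all: report F = 0 rather than 0/0
    Fval <- 0
    pval <- 1
  }
  structure(
    list(F = Fval,
         df = c(between = tab[1L, "Df"], within = tab[2L, "Df"]),
         p_value = pval,
         ms_within = tab[2L, "Mean Sq"],
         means = tapply(values, g, mean),
         n = as.integer(table(g))),
    class = "anova_groups"
  )
}

#' @export
print.anova_groups <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p_value))
  invisible(x)
}

#' Least-significant-difference post hoc comparisons
#'
#' Pairwise Fisher LSD tests after a one-way ANOVA:
#' \deqn{LSD_{ij} = t_{1-\alpha/2,\,df_W}\sqrt{MS_W (1/n_i + 1/n_j)},}
#' flagging pairs whose absolute mean difference exceeds their LSD.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level (default 0.05).
#' @return A data frame with one row per group pair: `group1`, `group2`,
#'   `diff` (mean difference), `lsd`, `significant`.
#' @export
lsd_posthoc <- function(values, groups, alpha = 0.05) {
  an <- one_way_anova(values, groups)
  lev <- names(an$means)
  tcrit <- stats::qt(1 - alpha / 2, an$df[["within"]])
  pairs <- utils::combn(seq_along(lev), 2)
  out <- data.frame(
    group1 = lev[pairs[1L, ]],
    group2 = lev[pairs[2L, ]],
    diff = an$means[pairs[1L, ]] - an$means[pairs[2L, ]],
    lsd = tcrit * sqrt(an$ms_within *
                         (1 / an$n[pairs[1L, ]] + 1 / an$n[pairs[2L, ]])),
    row.names = NULL
  )
  out$significant <- abs(out$diff) > out$lsd
  out
}

#' Hartley's Fmax variance-ratio screen
#'
#' Ratio of the largest to the smallest group variance, compared with a
#' user-supplied critical value (Hartley tables depend on group count and
#' per-group df; the default 39.2 is the usual tabulated value for 4
#' groups with 3 df each at alpha = 0.05).
#'
#' @inheritParams one_way_anova
#' @param critical Critical value for the equal-variance decision.
#' @return A list: `fmax`, `variances`, `critical`,
#'   `equal_variances` (TRUE when `fmax` is below `critical`).
#' @export
hartley_fmax <- function(values, groups, critical = 39.2) {
  g <- .check_groups(values, groups)
  v <- tapply(values, g, stats::var)
  if (any(v == 0)) {
    fmax <- if (all(v == 0)) 1 else Inf
  } else {
    fmax <- max(v) / min(v)
  }
  list(fmax = fmax, variances = v, critical = critical,
       equal_variances = fmax < critical)
}

#' Pearson correlation matrix
#'
#' Pairwise Pearson correlations of the numeric columns of a table, e.g.
#' acid concentrations against cumulative methane across sampling days.
#'
#' @param data A data frame or matrix of numeric columns (at least 2).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("all columns must be numeric")
  if (ncol(m) < 2) stop("need at least two columns")
  stats::cor(m, method = "pearson")
}
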