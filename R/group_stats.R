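#' Mean and SEM by group
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return data frame `group`, `n`, `mean`, `sem` (SEM is `NA` for
#'   `n < 2`).
#' @export
summarize_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  sp <- split(values, groups)
  data.frame(group = names(sp),
             n = vapply(sp, length, integer(1)),
             mean = vapply(sp, mean, numeric(1)),
             sem = vapply(sp, sem, numeric(1)),
             row.names = NULL)
}

#' Decision-tree group comparison
#'
#' Reproduces the standard applied decision tree for comparing a
#' quantitative metric across groups of syncytia. Normality is assessed
#' per group with a Kolmogorov-Smirnov test on standardized residuals
#' (sample mean and SD plugged in); homoscedasticity with an F-test for
#' variances (for more than two groups, the largest-variance vs
#' smallest-variance pair, Bonferroni-adjusted). If every premise holds at
#' level `alpha`, the parametric branch runs one-way ANOVA followed by
#' Tukey's HSD; otherwise the nonparametric branch runs Kruskal-Wallis
#' followed by pairwise Mann-Whitney U tests. Pairwise significance uses a
#' Bonferroni-adjusted level (`alpha / n_comparisons`); both raw and
#' adjusted pairwise p-values are reported. A constant-valued group makes
#' the variance premise undefined and forces the nonparametric branch
#' (noted in the audit trail).
#'
#' @param values numeric vector of per-recording values.
#' @param groups group membership, same length.
#' @param alpha significance level (default 0.05).
#' @return object of class `group_comparison`: `summary` (per-group
#'   n/mean/SEM), `normality_p`, `variance_p`, `branch`
#'   (`"parametric"`/`"nonparametric"`), `omnibus` (statistic, df, p,
#'   method), `pairwise` (data frame with raw and Bonferroni-adjusted
#'   p-values and significance flags), `alpha`, `alpha_adjusted`, `notes`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  sp <- split(values, groups)
  if (length(sp) < 2) stop("need at least 2 groups")
  ns <- vapply(sp, length, integer(1))
  if (any(ns < 2)) stop("every group needs n >= 2")
  notes <- character(0)

  norm_p <- vapply(sp, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    z <- (x - mean(x)) / stats::sd(x)
    suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
  }, numeric(1))

  vars <- vapply(sp, stats::var, numeric(1))
  if (any(vars == 0)) {
    var_p <- NA_real_
    notes <- c(notes, "constant-valued group: variance premise undefined; nonparametric branch forced")
  } else if (length(sp) == 2) {
    var_p <- stats::var.test(sp[[1]], sp[[2]])$p.value
  } else {
    p_raw <- stats::var.test(sp[[which.max(vars)]],
                             sp[[which.min(vars)]])$p.value
    var_p <- min(1, p_raw * choose(length(sp), 2))
    notes <- c(notes, "k>2: F-test on max-vs-min variance pair, Bonferroni-adjusted")
  }

  parametric <- all(!is.na(norm_p)) && all(norm_p > alpha) &&
    !is.na(var_p) && var_p > alpha
  n_pairs <- choose(length(sp), 2)
  alpha_adj <- alpha / n_pairs
  df <- data.frame(value = values, group = groups)

  if (parametric) {
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    omnibus <- list(method = "one-way ANOVA", statistic = an[1, "F value"],
                    df = c(an[1, "Df"], an[2, "Df"]),
                    p = an[1, "Pr(>F)"])
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    pw <- data.frame(comparison = rownames(tk),
                     estimate = tk[, "diff"],
                     p = tk[, "p adj"], row.names = NULL)
    pw$p_bonferroni <- pmin(1, pw$p * n_pairs)
    pw$method <- "Tukey HSD"
  } else {
    kw <- stats::kruskal.test(value ~ group, data = df)
    omnibus <- list(method = "Kruskal-Wallis", statistic = kw$statistic[[1]],
                    df = kw$parameter[[1]], p = kw$p.value)
    gn <- names(sp)
    pairs <- utils::combn(gn, 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(pairs, function(pr) {
      wt <- suppressWarnings(stats::wilcox.test(sp[[pr[1]]], sp[[pr[2]]]))
      data.frame(comparison = paste(pr[2], pr[1], sep = "-"),
                 estimate = stats::median(sp[[pr[2]]]) -
                   stats::median(sp[[pr[1]]]),
                 p = wt$p.value)
    }))
    pw$p_bonferroni <- pmin(1, pw$p * n_pairs)
    pw$method <- "Mann-Whitney U"
  }
  pw$significant <- pw$p_bonferroni < alpha

  structure(list(summary = summarize_groups(values, groups),
                 normality_p = norm_p, variance_p = var_p,
                 branch = if (parametric) "parametric" else "nonparametric",
                 omnibus = omnibus, pairwise = pw,
                 alpha = alpha, alpha_adjusted = alpha_adj,
                 notes = notes),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s branch; omnibus %s: stat=%.4g, p=%.4g\n",
              x$branch, x$omnibus$method, x$omnibus$statistic, x$omnibus$p))
  print(x$summary, row.names = FALSE)
  cat(sprintf("Pairwise (%s; Bonferroni-adjusted alpha = %.4g):\n",
              x$pairwise$method[1], x$alpha_adjusted))
  print(x$pairwise[, c("comparison", "estimate", "p", "p_bonferroni",
                       "significant")], row.names = FALSE)
  for (n in x$notes) cat("note: ", n, "\n", sep = "")
  invisible(x)
}

#' Chi-square test of arrhythmia incidence
#'
#' Pearson chi-square (no continuity correction by default, which makes
#' the 2x2 statistic the textbook
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`) on a `2 x k` contingency
#' table of arrhythmic vs non-arrhythmic counts per group.
#'
#' @param counts `2 x k` matrix of non-negative integers (rows: outcome,
#'   columns: groups), `k >= 2`.
#' @param correct logical; apply Yates continuity correction (default
#'   `FALSE`; the choice is recorded in the result).
#' @return list: `statistic`, `df`, `p`, `correct`, `expected`.
#' @export
incidence_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2)
    stop("'counts' must be a 2 x k matrix with k >= 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must hold non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("undefined: zero row or column margin in the contingency table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = ct$statistic[[1]], df = ct$parameter[[1]],
       p = ct$p.value, correct = correct, expected = ct$expected)
}
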