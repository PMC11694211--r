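#' Build a variable table (units of analysis x conditions)
#'
#' Reshapes a trial-level feature table into the n x 4 matrix analysed by the
#' omnibus tests. With `unit = "subject_mean"` each cell is a subject's mean
#' over their trials of a condition (the default unit of analysis); with
#' `unit = "trial"` rows are subject-by-trial-index combinations, pairing
#' trial k of each condition within a subject.
#'
#' @param features Feature table (rows = trials) with `subject_id`,
#'   `condition`, `trial_index` and the variable column.
#' @param variable Name of the feature column.
#' @param unit `"subject_mean"` or `"trial"`.
#'
#' @return Numeric matrix, one column per condition in
#'   [snatch_conditions] order, complete cases only.
#' @export
variable_table <- function(features, variable,
                           unit = c("subject_mean", "trial")) {
  unit <- match.arg(unit)
  if (!variable %in% names(features))
    stop("variable_table: no column called ", variable)
  key <- if (unit == "subject_mean") features$subject_id
         else paste(features$subject_id, features$trial_index, sep = ":")
  val <- features[[variable]]
  tab <- tapply(val, list(key, factor(features$condition,
                                      levels = snatch_conditions())),
                mean)
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < 3)
    stop("variable_table: fewer than 3 complete units of analysis")
  tab
}

#' Normality gate: choose the omnibus test
#'
#' Shapiro-Wilk on each condition's values; the parametric repeated-measures
#' ANOVA is used only if every condition passes at the configured alpha,
#' otherwise the Friedman test. A degenerate (zero-variance) column fails the
#' gate.
#'
#' @param tab n x k variable table.
#' @param alpha Gate level.
#'
#' @return `"rm_anova"` or `"friedman"`.
#' @export
choose_test <- function(tab, alpha = 0.05) {
  if (nrow(tab) < 3) stop("choose_test: need at least 3 rows")
  p <- apply(tab, 2, function(col) {
    if (stats::sd(col) == 0) return(0)      # degenerate: not normal
    tryCatch(stats::shapiro.test(col)$p.value, error = function(e) 0)
  })
  if (all(p >= alpha)) "rm_anova" else "friedman"
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA by direct sums-of-squares decomposition:
#' F = MS_condition / MS_error with df (k-1, (k-1)(n-1)), error SS being the
#' subject-by-condition interaction. Effect size is partial eta squared,
#' SS_condition / (SS_condition + SS_error). No sphericity correction is
#' applied.
#'
#' @param tab n x k variable table (rows = subjects).
#'
#' @return List of class `omnibus_result`: `test`, `statistic`, `df`,
#'   `p_value`, `effect_size`, `effect_type`.
#' @export
rm_anova <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  if (n < 2 || k < 2) stop("rm_anova: need at least 2 rows and 2 columns")
  grand <- mean(tab)
  ss_cond <- n * sum((colMeans(tab) - grand)^2)
  ss_subj <- k * sum((rowMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_tot == 0)
    stop("rm_anova: degenerate table (no variance at all)")
  if (ss_cond <= .Machine$double.eps * ss_tot) {
    return(structure(list(test = "rm_anova", statistic = 0,
                          df = c(df1 = df1, df2 = df2), p_value = 1,
                          effect_size = 0,
                          effect_type = "partial_eta_squared"),
                     class = "omnibus_result"))
  }
  if (ss_err <= .Machine$double.eps * ss_tot)
    stop("rm_anova: degenerate error variance (all subjects respond identically)")
  f <- (ss_cond / df1) / (ss_err / df2)
  structure(list(test = "rm_anova", statistic = f,
                 df = c(df1 = df1, df2 = df2),
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 effect_size = ss_cond / (ss_cond + ss_err),
                 effect_type = "partial_eta_squared"),
            class = "omnibus_result")
}

#' Friedman rank test
#'
#' Nonparametric omnibus test on within-row mid-ranks with tie correction
#' (the same statistic as `stats::friedman.test`). The effect size reported
#' is Kendall's W, the statistic divided by n(k-1).
#'
#' @param tab n x k variable table.
#'
#' @return List of class `omnibus_result` (chi-squared statistic on k-1 df).
#' @export
friedman_test <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  if (n < 2 || k < 2) stop("friedman_test: need at least 2 rows and 2 columns")
  r <- t(apply(tab, 1, rank))
  ties <- sum(apply(r, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  stat <- if (denom <= 0) 0 else
    12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  df <- k - 1
  structure(list(test = "friedman", statistic = stat,
                 df = c(df = df),
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 effect_size = stat / (n * (k - 1)),
                 effect_type = "kendalls_w"),
            class = "omnibus_result")
}

#' @export
print.omnibus_result <- function(x, ...) {
  dfs <- paste(x$df, collapse = ", ")
  cat(sprintf("%s: statistic = %.4g (df %s), p = %.4g, %s = %.3f\n",
              x$test, x$statistic, dfs, x$p_value, x$effect_type,
              x$effect_size))
  invisible(x)
}

# Wilcoxon signed-rank with Pratt handling of zero differences: zeros are
# ranked with the rest, then dropped from the rank sums; normal approximation
# with tie and zero corrections. Identical samples give p = 1 by convention.
.wilcoxon_pratt <- function(x, y) {
  d <- x - y
  n <- length(d)
  nz <- sum(d == 0)
  if (nz == n) return(list(statistic = 0, p_value = 1))
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  mu <- (n * (n + 1) / 2 - nz * (nz + 1) / 2) / 2
  tie_tab <- table(rk[d != 0])
  v <- n * (n + 1) * (2 * n + 1) / 24 -
    nz * (nz + 1) * (2 * nz + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (v <= 0) return(list(statistic = w_pos, p_value = 1))
  z <- (w_pos - mu) / sqrt(v)
  list(statistic = w_pos, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Pairwise post-hoc comparisons
#'
#' All k(k-1)/2 pairwise comparisons between conditions: paired t tests after
#' a parametric omnibus, Wilcoxon signed-rank tests (Pratt zero handling)
#' after a Friedman omnibus. P values are Bonferroni-adjusted by the number
#' of pairs and capped at 1.
#'
#' @param tab n x k variable table with condition column names.
#' @param test_used `"rm_anova"` or `"friedman"` (selects t vs Wilcoxon).
#'
#' @return Data frame with `pair`, `statistic`, `p_raw`, `p_adj`.
#' @export
posthoc <- function(tab, test_used = c("rm_anova", "friedman")) {
  test_used <- match.arg(test_used)
  k <- ncol(tab)
  cn <- colnames(tab)
  if (is.null(cn)) cn <- paste0("C", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(j) {
    a <- tab[, pairs[1, j]]; b <- tab[, pairs[2, j]]
    if (test_used == "rm_anova") {
      if (stats::sd(a - b) == 0) {
        st <- 0; p <- 1
      } else {
        tt <- stats::t.test(a, b, paired = TRUE)
        st <- unname(tt$statistic); p <- tt$p.value
      }
    } else {
      wt <- .wilcoxon_pratt(a, b)
      st <- wt$statistic; p <- wt$p_value
    }
    data.frame(pair = paste(cn[pairs[1, j]], cn[pairs[2, j]], sep = " vs "),
               statistic = st, p_raw = p, p_adj = min(1, p * m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Analyse one variable across the four conditions
#'
#' Runs the decision battery on a variable table: Shapiro-Wilk normality gate
#' selecting RM-ANOVA or Friedman, the omnibus test, and (only when the
#' omnibus is significant at `alpha`) the matching Bonferroni-corrected
#' post-hoc pairwise comparisons.
#'
#' @param tab n x k variable table.
#' @param alpha Significance level.
#'
#' @return An `omnibus_result` with a `posthoc` element (`NULL` when the
#'   omnibus is not significant) and an `n` element.
#' @export
analyze_variable <- function(tab, alpha = 0.05) {
  test <- choose_test(tab, alpha)
  res <- if (test == "rm_anova") rm_anova(tab) else friedman_test(tab)
  res$n <- nrow(tab)
  res$posthoc <- if (res$p_value < alpha) posthoc(tab, test) else NULL
  res
}

#' Fit the full study comparison
#'
#' The study-level analysis: for every requested parameter, aggregate the
#' trial-level feature table to the unit of analysis, run the normality-gated
#' omnibus battery across the four learning conditions, and collect
#' statistics, effect sizes and post hocs, together with the per-condition
#' barbell-path adherence counts.
#'
#' @param features Trial-level feature table (as produced by
#'   [process_trial]/[write_features] round trips or [generate_cohort]).
#' @param variables Feature columns to analyse; defaults to all 23
#'   parameters present in `features`.
#' @param unit Unit of analysis, `"subject_mean"` (default) or `"trial"`.
#' @param alpha Significance level.
#'
#' @return Object of class `snatch_study` with elements `results` (named
#'   list of `omnibus_result`), `table` (tidy per-variable summary data
#'   frame), `adherence`, `unit`, `alpha`.
#' @export
snatch_study <- function(features, variables = NULL,
                         unit = c("subject_mean", "trial"), alpha = 0.05) {
  unit <- match.arg(unit)
  if (is.null(variables))
    variables <- intersect(.feature_cols, names(features))
  if (!length(variables)) stop("snatch_study: no feature columns found")
  results <- lapply(variables, function(v) {
    tab <- variable_table(features, v, unit)
    analyze_variable(tab, alpha)
  })
  names(results) <- variables
  table <- do.call(rbind, lapply(variables, function(v) {
    r <- results[[v]]
    data.frame(variable = v, test = r$test, statistic = r$statistic,
               df = paste(r$df, collapse = ","), p_value = r$p_value,
               effect_size = r$effect_size, effect_type = r$effect_type,
               n = r$n, stringsAsFactors = FALSE)
  }))
  adherence <- if (all(c("X1", "X2", "X3_DxT") %in% names(features)))
    path_adherence(features) else NULL
  structure(list(results = results, table = table, adherence = adherence,
                 unit = unit, alpha = alpha),
            class = "snatch_study")
}

#' @export
print.snatch_study <- function(x, digits = 3, ...) {
  cat(sprintf("snatch_study: %d variables, unit = %s, alpha = %g\n",
              nrow(x$table), x$unit, x$alpha))
  tb <- x$table
  tb$statistic <- signif(tb$statistic, digits)
  tb$p_value <- signif(tb$p_value, digits)
  tb$effect_size <- signif(tb$effect_size, digits)
  print(tb[, c("variable", "test", "statistic", "df", "p_value",
               "effect_size")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.snatch_study <- function(object, ...) {
  print(object)
  sig <- object$table$variable[object$table$p_value < object$alpha]
  if (length(sig)) {
    cat("\nSignificant omnibus effects with post hocs:\n")
    for (v in sig) {
      cat("--", v, "--\n")
      print(object$results[[v]]$posthoc, row.names = FALSE)
    }
  } else {
    cat("\nNo significant omnibus effect at alpha =", object$alpha, "\n")
  }
  if (!is.null(object$adherence)) {
    cat("\nOptimal-path adherence (subjects adhering on every trial):\n")
    print(object$adherence, row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.snatch_study <- function(x, ...) x$table
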