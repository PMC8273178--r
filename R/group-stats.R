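# Group-level inference: one-way repeated-measures ANOVA with subject as a
# blocking factor, Tukey HSD pairwise comparisons on the condition means,
# and two-group t comparisons.

#' One-way repeated-measures ANOVA
#'
#' Standard within-subject decomposition of a complete subject x condition
#' table: `SS_total = SS_condition + SS_subject + SS_residual`, with
#' `F = MS_condition / MS_residual` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom. No sphericity correction is applied.
#'
#' @param table Data frame with columns `subject`, `condition`, `value`;
#'   every subject must have exactly one value per condition.
#' @return An object of class `anova_table`: a data frame with rows
#'   `Condition`, `Subject`, `Residuals` and columns `df`, `sum_sq`,
#'   `mean_sq`, `F`, `p`.
#' @export
#' @examples
#' tab <- expand.grid(subject = 1:13, condition = c("/0", "/2", "/4", "/6"))
#' tab$value <- rnorm(nrow(tab))
#' rm_anova_oneway(tab)
rm_anova_oneway <- function(table) {
  need <- c("subject", "condition", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  subj <- factor(table$subject)
  cond <- factor(table$condition)
  y <- table$value
  n <- nlevels(subj)
  k <- nlevels(cond)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions",
    call. = FALSE
  )
  counts <- table(subj, cond)
  if (any(counts != 1L)) {
    stop("incomplete crossing: every subject needs exactly one value per condition",
      call. = FALSE
    )
  }
  gm <- mean(y)
  mc <- tapply(y, cond, mean)
  ms <- tapply(y, subj, mean)
  ss_total <- sum((y - gm)^2)
  ss_cond <- n * sum((mc - gm)^2)
  ss_subj <- k * sum((ms - gm)^2)
  ss_resid <- ss_total - ss_cond - ss_subj
  df_cond <- k - 1L
  df_subj <- n - 1L
  df_resid <- df_cond * df_subj
  ms_cond <- ss_cond / df_cond
  ms_resid <- ss_resid / df_resid
  # guard degenerate tables (no condition effect and/or no residual noise)
  f <- if (ms_cond <= 0) {
    0
  } else if (ms_resid <= 0) {
    Inf
  } else {
    ms_cond / ms_resid
  }
  p <- stats::pf(f, df_cond, df_resid, lower.tail = FALSE)
  out <- data.frame(
    source = c("Condition", "Subject", "Residuals"),
    df = c(df_cond, df_subj, df_resid),
    sum_sq = c(ss_cond, ss_subj, ss_resid),
    mean_sq = c(ms_cond, ss_subj / df_subj, ms_resid),
    F = c(f, NA, NA), p = c(p, NA, NA)
  )
  structure(out,
    class = c("anova_table", "data.frame"),
    n_subjects = n, k_conditions = k,
    condition_means = mc
  )
}

#' @export
print.anova_table <- function(x, ...) {
  cat("One-way repeated-measures ANOVA\n")
  df <- as.data.frame(x)
  df$sum_sq <- signif(df$sum_sq, 4)
  df$mean_sq <- signif(df$mean_sq, 4)
  df$F <- signif(df$F, 4)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE, na.print = "")
  invisible(x)
}

#' Tukey HSD pairwise comparisons after a repeated-measures ANOVA
#'
#' All `k (k - 1) / 2` condition pairs: studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MS_residual / n)` with adjusted p from the
#' studentized-range distribution on the ANOVA's residual degrees of
#' freedom.
#'
#' @param table The subject x condition data frame the ANOVA was computed
#'   on.
#' @param anova The matching [rm_anova_oneway()] result (computed from
#'   `table` if omitted).
#' @return A data frame with columns `pair`, `diff`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(table, anova = rm_anova_oneway(table)) {
  stopifnot(inherits(anova, "anova_table"))
  n <- attr(anova, "n_subjects")
  k <- attr(anova, "k_conditions")
  df_resid <- anova$df[anova$source == "Residuals"]
  if (df_resid < 1L) stop("residual degrees of freedom < 1", call. = FALSE)
  ms_resid <- anova$mean_sq[anova$source == "Residuals"]
  means <- attr(anova, "condition_means")
  se <- sqrt(ms_resid / n)
  pairs <- utils::combn(names(means), 2)
  out <- data.frame(
    pair = apply(pairs, 2, paste, collapse = " - "),
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    stringsAsFactors = FALSE
  )
  out$q <- abs(out$diff) / se
  out$p_adj <- stats::ptukey(out$q, nmeans = k, df = df_resid,
    lower.tail = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Two-group mean comparison
#'
#' Paired or Welch two-sample t test (two-sided), for comparing response
#' magnitudes between the main and control experiments.
#'
#' @param a,b Numeric vectors; `mode = "paired"` requires equal lengths.
#' @param mode `"welch"` (default: cohorts overlap only partially) or
#'   `"paired"`.
#' @return A list with `t`, `df`, `p`, `mean_diff`, `mode`.
#' @export
compare_means <- function(a, b, mode = c("welch", "paired")) {
  mode <- match.arg(mode)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (mode == "paired" && length(a) != length(b)) {
    stop("paired mode requires equal-length groups", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  if (mode == "paired" && stats::var(a - b) == 0) {
    # degenerate paired case: identical differences everywhere
    d <- mean(a - b)
    return(list(
      t = if (d == 0) 0 else sign(d) * Inf,
      df = length(a) - 1, p = if (d == 0) 1 else 0,
      mean_diff = d, mode = mode
    ))
  }
  tt <- stats::t.test(a, b, paired = mode == "paired", var.equal = FALSE)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_diff = mean(a) - mean(b), mode = mode
  )
}

#' Inside/on response-magnitude ratio
#'
#' The quotient of condition-averaged response magnitudes for the regions
#' retinotopically inside the patch ring versus on the patches — plain
#' arithmetic, exposed as a documented helper.
#'
#' @param inside,on Numeric vectors of per-subject (or per-condition)
#'   response magnitudes.
#' @return `mean(inside) / mean(on)`.
#' @export
inside_on_ratio <- function(inside, on) {
  mean(inside) / mean(on)
}
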