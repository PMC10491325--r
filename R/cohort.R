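## Cohort summaries, two-sample tests, one-way ANOVA, relative collagen
## abundances and Bonferroni correction.

#' Summary statistics of one group of values
#'
#' Mean, sample standard deviation (n - 1 denominator) and standard error of
#' the mean. Summaries of cohorts are conventionally printed both as
#' mean +/- SD (tables) and mean +/- SEM (results text), so all three are
#' returned. For n = 1 the SD and SEM are `NA`.
#'
#' @param values Numeric vector, length >= 1.
#' @return One-row data.frame with columns `n`, `mean`, `sd`, `sem`.
#' @examples
#' groupSummary(c(66, 61, 80, 72))   # mean 69.8, SD 8.2
#' @export
groupSummary <- function(values) {
  stopIfNot(is.numeric(values) && length(values) >= 1 && all(is.finite(values)),
            "values must be a non-empty finite numeric vector", "invalidInput")
  n <- length(values)
  s <- if (n > 1) stats::sd(values) else NA_real_
  data.frame(n = n, mean = mean(values), sd = s, sem = s / sqrt(n))
}

#' Validate a cohort table
#'
#' A cohort table holds one row per measured arterial segment with columns
#' `group` (one of control/early/intermediate/advanced), `donor` (donor
#' identifier; several segments may share a donor), `age` (years), `sex`,
#' `thickness_mm`, `inner_diameter_mm`, `outer_diameter_mm`.
#'
#' @param table data.frame to validate.
#' @return The table, invisibly, after validation.
#' @export
validateCohortTable <- function(table) {
  need <- c("group", "donor", "age", "sex", "thickness_mm",
            "inner_diameter_mm", "outer_diameter_mm")
  miss <- setdiff(need, names(table))
  stopIfNot(length(miss) == 0,
            paste0("cohort table missing column(s): ", paste(miss, collapse = ", ")),
            "parseError")
  stopIfNot(all(table$group %in% c("control", "early", "intermediate", "advanced")),
            "group labels must be control/early/intermediate/advanced", "parseError")
  dims <- c("thickness_mm", "inner_diameter_mm", "outer_diameter_mm")
  stopIfNot(all(vapply(table[dims], function(x) all(x > 0), logical(1))),
            "all dimensions must be > 0", "parseError")
  invisible(table)
}

#' Per-group summaries of a cohort table
#'
#' Dimensions are averaged over segments while donor-level variables (age)
#' are averaged over donors, mirroring how such tables are conventionally
#' reported: a donor contributing two segments contributes two thickness
#' values but one age.
#'
#' @param table A validated cohort table (see [validateCohortTable()]).
#' @param variable Column to summarise.
#' @param unit `"segment"` (one value per row) or `"donor"` (first value per
#'   donor).
#' @return data.frame with one row per group: `group`, `n`, `mean`, `sd`,
#'   `sem`.
#' @examples
#' cohortSummary(acaCohort(), "age", unit = "donor")
#' cohortSummary(acaCohort(), "thickness_mm")
#' @export
cohortSummary <- function(table, variable, unit = c("segment", "donor")) {
  unit <- match.arg(unit)
  validateCohortTable(table)
  stopIfNot(variable %in% names(table),
            paste0("no such column: ", variable), "invalidInput")
  out <- lapply(split(table, table$group), function(g) {
    v <- if (unit == "donor") {
      vapply(split(g[[variable]], g$donor), `[`, numeric(1), 1)
    } else g[[variable]]
    cbind(group = g$group[1], groupSummary(v))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$group, c("early", "intermediate", "advanced", "control"))), ]
}

#' Two-sample t-test
#'
#' Two-sided Student (pooled-variance) or Welch t-test.
#'
#' @param x,y Numeric samples, each n >= 2.
#' @param variance `"pooled"` (Student, default) or `"welch"`.
#' @return List with `t`, `p`, `df` and `method`.
#' @export
tTestTwoSample <- function(x, y, variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  stopIfNot(length(x) >= 2 && length(y) >= 2,
            "each sample must have n >= 2", "invalidInput")
  ht <- stats::t.test(x, y, var.equal = variance == "pooled")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), method = variance)
}

#' One-way ANOVA
#'
#' Standard one-way fixed-effects F test across k groups (equal variances
#' assumed, matching the pooled t-test: for two groups F = t^2). Degenerate
#' input with zero variance everywhere returns F = 0, p = 1.
#'
#' @param groups List of numeric vectors, >= 2 groups with n >= 2 each.
#' @return List with `F`, `p`, `df` (numerator, denominator).
#' @export
anovaOneway <- function(groups) {
  stopIfNot(is.list(groups) && length(groups) >= 2,
            "at least two groups required", "invalidInput")
  stopIfNot(all(lengths(groups) >= 2), "each group must have n >= 2",
            "invalidInput")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) == 0)
    return(list(F = 0, p = 1, df = c(length(groups) - 1,
                                     length(values) - length(groups))))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Validate an abundance table
#'
#' An abundance table holds one row per sample with columns `sample`,
#' `group`, and one non-negative abundance column per collagen type
#' (arbitrary label-free quantitation units).
#'
#' @param table data.frame to validate.
#' @return Character vector of collagen column names, invisibly.
#' @export
validateAbundanceTable <- function(table) {
  stopIfNot(all(c("sample", "group") %in% names(table)),
            "abundance table needs 'sample' and 'group' columns", "parseError")
  types <- setdiff(names(table), c("sample", "group"))
  stopIfNot(length(types) >= 1, "no collagen columns found", "parseError")
  stopIfNot(all(vapply(table[types], function(x) all(x >= 0), logical(1))),
            "abundances must be >= 0", "parseError")
  invisible(types)
}

#' Relative collagen abundances (percent of total collagen)
#'
#' Re-expresses each sample's collagen abundances as percentages of that
#' sample's total collagen abundance; percentages sum to 100 per sample.
#'
#' @param table An abundance table (see [validateAbundanceTable()]).
#' @return The table with abundance columns replaced by percentages.
#' @examples
#' t <- data.frame(sample = "s1", group = "control", I = 50, III = 30, IV = 20)
#' relativeCollagenAbundance(t)
#' @export
relativeCollagenAbundance <- function(table) {
  types <- validateAbundanceTable(table)
  tot <- rowSums(table[types])
  stopIfNot(all(tot > 0), "zero total collagen abundance in at least one sample",
            "invalidInput")
  table[types] <- 100 * table[types] / tot
  table
}

#' Bonferroni correction
#'
#' Family-wise error control: adjusted p = min(1, p * m). The family size
#' `m` defaults to the number of p-values supplied but can be set explicitly
#' when the tested family is larger than the vector at hand.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Significance level for the flags (default 0.05).
#' @param m Family size (default `length(p)`).
#' @return data.frame with `p`, `p_adjusted`, `significant`.
#' @examples
#' bonferroni(c(0.004, 0.2, 0.9))
#' @export
bonferroni <- function(p, alpha = 0.05, m = length(p)) {
  stopIfNot(is.numeric(p) && all(p >= 0) && all(p <= 1),
            "p-values must lie in [0, 1]", "invalidInput")
  stopIfNot(m >= length(p), "family size m cannot be smaller than length(p)",
            "invalidInput")
  adj <- stats::p.adjust(p, method = "bonferroni", n = m)
  data.frame(p = p, p_adjusted = adj, significant = adj < alpha)
}
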