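#' Group comparison of per-animal metrics
#'
#' Two groups: two-tailed Student's t test (equal variances). Three or more
#' groups: one-way ANOVA followed by Tukey HSD all-pairs comparisons.
#' Significance is flagged at 0.05 (presentation only; p-values are reported
#' to full precision). Degenerate input in which every value is identical
#' across groups is reported as p = 1, not significant.
#'
#' @param table data.frame with columns `group`, `animal_id`, `value` (one
#'   value per animal).
#' @param design `"auto"` (default: decided by the number of groups),
#'   `"two-group"` or `"multi-group"`.
#' @return A `group_test` object: list with `design`, `statistic`, `p_value`,
#'   `significant`, `group_means`, and for multi-group designs `pairwise`
#'   (data.frame of Tukey-adjusted comparisons).
#' @export
#' @examples
#' tbl <- data.frame(group = rep(c("healthy", "injured"), each = 5),
#'                   animal_id = 1:10,
#'                   value = c(rnorm(5, 0.9, 0.05), rnorm(5, 0.4, 0.05)))
#' compare_groups(tbl)
compare_groups <- function(table, design = c("auto", "two-group", "multi-group")) {
  design <- match.arg(design)
  need <- c("group", "animal_id", "value")
  if (!all(need %in% names(table)))
    stop_field("table", paste("must have columns", paste(need, collapse = ", ")))
  table$group <- factor(table$group)
  k <- nlevels(table$group)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tapply(table$value, table$group, length) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  if (anyDuplicated(paste(table$group, table$animal_id)))
    stop("one value per animal per group is required", call. = FALSE)
  if (design == "auto") design <- if (k == 2) "two-group" else "multi-group"
  means <- tapply(table$value, table$group, mean)

  if (design == "two-group") {
    if (k != 2) stop("two-group design requires exactly 2 groups", call. = FALSE)
    if (stats::var(table$value) == 0) {
      res <- list(statistic = 0, p_value = 1)
    } else {
      tt <- stats::t.test(value ~ group, data = table, var.equal = TRUE)
      res <- list(statistic = unname(tt$statistic), p_value = tt$p.value)
    }
    out <- list(design = "two-group", statistic = res$statistic,
                p_value = res$p_value, significant = res$p_value < 0.05,
                group_means = means, pairwise = NULL)
  } else {
    if (stats::var(table$value) == 0) {
      lev <- levels(table$group)
      prs <- utils::combn(lev, 2)
      out <- list(design = "multi-group", statistic = 0, p_value = 1,
                  significant = FALSE, group_means = means,
                  pairwise = data.frame(
                    comparison = paste(prs[2, ], prs[1, ], sep = "-"),
                    diff = 0, p_adj = 1, significant = FALSE))
    } else {
      fit <- stats::aov(value ~ group, data = table)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$group
      out <- list(design = "multi-group",
                  statistic = an[["F value"]][1],
                  p_value = an[["Pr(>F)"]][1],
                  significant = an[["Pr(>F)"]][1] < 0.05,
                  group_means = means,
                  pairwise = data.frame(
                    comparison = rownames(tk),
                    diff = unname(tk[, "diff"]),
                    p_adj = unname(tk[, "p adj"]),
                    significant = unname(tk[, "p adj"] < 0.05)))
    }
  }
  structure(out, class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  if (x$design == "two-group") {
    cat("Two-tailed Student's t test: t =", signif(x$statistic, 4),
        ", p =", format(x$p_value, digits = 4),
        if (x$significant) "(significant at 0.05)" else "(NS)", "\n")
  } else {
    cat("One-way ANOVA: F =", signif(x$statistic, 4),
        ", p =", format(x$p_value, digits = 4),
        if (x$significant) "(significant at 0.05)" else "(NS)", "\n")
    cat("Tukey HSD pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
  }
  cat("Group means:\n")
  print(round(x$group_means, 4))
  invisible(x)
}
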