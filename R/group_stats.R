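significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Compare two groups with a normality/equal-variance gated test
#'
#' Implements the two-group decision procedure used throughout the analyses:
#' each group is checked for normality (Shapiro-Wilk) and the pair for equal
#' variance (Levene's test, Brown-Forsythe median centering via
#' [car::leveneTest()]); if both criteria hold at the gate alpha, a pooled
#' two-sample t-test is used, otherwise a Mann-Whitney U test. The result
#' records which path fired and the gating diagnostics.
#'
#' @param a,b Numeric vectors, each of length >= 3.
#' @param gate_alpha Significance level of the gating tests (default 0.05).
#' @param labels Length-2 character vector naming the groups.
#' @return A `comparison_result` list: `test` (one of `"t-test"`,
#'   `"Mann-Whitney U"`), `statistic`, `p_value`, `stars`, `n`,
#'   `normality_p` (per group), `equal_variance_p`, `labels`.
#' @export
#' @examples
#' set.seed(1)
#' compare_two_groups(rnorm(8), rnorm(8, mean = 3))
compare_two_groups <- function(a, b, gate_alpha = 0.05,
                               labels = c("group1", "group2")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b)) stop("NA values in input groups")
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs n >= 3 (got ", length(a), " and ", length(b), ")")
  if (sd(a) == 0 && sd(b) == 0)
    stop("both groups have zero variance; no comparison is possible")
  shapiro_p <- vapply(list(a, b), function(x) {
    if (sd(x) == 0) return(NA_real_)  # degenerate: cannot pass the gate
    shapiro.test(x)$p.value
  }, numeric(1))
  lev <- car::leveneTest(c(a, b),
                         factor(rep(labels, c(length(a), length(b)))))
  levene_p <- lev[["Pr(>F)"]][1]
  gate_ok <- !anyNA(shapiro_p) && all(shapiro_p > gate_alpha) &&
    !is.na(levene_p) && levene_p > gate_alpha
  if (gate_ok) {
    ht <- t.test(a, b, var.equal = TRUE)
    test <- "t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
    test <- "Mann-Whitney U"
  }
  res <- list(test = test,
              statistic = unname(ht$statistic),
              p_value = ht$p.value,
              stars = significance_stars(ht$p.value),
              n = c(length(a), length(b)),
              normality_p = setNames(shapiro_p, labels),
              equal_variance_p = levene_p,
              gate_alpha = gate_alpha,
              labels = labels)
  class(res) <- "comparison_result"
  res
}

#' Compare three or more groups with one-way ANOVA and Tukey HSD
#'
#' @param groups A named (or unnamed) list of numeric vectors, each n >= 3.
#' @return A `comparison_result` list: `test = "one-way ANOVA + Tukey"`,
#'   omnibus `statistic` (F), `p_value`, `df`, and `pairwise` — a tibble of
#'   Tukey-adjusted pairwise comparisons with significance stars.
#' @export
#' @examples
#' set.seed(1)
#' g <- list(p = rnorm(6), m = rnorm(6), d = rnorm(6, 2))
#' compare_multi_groups(g)$pairwise
compare_multi_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stop("need a list of >= 3 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 3))
    stop("every group needs n >= 3; offending group(s): ",
         paste(names(groups)[sizes < 3], collapse = ", "))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))
  if (anyNA(df$value)) stop("NA values in input groups")
  fit <- aov(value ~ group, data = df)
  atab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairwise <- tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    stars = vapply(tk[, "p adj"], significance_stars, character(1)))
  res <- list(test = "one-way ANOVA + Tukey",
              statistic = atab[["F value"]][1],
              p_value = atab[["Pr(>F)"]][1],
              df = c(atab[["Df"]][1], atab[["Df"]][2]),
              n = sizes,
              pairwise = pairwise,
              labels = names(groups))
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 3),
      if (!is.null(x$stars)) paste0(" (", x$stars, ")"), "\n", sep = "")
  if (!is.null(x$normality_p))
    cat("  gates: Shapiro p = [",
        paste(format(x$normality_p, digits = 3), collapse = ", "),
        "], Levene p = ", format(x$equal_variance_p, digits = 3), "\n",
        sep = "")
  if (!is.null(x$pairwise)) {
    cat("  Tukey pairwise:\n")
    print(as.data.frame(x$pairwise), row.names = FALSE)
  }
  invisible(x)
}

#' Serialize comparison results to a flat table
#'
#' @param results A list of `comparison_result` objects.
#' @param path Optional CSV path; if given, the table is written there.
#' @return A tibble, one row per comparison.
#' @export
comparison_table <- function(results, path = NULL) {
  if (inherits(results, "comparison_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    tibble::tibble(
      comparison = paste(r$labels, collapse = " vs "),
      test = r$test,
      statistic = r$statistic,
      p_value = r$p_value,
      stars = r$stars %||% NA_character_,
      n = paste(r$n, collapse = "/"))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) readr::write_csv(out, path, progress = FALSE)
  out
}
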