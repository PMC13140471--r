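#' Normality-gated two-sample comparison
#'
#' The statistical battery used throughout: Shapiro-Wilk normality on each
#' group at `alpha_normality`; if both groups are compatible with normality
#' the unpaired Student's t-test is used, otherwise the Wilcoxon rank-sum
#' test. Two-tailed throughout. Groups whose Shapiro-Wilk test cannot run
#' (n < 3, or zero within-group range) are treated as non-normal and routed
#' to the rank test; two groups with identical constant values give p = 1.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param alpha_normality significance level of the normality gate.
#' @return list: `method` ("t" or "wilcoxon"), `p_value`, `estimate_x`,
#'   `estimate_y` (group medians), `direction` (`"x_higher"`, `"y_higher"`
#'   or `"none"` by median comparison).
#' @export
gated_two_sample_test <- function(x, y, alpha_normality = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 finite observations", call. = FALSE)
  }
  normal_ok <- function(v) {
    if (length(v) < 3 || length(v) > 5000 || diff(range(v)) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha_normality
  }
  both_normal <- normal_ok(x) && normal_ok(y)
  if (diff(range(c(x, y))) == 0) {
    # all observations identical across both groups
    p <- 1
    method <- "wilcoxon"
  } else if (both_normal) {
    p <- stats::t.test(x, y, var.equal = TRUE)$p.value
    method <- "t"
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE)$p.value)
    method <- "wilcoxon"
  }
  mx <- stats::median(x); my <- stats::median(y)
  list(method = method, p_value = p, estimate_x = mx, estimate_y = my,
       direction = if (mx > my) "x_higher" else if (my > mx) "y_higher"
                   else "none")
}

#' Kruskal-Wallis comparison across more than two groups
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 3 levels with data).
#' @return list with `p_value` and `method = "kruskal"`.
#' @export
multi_group_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 3) {
    stop("multi_group_test needs at least 3 non-empty groups", call. = FALSE)
  }
  list(method = "kruskal",
       p_value = stats::kruskal.test(values, groups)$p.value)
}
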