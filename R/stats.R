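#' Assumption-gated two-group comparison
#'
#' Mirrors the study-wide testing policy: Shapiro-Wilk normality on each
#' sample and Levene's test for homogeneity of variances, each gated at
#' `alpha_gate` (default 0.05). Both samples normal and variances
#' homogeneous: pooled two-sample t test. Normal but heteroscedastic:
#' separate-variance (Welch) t test. Otherwise: Wilcoxon rank-sum. Samples
#' too small for Shapiro-Wilk (n < 3) or constant take the nonparametric
#' branch.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param alpha_gate significance gate for the assumption checks.
#' @return A list of class `group_comparison`: `test_name`, `statistic`,
#'   `p_raw`, `p_adjusted` (`NA` until a family adjustment is applied),
#'   `effect_direction` (`"b>a"`, `"a>b"` or `"none"`, by difference of
#'   means), `normality_p` (the smaller of the two Shapiro p-values),
#'   `variance_p`.
#' @export
auto_two_group_test <- function(a, b, alpha_gate = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  check_scalar_num(alpha_gate, "alpha_gate", positive = TRUE)
  sw <- function(x) {
    if (length(x) < 3L || stats::sd(x) == 0) return(0)  # force nonparametric
    stats::shapiro.test(x)$p.value
  }
  norm_p <- min(sw(a), sw(b))
  var_p <- levene_two_group(a, b)
  if (norm_p >= alpha_gate && var_p >= alpha_gate) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    name <- "pooled_t"; stat <- unname(tt$statistic); p <- tt$p.value
  } else if (norm_p >= alpha_gate) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    name <- "welch_t"; stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    name <- "rank_sum"; stat <- unname(wt$statistic); p <- wt$p.value
  }
  d <- mean(b) - mean(a)
  structure(list(test_name = name, statistic = stat, p_raw = p,
                 p_adjusted = NA_real_,
                 effect_direction = if (d > 0) "b>a" else if (d < 0) "a>b" else "none",
                 normality_p = norm_p, variance_p = var_p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic %.3f, p = %.4g (direction %s)\n",
              x$test_name, x$statistic, x$p_raw, x$effect_direction))
  invisible(x)
}

# Levene's test (center = mean) for two groups: the one-way F statistic on
# absolute deviations reduces to the square of the pooled t statistic, so
# the pooled t test on |x - group mean| gives the identical p-value.
levene_two_group <- function(a, b, center = mean) {
  da <- abs(a - center(a)); db <- abs(b - center(b))
  if (stats::sd(da) == 0 && stats::sd(db) == 0) return(1)
  stats::t.test(da, db, var.equal = TRUE)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a hypothesis family.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_field("p", "must be numeric")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop_field("p", "values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
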