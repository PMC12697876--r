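#' Fit a brain-wide activation map
#'
#' The package's core estimator: given per-animal FOS counts across brain
#' regions and a two-level group label, it (i) z-scores each region across
#' all animals pooled, (ii) fits a soft-margin linear SVM discriminating
#' the groups, (iii) estimates the region covariance with (by default
#' automatic) shrinkage toward the diagonal, and (iv) applies the
#' forward-model transformation `A = Sigma_x W Sigma_s^{-1}` so that the
#' fitted pattern `A` is interpretable region-wise: positive entries mark
#' regions with higher standardized FOS in the second group level.
#'
#' @param x a [region_counts()] object, a numeric matrix (animals x
#'   regions), or a data frame with a `group` column and one numeric
#'   column per region.
#' @param group two-level factor; taken from `x` when it carries one.
#' @param shrinkage `"auto"` or fixed intensity in `[0, 1]` (see
#'   [feature_covariance()]).
#' @param cost SVM soft-margin parameter.
#' @param cv cross-validation scheme passed to [cross_validate()], or
#'   `"none"`.
#' @param seed integer seed for the CV fold assignment.
#' @param ... unused.
#'
#' @return An object of class `activation_map` with components `pattern`
#'   (the `activation_pattern`), `classifier`, `curve`, `zscores`, `group`,
#'   `cv`, and the call. Methods: [print()], [summary()], [coef()]
#'   (weights and pattern side by side), [predict()] (classify new count
#'   rows), [plot()] (pattern barplot + contribution curve).
#' @examples
#' rc <- simulate_region_counts(n_per_group = 10, region_names = sprintf("R%02d", 1:12),
#'                              effect_regions = 1:3, effect_log_fold = 0.7, seed = 1)
#' fit <- activation_map(rc, seed = 1)
#' print(fit)
#' head(coef(fit))
#' @export
activation_map <- function(x, ...) UseMethod("activation_map")

#' @rdname activation_map
#' @export
activation_map.data.frame <- function(x, group = NULL, ...) {
  if (is.null(group)) {
    if (!"group" %in% names(x))
      stop("data frame input needs a `group` column", call. = FALSE)
    group <- x$group
    x <- x[setdiff(names(x), "group")]
  }
  activation_map(region_counts(as.matrix(x), group), ...)
}

#' @rdname activation_map
#' @export
activation_map.default <- function(x, group = attr(x, "group"),
                                   shrinkage = "auto", cost = 1,
                                   cv = c("loo", "none", "stratified-k"),
                                   seed = NULL, ...) {
  cv <- match.arg(cv)
  if (!inherits(x, "region_counts")) x <- region_counts(as.matrix(x), group)
  z <- zscore_regions(x)
  clf <- fit_linear_classifier(z, cost = cost, seed = seed)
  sigma_x <- feature_covariance(z, shrinkage = shrinkage)
  pat <- haufe_transform(clf, sigma_x)
  curve <- contribution_curve(pat)
  cv_res <- if (cv == "none") NULL else
    cross_validate(z, scheme = cv, cost = cost, seed = seed)
  structure(list(pattern = pat, classifier = clf, curve = curve,
                 zscores = z, group = attr(x, "group"),
                 center = attr(z, "center"), scale = attr(z, "scale"),
                 degenerate_regions = attr(z, "degenerate_regions"),
                 cv = cv_res, call = match.call()),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  g <- x$group
  cat("Brain-wide activation map (forward-model transform of linear SVM weights)\n")
  cat(sprintf("  %d animals (%s) x %d regions\n", length(g),
              paste(sprintf("%s: %d", levels(g), table(g)), collapse = ", "),
              nrow(x$pattern$A)))
  cat(sprintf("  covariance shrinkage: %.3f   training accuracy: %.3f\n",
              x$pattern$shrinkage_used, x$classifier$training_accuracy))
  if (!is.null(x$cv))
    cat(sprintf("  %s cross-validated accuracy: %.3f\n", x$cv$scheme, x$cv$accuracy))
  cat("  top regions by |pattern|: ",
      paste(utils::head(x$curve$region, 5L), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.activation_map <- function(object, ...) {
  cbind(weight = drop(object$classifier$weights),
        pattern = drop(object$pattern$A))
}

#' @export
summary.activation_map <- function(object, top_k = 10L, ...) {
  ts <- attr(object$curve, "threshold_sets")
  structure(list(fit = object,
                 top = utils::head(object$curve, top_k),
                 threshold_sets = ts),
            class = "summary.activation_map")
}

#' @export
print.summary.activation_map <- function(x, ...) {
  print(x$fit)
  cat("\nLeading contributors:\n")
  print(x$top, digits = 3)
  cat("\nRegions needed for contribution fractions:\n")
  print(x$threshold_sets)
  invisible(x)
}

#' @export
predict.activation_map <- function(object, newdata,
                                   type = c("class", "decision"), ...) {
  type <- match.arg(type)
  nd <- as.matrix(newdata)
  if (ncol(nd) != length(object$center))
    stop("newdata must have the same regions as the fit", call. = FALSE)
  z <- sweep(sweep(nd, 2L, object$center, "-"), 2L, object$scale, "/")
  dec <- drop(z %*% object$classifier$weights) + object$classifier$bias
  if (type == "decision") return(dec)
  factor(object$classifier$levels[(dec > 0) + 1L],
         levels = object$classifier$levels)
}

#' @export
plot.activation_map <- function(x, top_k = 15L, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  top <- utils::head(x$curve, top_k)
  a <- drop(x$pattern$A)[top$region]
  graphics::barplot(a, names.arg = top$region, las = 2,
                    col = ifelse(a >= 0, "firebrick", "steelblue"),
                    ylab = "activation pattern A",
                    main = sprintf("Top %d regions", top_k))
  graphics::plot(seq_len(nrow(x$curve)), x$curve$cumulative_fraction,
                 type = "s", xlab = "regions (ranked by |A|)",
                 ylab = "cumulative contribution",
                 main = "Cumulative activation contribution", ylim = c(0, 1))
  graphics::abline(h = 0.8, lty = 2, col = "grey50")
  invisible(x)
}
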