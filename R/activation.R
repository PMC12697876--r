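#' Z-score region counts across animals
#'
#' Standardizes every region column to mean 0 and sample SD 1 (denominator
#' N - 1), pooling both groups. Zero-variance columns are set to 0 and
#' flagged via the `degenerate_regions` attribute rather than erroring, so
#' brain-wide tables with silent regions remain usable.
#'
#' @param data a [region_counts()] object or numeric matrix (animals x
#'   regions).
#' @return The standardized matrix with attributes `center`, `scale`,
#'   `degenerate_regions`, plus `group` when present on the input.
#' @export
zscore_regions <- function(data) {
  x <- unclass(data)
  attr(x, "ground_truth") <- NULL
  if (nrow(x) < 2L) stop("z-scoring needs at least 2 animals", call. = FALSE)
  ctr <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  degen <- which(sdev == 0 | !is.finite(sdev))
  sdev[degen] <- 1
  z <- sweep(sweep(x, 2L, ctr, "-"), 2L, sdev, "/")
  z[, degen] <- 0
  structure(z, center = ctr, scale = sdev,
            degenerate_regions = colnames(x)[degen],
            group = attr(data, "group"))
}

#' Shrinkage estimate of the region covariance matrix
#'
#' Computes the sample covariance S (denominator N - 1) and shrinks it
#' toward its diagonal: `Sigma = (1 - s) * S + s * diag(S)`. With
#' `shrinkage = "auto"` the intensity is chosen by the analytic
#' (Schafer-Strimmer) rule that minimizes expected squared error, which is
#' essential when N << M (e.g. 6 animals x 129 regions) where S is
#' singular.
#'
#' @param z standardized matrix from [zscore_regions()] (or any numeric
#'   animals x regions matrix).
#' @param shrinkage `"auto"` or a fixed intensity in `[0, 1]`.
#' @return Symmetric PSD matrix with attribute `shrinkage_used`.
#' @export
feature_covariance <- function(z, shrinkage = "auto") {
  z <- as.matrix(unclass(z))
  n <- nrow(z)
  if (n < 2L) stop("covariance needs at least 2 animals", call. = FALSE)
  S <- stats::cov(z)
  if (identical(shrinkage, "auto")) {
    s <- shrinkage_intensity(z, S)
  } else {
    check_scalar_num(shrinkage, "shrinkage")
    if (shrinkage < 0 || shrinkage > 1) stop_field("shrinkage", "must be in [0, 1]")
    s <- shrinkage
  }
  Sigma <- (1 - s) * S
  diag(Sigma) <- diag(S)
  structure(Sigma, shrinkage_used = s)
}

# Schafer-Strimmer analytic shrinkage toward diag(S):
# lambda* = sum_{i != j} Var-hat(S_ij) / sum_{i != j} S_ij^2, clipped to [0, 1]
shrinkage_intensity <- function(z, S = stats::cov(z)) {
  n <- nrow(z)
  xc <- sweep(z, 2L, colMeans(z), "-")
  # w_kij = xc[k,i] * xc[k,j]; Var-hat(S_ij) = n/(n-1)^3 * sum_k (w_kij - wbar_ij)^2
  sum_w2 <- crossprod(xc^2)           # sum_k w_kij^2
  sum_w <- crossprod(xc)              # sum_k w_kij = (n-1) S_ij
  var_s <- n / (n - 1)^3 * (sum_w2 - sum_w^2 / n)
  off <- upper.tri(S) | lower.tri(S)
  denom <- sum(S[off]^2)
  if (denom <= 0) return(0)
  min(1, max(0, sum(var_s[off]) / denom))
}

#' Fit a linear support vector classifier on z-scored region data
#'
#' Soft-margin linear SVM (libsvm via \pkg{e1071}) discriminating the two
#' groups. For a two-class problem the weight matrix W is M x 1. The sign
#' convention is fixed so that a positive decision value — and hence a
#' positive weight on a region — points toward the *second* group level
#' (the model/MA class when levels are `c("CON", "MA")`).
#'
#' @param z standardized matrix with a `group` attribute, or pass `group`
#'   explicitly.
#' @param group two-level factor (overrides the attribute).
#' @param cost soft-margin regularization parameter C, default 1.
#' @param seed integer seed (the solver is deterministic; the seed fixes
#'   the RNG contract for downstream reproducibility bookkeeping).
#' @return A list of class `linear_classifier`: `weights` (M x 1), `bias`,
#'   `training_accuracy`, `cost`, `levels`, `decision_values`.
#' @export
fit_linear_classifier <- function(z, group = attr(z, "group"), cost = 1,
                                  seed = NULL) {
  z <- as.matrix(unclass(z))
  if (ncol(z) < 1L) stop("no features to classify on", call. = FALSE)
  if (is.null(group)) stop("`group` labels are required", call. = FALSE)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop("classification needs exactly two classes", call. = FALSE)
  check_scalar_num(cost, "cost", positive = TRUE)
  fit <- with_seed(seed,
    e1071::svm(x = z, y = group, kernel = "linear", cost = cost,
               scale = FALSE, type = "C-classification"))
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  dec <- drop(z %*% w) + b
  # enforce: larger decision value = second level
  if (mean(dec[group == levels(group)[2L]]) < mean(dec[group == levels(group)[1L]])) {
    w <- -w; b <- -b; dec <- -dec
  }
  pred <- factor(levels(group)[(dec > 0) + 1L], levels = levels(group))
  structure(list(weights = matrix(w, ncol = 1L,
                                  dimnames = list(colnames(z), NULL)),
                 bias = b,
                 training_accuracy = mean(pred == group),
                 cost = cost, levels = levels(group),
                 decision_values = dec),
            class = "linear_classifier")
}

#' @export
print.linear_classifier <- function(x, ...) {
  cat(sprintf("<linear_classifier> %d features, %s vs %s, training accuracy %.3f\n",
              nrow(x$weights), x$levels[1L], x$levels[2L], x$training_accuracy))
  invisible(x)
}

#' Forward-model (Haufe) transformation of classifier weights
#'
#' Converts backward-model weights W into the activation pattern
#' `A = Sigma_x W Sigma_s^{-1}` with `Sigma_s = t(W) Sigma_x W`, the
#' covariance of the latent decision variable. Unlike raw weights, large
#' `|A[m]|` identifies regions whose measured signal actually carries the
#' class difference.
#'
#' The returned object carries the pattern in two equivalent scalings:
#' `A`, the plain formula above (which shrinks by `1/c` if W is rescaled
#' by `c`, since `Sigma_s` absorbs `c^2`), and `A_std`, the pattern
#' re-expressed for a unit-variance latent score
#' (`A_std = Sigma_x W Sigma_s^{-1/2}`), whose magnitude is invariant to
#' any rescaling of W (its orientation follows the sign convention fixed
#' by [fit_linear_classifier()]). Region rankings and contribution curves
#' are identical under either scaling.
#'
#' @param model a `linear_classifier` or an M x K weight matrix.
#' @param sigma_x M x M data covariance (see [feature_covariance()]).
#' @return A list of class `activation_pattern`: `A` (M x K), `A_std`,
#'   `sigma_x`, `sigma_s`, `shrinkage_used`.
#' @export
haufe_transform <- function(model, sigma_x) {
  W <- if (inherits(model, "linear_classifier")) model$weights else as.matrix(model)
  sigma_x <- as.matrix(sigma_x)
  if (nrow(W) != nrow(sigma_x) || nrow(sigma_x) != ncol(sigma_x))
    stop("dimensions of W and sigma_x do not agree", call. = FALSE)
  if (!all(is.finite(W))) stop("weights must be finite", call. = FALSE)
  sigma_s <- t(W) %*% sigma_x %*% W
  kap <- tryCatch(suppressWarnings(kappa(sigma_s, exact = TRUE)),
                  error = function(e) NA_real_)
  if (!all(is.finite(sigma_s)) || !is.finite(kap) || kap > 1e12 ||
      any(diag(sigma_s) <= 0))
    stop("latent covariance Sigma_s is singular; increase covariance shrinkage",
         call. = FALSE)
  A <- sigma_x %*% W %*% solve(sigma_s)
  eg <- eigen(sigma_s, symmetric = TRUE)
  inv_sqrt <- eg$vectors %*% diag(1 / sqrt(eg$values), ncol(sigma_s)) %*% t(eg$vectors)
  A_std <- sigma_x %*% W %*% inv_sqrt
  rownames(A) <- rownames(A_std) <- rownames(W)
  structure(list(A = A, A_std = A_std, sigma_x = sigma_x, sigma_s = sigma_s,
                 shrinkage_used = attr(sigma_x, "shrinkage_used") %||% NA_real_),
            class = "activation_pattern")
}

#' @export
print.activation_pattern <- function(x, ...) {
  cat(sprintf("<activation_pattern> %d regions x %d component(s), shrinkage %.3f\n",
              nrow(x$A), ncol(x$A), x$shrinkage_used))
  invisible(x)
}

#' Cumulative activation contribution curve
#'
#' Orders regions by descending `|A|` (ties broken alphabetically by region
#' name) and accumulates `|A|` as a fraction of its total, giving the curve
#' of cumulative activation contribution: how many regions are needed to
#' account for a given share of the discriminative pattern.
#'
#' @param pattern an `activation_pattern` with K = 1 (or a named numeric
#'   vector of pattern values).
#' @param fractions contribution levels for which to report the number of
#'   regions required (default 0.5 and 0.8).
#' @return A data frame of class `contribution_curve` with columns
#'   `region`, `abs_pattern`, `cumulative_fraction`; attribute
#'   `threshold_sets` maps each fraction to the region count reaching it.
#' @export
contribution_curve <- function(pattern, fractions = c(0.5, 0.8)) {
  a <- pattern_vector(pattern)
  if (all(a == 0)) stop("all-zero activation pattern", call. = FALSE)
  nm <- names(a) %||% paste0("R", seq_along(a))
  aa <- abs(a)
  ord <- order(-aa, nm)
  cf <- cumsum(aa[ord]) / sum(aa)
  ts <- vapply(fractions, function(f) which(cf >= f - 1e-12)[1L], integer(1))
  names(ts) <- paste0("frac_", fractions)
  structure(data.frame(region = nm[ord], abs_pattern = aa[ord],
                       cumulative_fraction = cf, row.names = NULL),
            threshold_sets = ts,
            class = c("contribution_curve", "data.frame"))
}

pattern_vector <- function(pattern) {
  if (inherits(pattern, "activation_pattern")) {
    if (ncol(pattern$A) != 1L)
      stop("contribution curve is defined for K = 1 patterns", call. = FALSE)
    a <- drop(pattern$A)
    names(a) <- rownames(pattern$A)
    a
  } else {
    a <- drop(as.matrix(pattern))
    if (!is.null(dim(a))) stop("need a single pattern component", call. = FALSE)
    a
  }
}

#' Top regions by absolute activation pattern
#'
#' @param pattern an `activation_pattern` (K = 1) or named numeric vector.
#' @param top_k how many regions to return.
#' @return Character vector of region names, strongest first (alphabetical
#'   tie-break).
#' @export
rank_regions <- function(pattern, top_k = 10L) {
  a <- pattern_vector(pattern)
  top_k <- check_count(top_k, "top_k")
  if (top_k > length(a)) stop_field("top_k", "exceeds the number of regions")
  nm <- names(a) %||% paste0("R", seq_along(a))
  nm[order(-abs(a), nm)][seq_len(top_k)]
}

#' Cross-validated discrimination accuracy
#'
#' Leave-one-out or stratified k-fold cross-validation of the linear
#' classifier on a standardized region matrix. Reported as a descriptive
#' estimate of group separability; at cohort sizes of a few animals per
#' group it has large variance.
#'
#' @param z standardized matrix with `group` attribute (or pass `group`).
#' @param group two-level factor.
#' @param scheme `"loo"` or `"stratified-k"`.
#' @param k folds for the stratified scheme.
#' @param cost SVM cost.
#' @param seed integer seed controlling fold assignment.
#' @return A list of class `cv_result`: `accuracy`, `folds` (data frame of
#'   per-fold held-out results), `scheme`.
#' @export
cross_validate <- function(z, group = attr(z, "group"),
                           scheme = c("loo", "stratified-k"), k = 3L,
                           cost = 1, seed = NULL) {
  scheme <- match.arg(scheme)
  z <- as.matrix(unclass(z))
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("need exactly two classes", call. = FALSE)
  n <- nrow(z)
  tab <- table(group)
  if (scheme == "loo") {
    if (any(tab < 2L))
      stop("leave-one-out needs >= 2 animals per group", call. = FALSE)
    fold_id <- seq_len(n)
  } else {
    k <- check_count(k, "k", min = 2L)
    if (any(tab < k))
      stop(sprintf("stratified %d-fold is infeasible: smallest group has %d animal(s)",
                   k, min(tab)), call. = FALSE)
    fold_id <- integer(n)
    with_seed(seed, for (g in levels(group)) {
      idx <- which(group == g)
      fold_id[idx] <- sample(rep_len(seq_len(k), length(idx)))
    })
  }
  res <- lapply(sort(unique(fold_id)), function(f) {
    test <- fold_id == f
    fit <- fit_linear_classifier(z[!test, , drop = FALSE], group[!test],
                                 cost = cost)
    dec <- drop(z[test, , drop = FALSE] %*% fit$weights) + fit$bias
    pred <- factor(fit$levels[(dec > 0) + 1L], levels = levels(group))
    data.frame(fold = f, n_test = sum(test),
               correct = sum(pred == group[test]))
  })
  folds <- do.call(rbind, res)
  structure(list(accuracy = sum(folds$correct) / sum(folds$n_test),
                 folds = folds, scheme = scheme),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: held-out accuracy %.3f over %d folds\n",
              x$scheme, x$accuracy, nrow(x$folds)))
  invisible(x)
}
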