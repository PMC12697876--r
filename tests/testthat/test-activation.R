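make_rc <- function(X, g = NULL, names = NULL) {
  g <- g %||% factor(rep(c("CON", "MA"), each = nrow(X) / 2),
                     levels = c("CON", "MA"))
  region_counts(X, g, names %||% sprintf("R%02d", seq_len(ncol(X))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("z-scoring standardizes columns with sample SD and flags degeneracy", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 4, 6, 8))
  z <- zscore_regions(X)
  expect_equal(unname(z[1:3, "a"]), (c(1, 2, 3) - 2.5) / sd(1:4))
  # hand case: column (1,2,3) -> (-1, 0, 1)
  z3 <- zscore_regions(cbind(x = c(1, 2, 3), y = c(0, 1, 0)))
  expect_equal(unname(z3[, "x"]), c(-1, 0, 1))
  expect_equal(unname(z[, "b"]), rep(0, 4))
  expect_identical(attr(z, "degenerate_regions"), "b")
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_error(zscore_regions(matrix(1, 1, 3)), "2 animals")
})

test_that("feature covariance matches the direct sum at s = 0 and shrinks correctly", {
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  S <- feature_covariance(X, shrinkage = 0)
  xbar <- colMeans(X)
  brute <- Reduce(`+`, lapply(1:4, function(i) tcrossprod(X[i, ] - xbar))) / 3
  expect_equal(unclass(S), brute, ignore_attr = TRUE, tolerance = 1e-12)

  # two perfectly correlated columns: correlation 1 off-diagonal at s = 0
  Y <- cbind(1:5, 2 * (1:5))
  S2 <- feature_covariance(scale(Y), shrinkage = 0)
  expect_equal(S2[1, 2], 1)

  S3 <- feature_covariance(X, shrinkage = 1)
  expect_equal(unclass(S3), diag(diag(cov(X))), ignore_attr = TRUE)
  expect_equal(attr(S3, "shrinkage_used"), 1)

  Sa <- feature_covariance(X, shrinkage = "auto")
  s <- attr(Sa, "shrinkage_used")
  expect_true(s >= 0 && s <= 1)
  expect_true(all(eigen(Sa, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  expect_error(feature_covariance(X, shrinkage = 2), "shrinkage")
})

test_that("linear classifier separates, respects the sign convention, and validates", {
  X <- cbind(c(-1, -1.2, -0.8, 1, 1.1, 0.9))
  g <- factor(rep(c("CON", "MA"), each = 3), levels = c("CON", "MA"))
  fit <- fit_linear_classifier(X, g)
  expect_equal(fit$training_accuracy, 1)
  expect_gt(fit$weights[1, 1], 0)  # positive weight points toward MA

  rc <- simulate_region_counts(n_per_group = 3, seed = 1)
  clf <- fit_linear_classifier(zscore_regions(rc))
  expect_equal(dim(clf$weights), c(129L, 1L))

  expect_error(fit_linear_classifier(X, factor(rep("a", 6))), "two classes")
})

test_that("the forward-model transform obeys its algebraic laws", {
  # identity covariance, w = (3, 4): Sigma_s = 25, A = (0.12, 0.16)
  W <- matrix(c(3, 4), 2, 1)
  pat <- haufe_transform(W, diag(2))
  expect_equal(drop(pat$sigma_s), 25)
  expect_equal(drop(pat$A), c(0.12, 0.16))
  cs <- sum(pat$A * W) / sqrt(sum(pat$A^2) * sum(W^2))
  expect_equal(cs, 1, tolerance = 1e-12)

  # random instances match the loop-and-adjugate oracle
  set.seed(2)
  for (i in 1:20) {
    M <- sample(2:10, 1); K <- sample(seq_len(min(3, M)), 1)
    W <- matrix(rnorm(M * K), M, K)
    S <- rand_spd(M)
    expect_equal(haufe_transform(W, S)$A, haufe_oracle(W, S),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # scale equivariance: rescaling W leaves the unit-latent pattern unchanged
  # (the plain pattern scales as 1/c because Sigma_s absorbs c^2)
  W <- matrix(rnorm(6), 6, 1); S <- rand_spd(6)
  base <- haufe_transform(W, S)
  up <- haufe_transform(3.7 * W, S)
  expect_equal(up$A_std, base$A_std, tolerance = 1e-10)
  expect_equal(up$A, base$A / 3.7, tolerance = 1e-10)
  neg <- haufe_transform(-2 * W, S)
  expect_equal(abs(neg$A_std), abs(base$A_std), tolerance = 1e-10)
  # rankings are scale-independent either way
  expect_equal(rank_regions(setNames(drop(up$A), paste0("r", 1:6)), 6),
               rank_regions(setNames(drop(base$A), paste0("r", 1:6)), 6))

  expect_error(haufe_transform(matrix(0, 3, 1), rand_spd(3)), "shrinkage")
  expect_error(haufe_transform(matrix(1, 4, 1), rand_spd(3)), "dimensions")
})

test_that("contribution curve orders, normalizes and breaks ties deterministically", {
  cc <- contribution_curve(c(r1 = 0, r2 = 0, r3 = 5))
  expect_equal(cc$region[1], "r3")
  expect_equal(cc$cumulative_fraction, c(1, 1, 1))

  cc2 <- contribution_curve(c(a = 3, b = -2, c = 1))
  expect_equal(cc2$region, c("a", "b", "c"))
  expect_equal(cc2$cumulative_fraction, c(0.5, 5 / 6, 1))

  # ties break alphabetically
  cc3 <- contribution_curve(c(zz = 1, aa = -1, mm = 1))
  expect_equal(cc3$region, c("aa", "mm", "zz"))

  # property: monotone, ends at 1, invariant to input permutation
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(8); names(a) <- paste0("R", sample(100, 8))
    cc <- contribution_curve(a)
    expect_true(all(diff(cc$cumulative_fraction) >= -1e-12))
    expect_equal(cc$cumulative_fraction[8], 1, tolerance = 1e-9)
    perm <- sample(8)
    expect_equal(contribution_curve(a[perm])$region, cc$region)
  }
  expect_error(contribution_curve(c(a = 0, b = 0)), "all-zero")
})

test_that("region ranking matches a sort oracle and validates top_k", {
  a <- c(R1 = 0.2, R2 = -3, R3 = 1.5, R4 = 0.7)
  expect_equal(rank_regions(a, 4), names(a)[order(-abs(a))])
  expect_setequal(rank_regions(a, 4), names(a))
  expect_error(rank_regions(a, 5), "top_k")
})

test_that("cross-validation scores held-out animals and detects infeasible designs", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40, -3), 8), matrix(rnorm(40, 3), 8))
  g <- factor(rep(c("CON", "MA"), each = 8), levels = c("CON", "MA"))
  cv <- cross_validate(X, g, scheme = "loo")
  expect_equal(cv$accuracy, 1)
  expect_equal(sum(cv$folds$n_test), 16)

  cvk <- cross_validate(X, g, scheme = "stratified-k", k = 4, seed = 1)
  expect_equal(cvk$accuracy, 1)
  g1 <- factor(c(rep("CON", 15), "MA"))
  expect_error(cross_validate(X, g1, scheme = "stratified-k", k = 3),
               "infeasible")
  expect_error(cross_validate(X, g1, scheme = "loo"), ">= 2 animals")

  # null data: held-out accuracy stays at or below chance (LOO at small n
  # is pessimistically biased, never optimistic)
  set.seed(5)
  accs <- replicate(100, {
    Xn <- matrix(rnorm(12 * 5), 12)
    gn <- factor(rep(c("a", "b"), each = 6))
    cross_validate(Xn, gn, scheme = "loo")$accuracy
  })
  expect_lt(mean(accs), 0.5 + 2 * sd(accs) / 10)
  expect_gt(mean(accs), 0.25)
})

test_that("activation_map fit object wires the stages together", {
  rc <- simulate_region_counts(n_per_group = 10,
                               region_names = sprintf("R%02d", 1:12),
                               effect_regions = 1:3, effect_log_fold = 0.7,
                               seed = 1)
  fit <- activation_map(rc, seed = 1)
  expect_s3_class(fit, "activation_map")
  expect_equal(dim(coef(fit)), c(12L, 2L))
  expect_output(print(fit), "activation map")
  expect_equal(unname(predict(fit, unclass(rc)[1:2, ])),
               factor(c("CON", "CON"), levels = c("CON", "MA")))
  expect_equal(length(predict(fit, unclass(rc), type = "decision")), 20L)
  # data-frame method with group column
  df <- data.frame(unclass(rc), group = attr(rc, "group"), check.names = FALSE)
  fit2 <- activation_map(df, cv = "none")
  expect_equal(coef(fit2)[, "pattern"], coef(activation_map(rc, cv = "none"))[, "pattern"])
  s <- summary(fit, top_k = 3)
  expect_equal(nrow(s$top), 3L)
})
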