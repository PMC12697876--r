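#' Action proportions of an ethogram
#'
#' Fraction of the session spent in (time weighting, the default) or
#' fraction of bouts belonging to (bout weighting) each action of the
#' alphabet. Labels with no bouts get proportion 0; the vector always sums
#' to 1.
#'
#' @param e an [ethogram()].
#' @param weighting `"time"` or `"bout"`.
#' @return Named numeric vector over the full label set.
#' @export
action_proportions <- function(e, weighting = c("time", "bout")) {
  weighting <- match.arg(weighting)
  if (!inherits(e, "ethogram")) stop("`e` must be an ethogram", call. = FALSE)
  if (nrow(e) == 0L) stop("empty ethogram", call. = FALSE)
  labs <- attr(e, "label_set")
  w <- if (weighting == "time") e$end_s - e$start_s else rep(1, nrow(e))
  tot <- vapply(labs, function(l) sum(w[e$label == l]), numeric(1))
  tot / sum(tot)
}

#' Bout-to-bout transition matrix
#'
#' Counts transitions between consecutive bouts — including self-
#' transitions, i.e. consecutive bouts with the same label — over the full
#' action alphabet, adds `pseudocount` to every cell, and row-normalizes.
#' Rows with no observed outgoing transition (and pseudocount 0) are
#' emitted as all-zero and listed in the `unobserved_rows` attribute
#' rather than being filled uniformly.
#'
#' @param e an [ethogram()] with at least 2 bouts.
#' @param pseudocount nonnegative value added to every cell before
#'   normalization (0 = unbiased estimate; 0.5 regularizes sparse chains).
#' @return A list of class `transition_matrix`: `probabilities`, `counts`,
#'   `pseudocount`; attribute `unobserved_rows`.
#' @export
transition_matrix <- function(e, pseudocount = 0) {
  if (!inherits(e, "ethogram")) stop("`e` must be an ethogram", call. = FALSE)
  if (nrow(e) < 2L) stop("need >= 2 bouts to count transitions", call. = FALSE)
  check_scalar_num(pseudocount, "pseudocount", nonneg = TRUE)
  labs <- attr(e, "label_set")
  K <- length(labs)
  f <- factor(e$label, levels = labs)
  counts <- table(from = f[-nrow(e)], to = f[-1L])
  counts <- matrix(as.integer(counts), K, K, dimnames = list(labs, labs))
  aug <- counts + pseudocount
  rs <- rowSums(aug)
  P <- aug / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  structure(list(probabilities = P, counts = counts, pseudocount = pseudocount),
            unobserved_rows = labs[rowSums(counts) == 0 & pseudocount == 0],
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d x %d, pseudocount %g, %d transitions\n",
              nrow(x$probabilities), ncol(x$probabilities), x$pseudocount,
              sum(x$counts)))
  invisible(x)
}

#' Long-format transition flow table for chord/heatmap displays
#'
#' Emits one row per (from, to) cell with its transition probability and
#' the source action's proportion (the arc length in a chord diagram),
#' plus each label's self-transition share.
#'
#' @param tm a [transition_matrix()].
#' @param props proportion vector (e.g. from [action_proportions()]),
#'   aligned with the matrix labels.
#' @param floor drop cells with probability strictly below this display
#'   floor (0 keeps all K^2 rows).
#' @return A list: `flows` (data frame `from, to, probability,
#'   from_proportion`) and `self_transition_share` (named vector,
#'   `diag(P)`).
#' @export
summarize_transitions <- function(tm, props, floor = 0) {
  P <- tm$probabilities
  labs <- rownames(P)
  if (!setequal(names(props), labs))
    stop("`props` labels do not match the transition matrix", call. = FALSE)
  props <- props[labs]
  flows <- data.frame(from = rep(labs, times = ncol(P)),
                      to = rep(labs, each = nrow(P)),
                      probability = as.vector(P),
                      from_proportion = rep(unname(props), times = ncol(P)))
  flows <- flows[flows$probability >= floor, , drop = FALSE]
  rownames(flows) <- NULL
  list(flows = flows, self_transition_share = stats::setNames(diag(P), labs))
}

#' Hierarchical clustering of per-animal action proportions
#'
#' Agglomerative clustering (Euclidean distance) of animals by their
#' action-proportion vectors, cut at `k` clusters (default 2, the
#' control-vs-model cut).
#'
#' @param table numeric matrix, animals x actions (rows should sum to 1).
#' @param k number of clusters.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return A list: `assignments` (named integer vector), `order`
#'   (dendrogram leaf order), `hclust`.
#' @export
cluster_proportions <- function(table, k = 2L, linkage = "ward.D2") {
  table <- as.matrix(table)
  k <- check_count(k, "k")
  if (k > nrow(table)) stop_field("k", "exceeds the number of animals")
  hc <- stats::hclust(stats::dist(table), method = linkage)
  list(assignments = stats::cutree(hc, k = k), order = hc$order, hclust = hc)
}

#' t-SNE embedding with a linear decision boundary
#'
#' Embeds per-animal behavioral feature vectors (action proportions or
#' flattened transition probabilities) into 2-D with exact t-SNE, then
#' fits a linear SVM in the embedding and reports its training accuracy.
#' The embedding and the accuracy are *descriptive* — the classifier is
#' fitted on the same points it is evaluated on and the embedding is
#' nonlinear — so they visualize, but do not test, group separation.
#'
#' @param features numeric matrix, animals x features.
#' @param labels two-level factor of group labels.
#' @param perplexity t-SNE perplexity; default `min(5, floor((N - 1) / 3))`
#'   suits the small cohorts involved. Must satisfy
#'   `3 * perplexity < N - 1`.
#' @param seed integer seed; fixed seed gives identical coordinates.
#' @param ... passed to the internal t-SNE (e.g. `max_iter`).
#' @return A list of class `behavior_embedding`: `embedding` (N x 2),
#'   `labels`, `boundary` (weights/bias in embedding space), `accuracy`,
#'   `perplexity`.
#' @export
embed_and_classify <- function(features, labels, perplexity = NULL,
                               seed = NULL, ...) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples to embed", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != n) stop("`labels` length must match rows", call. = FALSE)
  perplexity <- perplexity %||% min(5, floor((n - 1) / 3))
  if (perplexity < 1 || 3 * perplexity > n - 1)
    stop_field("perplexity", sprintf("infeasible for N = %d", n))
  Y <- with_seed(seed, tsne_exact(X, perplexity = perplexity, ...))
  colnames(Y) <- c("tsne1", "tsne2")
  clf <- fit_linear_classifier(Y, labels)
  structure(list(embedding = Y, labels = labels,
                 boundary = list(weights = clf$weights, bias = clf$bias),
                 accuracy = clf$training_accuracy, perplexity = perplexity),
            class = "behavior_embedding")
}

#' @export
print.behavior_embedding <- function(x, ...) {
  cat(sprintf("<behavior_embedding> %d samples, perplexity %g, boundary accuracy %.2f (descriptive)\n",
              nrow(x$embedding), x$perplexity, x$accuracy))
  invisible(x)
}

#' @export
plot.behavior_embedding <- function(x, ...) {
  cols <- c("firebrick", "steelblue")[as.integer(x$labels)]
  graphics::plot(x$embedding, col = cols, pch = 19,
                 main = "t-SNE of behavioral features", ...)
  w <- drop(x$boundary$weights); b <- x$boundary$bias
  if (abs(w[2L]) > 1e-12)
    graphics::abline(a = -b / w[2L], b = -w[1L] / w[2L], lty = 2)
  graphics::legend("topright", legend = levels(x$labels), col = c("firebrick",
                   "steelblue"), pch = 19, bty = "n")
  invisible(x)
}

#' Differential testing of action proportions between groups
#'
#' Runs the shared two-group test selector ([auto_two_group_test()]) on
#' every action of a per-animal proportion table and adjusts the raw
#' p-values across the action family by Benjamini-Hochberg.
#'
#' @param table numeric matrix, animals x actions.
#' @param group two-level factor per animal.
#' @param fdr_q FDR level used for the `significant` decision column.
#' @return Data frame with one row per action: `action`, `test`,
#'   `statistic`, `p_raw`, `p_adjusted`, `direction`, `significant`.
#' @export
differential_actions <- function(table, group, fdr_q = 0.05) {
  table <- as.matrix(table)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("need exactly two groups", call. = FALSE)
  if (any(table(group) < 2L)) stop("need >= 2 animals per group", call. = FALSE)
  acts <- colnames(table) %||% paste0("action", seq_len(ncol(table)))
  res <- lapply(seq_len(ncol(table)), function(j) {
    r <- auto_two_group_test(table[group == levels(group)[1L], j],
                             table[group == levels(group)[2L], j])
    data.frame(action = acts[j], test = r$test_name, statistic = r$statistic,
               p_raw = r$p_raw, direction = r$effect_direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out$significant <- out$p_adjusted <= fdr_q
  out[c("action", "test", "statistic", "p_raw", "p_adjusted",
        "direction", "significant")]
}

#' Speed map and locomotion summary of a trajectory
#'
#' Instantaneous speed is the finite-difference displacement divided by
#' the sample interval; each path segment is binned by the grid cell of
#' its starting point. Cells never visited are `NA`.
#'
#' @param traj a [trajectory()] (square arena).
#' @param grid_cm grid cell size in cm.
#' @return A list: `grid` (matrix of mean speeds, cm/s, `NA` = unvisited),
#'   `mean_speed`, `total_distance_cm`.
#' @export
speed_map <- function(traj, grid_cm = 5) {
  if (!inherits(traj, "trajectory")) stop("`traj` must be a trajectory", call. = FALSE)
  if (nrow(traj) < 2L) stop("need >= 2 samples", call. = FALSE)
  check_scalar_num(grid_cm, "grid_cm", positive = TRUE)
  arena <- attr(traj, "arena")
  if (arena$type != "square")
    stop("speed maps are defined for square arenas", call. = FALSE)
  dx <- diff(traj$x_cm); dy <- diff(traj$y_cm); dt <- diff(traj$t_s)
  disp <- sqrt(dx^2 + dy^2)
  speed <- disp / dt
  ncell <- max(1L, ceiling(arena$side / grid_cm))
  ix <- pmin(ncell, pmax(1L, ceiling(traj$x_cm[-nrow(traj)] / grid_cm + 1e-12)))
  iy <- pmin(ncell, pmax(1L, ceiling(traj$y_cm[-nrow(traj)] / grid_cm + 1e-12)))
  grid <- matrix(NA_real_, ncell, ncell)
  agg <- tapply(speed, list(ix, iy), mean)
  grid[cbind(as.integer(rep(rownames(agg), ncol(agg))),
             as.integer(rep(colnames(agg), each = nrow(agg))))] <- as.vector(agg)
  list(grid = grid, mean_speed = mean(speed),
       total_distance_cm = sum(disp))
}
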