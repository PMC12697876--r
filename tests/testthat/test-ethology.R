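mk_etho <- function(labels, durs, label_set = NULL) {
  ends <- cumsum(durs)
  ethogram(labels, c(0, ends[-length(ends)]), ends, label_set = label_set)
}

test_that("action proportions are correct under both weightings", {
  e <- mk_etho(c("walk", "groom"), c(360, 240))
  expect_equal(action_proportions(e, "time"),
               c(groom = 0.4, walk = 0.6))
  e1 <- mk_etho("rear", 5, label_set = c("rear", "walk"))
  expect_equal(action_proportions(e1), c(rear = 1, walk = 0))
  e2 <- mk_etho(c("a", "a", "b"), c(1, 1, 10))
  expect_equal(action_proportions(e2, "bout"), c(a = 2 / 3, b = 1 / 3))
  set.seed(1)
  for (i in 1:5) {
    e <- simulate_ethogram(sticky_transition_matrix(6, 0.4),
                           labels = letters[1:6], total_duration = 60)
    expect_equal(sum(action_proportions(e, "time")), 1)
    expect_equal(sum(action_proportions(e, "bout")), 1)
  }
})

test_that("transition matrices count bout-to-bout moves including self-transitions", {
  e <- mk_etho(c("A", "A", "A"), c(1, 1, 1))
  tm <- transition_matrix(e)
  expect_equal(tm$probabilities["A", "A"], 1)
  expect_equal(sum(tm$counts), 2L)

  e2 <- mk_etho(c("A", "B", "A", "B"), rep(1, 4))
  tm2 <- transition_matrix(e2)
  expect_equal(tm2$probabilities["A", "B"], 1)
  expect_equal(tm2$probabilities["B", "A"], 1)

  e10 <- simulate_ethogram(sticky_transition_matrix(10, 0.3),
                           total_duration = 120, seed = 2)
  expect_equal(dim(transition_matrix(e10)$probabilities), c(10L, 10L))

  # unobserved rows: zero and flagged at pseudocount 0, filled at 0.5
  e3 <- mk_etho(c("A", "B"), c(1, 1), label_set = c("A", "B", "C"))
  tm3 <- transition_matrix(e3)
  expect_equal(unname(tm3$probabilities["C", ]), rep(0, 3))
  expect_true("C" %in% attr(tm3, "unobserved_rows"))
  tm4 <- transition_matrix(e3, pseudocount = 0.5)
  expect_true(is_rowstoch <- all(abs(rowSums(tm4$probabilities) - 1) < 1e-9))
  expect_error(transition_matrix(mk_etho("A", 1)), "2 bouts")
})

test_that("flow summaries expose chord-diagram quantities", {
  e <- mk_etho(c("A", "A", "B", "B"), rep(1, 4), label_set = c("A", "B"))
  tm <- transition_matrix(e)
  props <- action_proportions(e)
  fl <- summarize_transitions(tm, props)
  expect_equal(nrow(fl$flows), 4L)  # K^2 at floor 0
  expect_equal(fl$self_transition_share,
               c(A = tm$probabilities["A", "A"], B = tm$probabilities["B", "B"]))

  # identity matrix: self-share 1 everywhere
  ident <- mk_etho(c("A", "A", "B", "B"), rep(1, 4))
  tmi <- transition_matrix(ident)
  expect_equal(unname(fl$self_transition_share["A"]),
               tmi$probabilities["A", "A"])

  # uniform chain: all cells 1/K
  K <- 3
  labs <- c("A", "B", "C")
  tmu <- list(probabilities = matrix(1 / K, K, K, dimnames = list(labs, labs)),
              counts = matrix(1L, K, K), pseudocount = 0)
  class(tmu) <- "transition_matrix"
  flu <- summarize_transitions(tmu, setNames(rep(1 / 3, 3), labs))
  expect_true(all(abs(flu$flows$probability - 1 / K) < 1e-12))
  expect_equal(nrow(flu$flows), K^2)
  fl_floor <- summarize_transitions(tmu, setNames(rep(1 / 3, 3), labs),
                                    floor = 0.5)
  expect_equal(nrow(fl_floor$flows), 0L)
})

test_that("hierarchical clustering recovers planted repertoires", {
  set.seed(10)
  g1 <- rand_props(6, 5, alpha = c(10, 1, 1, 1, 1))
  g2 <- rand_props(6, 5, alpha = c(1, 1, 1, 1, 10))
  tab <- rbind(g1, g2)
  cl <- cluster_proportions(tab, k = 2)
  expect_equal(length(unique(cl$assignments[1:6])), 1L)
  expect_equal(length(unique(cl$assignments[7:12])), 1L)
  expect_true(cl$assignments[1] != cl$assignments[7])

  dup <- rbind(tab, tab[1, , drop = FALSE])
  cld <- cluster_proportions(dup, k = 2)
  expect_equal(unname(cld$assignments[13]), unname(cld$assignments[1]))
  expect_error(cluster_proportions(tab, k = 20), "k")
})

test_that("t-SNE embedding is seed-reproducible and separates planted groups", {
  set.seed(11)
  feats <- rbind(rand_props(8, 6, c(8, 1, 1, 1, 1, 1)),
                 rand_props(8, 6, c(1, 1, 1, 1, 1, 8)))
  labs <- factor(rep(c("CON", "MA"), each = 8))
  e1 <- embed_and_classify(feats, labs, seed = 42)
  e2 <- embed_and_classify(feats, labs, seed = 42)
  expect_identical(e1$embedding, e2$embedding)
  expect_gt(e1$accuracy, 0.9)
  expect_error(embed_and_classify(feats, labs, perplexity = 10), "perplexity")
  expect_error(embed_and_classify(feats[1:3, ], labs[1:3]), "4 samples")
})

test_that("embedding boundary accuracy is calibrated on null and planted data", {
  set.seed(12)
  null_acc <- replicate(25, {
    f <- rand_props(12, 6)
    g <- factor(rep(c("a", "b"), each = 6))
    embed_and_classify(f, g, max_iter = 250)$accuracy
  })
  # same distribution in both groups: no better than mildly overfit chance
  expect_lt(mean(null_acc), 0.85)
  planted_acc <- replicate(25, {
    f <- rbind(rand_props(10, 6, c(30, 1, 1, 1, 1, 1)),
               rand_props(10, 6, c(1, 1, 1, 1, 1, 30)))
    g <- factor(rep(c("a", "b"), each = 10))
    embed_and_classify(f, g, max_iter = 400)$accuracy
  })
  expect_gt(mean(planted_acc), 0.9)
  expect_gt(mean(planted_acc) - mean(null_acc), 0.1)
})

test_that("differential action testing adjusts exactly one family and finds shifts", {
  set.seed(13)
  tab <- rbind(rand_props(20, 10), rand_props(20, 10))
  colnames(tab) <- action_labels()
  # plant a shift in one action
  tab[21:40, 1] <- tab[21:40, 1] + 0.25
  tab <- tab / rowSums(tab)
  g <- factor(rep(c("CON", "MA"), each = 20))
  res <- differential_actions(tab, g)
  expect_equal(nrow(res), 10L)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_true(res$significant[res$action == "running"])
  expect_equal(res$direction[1], "b>a")
  expect_error(differential_actions(tab[c(1, 21), ], g[c(1, 21)]), "2 animals")
})

test_that("speed maps obey closed-form kinematics", {
  # constant-velocity straight path at 10 cm/s
  tr <- trajectory(seq(0, 4, by = 0.1), seq(1, 41, length.out = 41),
                   rep(25, 41), square_arena(50))
  sm <- speed_map(tr, grid_cm = 5)
  occupied <- sm$grid[!is.na(sm$grid)]
  expect_true(all(abs(occupied - 10) < 1e-9))
  expect_equal(sm$total_distance_cm, 40)
  # total distance invariant to the grid
  expect_equal(speed_map(tr, grid_cm = 2)$total_distance_cm, 40)
  # stationary path
  still <- trajectory(0:10, rep(5, 11), rep(5, 11), square_arena(50))
  sm0 <- speed_map(still)
  expect_equal(sm0$total_distance_cm, 0)
  expect_equal(sm0$grid[2, 2], 0)
  expect_error(speed_map(trajectory(0, 1, 1, square_arena(50))), "2 samples")
})
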