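test_that("all generators are bit-reproducible under a fixed seed", {
  p1 <- simulate_region_counts(n_per_group = 4, region_names = paste0("R", 1:6),
                               effect_regions = 1:2, effect_log_fold = 0.3, seed = 7)
  p2 <- simulate_region_counts(n_per_group = 4, region_names = paste0("R", 1:6),
                               effect_regions = 1:2, effect_log_fold = 0.3, seed = 7)
  expect_identical(unclass(p1), unclass(p2))

  P <- sticky_transition_matrix(4, 0.4)
  e1 <- simulate_ethogram(P, labels = letters[1:4], total_duration = 120, seed = 3)
  e2 <- simulate_ethogram(P, labels = letters[1:4], total_duration = 120, seed = 3)
  expect_identical(as.data.frame(e1), as.data.frame(e2))

  t1 <- simulate_trajectory(duration = 30, seed = 5)
  t2 <- simulate_trajectory(duration = 30, seed = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  r1 <- simulate_photometry(duration = 10, event_times_s = 5, seed = 9)
  r2 <- simulate_photometry(duration = 10, event_times_s = 5, seed = 9)
  expect_identical(r1$f470, r2$f470)

  v1 <- simulate_vonfrey(seed = 11)
  v2 <- simulate_vonfrey(seed = 11)
  expect_identical(v1$positives, v2$positives)
})

test_that("region-count generator matches the brain-wide design and its ground truth", {
  rc <- simulate_region_counts(n_per_group = 3, seed = 1)
  expect_equal(dim(rc), c(6L, 129L))
  expect_equal(levels(attr(rc, "group")), c("CON", "MA"))
  expect_true(all(rc >= 0) && all(rc == round(rc)))
  gt <- attr(rc, "ground_truth")
  expect_equal(gt$mu_ma, gt$mu_con)  # no effect regions requested

  rc2 <- simulate_region_counts(n_per_group = 5, region_names = paste0("R", 1:4),
                                effect_regions = 2L, effect_log_fold = 1, seed = 2)
  gt2 <- attr(rc2, "ground_truth")
  expect_equal(gt2$mu_ma[2] / gt2$mu_con[2], exp(1))
  expect_error(simulate_region_counts(n_per_group = 0), "n_per_group")
  expect_error(simulate_region_counts(dispersion = -1), "dispersion")
  expect_error(simulate_region_counts(effect_regions = 200), "effect_regions")
})

test_that("null-effect count tables are calibrated: nominal-0.05 t-test rejects ~5%", {
  set.seed(101)
  nsim <- 1000
  rej <- replicate(nsim, {
    rc <- simulate_region_counts(n_per_group = 6, region_names = paste0("R", 1:3),
                                 effect_log_fold = 0)
    g <- attr(rc, "group")
    t.test(rc[g == "CON", 1], rc[g == "MA", 1])$p.value < 0.05
  })
  # binomial MC error at p = 0.05, n = 1000: sd ~ 0.0069
  expect_gt(mean(rej), 0.05 - 3.5 * 0.0069)
  expect_lt(mean(rej), 0.05 + 3.5 * 0.0069)
})

test_that("ethogram generator follows its Markov chain", {
  # identity chain is absorbing
  e <- simulate_ethogram(diag(3), labels = c("sniffing", "a", "b"),
                         start_label = "sniffing", total_duration = 60, seed = 4)
  expect_true(all(e$label == "sniffing"))
  # default alphabet is the 10-action repertoire
  e10 <- simulate_ethogram(sticky_transition_matrix(10, 0.3),
                           total_duration = 60, seed = 5)
  expect_identical(attr(e10, "label_set"), action_labels())
  expect_length(action_labels(), 10L)
  # bouts tile the session contiguously and end at total_duration
  expect_equal(e10$start_s[-1], e10$end_s[-nrow(e10)])
  expect_equal(max(e10$end_s), 60)
  expect_error(simulate_ethogram(matrix(1, 2, 2), labels = c("a", "b")),
               "row")
  # empirical transition matrix converges to the generating one
  P <- sticky_transition_matrix(5, 0.5)
  big <- simulate_ethogram(P, labels = letters[1:5], total_duration = 1e6,
                           max_bouts = 2e4, seed = 6)
  tv <- total_variation_rows(transition_matrix(big)$probabilities, P)
  expect_true(all(tv < 0.05))
})

test_that("trajectory generator respects bounds, speed and center avoidance", {
  tr <- simulate_trajectory(arena = square_arena(50), duration = 60,
                            sample_rate = 10, seed = 1)
  expect_true(all(tr$x_cm >= 0 & tr$x_cm <= 50 & tr$y_cm >= 0 & tr$y_cm <= 50))
  still <- simulate_trajectory(speed_scale = 0, duration = 10, seed = 2)
  expect_equal(sum(sqrt(diff(still$x_cm)^2 + diff(still$y_cm)^2)), 0)
  expect_error(simulate_trajectory(duration = -1), "duration")

  set.seed(303)
  center_time <- function(ca) {
    tr <- simulate_trajectory(duration = 60, sample_rate = 5, speed_scale = 8,
                              center_avoidance = ca)
    openfield_metrics(tr)$time_in_zone_s
  }
  t0 <- replicate(200, center_time(0))
  t5 <- replicate(200, center_time(5))
  expect_lt(mean(t5), mean(t0))
})

test_that("photometry generator injects recoverable transients", {
  rec <- simulate_photometry(duration = 60, sample_rate = 50,
                             event_times_s = c(10, 30, 50),
                             transient_amplitude = 0.2, noise_sd = 0.01,
                             seed = 8)
  expect_length(rec$f470, length(rec$f410))
  peri <- peri_event(compute_dff(rec), window_pre_s = 2, window_post_s = 5)
  peaks <- apply(peri, 1, max)
  expect_true(all(abs(peaks - 0.2) / 0.2 < 0.05))

  null <- simulate_photometry(duration = 60, sample_rate = 50,
                              transient_amplitude = 0, noise_sd = 0.2,
                              event_times_s = seq(5, 55, by = 5), seed = 9)
  dff <- compute_dff(null)$dff
  expect_lt(abs(mean(dff)), 3 * sd(dff) / sqrt(length(dff)))
  expect_error(simulate_photometry(duration = 10, event_times_s = 20),
               "event_times_s")
})

test_that("von Frey generator follows its psychometric function", {
  # near-step function: all-or-none counts around the true threshold
  v <- simulate_vonfrey(true_threshold = 2.6, slope = 1e6, seed = 1)
  expect_identical(v$positives, c(0L, 0L, 0L, 10L, 10L, 10L))
  expect_identical(v$filament, vonfrey_ladder())
  expect_error(simulate_vonfrey(filaments = numeric()), "filaments")

  set.seed(99)
  est <- replicate(500, vonfrey_threshold(simulate_vonfrey(
    true_threshold = 2.6, slope = 10))$value)
  expect_equal(median(est), vonfrey_ladder()[vonfrey_ladder() >= 2.6][1])
})
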