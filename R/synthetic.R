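#' Simulate region-wise FOS count tables with a planted group effect
#'
#' Draws per-animal, per-region FOS-positive cell counts for a two-group
#' design (CON vs MA) from a negative binomial distribution parameterized
#' by mean and overdispersion (`variance = mean + dispersion * mean^2`).
#' A subset of regions carries a multiplicative group effect: the MA-group
#' mean is `baseline_mean * exp(effect_log_fold)` in those regions.
#'
#' @param n_per_group animals per group.
#' @param region_names region identifiers (length M >= 2). Defaults to
#'   `R001..R129`, the brain-wide design size.
#' @param baseline_mean expected count per region in the control condition.
#' @param dispersion overdispersion (> 0); the negative binomial `size`
#'   is `1/dispersion`.
#' @param effect_regions indices (into `region_names`) of regions carrying
#'   the group effect.
#' @param effect_log_fold log fold change of the MA mean in effect regions
#'   (0 = null).
#' @param seed integer seed for bit-reproducible output; `NULL` uses the
#'   current RNG stream.
#'
#' @return A [region_counts()] object with attribute `ground_truth`, a list
#'   recording the effect regions, log fold, and per-group region means.
#' @export
simulate_region_counts <- function(n_per_group = 3L,
                                   region_names = sprintf("R%03d", 1:129),
                                   baseline_mean = 100,
                                   dispersion = 0.05,
                                   effect_regions = integer(),
                                   effect_log_fold = 0,
                                   seed = NULL) {
  n_per_group <- check_count(n_per_group, "n_per_group")
  if (length(region_names) < 2L) stop_field("region_names", "needs M >= 2")
  M <- length(region_names)
  check_scalar_num(baseline_mean, "baseline_mean", positive = TRUE)
  check_scalar_num(dispersion, "dispersion", positive = TRUE)
  check_scalar_num(effect_log_fold, "effect_log_fold")
  effect_regions <- as.integer(effect_regions)
  if (length(effect_regions) &&
      (any(effect_regions < 1L) || any(effect_regions > M)))
    stop_field("effect_regions", "indices must lie in 1..M")
  mu_con <- rep(baseline_mean, M)
  mu_ma <- mu_con
  mu_ma[effect_regions] <- mu_ma[effect_regions] * exp(effect_log_fold)
  with_seed(seed, {
    draw <- function(mu) {
      t(vapply(seq_len(n_per_group),
               function(i) stats::rnbinom(M, size = 1 / dispersion, mu = mu),
               numeric(M)))
    }
    counts <- rbind(draw(mu_con), draw(mu_ma))
  })
  group <- factor(rep(c("CON", "MA"), each = n_per_group), levels = c("CON", "MA"))
  out <- region_counts(counts, group, region_names)
  attr(out, "ground_truth") <- list(
    effect_regions = effect_regions,
    effect_log_fold = effect_log_fold,
    mu_con = mu_con, mu_ma = mu_ma, dispersion = dispersion)
  out
}

#' Simulate an ethogram from a bout-level Markov chain
#'
#' Samples a sequence of behavioral bouts from a row-stochastic transition
#' matrix (self-transitions permitted) with exponentially distributed bout
#' durations, truncated at the session end.
#'
#' @param transition_matrix K x K row-stochastic matrix; rows/columns are
#'   taken in the order of `labels` (dimnames, when present, must match).
#' @param labels action alphabet; defaults to [action_labels()].
#' @param mean_bout_duration mean bout length in seconds (scalar or
#'   per-action vector).
#' @param total_duration session length in seconds; the last bout is
#'   clipped to it.
#' @param start_label label of the first bout; default random uniform.
#' @param max_bouts optional hard cap on the number of bouts (overrides
#'   `total_duration` truncation when reached first).
#' @param animal_id,group metadata passed to [ethogram()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#'
#' @return An [ethogram()] with attribute `ground_truth` recording the
#'   generating matrix and mean durations.
#' @export
simulate_ethogram <- function(transition_matrix,
                              labels = action_labels(),
                              mean_bout_duration = 2,
                              total_duration = 600,
                              start_label = NULL,
                              max_bouts = NULL,
                              animal_id = NA_character_,
                              group = NA_character_,
                              seed = NULL) {
  K <- length(labels)
  if (!is.matrix(transition_matrix) || !all(dim(transition_matrix) == K))
    stop_field("transition_matrix", sprintf("must be %d x %d", K, K))
  if (!is_row_stochastic(transition_matrix))
    stop_field("transition_matrix", "rows must be nonnegative and sum to 1")
  check_scalar_num(total_duration, "total_duration", positive = TRUE)
  mean_bout_duration <- rep_len(mean_bout_duration, K)
  if (any(mean_bout_duration <= 0))
    stop_field("mean_bout_duration", "must be > 0")
  if (!is.null(start_label) && !start_label %in% labels)
    stop_field("start_label", "not in `labels`")
  nmax <- max_bouts %||% Inf
  with_seed(seed, {
    state <- if (is.null(start_label)) sample.int(K, 1L) else match(start_label, labels)
    lab <- integer(0); dur <- numeric(0); t <- 0
    # states are sampled sequentially (Markov), durations vectorized per
    # chunk so 1e5-bout sessions stay linear-time
    repeat {
      chunk <- min(nmax - length(lab),
                   max(16, ceiling((total_duration - t) /
                                     min(mean_bout_duration) * 1.2)),
                   65536)
      if (chunk < 1) break
      st <- integer(chunk)
      for (i in seq_len(chunk)) {
        st[i] <- state
        state <- sample.int(K, 1L, prob = transition_matrix[state, ])
      }
      d <- stats::rexp(chunk, rate = 1 / mean_bout_duration[st])
      lab <- c(lab, st); dur <- c(dur, d); t <- t + sum(d)
      if (length(lab) >= nmax || t >= total_duration) break
    }
  })
  cum <- cumsum(dur)
  cut <- which(cum >= total_duration)[1L]
  if (!is.na(cut)) {
    lab <- lab[seq_len(cut)]; dur <- dur[seq_len(cut)]
    dur[cut] <- dur[cut] - (cum[cut] - total_duration)
  }
  ends <- cumsum(dur)
  out <- ethogram(labels[lab], c(0, ends[-length(ends)]), ends,
                  label_set = labels, animal_id = animal_id, group = group)
  attr(out, "ground_truth") <- list(transition_matrix = transition_matrix,
                                    mean_bout_duration = mean_bout_duration)
  out
}

#' Simulate a bounded random-walk trajectory
#'
#' Generates a reflected random walk inside a square open field or a plus
#' maze. A nonnegative `center_avoidance` bias pushes each step away from
#' the arena center, lowering expected center-zone (or open-arm) occupancy;
#' the step length is fixed at `speed_scale / sample_rate`, so
#' `speed_scale = 0` yields a stationary path.
#'
#' @param arena [square_arena()] or [plus_maze_arena()].
#' @param duration session length (s).
#' @param sample_rate Hz.
#' @param speed_scale nominal speed (cm/s).
#' @param center_avoidance unitless bias >= 0.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [trajectory()] with attribute `ground_truth`.
#' @export
simulate_trajectory <- function(arena = square_arena(50),
                                duration = 600,
                                sample_rate = 10,
                                speed_scale = 8,
                                center_avoidance = 0,
                                seed = NULL) {
  check_scalar_num(duration, "duration", positive = TRUE)
  check_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  check_scalar_num(speed_scale, "speed_scale", nonneg = TRUE)
  check_scalar_num(center_avoidance, "center_avoidance", nonneg = TRUE)
  n <- max(2L, floor(duration * sample_rate) + 1L)
  step <- speed_scale / sample_rate
  ctr <- if (arena$type == "square") c(arena$side / 2, arena$side / 2) else c(0, 0)
  pos <- matrix(NA_real_, n, 2L)
  pos[1L, ] <- ctr
  with_seed(seed, {
    theta <- stats::runif(n - 1L, 0, 2 * pi)
    for (i in 2:n) {
      dir <- c(cos(theta[i - 1L]), sin(theta[i - 1L]))
      away <- pos[i - 1L, ] - ctr
      nrm <- sqrt(sum(away^2))
      if (nrm > 1e-12) dir <- dir + center_avoidance * away / nrm
      nrm <- sqrt(sum(dir^2))
      if (nrm > 1e-12) dir <- dir / nrm
      cand <- pos[i - 1L, ] + step * dir
      pos[i, ] <- reflect_into_arena(cand, pos[i - 1L, ], arena)
    }
  })
  t_s <- (seq_len(n) - 1L) / sample_rate
  out <- trajectory(t_s, pos[, 1L], pos[, 2L], arena, sample_rate = sample_rate)
  attr(out, "ground_truth") <- list(speed_scale = speed_scale,
                                    center_avoidance = center_avoidance)
  out
}

# keep a proposed step inside the arena; square walls reflect, plus-maze
# violations fall back to staying in place (simple and always valid)
reflect_into_arena <- function(cand, prev, arena) {
  if (arena$type == "square") {
    s <- arena$side
    for (k in 1:2) {
      if (cand[k] < 0) cand[k] <- -cand[k]
      if (cand[k] > s) cand[k] <- 2 * s - cand[k]
      cand[k] <- min(max(cand[k], 0), s)
    }
    cand
  } else {
    if (epm_zone(cand[1L], cand[2L], arena) != "outside") cand else prev
  }
}

#' Simulate a dual-channel photometry recording
#'
#' The isosbestic (410 nm) channel is baseline plus linear drift plus
#' Gaussian noise; the signal (470 nm) channel shares the baseline and
#' drift and adds exponentially decaying calcium transients of amplitude
#' `transient_amplitude` (in dF/F units, i.e. as a fraction of baseline)
#' at each event time.
#'
#' @param duration recording length (s).
#' @param sample_rate Hz.
#' @param event_times_s transient onset times, all within `[0, duration]`.
#' @param transient_amplitude peak transient size in dF/F units.
#' @param transient_tau decay time constant (s), > 0.
#' @param baseline mean fluorescence (arbitrary units).
#' @param drift_slope linear drift in fluorescence units per second.
#' @param noise_sd Gaussian noise SD (fluorescence units), per channel.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [photometry_recording()] with attribute `ground_truth`.
#' @export
simulate_photometry <- function(duration = 120,
                                sample_rate = 100,
                                event_times_s = numeric(),
                                transient_amplitude = 0.2,
                                transient_tau = 1.5,
                                baseline = 100,
                                drift_slope = -0.01,
                                noise_sd = 0.2,
                                seed = NULL) {
  check_scalar_num(duration, "duration", positive = TRUE)
  check_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  check_scalar_num(transient_tau, "transient_tau", positive = TRUE)
  check_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(event_times_s) &&
      (min(event_times_s) < 0 || max(event_times_s) > duration))
    stop_field("event_times_s", "must lie within [0, duration]")
  n <- floor(duration * sample_rate) + 1L
  t_s <- (seq_len(n) - 1L) / sample_rate
  trend <- baseline + drift_slope * t_s
  transients <- numeric(n)
  for (ev in event_times_s) {
    after <- t_s >= ev
    transients[after] <- transients[after] +
      transient_amplitude * exp(-(t_s[after] - ev) / transient_tau)
  }
  with_seed(seed, {
    f410 <- trend + stats::rnorm(n, 0, noise_sd)
    f470 <- trend + baseline * transients + stats::rnorm(n, 0, noise_sd)
  })
  out <- photometry_recording(t_s, f470, f410, event_times_s,
                              sample_rate = sample_rate)
  attr(out, "ground_truth") <- list(transient_amplitude = transient_amplitude,
                                    transient_tau = transient_tau,
                                    baseline = baseline,
                                    drift_slope = drift_slope)
  out
}

#' Simulate a von Frey assay
#'
#' Positive-response counts per filament are binomial with success
#' probability `plogis((filament - true_threshold) * slope)`.
#'
#' @param true_threshold filament value at which the response probability
#'   is 50%.
#' @param slope psychometric steepness (per filament unit); large values
#'   approach a step function.
#' @param filaments strictly increasing ladder; defaults to [vonfrey_ladder()].
#' @param trials_per_filament trials per filament, default 10.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [vonfrey_assay()] with attribute `ground_truth`.
#' @export
simulate_vonfrey <- function(true_threshold = 2.6,
                             slope = 10,
                             filaments = vonfrey_ladder(),
                             trials_per_filament = 10L,
                             seed = NULL) {
  if (length(filaments) == 0L) stop_field("filaments", "empty ladder")
  if (any(diff(filaments) <= 0)) stop_field("filaments", "must be strictly increasing")
  trials_per_filament <- check_count(trials_per_filament, "trials_per_filament")
  p <- stats::plogis((filaments - true_threshold) * slope)
  pos <- with_seed(seed, stats::rbinom(length(filaments), trials_per_filament, p))
  out <- vonfrey_assay(filaments, pos, trials_per_filament)
  attr(out, "ground_truth") <- list(true_threshold = true_threshold,
                                    slope = slope, prob = p)
  out
}
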