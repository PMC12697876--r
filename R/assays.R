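#' Von Frey mechanical threshold
#'
#' Applies the ladder rule: the threshold is the smallest filament whose
#' positive-response rate exceeds 60% (more than 6 of 10 with the standard
#' 10 trials). If no filament qualifies the animal is censored above the
#' ladder: the returned value carries the ladder maximum as a numeric
#' sentinel, `censored = TRUE`, and a `"> max"` label (this keeps
#' downstream rank-based statistics usable).
#'
#' @param assay a [vonfrey_assay()].
#' @return A list of class `vonfrey_threshold`: `value`, `censored`,
#'   `label`.
#' @export
vonfrey_threshold <- function(assay) {
  if (!inherits(assay, "vonfrey_assay"))
    stop("`assay` must be a vonfrey_assay", call. = FALSE)
  hit <- which(assay$positives / assay$trials > 0.6)
  if (length(hit)) {
    v <- assay$filament[hit[1L]]
    structure(list(value = v, censored = FALSE, label = format(v)),
              class = "vonfrey_threshold")
  } else {
    mx <- max(assay$filament)
    structure(list(value = mx, censored = TRUE,
                   label = paste0("> ", format(mx))),
              class = "vonfrey_threshold")
  }
}

#' @export
print.vonfrey_threshold <- function(x, ...) {
  cat("von Frey threshold:", x$label,
      if (x$censored) "(censored above ladder)" else "", "\n")
  invisible(x)
}

#' Per-filament response-frequency curve
#'
#' @param assay a [vonfrey_assay()].
#' @return Data frame with `filament` and `response_pct`
#'   (`100 * positives / trials`).
#' @export
response_frequency <- function(assay) {
  if (!inherits(assay, "vonfrey_assay"))
    stop("`assay` must be a vonfrey_assay", call. = FALSE)
  if (any(assay$trials == 0L)) stop("trials must be positive", call. = FALSE)
  data.frame(filament = assay$filament,
             response_pct = 100 * assay$positives / assay$trials)
}

#' Open-field center-zone metrics
#'
#' Scores a square-arena trajectory against a concentric center square
#' whose side is `center_fraction` times the arena side (default 0.5, the
#' standard open-field convention). Time in zone is counted per sample;
#' an entry is a strict outside-to-inside transition of the tracked point,
#' with a path that starts inside counting as one entry; each displacement
#' segment is attributed to the zone of its starting sample.
#'
#' @param traj a [trajectory()] in a [square_arena()].
#' @param center_fraction side of the center zone relative to the arena.
#' @return A list of class `zone_metrics`: `time_in_zone_s`, `entries`,
#'   `distance_in_zone_cm`, `total_distance_cm`, `zone_fraction_of_path`,
#'   `total_time_s`.
#' @export
openfield_metrics <- function(traj, center_fraction = 0.5) {
  if (!inherits(traj, "trajectory")) stop("`traj` must be a trajectory", call. = FALSE)
  arena <- attr(traj, "arena")
  if (arena$type != "square") stop("open-field metrics need a square arena", call. = FALSE)
  check_scalar_num(center_fraction, "center_fraction", positive = TRUE)
  if (center_fraction > 1) stop_field("center_fraction", "must be <= 1")
  half <- arena$side * center_fraction / 2
  ctr <- arena$side / 2
  inside <- abs(traj$x_cm - ctr) <= half & abs(traj$y_cm - ctr) <= half
  zone_metrics_from_state(traj, inside)
}

zone_metrics_from_state <- function(traj, inside) {
  sr <- attr(traj, "sample_rate")
  n <- nrow(traj)
  time_in <- sum(inside) / sr
  entries <- sum(inside & !c(FALSE, inside[-n]))
  if (n > 1L) {
    seg <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)
    dist_in <- sum(seg[inside[-n]])
    total <- sum(seg)
  } else {
    dist_in <- 0; total <- 0
  }
  structure(list(time_in_zone_s = time_in, entries = entries,
                 distance_in_zone_cm = dist_in, total_distance_cm = total,
                 zone_fraction_of_path = if (total > 0) dist_in / total else 0,
                 total_time_s = n / sr),
            class = "zone_metrics")
}

#' @export
print.zone_metrics <- function(x, ...) {
  cat(sprintf("zone time %.1f s of %.1f s, %d entries, %.1f of %.1f cm in zone\n",
              x$time_in_zone_s, x$total_time_s, x$entries,
              x$distance_in_zone_cm, x$total_distance_cm))
  invisible(x)
}

#' Elevated plus-maze metrics
#'
#' Assigns every sample to the open arms, closed arms, or center platform
#' of a [plus_maze_arena()] and scores each zone class with the same
#' time / entry / distance rules as [openfield_metrics()] (an entry is a
#' transition into the class from any other class; starting in the class
#' counts as one entry).
#'
#' @param traj a [trajectory()] in a plus maze.
#' @return Named list of class `epm_metrics` with one `zone_metrics` per
#'   zone class (`open`, `closed`, `center`) and `total_distance_cm`.
#' @export
epm_metrics <- function(traj) {
  if (!inherits(traj, "trajectory")) stop("`traj` must be a trajectory", call. = FALSE)
  arena <- attr(traj, "arena")
  if (arena$type != "plus_maze") stop("EPM metrics need a plus-maze arena", call. = FALSE)
  zone <- epm_zone(traj$x_cm, traj$y_cm, arena)
  out <- lapply(c(open = "open", closed = "closed", center = "center"),
                function(zc) zone_metrics_from_state(traj, zone == zc))
  out$total_distance_cm <- if (nrow(traj) > 1L)
    sum(sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)) else 0
  structure(out, class = "epm_metrics")
}

#' @export
print.epm_metrics <- function(x, ...) {
  cat(sprintf("EPM: open %.1f s (%d entries), closed %.1f s, center %.1f s; %.1f cm total\n",
              x$open$time_in_zone_s, x$open$entries, x$closed$time_in_zone_s,
              x$center$time_in_zone_s, x$total_distance_cm))
  invisible(x)
}
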