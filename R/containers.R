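#' Region-by-animal FOS count matrix
#'
#' Container for per-animal FOS-positive cell counts across named brain
#' regions, with a two-level group factor (typically control vs. model).
#' This is the input to [activation_map()] and friends.
#'
#' @param counts numeric matrix, animals in rows, regions in columns;
#'   nonnegative, no missing cells.
#' @param group factor or character vector of length `nrow(counts)` with
#'   exactly two levels. The *second* level is the "positive" class: fitted
#'   weights and activation patterns point toward it.
#' @param region_names character vector of region identifiers (Allen-style
#'   acronyms); defaults to `colnames(counts)`.
#' @param validate_regions warn about region names not found in the bundled
#'   Allen acronym list (never an error).
#'
#' @return An object of class `region_counts`: the count matrix with
#'   `group` and `region_names` attributes.
#' @export
region_counts <- function(counts, group, region_names = colnames(counts),
                          validate_regions = FALSE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop_field("counts", "must be numeric")
  if (anyNA(counts)) stop_field("counts", "contains missing cells")
  if (any(counts < 0)) stop_field("counts", "contains negative counts")
  if (nrow(counts) < 2L) stop_field("counts", "needs at least 2 animals")
  if (ncol(counts) < 2L) stop_field("counts", "needs at least 2 regions")
  if (is.null(region_names)) region_names <- paste0("R", seq_len(ncol(counts)))
  if (length(region_names) != ncol(counts))
    stop_field("region_names", "length must match number of regions")
  group <- as.factor(group)
  if (length(group) != nrow(counts))
    stop_field("group", "length must match number of animals")
  group <- droplevels(group)
  if (nlevels(group) != 2L) stop_field("group", "needs exactly two levels")
  if (any(table(group) < 1L)) stop_field("group", "each group needs >= 1 animal")
  if (validate_regions) {
    known <- allen_acronyms()
    unknown <- setdiff(region_names, known)
    if (length(unknown))
      warning("region names not in bundled Allen acronym list: ",
              paste(utils::head(unknown, 10L), collapse = ", "),
              if (length(unknown) > 10L) ", ..." else "", call. = FALSE)
  }
  colnames(counts) <- region_names
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0(as.character(group), "_", seq_len(nrow(counts)))
  structure(counts, group = group, class = c("region_counts", "matrix", "array"))
}

#' @export
print.region_counts <- function(x, ...) {
  g <- attr(x, "group")
  cat(sprintf("<region_counts> %d animals x %d regions (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: %d", levels(g), table(g)), collapse = ", ")))
  invisible(x)
}

#' Bundled Allen-atlas region acronyms
#'
#' A plain-text list of common Allen Mouse Brain Atlas structure acronyms
#' used to sanity-check user-supplied region names (unknown names warn,
#' never fail).
#'
#' @return Character vector of acronyms.
#' @export
allen_acronyms <- function() {
  path <- system.file("extdata", "allen_acronyms.txt", package = "accmap")
  readLines(path, warn = FALSE)
}

#' Behavioral ethogram (labeled bout sequence)
#'
#' An ordered sequence of labeled behavioral bouts. Bouts must be
#' non-overlapping, time-ordered, and have `start_s < end_s`.
#'
#' @param label character vector of action labels per bout.
#' @param start_s,end_s numeric bout boundaries in seconds.
#' @param label_set the full action alphabet (labels with zero bouts are
#'   retained in proportion vectors and transition matrices); defaults to
#'   the sorted set of observed labels.
#' @param animal_id,group optional metadata.
#'
#' @return A data frame of class `ethogram` with columns
#'   `label`, `start_s`, `end_s` and attributes `label_set`, `animal_id`,
#'   `group`.
#' @export
ethogram <- function(label, start_s, end_s, label_set = NULL,
                     animal_id = NA_character_, group = NA_character_) {
  label <- as.character(label)
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  n <- length(label)
  if (n == 0L) stop_field("label", "ethogram has no bouts")
  if (length(start_s) != n || length(end_s) != n)
    stop_field("start_s/end_s", "lengths must match `label`")
  if (anyNA(start_s) || anyNA(end_s)) stop_field("start_s/end_s", "missing values")
  if (any(end_s <= start_s)) stop_field("end_s", "every bout needs start_s < end_s")
  if (n > 1L && any(start_s[-1L] < end_s[-n] - 1e-9))
    stop_field("start_s", "bouts overlap or are out of order")
  if (is.null(label_set)) label_set <- sort(unique(label))
  if (!all(label %in% label_set))
    stop_field("label", "contains labels outside `label_set`")
  structure(data.frame(label = label, start_s = start_s, end_s = end_s,
                       stringsAsFactors = FALSE),
            label_set = label_set, animal_id = animal_id, group = group,
            class = c("ethogram", "data.frame"))
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %d bouts, %.1f s, %d-action alphabet\n",
              nrow(x), max(x$end_s) - min(x$start_s),
              length(attr(x, "label_set"))))
  invisible(x)
}

#' 2-D locomotor trajectory
#'
#' @param t_s strictly increasing sample times (s).
#' @param x_cm,y_cm coordinates in cm.
#' @param arena arena geometry: [square_arena()] or [plus_maze_arena()].
#' @param sample_rate sampling rate in Hz; inferred from `t_s` when `NULL`.
#'
#' @return A data frame of class `trajectory` with attributes `arena` and
#'   `sample_rate`.
#' @export
trajectory <- function(t_s, x_cm, y_cm, arena, sample_rate = NULL) {
  t_s <- as.numeric(t_s); x_cm <- as.numeric(x_cm); y_cm <- as.numeric(y_cm)
  n <- length(t_s)
  if (n < 1L || length(x_cm) != n || length(y_cm) != n)
    stop_field("t_s", "t/x/y must have equal positive length")
  if (n > 1L && any(diff(t_s) <= 0)) stop_field("t_s", "must be strictly increasing")
  if (is.null(sample_rate))
    sample_rate <- if (n > 1L) 1 / stats::median(diff(t_s)) else 1
  if (!inside_arena_all(x_cm, y_cm, arena))
    stop_field("x_cm/y_cm", "points fall outside the arena bounds")
  structure(data.frame(t_s = t_s, x_cm = x_cm, y_cm = y_cm),
            arena = arena, sample_rate = sample_rate,
            class = c("trajectory", "data.frame"))
}

#' Arena geometries
#'
#' `square_arena()` describes a square open-field box; `plus_maze_arena()`
#' an elevated plus maze centered at the origin with open arms along the
#' x axis and closed arms along the y axis.
#'
#' @param side side length of the square box (cm).
#' @param arm_length,arm_width arm dimensions (cm).
#' @param center_size side of the central platform (cm).
#' @return A list describing the geometry, class `arena`.
#' @export
square_arena <- function(side = 50) {
  check_scalar_num(side, "side", positive = TRUE)
  structure(list(type = "square", side = side), class = "arena")
}

#' @rdname square_arena
#' @export
plus_maze_arena <- function(arm_length = 30, arm_width = 5, center_size = 5) {
  check_scalar_num(arm_length, "arm_length", positive = TRUE)
  check_scalar_num(arm_width, "arm_width", positive = TRUE)
  check_scalar_num(center_size, "center_size", positive = TRUE)
  if (arm_width > center_size + 1e-9)
    stop_field("arm_width", "must not exceed center_size (arms join the platform)")
  structure(list(type = "plus_maze", arm_length = arm_length,
                 arm_width = arm_width, center_size = center_size),
            class = "arena")
}

inside_arena_all <- function(x, y, arena, tol = 1e-6) {
  if (!inherits(arena, "arena")) stop_field("arena", "must be an `arena` object")
  if (arena$type == "square") {
    all(x >= -tol & x <= arena$side + tol & y >= -tol & y <= arena$side + tol)
  } else {
    all(epm_zone(x, y, arena, tol = tol) != "outside")
  }
}

# zone of each (x, y) in a plus maze: "center", "open" (x arms),
# "closed" (y arms) or "outside"
epm_zone <- function(x, y, arena, tol = 1e-6) {
  h <- arena$center_size / 2
  w <- arena$arm_width / 2
  L <- arena$arm_length
  zone <- rep("outside", length(x))
  zone[abs(x) <= h + tol & abs(y) <= h + tol] <- "center"
  open <- abs(y) <= w + tol & abs(x) > h + tol & abs(x) <= h + L + tol
  zone[open] <- "open"
  closed <- abs(x) <= w + tol & abs(y) > h + tol & abs(y) <= h + L + tol
  zone[closed] <- "closed"
  zone
}

#' Dual-channel fiber-photometry recording
#'
#' @param t_s strictly increasing sample times (s).
#' @param f470 calcium-dependent signal channel (arbitrary fluorescence units).
#' @param f410 isosbestic control channel, same length and timebase.
#' @param event_times_s stimulus/event timestamps (s) within the recording.
#' @param sample_rate Hz; inferred from `t_s` when `NULL`.
#' @return A list of class `photometry_recording`.
#' @export
photometry_recording <- function(t_s, f470, f410, event_times_s = numeric(),
                                 sample_rate = NULL) {
  n <- length(t_s)
  if (length(f470) != n || length(f410) != n)
    stop_field("f470/f410", "channel lengths must equal length(t_s)")
  if (n > 1L && any(diff(t_s) <= 0)) stop_field("t_s", "must be strictly increasing")
  if (length(event_times_s) &&
      (min(event_times_s) < min(t_s) - 1e-9 || max(event_times_s) > max(t_s) + 1e-9))
    stop_field("event_times_s", "events fall outside the recording")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(diff(t_s))
  structure(list(t_s = as.numeric(t_s), f470 = as.numeric(f470),
                 f410 = as.numeric(f410),
                 event_times_s = as.numeric(event_times_s),
                 sample_rate = sample_rate),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %.1f s @ %.1f Hz, %d events\n",
              max(x$t_s) - min(x$t_s), x$sample_rate, length(x$event_times_s)))
  invisible(x)
}

#' Von Frey assay table
#'
#' A filament ladder with the number of positive responses per filament.
#'
#' @param filaments strictly increasing filament specification values
#'   (ordinal scores as printed on the filaments, no gram-force conversion).
#' @param positives positive-response count per filament.
#' @param trials trials per filament (scalar or vector), default 10.
#' @return A data frame of class `vonfrey_assay`.
#' @export
vonfrey_assay <- function(filaments, positives, trials = 10L) {
  filaments <- as.numeric(filaments)
  if (length(filaments) == 0L) stop_field("filaments", "empty ladder")
  if (any(diff(filaments) <= 0)) stop_field("filaments", "must be strictly increasing")
  positives <- as.integer(positives)
  if (length(positives) != length(filaments))
    stop_field("positives", "length must match `filaments`")
  trials <- as.integer(rep_len(trials, length(filaments)))
  if (any(trials < 1L)) stop_field("trials", "must be >= 1")
  if (any(positives < 0L | positives > trials))
    stop_field("positives", "must lie in [0, trials]")
  structure(data.frame(filament = filaments, positives = positives,
                       trials = trials),
            class = c("vonfrey_assay", "data.frame"))
}

#' Default von Frey filament ladder
#'
#' The six-filament specification-value ladder used for orofacial
#' mechanical testing.
#' @return Numeric vector of filament values.
#' @export
vonfrey_ladder <- function() c(1.65, 2.36, 2.44, 2.83, 3.22, 3.61)

#' Default action alphabet
#'
#' The 10-action repertoire used for the spontaneous-behavior ethograms:
#' running, trotting, stepping, walking, rearing, hunching, right turning,
#' curling-up, sniffing and self-grooming.
#' @return Character vector of 10 labels.
#' @export
action_labels <- function() {
  c("running", "trotting", "stepping", "walking", "rearing",
    "hunching", "right_turning", "curling_up", "sniffing", "self_grooming")
}
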