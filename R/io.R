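# All tabular I/O is plain CSV with JSON sidecars for ground truth and run
# metadata; desk-scale data never justifies binary formats.

read_checked_csv <- function(path, required, numeric_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse CSV ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("empty table: ", path, call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cl in (numeric_cols %||% setdiff(names(df), c("group", "animal", "label")))) {
    if (cl %in% names(df) && !is.numeric(df[[cl]]))
      stop("non-numeric values in column `", cl, "` of ", path, call. = FALSE)
  }
  df
}

#' Read / write region count tables
#'
#' CSV layout: one row per animal, one numeric column per region, plus a
#' `group` column (and an optional leading `animal` identifier column).
#' Writing a table that carries generator ground truth also writes a
#' `<file>.truth.json` sidecar.
#'
#' @param path CSV path.
#' @param validate_regions warn on region names missing from the bundled
#'   Allen acronym list.
#' @return [read_region_counts()] returns a [region_counts()] object.
#' @export
read_region_counts <- function(path, validate_regions = FALSE) {
  df <- read_checked_csv(path, required = "group")
  id_col <- intersect("animal", names(df))
  regions <- setdiff(names(df), c("group", id_col))
  m <- as.matrix(df[regions])
  if (length(id_col)) rownames(m) <- df[[id_col]]
  region_counts(m, df$group, regions, validate_regions = validate_regions)
}

#' @rdname read_region_counts
#' @param x object to serialize.
#' @export
write_region_counts <- function(x, path) {
  df <- data.frame(animal = rownames(x), group = attr(x, "group"),
                   as.data.frame(unclass(x)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  write_truth_sidecar(x, path)
  invisible(path)
}

write_truth_sidecar <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(gt, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write ethograms
#'
#' CSV layout: `label,start_s,end_s`, one row per bout.
#' @param path CSV path.
#' @param label_set optional full alphabet (defaults to observed labels).
#' @param animal_id,group metadata.
#' @export
read_ethogram <- function(path, label_set = NULL, animal_id = NA_character_,
                          group = NA_character_) {
  df <- read_checked_csv(path, required = c("label", "start_s", "end_s"),
                         numeric_cols = c("start_s", "end_s"))
  ethogram(df$label, df$start_s, df$end_s, label_set = label_set,
           animal_id = animal_id, group = group)
}

#' @rdname read_ethogram
#' @param x object to serialize.
#' @export
write_ethogram <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("label", "start_s", "end_s")], path,
                   row.names = FALSE)
  write_truth_sidecar(x, path)
  invisible(path)
}

#' Read / write trajectories
#'
#' CSV layout: `t_s,x_cm,y_cm`; the arena geometry travels in a JSON
#' config (written next to the CSV as `<file>.arena.json`).
#' @param path CSV path.
#' @param arena an `arena` object; when `NULL` it is read from the
#'   sidecar.
#' @export
read_trajectory <- function(path, arena = NULL) {
  df <- read_checked_csv(path, required = c("t_s", "x_cm", "y_cm"))
  if (is.null(arena)) {
    side <- paste0(path, ".arena.json")
    if (!file.exists(side))
      stop("no `arena` given and no sidecar ", side, call. = FALSE)
    cfg <- jsonlite::read_json(side, simplifyVector = TRUE)
    arena <- if (cfg$type == "square") square_arena(cfg$side)
             else plus_maze_arena(cfg$arm_length, cfg$arm_width, cfg$center_size)
  }
  trajectory(df$t_s, df$x_cm, df$y_cm, arena)
}

#' @rdname read_trajectory
#' @param x object to serialize.
#' @export
write_trajectory <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  arena <- attr(x, "arena")
  jsonlite::write_json(unclass(arena), paste0(path, ".arena.json"),
                       auto_unbox = TRUE, digits = NA)
  write_truth_sidecar(x, path)
  invisible(path)
}

#' Read / write photometry recordings
#'
#' CSV layout: `t_s,f470,f410`; event times go to a
#' `<file>.events.json` sidecar.
#' @param path CSV path.
#' @export
read_photometry <- function(path) {
  df <- read_checked_csv(path, required = c("t_s", "f470", "f410"))
  side <- paste0(path, ".events.json")
  ev <- if (file.exists(side))
    as.numeric(jsonlite::read_json(side, simplifyVector = TRUE)) else numeric()
  photometry_recording(df$t_s, df$f470, df$f410, ev)
}

#' @rdname read_photometry
#' @param x object to serialize.
#' @export
write_photometry <- function(x, path) {
  utils::write.csv(data.frame(t_s = x$t_s, f470 = x$f470, f410 = x$f410),
                   path, row.names = FALSE)
  jsonlite::write_json(x$event_times_s, paste0(path, ".events.json"),
                       digits = NA)
  write_truth_sidecar(x, path)
  invisible(path)
}

#' Read / write von Frey tables
#'
#' CSV layout: `filament,positives,trials`.
#' @param path CSV path.
#' @export
read_vonfrey <- function(path) {
  df <- read_checked_csv(path, required = c("filament", "positives", "trials"))
  vonfrey_assay(df$filament, df$positives, df$trials)
}

#' @rdname read_vonfrey
#' @param x object to serialize.
#' @export
write_vonfrey <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  write_truth_sidecar(x, path)
  invisible(path)
}

#' Run the synthetic end-to-end pipeline from a config
#'
#' Executes the requested stages in dependency order on seeded synthetic
#' data, writes every declared output CSV under `out_dir`, and returns (and
#' writes) a JSON manifest recording inputs, parameters, seed, package
#' version and the MD5 of every file produced. Re-running the same config
#' reproduces byte-identical outputs and manifest.
#'
#' Recognized stages: `"simulate"` (region counts, ethograms), and the
#' consumers `"map_activation"` and `"ethology"`. Configs may be a list or
#' a YAML/JSON file path with fields `seed`, `stages`, `out_dir`, and
#' optional parameter blocks `region_counts` (n_per_group, n_regions,
#' effect_regions, effect_log_fold), `ethograms` (n_per_group,
#' total_duration), `activation` (shrinkage, cost), `ethology`
#' (pseudocount).
#'
#' @param config list or path to a YAML/JSON config.
#' @param out_dir output directory (overrides the config's).
#' @return The manifest, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("`config` must be a list or file path", call. = FALSE)
  out_dir <- out_dir %||% config$out_dir %||% stop("config needs `out_dir`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- check_count(config$seed %||% 1L, "seed", min = 0L)
  stages <- config$stages %||% c("simulate", "map_activation", "ethology")
  known <- c("simulate", "map_activation", "ethology")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  files <- character()
  params <- list()

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  if ("simulate" %in% stages) {
    rcp <- config$region_counts %||% list()
    params$region_counts <- rcp <- utils::modifyList(
      list(n_per_group = 3L, n_regions = 129L, effect_regions = 1:5,
           effect_log_fold = 0.5), rcp)
    run_stage("simulate", {
      rc <- simulate_region_counts(
        n_per_group = rcp$n_per_group,
        region_names = sprintf("R%03d", seq_len(rcp$n_regions)),
        effect_regions = rcp$effect_regions,
        effect_log_fold = rcp$effect_log_fold, seed = seed)
      write_region_counts(rc, file.path(out_dir, "region_counts.csv"))
      ecp <- config$ethograms %||% list()
      params$ethograms <- ecp <- utils::modifyList(
        list(n_con = 11L, n_ma = 6L, total_duration = 600), ecp)
      P_con <- sticky_transition_matrix(length(action_labels()), stay = 0.3)
      P_ma <- sticky_transition_matrix(length(action_labels()), stay = 0.6)
      ids <- c(sprintf("CON_%02d", seq_len(ecp$n_con)),
               sprintf("MA_%02d", seq_len(ecp$n_ma)))
      grp <- rep(c("CON", "MA"), c(ecp$n_con, ecp$n_ma))
      for (i in seq_along(ids)) {
        e <- simulate_ethogram(if (grp[i] == "CON") P_con else P_ma,
                               total_duration = ecp$total_duration,
                               animal_id = ids[i], group = grp[i],
                               seed = seed + i)
        write_ethogram(e, file.path(out_dir, paste0("ethogram_", ids[i], ".csv")))
      }
      utils::write.csv(data.frame(animal = ids, group = grp),
                       file.path(out_dir, "groups.csv"), row.names = FALSE)
    })
  }

  if ("map_activation" %in% stages) {
    acp <- config$activation %||% list()
    params$activation <- acp <- utils::modifyList(
      list(shrinkage = "auto", cost = 1), acp)
    run_stage("map_activation", {
      rc <- read_region_counts(file.path(out_dir, "region_counts.csv"))
      fit <- activation_map(rc, shrinkage = acp$shrinkage, cost = acp$cost,
                            cv = "loo", seed = seed)
      curve <- fit$curve
      ranks <- match(rownames(fit$pattern$A), curve$region)
      out <- data.frame(region = rownames(fit$pattern$A),
                        weight = drop(fit$classifier$weights),
                        pattern = drop(fit$pattern$A),
                        abs_rank = ranks,
                        cum_fraction = curve$cumulative_fraction[ranks])
      utils::write.csv(out, file.path(out_dir, "activation_pattern.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(fit$pattern$sigma_x),
                       file.path(out_dir, "feature_covariance.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(shrinkage_used = fit$pattern$shrinkage_used,
             training_accuracy = fit$classifier$training_accuracy,
             loo_accuracy = fit$cv$accuracy),
        file.path(out_dir, "activation_meta.json"),
        auto_unbox = TRUE, digits = NA)
    })
  }

  if ("ethology" %in% stages) {
    etp <- config$ethology %||% list()
    params$ethology <- etp <- utils::modifyList(list(pseudocount = 0), etp)
    run_stage("ethology", {
      groups <- utils::read.csv(file.path(out_dir, "groups.csv"))
      ethos <- lapply(groups$animal, function(id)
        read_ethogram(file.path(out_dir, paste0("ethogram_", id, ".csv")),
                      label_set = action_labels(), animal_id = id))
      props <- t(vapply(ethos, action_proportions,
                        numeric(length(action_labels()))))
      rownames(props) <- groups$animal
      utils::write.csv(data.frame(animal = groups$animal, props,
                                  check.names = FALSE),
                       file.path(out_dir, "action_proportions.csv"),
                       row.names = FALSE)
      tms <- lapply(ethos, transition_matrix, pseudocount = etp$pseudocount)
      flows <- do.call(rbind, lapply(seq_along(tms), function(i) {
        fl <- summarize_transitions(tms[[i]], props[i, ])$flows
        cbind(animal = groups$animal[i], fl)
      }))
      utils::write.csv(flows, file.path(out_dir, "transition_flows.csv"),
                       row.names = FALSE)
      diff <- differential_actions(props, groups$group)
      utils::write.csv(diff, file.path(out_dir, "differential_actions.csv"),
                       row.names = FALSE)
      cl <- cluster_proportions(props, k = 2)
      utils::write.csv(data.frame(animal = groups$animal,
                                  cluster = cl$assignments),
                       file.path(out_dir, "clusters.csv"), row.names = FALSE)
      emb <- embed_and_classify(props, groups$group, seed = seed)
      utils::write.csv(data.frame(animal = groups$animal, emb$embedding,
                                  group = groups$group),
                       file.path(out_dir, "embedding.csv"), row.names = FALSE)
    })
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("accmap")),
    seed = seed, stages = stages, parameters = params,
    outputs = lapply(files, function(f)
      list(file = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Row-stochastic matrix with a common self-transition probability
#'
#' Convenience generator of "sticky" bout-level transition matrices:
#' probability `stay` on the diagonal, the remainder spread uniformly.
#'
#' @param K alphabet size.
#' @param stay self-transition probability in `[0, 1)`.
#' @return K x K row-stochastic matrix.
#' @export
sticky_transition_matrix <- function(K, stay = 0.5) {
  K <- check_count(K, "K", min = 2L)
  check_scalar_num(stay, "stay", nonneg = TRUE)
  if (stay >= 1) stop_field("stay", "must be < 1")
  P <- matrix((1 - stay) / (K - 1), K, K)
  diag(P) <- stay
  P
}
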