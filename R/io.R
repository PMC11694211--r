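#' @title Marker and force file dialects
#' @description
#' The reference on-disk dialect is a tab-separated table with one header
#' line. Marker files carry a `time` column (seconds) and per-marker columns
#' `left_X left_Y left_Z right_X right_Y right_Z` in millimetres (the export
#' convention of optical capture systems). Force files carry `time` plus
#' `p1_X p1_Y p1_Z p2_X p2_Y p2_Z` in newtons. The axis letters are mapped to
#' the canonical frame (AP toward the lifter, V up) through an [axis_map].
#' @name snatch_files
NULL

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE)
}

.check_time <- function(tm, path) {
  if (is.null(tm)) stop("format error in ", path, ": missing column 'time'")
  if (any(diff(tm) <= 0))
    stop("format error in ", path, ": non-monotone time column")
  1 / stats::median(diff(tm))
}

.pick_cols <- function(df, prefix, map, path) {
  plan <- .axis_plan(map)
  out <- matrix(NA_real_, nrow(df), 3, dimnames = list(NULL, plan$canon))
  for (i in seq_len(nrow(plan))) {
    col <- paste0(prefix, "_", plan$src[i])
    if (is.null(df[[col]]))
      stop("format error in ", path, ": missing column '", col, "'")
    out[, plan$canon[i]] <- plan$sign[i] * df[[col]]
  }
  out[, c("AP", "ML", "V"), drop = FALSE]
}

#' Read a marker file
#'
#' Reads the two bar-end marker trajectories from a tab-separated export (see
#' [snatch_files]), converts millimetres to metres and maps file axes to the
#' canonical frame.
#'
#' @param path File path.
#' @param map An [axis_map].
#'
#' @return List with `marker_left`, `marker_right` (n x 3, metres) and
#'   `f_kin` (Hz).
#' @export
read_marker_file <- function(path, map = axis_map()) {
  df <- .read_tsv(path)
  f_kin <- .check_time(df$time, path)
  list(marker_left = .pick_cols(df, "left", map, path) / 1000,
       marker_right = .pick_cols(df, "right", map, path) / 1000,
       f_kin = f_kin)
}

#' Write a marker file
#'
#' @param marker_left,marker_right n x 3 canonical matrices (metres).
#' @param f_kin Sampling rate (Hz).
#' @param path Output path.
#' @param map An [axis_map] describing the file axes to write.
#' @export
write_marker_file <- function(marker_left, marker_right, f_kin, path,
                              map = axis_map()) {
  plan <- .axis_plan(map)
  n <- nrow(marker_left)
  df <- data.frame(time = (seq_len(n) - 1) / f_kin)
  for (side in c("left", "right")) {
    m <- if (side == "left") marker_left else marker_right
    for (i in seq_len(nrow(plan)))
      df[[paste0(side, "_", plan$src[i])]] <-
        plan$sign[i] * m[, plan$canon[i]] * 1000
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a force-plate file
#'
#' @param path File path.
#' @param map An [axis_map].
#'
#' @return List with `plate1`, `plate2` (n x 3, newtons) and `f_force` (Hz).
#' @export
read_force_file <- function(path, map = axis_map()) {
  df <- .read_tsv(path)
  f_force <- .check_time(df$time, path)
  list(plate1 = .pick_cols(df, "p1", map, path),
       plate2 = .pick_cols(df, "p2", map, path),
       f_force = f_force)
}

#' Write a force-plate file
#'
#' @param plate1,plate2 n x 3 canonical force matrices (newtons).
#' @param f_force Sampling rate (Hz).
#' @param path Output path.
#' @param map An [axis_map].
#' @export
write_force_file <- function(plate1, plate2, f_force, path,
                             map = axis_map()) {
  plan <- .axis_plan(map)
  n <- nrow(plate1)
  df <- data.frame(time = (seq_len(n) - 1) / f_force)
  for (pl in c("p1", "p2")) {
    m <- if (pl == "p1") plate1 else plate2
    for (i in seq_len(nrow(plan)))
      df[[paste0(pl, "_", plan$src[i])]] <-
        plan$sign[i] * m[, plan$canon[i]]
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write both files of a raw trial
#'
#' @param raw A [raw_trial].
#' @param marker_path,force_path Output paths.
#' @param map An [axis_map].
#' @export
write_trial <- function(raw, marker_path, force_path, map = axis_map()) {
  write_marker_file(raw$marker_left, raw$marker_right, raw$f_kin,
                    marker_path, map)
  write_force_file(raw$plate1, raw$plate2, raw$f_force, force_path, map)
  invisible(c(marker_path, force_path))
}

#' Write / read a feature table
#'
#' One row per trial, identity columns (`subject_id`, `condition`,
#' `trial_index`) followed by the 23 parameters under their standard names
#' (displacements in cm, forces in BW, RFD in BW/s, power in W/kg).
#'
#' @param features Feature data frame (non-empty).
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  if (is.null(features) || !nrow(features))
    stop("write_features: empty feature table")
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load a cohort manifest
#'
#' A manifest maps subjects x conditions x trials to their recording files.
#' YAML manifests have a `subjects` list (`id`, `body_height`, and either
#' `body_mass` or `static_file`) and a `trials` list (`subject`, `condition`,
#' `trial`, `marker_file`, `force_file`, optional integer `offset` of the
#' force record relative to the kinematics, in force samples). CSV manifests
#' are a flat trials table with columns `subject`, `condition`, `trial`,
#' `marker_file`, `force_file`, `body_height` and `body_mass`/`static_file`.
#'
#' Duplicate (subject, condition, trial) cells are an error; missing cells
#' (relative to the complete subjects x 4 conditions x 3 trials grid) produce
#' a warning listing each absent cell.
#'
#' @param path Manifest path (.yaml/.yml or .csv).
#' @param n_trials Expected trials per condition (default 3).
#'
#' @return Object of class `snatch_manifest`: list with `subjects` and
#'   `trials` data frames, `dir` (manifest directory, for resolving relative
#'   paths) and `missing` (character vector of absent cells).
#' @export
load_manifest <- function(path, n_trials = 3) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tr <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("subject", "condition", "trial", "marker_file", "force_file")
    miss <- setdiff(need, names(tr))
    if (length(miss))
      stop("manifest: missing columns ", paste(miss, collapse = ", "))
    subj_cols <- intersect(c("subject", "body_height", "body_mass",
                             "static_file"), names(tr))
    subjects <- unique(tr[subj_cols])
    names(subjects)[1] <- "id"
    trials <- tr[c(need, intersect("offset", names(tr)))]
  } else {
    y <- yaml::read_yaml(path)
    if (is.null(y$subjects) || is.null(y$trials))
      stop("manifest: YAML must contain 'subjects' and 'trials'")
    subjects <- do.call(rbind, lapply(y$subjects, function(s)
      data.frame(id = s$id,
                 body_height = s$body_height %||% NA_real_,
                 body_mass = s$body_mass %||% NA_real_,
                 static_file = s$static_file %||% NA_character_,
                 stringsAsFactors = FALSE)))
    trials <- do.call(rbind, lapply(y$trials, function(tr)
      data.frame(subject = tr$subject, condition = tr$condition,
                 trial = as.integer(tr$trial),
                 marker_file = tr$marker_file, force_file = tr$force_file,
                 offset = as.integer(tr$offset %||% 0L),
                 stringsAsFactors = FALSE)))
  }
  trials$condition <- as.character(trials$condition)
  .as_condition(trials$condition)
  key <- paste(trials$subject, trials$condition, trials$trial, sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("manifest: duplicate trial entries: ", paste(unique(dup), collapse = ", "))
  grid <- expand.grid(subject = unique(trials$subject),
                      condition = snatch_conditions(),
                      trial = seq_len(n_trials), stringsAsFactors = FALSE)
  full <- paste(grid$subject, grid$condition, grid$trial, sep = "/")
  missing_cells <- setdiff(full, key)
  if (length(missing_cells))
    warning("manifest: missing trial cells: ",
            paste(missing_cells, collapse = ", "))
  structure(list(subjects = subjects, trials = trials,
                 dir = dirname(normalizePath(path)),
                 missing = missing_cells),
            class = "snatch_manifest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.snatch_manifest <- function(x, ...) {
  cat(sprintf("snatch_manifest: %d subjects, %d trial entries, %d missing cells\n",
              nrow(x$subjects), nrow(x$trials), length(x$missing)))
  invisible(x)
}

#' Process every trial of a manifest
#'
#' Reads and processes each trial listed in a manifest into the feature
#' table. Subject mass is taken from the manifest or measured from the static
#' record when a `static_file` is given. A positive `offset` drops that many
#' leading force samples to align the streams.
#'
#' @param manifest A [load_manifest] result or a path.
#' @param cfg A [pipeline_config].
#' @param map An [axis_map] for all files.
#' @param verbose Log per-trial progress to stderr.
#'
#' @return Feature data frame, one row per processed trial.
#' @export
process_cohort <- function(manifest, cfg = pipeline_config(),
                           map = axis_map(), verbose = FALSE) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  resolve <- function(f) if (file.exists(f)) f else file.path(manifest$dir, f)
  subj <- manifest$subjects
  subj_info <- list()
  for (i in seq_len(nrow(subj))) {
    mass <- subj$body_mass[i]
    if (is.na(mass)) {
      st <- read_force_file(resolve(subj$static_file[i]), map)
      rec <- static_record(subj$id[i], st$plate1, st$plate2, st$f_force)
      mass <- body_weight_from_static(rec, cfg$gravity)$mass_kg
    }
    subj_info[[subj$id[i]]] <- subject_info(subj$id[i], subj$body_height[i],
                                            mass)
  }
  rows <- lapply(seq_len(nrow(manifest$trials)), function(i) {
    tr <- manifest$trials[i, ]
    if (verbose)
      message(sprintf("processing %s %s trial %d", tr$subject, tr$condition,
                      tr$trial))
    mk <- read_marker_file(resolve(tr$marker_file), map)
    fc <- read_force_file(resolve(tr$force_file), map)
    off <- if (!is.null(tr$offset) && !is.na(tr$offset)) tr$offset else 0L
    if (off > 0) {
      fc$plate1 <- fc$plate1[-seq_len(off), , drop = FALSE]
      fc$plate2 <- fc$plate2[-seq_len(off), , drop = FALSE]
    }
    raw <- raw_trial(tr$subject, tr$condition, tr$trial,
                     mk$marker_left, mk$marker_right, mk$f_kin,
                     fc$plate1, fc$plate2, fc$f_force)
    process_trial(raw, subj_info[[tr$subject]], cfg)$features
  })
  do.call(rbind, rows)
}

#' Write study statistics as JSON
#'
#' One record per variable: `variable`, `test_used`, `statistic`, `df`, `p`,
#' `effect_size`, `effect_type`, `n` and the post-hoc table (empty unless the
#' omnibus was significant).
#'
#' @param study A [snatch_study] object.
#' @param path Output path.
#' @export
write_stats_json <- function(study, path) {
  stopifnot(inherits(study, "snatch_study"))
  recs <- lapply(names(study$results), function(v) {
    r <- study$results[[v]]
    list(variable = v, test_used = r$test, statistic = r$statistic,
         df = as.list(r$df), p = r$p_value, effect_size = r$effect_size,
         effect_type = r$effect_type, n = r$n,
         posthoc = if (is.null(r$posthoc)) list() else r$posthoc)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
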