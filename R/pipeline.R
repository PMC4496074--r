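#' Simulate a complete study
#'
#' Runs every mouse of a [cohort_design()] through the default study
#' schedule — six daily 10-minute training sessions followed by one
#' test session with all arms open — and simulates a matching home-cage
#' behaviour stream per mouse. Excluded mice (e.g. the circler profile)
#' are simulated but keep their exclusion flag.
#'
#' @param cohort a `cohort_design`.
#' @param config a `maze_config`.
#' @param design an `observation_design`.
#' @param n_training number of training sessions before the test.
#' @param make_tracks generate full tracking exports (`FALSE` keeps only
#'   ground-truth visits; much faster).
#' @return object of class `study_data`: `manifest`, `sessions` (per
#'   mouse: list of `sim_session`), `streams` (per mouse:
#'   `behavior_stream`), `config`, `design`, `n_training`.
#' @export
simulate_study <- function(cohort, config = default_maze_config(),
                           design = observation_design(),
                           n_training = 6L, make_tracks = TRUE) {
  stopifnot(inherits(cohort, "cohort_design"))
  man <- cohort$manifest
  obs_win <- observed_windows(design)
  sessions <- list(); streams <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$mouse_id[i]
    p <- cohort$params[[id]]
    ss <- vector("list", n_training + 1L)
    for (s in seq_len(n_training)) {
      ss[[s]] <- simulate_session(p, "TRAINING", config, session_index = s,
                                  make_track = make_tracks)
    }
    ss[[n_training + 1L]] <- simulate_session(p, "TEST", config,
                                              session_index = n_training + 1L,
                                              make_track = make_tracks)
    sessions[[id]] <- ss
    form <- man$stereotypy_form[i]
    streams[[id]] <- simulate_homecage(
      propensity = man$stereotypy_propensity[i],
      form = if (is.na(form) || form == "CIRCLING") "BAR_MOUTHING" else form,
      seed = derive_seed(cohort$seed, 2000L + i),
      mouse_id = id, windows = obs_win)
  }
  structure(list(manifest = man, sessions = sessions, streams = streams,
                 config = config, design = design, n_training = n_training),
            class = "study_data")
}

#' Run the full analysis pipeline on a study
#'
#' Orchestrates QC, visit extraction, per-session metrics and arm
#' scores, the home-cage one-zero/stereotypy layer, and the study's
#' statistical models:
#' \itemize{
#'   \item test-session models: reference, positive and near-positive
#'     arm scores each regressed on handling with `sqrt(stereotypy
#'     level)` as covariate and litter/cage random intercepts;
#'   \item longitudinal training model: positive arm score on handling,
#'     session (continuous) and their interaction;
#'   \item Bonferroni-corrected paired t-tests: positive vs negative
#'     occupancy, ambiguous vs reference occupancy, near-positive vs
#'     near-negative occupancy, and test vs last-training positive
#'     occupancy;
#'   \item Kruskal-Wallis comparison of stereotypy level across forms
#'     (when at least two forms are present).
#' }
#' Mice flagged `excluded` in the manifest, and trials failing the
#' tracking QC rule (not-found or skipped >= 1%) under
#' `qc_policy = "exclude"`, are omitted from analyses; every exclusion
#' is recorded in the run log.
#'
#' @param study a `study_data` (from [simulate_study()] or
#'   [read_study()]).
#' @param qc_policy `"exclude"` (default) or `"ignore"`.
#' @return object of class `study_results`: `metrics` (per mouse x
#'   session data.frame with scores), `onezero` (per-mouse activity and
#'   stereotypy level), `models` (list of `mixed_fit`), `comparisons`,
#'   `form_test`, `log` (character).
#' @export
run_study <- function(study, qc_policy = c("exclude", "ignore")) {
  qc_policy <- match.arg(qc_policy)
  stopifnot(inherits(study, "study_data"))
  man <- study$manifest
  config <- study$config
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  for (i in which(man$excluded)) {
    note("mouse %s excluded: %s", man$mouse_id[i], man$exclusion_reason[i])
  }
  ids <- man$mouse_id[!man$excluded]
  if (length(ids) == 0L) {
    stop("no mice remain after exclusions; nothing to analyse", call. = FALSE)
  }

  rows <- list()
  for (id in ids) {
    for (s in seq_along(study$sessions[[id]])) {
      sim <- study$sessions[[id]][[s]]
      mode <- sim$mode
      if (!is.null(sim$track)) {
        qc <- trial_qc(sim$track)
        if (!qc$passed) {
          note("mouse %s session %d failed QC (not found %.2f%%, skipped %.2f%%)%s",
               id, s, qc$pct_not_found, qc$pct_skipped,
               if (qc_policy == "exclude") "; trial excluded" else "")
          if (qc_policy == "exclude") next
        }
        vt <- visits_from_track(sim$track, config)
        visits <- vt$visits
      } else {
        visits <- sim$visits
      }
      m <- session_metrics(visits, mode, config, track = sim$track,
                          mouse_id = id, session_id = s,
                          pellets = sim$pellets)
      sc <- compute_arm_scores(m)
      row <- metrics_row(m)
      row$reference_arm_score <- sc$reference_arm_score
      row$positive_arm_score <- sc$positive_arm_score
      row$near_positive_arm_score <- sc$near_positive_arm_score
      rows[[length(rows) + 1L]] <- row
    }
  }
  metrics <- do.call(rbind, rows)
  metrics <- merge(metrics, man[, c("mouse_id", "cage", "litter", "handling",
                                    "stereotypy_form")],
                   by = "mouse_id", sort = FALSE)

  oz_rows <- list()
  for (id in ids) {
    stream <- study$streams[[id]]
    bouts <- classify_stereotypy_bouts(stream)
    oz <- one_zero_score(stream, bouts, study$design)
    oz_rows[[length(oz_rows) + 1L]] <- data.frame(
      mouse_id = id, n_slots = oz$n_slots, n_observed = oz$n_observed,
      activity = oz$activity,
      stereotypy_level = ifelse(is.na(oz$stereotypy_level), 0,
                                oz$stereotypy_level),
      stringsAsFactors = FALSE)
  }
  onezero <- do.call(rbind, oz_rows)
  metrics <- merge(metrics, onezero[, c("mouse_id", "stereotypy_level")],
                   by = "mouse_id", sort = FALSE)
  metrics <- metrics[order(metrics$mouse_id, metrics$session_id), ]
  rownames(metrics) <- NULL

  test_rows <- metrics[metrics$mode == "TEST", , drop = FALSE]
  train_rows <- metrics[metrics$mode == "TRAINING", , drop = FALSE]

  models <- list()
  fit_quiet <- function(spec, data) {
    withCallingHandlers(
      tryCatch(fit_mixed_model(data, spec), error = function(e) {
        note("model '%s' failed: %s", spec$outcome, conditionMessage(e)); NULL
      }),
      warning = function(w) {
        note("model '%s': %s", spec$outcome, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  if (nrow(test_rows) >= 4L) {
    for (outc in c("reference_arm_score", "positive_arm_score",
                   "near_positive_arm_score")) {
      models[[outc]] <- fit_quiet(model_spec(outc), test_rows)
    }
  }
  if (nrow(train_rows) >= 8L) {
    models$training_positive <- fit_quiet(
      model_spec("positive_arm_score", session = "session_id",
                 interaction = TRUE), train_rows)
  }

  comparisons <- NULL
  if (nrow(test_rows) >= 2L) {
    wide <- test_rows
    wide$t_amb <- wide$t_nearpos + wide$t_nearneg
    wide$t_ref <- wide$t_pos + wide$t_neg
    last_train <- train_rows[train_rows$session_id ==
                               max(train_rows$session_id), ,
                             drop = FALSE]
    wide <- merge(wide, stats::setNames(
      last_train[, c("mouse_id", "t_pos")], c("mouse_id", "t_pos_lasttrain")),
      by = "mouse_id", all.x = TRUE)
    comparisons <- paired_arm_comparisons(wide, list(
      positive_vs_negative = c("t_pos", "t_neg"),
      ambiguous_vs_reference = c("t_amb", "t_ref"),
      near_positive_vs_near_negative = c("t_nearpos", "t_nearneg"),
      test_vs_last_training_positive = c("t_pos", "t_pos_lasttrain")))
  }

  form_test <- NULL
  oz_forms <- merge(onezero, man[, c("mouse_id", "stereotypy_form")],
                    by = "mouse_id")
  oz_forms <- oz_forms[!is.na(oz_forms$stereotypy_form) &
                         oz_forms$stereotypy_level > 0, , drop = FALSE]
  if (length(unique(oz_forms$stereotypy_form)) >= 2L) {
    form_test <- stereotypy_form_test(oz_forms$stereotypy_level,
                                      oz_forms$stereotypy_form)
  } else {
    note("fewer than two stereotypy forms expressed; form comparison skipped")
  }

  structure(list(metrics = metrics, onezero = onezero, models = models,
                 comparisons = comparisons, form_test = form_test, log = log),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d mice, %d session rows\n",
              length(unique(x$metrics$mouse_id)), nrow(x$metrics)))
  if (!is.null(x$comparisons)) {
    cat("paired comparisons:\n")
    print(as.data.frame(x$comparisons), row.names = FALSE, digits = 3)
  }
  if (!is.null(x$form_test)) print(x$form_test)
  if (length(x$log)) cat("log:", length(x$log), "entr(ies); see $log\n")
  invisible(x)
}

#' Write the results bundle as tidy CSVs
#'
#' @param results a `study_results`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$metrics, file.path(dir, "session_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(results$onezero, file.path(dir, "onezero_summary.csv"),
                   row.names = FALSE)
  if (!is.null(results$comparisons)) {
    utils::write.csv(as.data.frame(results$comparisons),
                     file.path(dir, "paired_comparisons.csv"), row.names = FALSE)
  }
  mod_rows <- list()
  for (nm in names(results$models)) {
    m <- results$models[[nm]]
    if (is.null(m)) next
    tab <- m$table
    tab$model <- nm
    mod_rows[[nm]] <- tab
  }
  if (length(mod_rows)) {
    utils::write.csv(do.call(rbind, mod_rows), file.path(dir, "model_fits.csv"),
                     row.names = FALSE)
  }
  if (!is.null(results$form_test)) {
    utils::write.csv(data.frame(statistic = results$form_test$statistic,
                                df = results$form_test$df,
                                p = results$form_test$p),
                     file.path(dir, "form_test.csv"), row.names = FALSE)
  }
  writeLines(results$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Read a study from disk
#'
#' Loads a study manifest CSV (columns `mouse_id`, `cage`, `litter`,
#' `handling`, `excluded`, `exclusion_reason`, `stream_file`, and
#' `session_file_<i>` columns pointing at tracking CSVs, with
#' `session_mode_<i>` giving `TRAINING`/`TEST`), reading each referenced
#' file. Missing or malformed files fail with the offending path.
#'
#' @param manifest_path path to the manifest CSV.
#' @param base_dir directory that relative paths resolve against.
#' @param config,design maze and observation configuration.
#' @return a `study_data`.
#' @export
read_study <- function(manifest_path, base_dir = dirname(manifest_path),
                       config = default_maze_config(),
                       design = observation_design()) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "cage", "litter", "handling", "excluded",
            "exclusion_reason", "stream_file")
  if (!all(need %in% names(man))) {
    stop("malformed manifest ", manifest_path, ": need columns ",
         paste(setdiff(need, names(man)), collapse = ", "), call. = FALSE)
  }
  man$excluded <- as.logical(man$excluded)
  sess_cols <- sort(grep("^session_file_", names(man), value = TRUE))
  mode_cols <- sub("session_file_", "session_mode_", sess_cols)
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  sessions <- list(); streams <- list()
  n_training <- 0L
  for (i in seq_len(nrow(man))) {
    id <- man$mouse_id[i]
    ss <- list()
    for (j in seq_along(sess_cols)) {
      f <- man[[sess_cols[j]]][i]
      if (is.na(f) || f == "") next
      path <- resolve(f)
      if (!file.exists(path)) stop("missing session file: ", path, call. = FALSE)
      track <- read_track_csv(path)
      mode <- man[[mode_cols[j]]][i]
      ss[[length(ss) + 1L]] <- list(track = track, visits = NULL, mode = mode,
                                    pellets = NA_integer_,
                                    session_index = length(ss) + 1L)
    }
    n_training <- max(n_training, sum(vapply(ss, function(s)
      s$mode == "TRAINING", logical(1))))
    sessions[[id]] <- ss
    sp <- resolve(man$stream_file[i])
    if (!file.exists(sp)) stop("missing stream file: ", sp, call. = FALSE)
    streams[[id]] <- read_stream_csv(sp)
  }
  structure(list(manifest = man, sessions = sessions, streams = streams,
                 config = config, design = design, n_training = n_training),
            class = "study_data")
}

#' Write a simulated study to disk
#'
#' Emits the tracking and behaviour-stream CSV dialects the readers
#' accept, plus a manifest CSV, so a simulated cohort round-trips
#' through [read_study()].
#'
#' @param study a `study_data` with tracks.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- study$manifest
  n_sess <- max(vapply(study$sessions, length, integer(1)))
  for (j in seq_len(n_sess)) {
    man[[paste0("session_file_", j)]] <- NA_character_
    man[[paste0("session_mode_", j)]] <- NA_character_
  }
  man$stream_file <- NA_character_
  for (i in seq_len(nrow(man))) {
    id <- man$mouse_id[i]
    for (j in seq_along(study$sessions[[id]])) {
      sim <- study$sessions[[id]][[j]]
      if (is.null(sim$track)) next
      f <- sprintf("%s_session%02d.csv", id, j)
      write_track_csv(sim$track, file.path(dir, f))
      man[[paste0("session_file_", j)]][i] <- f
      man[[paste0("session_mode_", j)]][i] <- sim$mode
    }
    f <- sprintf("%s_homecage.csv", id)
    write_stream_csv(study$streams[[id]], file.path(dir, f))
    man$stream_file[i] <- f
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}
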