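#' Home-cage behaviour categories
#'
#' The ethogram distinguishes general activity (`INACTIVE`, `ACTIVE`)
#' from four stereotypy forms: `BAR_MOUTHING`, `CIRCLING`,
#' `CAGE_TOP_TWIRLING`, `BACK_FLIPPING`.
#' @keywords internal
BEHAVIOUR_LABELS <- c("INACTIVE", "ACTIVE", "BAR_MOUTHING", "CIRCLING",
                      "CAGE_TOP_TWIRLING", "BACK_FLIPPING")

#' @keywords internal
STEREOTYPY_FORMS <- c("BAR_MOUTHING", "CIRCLING", "CAGE_TOP_TWIRLING",
                      "BACK_FLIPPING")

#' Home-cage observation design
#'
#' The sampling layout of the home-cage observations: within each
#' observed hour of the dark phase, each mouse is watched for the first
#' `window_length` seconds of every `window_period` seconds, and
#' behaviour is scored by one-zero sampling in `sample_interval`-second
#' slots. The default (hours 2, 3, 6 and 7 on 2 days; 5 min of every
#' 20 min; 30-s slots) yields 30 slots per hour and 240 per mouse.
#'
#' @param observed_hours 1-based hour indices within the dark phase.
#' @param days number of observation days.
#' @param window_length observation window length (s).
#' @param window_period window repeat period (s); `window_length` must
#'   not exceed it.
#' @param sample_interval one-zero slot length (s); must divide
#'   `window_length`.
#' @param day_offset seconds between the starts of consecutive
#'   observation days (default one day).
#' @return object of class `observation_design`.
#' @export
observation_design <- function(observed_hours = c(2L, 3L, 6L, 7L),
                               days = 2L,
                               window_length = 300,
                               window_period = 1200,
                               sample_interval = 30,
                               day_offset = 86400) {
  if (window_length > window_period) {
    stop("window_length must not exceed window_period", call. = FALSE)
  }
  if (window_length %% sample_interval != 0) {
    stop("sample_interval must divide window_length", call. = FALSE)
  }
  stopifnot(days >= 1L, length(observed_hours) >= 1L, all(observed_hours >= 1L))
  structure(
    list(observed_hours = as.integer(observed_hours), days = as.integer(days),
         window_length = window_length, window_period = window_period,
         sample_interval = sample_interval, day_offset = day_offset),
    class = "observation_design"
  )
}

#' Scheduled one-zero observation slots
#'
#' Expands an [observation_design()] into the absolute 30-s slots:
#' within each observed hour, the `window_length / sample_interval`
#' slots of the first `window_length` seconds of every `window_period`
#' seconds. Times are seconds from the start of the first day's dark
#' phase; intervals are half-open `[slot_start, slot_end)`.
#'
#' @param design an `observation_design`.
#' @return data.frame with columns `day`, `hour`, `window`, `slot`,
#'   `slot_start`, `slot_end`.
#' @export
schedule_observations <- function(design) {
  stopifnot(inherits(design, "observation_design"))
  wins_per_hour <- floor(3600 / design$window_period)
  slots_per_win <- design$window_length / design$sample_interval
  grid <- expand.grid(slot = seq_len(slots_per_win),
                      window = seq_len(wins_per_hour),
                      hour = design$observed_hours,
                      day = seq_len(design$days))
  start <- (grid$day - 1L) * design$day_offset +
    (grid$hour - 1L) * 3600 +
    (grid$window - 1L) * design$window_period +
    (grid$slot - 1L) * design$sample_interval
  out <- data.frame(day = grid$day, hour = grid$hour, window = grid$window,
                    slot = grid$slot, slot_start = start,
                    slot_end = start + design$sample_interval)
  out[order(out$slot_start), , drop = FALSE]
}

#' Build a behaviour stream
#'
#' Labelled, non-overlapping, time-ordered home-cage behaviour
#' intervals for one mouse.
#' @param behaviour labels from the ethogram (see `BEHAVIOUR_LABELS`).
#' @param start_s,end_s interval bounds (s), half-open.
#' @param mouse_id identifier.
#' @return data.frame of class `behavior_stream`.
#' @export
behavior_stream <- function(behaviour, start_s, end_s, mouse_id = NA_character_) {
  stopifnot(length(start_s) == length(behaviour), length(end_s) == length(behaviour))
  bad <- setdiff(unique(behaviour), BEHAVIOUR_LABELS)
  if (length(bad)) {
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(end_s <= start_s)) stop("intervals must have end_s > start_s", call. = FALSE)
  o <- order(start_s)
  s <- start_s[o]; e <- end_s[o]
  if (length(s) > 1L && any(s[-1] < e[-length(e)] - 1e-9)) {
    stop("behaviour intervals overlap", call. = FALSE)
  }
  structure(
    data.frame(mouse_id = mouse_id, behaviour = behaviour[o],
               start_s = s, end_s = e, stringsAsFactors = FALSE),
    class = c("behavior_stream", "data.frame")
  )
}

#' Classify stereotypy bouts
#'
#' Merges same-form stereotypy intervals separated by pauses of at most
#' `gap_max` seconds into runs, then qualifies each run: bar-mouthing
#' qualifies when the summed movement time (pauses excluded) reaches
#' `barmouth_min_s`; cage-top twirling, back-flipping and (by analogy,
#' configurable) circling qualify at `min_repetitions` merged intervals.
#' Non-qualifying runs are left out of the bout list and therefore count
#' as generic activity in downstream one-zero scoring.
#'
#' @param stream a `behavior_stream`.
#' @param gap_max longest pause (s) bridged within a run.
#' @param barmouth_min_s minimum summed duration (s) for bar-mouthing.
#' @param min_repetitions minimum repetitions for the repetition-scored
#'   forms.
#' @param repetition_forms forms scored by repetitions rather than
#'   duration.
#' @return data.frame of class `stereotypy_bouts`: `form`, `start_s`,
#'   `end_s` (run span), `repetitions`, `duration` (summed movement
#'   time, pauses excluded).
#' @export
classify_stereotypy_bouts <- function(stream, gap_max = 3,
                                      barmouth_min_s = 10,
                                      min_repetitions = 3L,
                                      repetition_forms = c("CAGE_TOP_TWIRLING",
                                                           "BACK_FLIPPING",
                                                           "CIRCLING")) {
  bad <- setdiff(unique(stream$behaviour), BEHAVIOUR_LABELS)
  if (length(bad)) {
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bouts <- list()
  beh <- stream$behaviour
  for (form in STEREOTYPY_FORMS) {
    sel <- which(beh == form)
    if (!length(sel)) next
    s <- stream$start_s[sel]; e <- stream$end_s[sel]
    o <- order(s); s <- s[o]; e <- e[o]
    m <- length(s)
    run_id <- cumsum(c(TRUE, s[-1] - e[-m] > gap_max))
    reps <- tabulate(run_id)
    dur <- as.vector(rowsum(e - s, run_id))
    first <- which(!duplicated(run_id))
    last <- c(first[-1] - 1L, m)
    ok <- if (form %in% repetition_forms) reps >= min_repetitions else
      dur >= barmouth_min_s
    if (any(ok)) {
      bouts[[length(bouts) + 1L]] <- quick_df(list(
        form = rep(form, sum(ok)), start_s = s[first][ok], end_s = e[last][ok],
        repetitions = as.integer(reps[ok]), duration = dur[ok]))
    }
  }
  out <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(form = character(0), start_s = numeric(0), end_s = numeric(0),
               repetitions = integer(0), duration = numeric(0))
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stereotypy_bouts", "data.frame")
  out
}

#' Observed-hour time blocks of a design
#'
#' One block per observed hour per day, in the absolute time base of
#' [schedule_observations()]. Useful as the `windows` argument of the
#' home-cage simulator.
#' @param design an `observation_design`.
#' @return data.frame with columns `start`, `end`.
#' @export
observed_windows <- function(design) {
  stopifnot(inherits(design, "observation_design"))
  g <- expand.grid(hour = design$observed_hours, day = seq_len(design$days))
  start <- (g$day - 1L) * design$day_offset + (g$hour - 1L) * 3600
  out <- data.frame(start = start, end = start + 3600)
  out[order(out$start), , drop = FALSE]
}

# for each query interval [s, e), whether any of the sorted, disjoint
# reference intervals overlaps it; returns the slot-indexed logical via
# contiguous index ranges (slots are sorted and disjoint)
mark_overlaps <- function(slot_start, slot_end, iv_start, iv_end) {
  hit <- logical(length(slot_start))
  if (!length(iv_start)) return(hit)
  o <- order(iv_start)
  iv_start <- iv_start[o]; iv_end <- iv_end[o]
  # slot k overlaps interval i iff slot_start[k] < iv_end[i] and
  # slot_end[k] > iv_start[i]; slots sorted -> contiguous range per interval
  lo <- findInterval(iv_start, slot_end, left.open = FALSE) + 1L
  hi <- findInterval(iv_end, slot_start, left.open = TRUE)
  for (i in seq_along(iv_start)) {
    if (lo[i] <= hi[i]) hit[lo[i]:hi[i]] <- TRUE
  }
  hit
}

#' One-zero sampling of a behaviour stream
#'
#' Scores each scheduled slot 1 for a category iff any overlap exists
#' between the slot and an interval of that category (one-zero rule).
#' A slot is *active* iff any non-twitch activity overlaps it: activity
#' intervals no longer than `twitch_max_s` count as twitches (the
#' inactivity definition allows brief single twitches of up to 5 s);
#' stereotypy-form intervals always count as activity. A slot is
#' *stereotypic* iff a qualifying bout (from
#' [classify_stereotypy_bouts()]) overlaps it; stereotypic slots are a
#' subset of active slots. Slots not fully covered by the stream are
#' handled per `on_gap`.
#'
#' @param stream a `behavior_stream` covering the scheduled windows.
#' @param bouts qualifying bouts, e.g. from
#'   [classify_stereotypy_bouts()].
#' @param design an `observation_design`.
#' @param twitch_max_s longest activity interval still counted as a
#'   twitch (s).
#' @param on_gap `"unobserved"` (default: slot excluded from summaries)
#'   or `"error"`.
#' @return object of class `one_zero_matrix`: the slot table with
#'   columns `active`, `stereotypic`, `observed`, plus summary fields
#'   `activity` (active / observed slots) and `stereotypy_level`
#'   (stereotypic / active slots, `NA` when no active slot).
#' @export
one_zero_score <- function(stream, bouts, design,
                           twitch_max_s = 5,
                           on_gap = c("unobserved", "error")) {
  on_gap <- match.arg(on_gap)
  slots <- schedule_observations(design)
  act <- stream[stream$behaviour != "INACTIVE", , drop = FALSE]
  is_twitch <- act$behaviour == "ACTIVE" & (act$end_s - act$start_s) <= twitch_max_s
  act <- act[!is_twitch, , drop = FALSE]

  n <- nrow(slots)
  active <- mark_overlaps(slots$slot_start, slots$slot_end,
                          act$start_s, act$end_s)
  stereo <- mark_overlaps(slots$slot_start, slots$slot_end,
                          bouts$start_s, bouts$end_s)
  # coverage check uses all intervals, including INACTIVE; the stream is
  # sorted and non-overlapping, so covered time in [0, t) is cumulative
  cov_s <- stream$start_s; cov_e <- stream$end_s
  cum <- c(0, cumsum(cov_e - cov_s))
  cov_at <- function(t) {
    i <- findInterval(t, cov_s)
    cum[i + 1L] - pmax(0, cov_e[pmax(i, 1L)] - t) * (i > 0L)
  }
  covered <- cov_at(slots$slot_end) - cov_at(slots$slot_start)
  observed <- covered >= (slots$slot_end - slots$slot_start) - 1e-9
  if (on_gap == "error" && any(!observed)) {
    stop("behaviour stream has gaps within ", sum(!observed),
         " scheduled slot(s)", call. = FALSE)
  }
  stereo <- stereo & active  # a stereotypic slot is by definition active
  slots$active <- as.integer(active)
  slots$stereotypic <- as.integer(stereo)
  slots$observed <- observed
  n_obs <- sum(observed)
  n_act <- sum(active & observed)
  structure(
    list(mouse_id = stream$mouse_id[1L], slots = slots,
         n_slots = n, n_observed = n_obs,
         activity = if (n_obs > 0) n_act / n_obs else NA_real_,
         stereotypy_level = if (n_act > 0)
           sum(stereo & observed) / n_act else NA_real_),
    class = "one_zero_matrix"
  )
}

#' @export
print.one_zero_matrix <- function(x, ...) {
  cat(sprintf("<one_zero_matrix> mouse %s: %d slots (%d observed), activity %.3f, stereotypy level %s\n",
              x$mouse_id, x$n_slots, x$n_observed, x$activity,
              ifelse(is.na(x$stereotypy_level), "NA",
                     sprintf("%.3f", x$stereotypy_level))))
  invisible(x)
}

#' Read / write behaviour stream CSV
#'
#' Fixed dialect: columns `mouse_id`, `behaviour`, `start_s`, `end_s`.
#' @param path file path.
#' @param stream a `behavior_stream`.
#' @return `read_stream_csv` returns a `behavior_stream`.
#' @export
read_stream_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "behaviour", "start_s", "end_s")
  if (!all(need %in% names(d))) {
    stop("malformed behaviour stream CSV ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  behavior_stream(d$behaviour, d$start_s, d$end_s, mouse_id = d$mouse_id[1L])
}

#' @rdname read_stream_csv
#' @export
write_stream_csv <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE)
  invisible(path)
}
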