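#' Per-session occupancy, entry and activity metrics
#'
#' Aggregates arm visits (and optionally the raw track) of one session
#' into role-level occupancy proportions, entry counts and proportions,
#' centre occupancy, running speed and pellet count. Occupancy is
#' expressed relative to trial duration (`config$session_duration`);
#' entry proportions are relative to all arms entered.
#'
#' @param visits visit data.frame (`arm`, `t_enter`, `t_exit`,
#'   `reached_end`, `t_reach_end`).
#' @param mode `"TRAINING"` or `"TEST"`. Training sessions containing
#'   visits to ambiguous arms are protocol errors.
#' @param config a `maze_config`.
#' @param track optional `maze_track` (enables centre time and speed).
#' @param mouse_id,session_id identifiers carried through.
#' @param pellets pellet count for the session (e.g. from the actuator
#'   log), or `NA`.
#' @return object of class `session_metrics`: lists `time_in` and
#'   `entries` keyed by role, `entry_prop`, `time_center`,
#'   `total_entries`, `speed`, `pellets`.
#' @export
session_metrics <- function(visits, mode, config, track = NULL,
                            mouse_id = NA_character_, session_id = NA_integer_,
                            pellets = NA_integer_) {
  mode <- match.arg(mode, c("TRAINING", "TEST"))
  roles <- ARM_ROLES
  if (nrow(visits)) {
    vrole <- arm_role(visits$arm, config)
    if (mode == "TRAINING" && any(vrole %in% c("NEAR_POSITIVE", "NEAR_NEGATIVE"))) {
      stop("protocol error: TRAINING session contains visits to ambiguous arms",
           call. = FALSE)
    }
    dur <- visits$t_exit - visits$t_enter
    time_in <- vapply(roles, function(r) sum(dur[vrole == r]), numeric(1)) /
      config$session_duration
    entries <- vapply(roles, function(r) sum(vrole == r), integer(1))
  } else {
    time_in <- stats::setNames(numeric(length(roles)), roles)
    entries <- stats::setNames(integer(length(roles)), roles)
  }
  total <- sum(entries)
  entry_prop <- if (total > 0) entries / total else
    stats::setNames(rep(NA_real_, length(roles)), roles)
  time_center <- NA_real_
  speed <- NA_real_
  if (!is.null(track)) {
    det <- track$detected & !is.na(track$x_cm)
    if (any(det)) {
      zone <- assign_zone(track$x_cm[det], track$y_cm[det], config)
      dt <- stats::median(diff(track$time_s))
      time_center <- sum(zone == "CENTER") * dt / config$session_duration
    }
    speed <- tryCatch(mean_speed(track), error = function(e) NA_real_)
  }
  structure(
    list(mouse_id = mouse_id, session_id = session_id, mode = mode,
         time_in = as.list(time_in), time_center = time_center,
         entries = as.list(entries), entry_prop = as.list(entry_prop),
         total_entries = total, speed = speed, pellets = pellets),
    class = "session_metrics"
  )
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("<session_metrics> mouse %s session %s (%s)\n",
              x$mouse_id, x$session_id, x$mode))
  cat(sprintf("  occupancy: pos %.3f neg %.3f near-pos %.3f near-neg %.3f center %.3f\n",
              x$time_in$POSITIVE, x$time_in$NEGATIVE, x$time_in$NEAR_POSITIVE,
              x$time_in$NEAR_NEGATIVE, x$time_center))
  cat(sprintf("  entries: %d total, speed %.2f cm/s, pellets %s\n",
              x$total_entries, x$speed, x$pellets))
  invisible(x)
}

#' Flatten session metrics into a one-row data.frame
#' @param m a `session_metrics`.
#' @return one-row data.frame.
#' @export
metrics_row <- function(m) {
  data.frame(
    mouse_id = m$mouse_id, session_id = m$session_id, mode = m$mode,
    t_pos = m$time_in$POSITIVE, t_neg = m$time_in$NEGATIVE,
    t_nearpos = m$time_in$NEAR_POSITIVE, t_nearneg = m$time_in$NEAR_NEGATIVE,
    t_center = m$time_center,
    n_pos = m$entries$POSITIVE, n_neg = m$entries$NEGATIVE,
    n_nearpos = m$entries$NEAR_POSITIVE, n_nearneg = m$entries$NEAR_NEGATIVE,
    p_pos = m$entry_prop$POSITIVE, p_neg = m$entry_prop$NEGATIVE,
    p_nearpos = m$entry_prop$NEAR_POSITIVE, p_nearneg = m$entry_prop$NEAR_NEGATIVE,
    total_entries = m$total_entries, speed = m$speed,
    pellets = as.integer(m$pellets),
    stringsAsFactors = FALSE
  )
}

#' Arm-preference scores
#'
#' Difference-over-sum occupancy indices. With `T_ref = T_pos + T_neg`
#' and `T_amb = T_nearpos + T_nearneg`:
#' \itemize{
#'   \item reference arm score `(T_ref - T_amb) / (T_ref + T_amb)` —
#'     higher means more time in reference arms, less in ambiguous arms;
#'   \item positive arm score `(T_pos - T_neg) / T_ref`;
#'   \item near-positive arm score `(T_nearpos - T_nearneg) / T_amb`.
#' }
#' Denominators use time in arms only (centre time excluded). A zero
#' denominator yields `NA` (undefined, not zero), which propagates into
#' downstream statistics as missing. In `TRAINING` mode the ambiguous
#' arms are closed, so only the positive arm score is defined.
#'
#' @param m a `session_metrics`, or `NULL` when passing occupancies
#'   directly.
#' @param t_pos,t_neg,t_nearpos,t_nearneg occupancy times (any common
#'   unit; scores are scale-invariant).
#' @param mode `"TRAINING"` or `"TEST"`.
#' @return object of class `arm_scores`: `reference_arm_score`,
#'   `positive_arm_score`, `near_positive_arm_score`.
#' @examples
#' compute_arm_scores(t_pos = 0.20, t_neg = 0.11,
#'                    t_nearpos = 0.26, t_nearneg = 0.20)
#' @export
compute_arm_scores <- function(m = NULL, t_pos, t_neg,
                               t_nearpos = NA_real_, t_nearneg = NA_real_,
                               mode = "TEST") {
  if (!is.null(m)) {
    stopifnot(inherits(m, "session_metrics"))
    t_pos <- m$time_in$POSITIVE; t_neg <- m$time_in$NEGATIVE
    t_nearpos <- m$time_in$NEAR_POSITIVE; t_nearneg <- m$time_in$NEAR_NEGATIVE
    mode <- m$mode
  }
  mode <- match.arg(mode, c("TRAINING", "TEST"))
  safe_ratio <- function(num, den) if (is.na(den) || den <= 0) NA_real_ else num / den
  t_ref <- t_pos + t_neg
  positive <- safe_ratio(t_pos - t_neg, t_ref)
  if (mode == "TRAINING") {
    reference <- NA_real_
    near_positive <- NA_real_
  } else {
    t_amb <- t_nearpos + t_nearneg
    reference <- safe_ratio(t_ref - t_amb, t_ref + t_amb)
    near_positive <- safe_ratio(t_nearpos - t_nearneg, t_amb)
  }
  structure(list(reference_arm_score = reference,
                 positive_arm_score = positive,
                 near_positive_arm_score = near_positive),
            class = "arm_scores")
}

#' @export
print.arm_scores <- function(x, ...) {
  cat(sprintf("<arm_scores> reference %.4f, positive %.4f, near-positive %.4f\n",
              x$reference_arm_score, x$positive_arm_score,
              x$near_positive_arm_score))
  invisible(x)
}
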