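#' Build a tracking sample table
#'
#' @param time_s sample times (s), strictly increasing.
#' @param x_cm,y_cm coordinates in cm (maze centroid at origin, arm 0
#'   along +x, arms counter-clockwise). `NA` allowed where undetected.
#' @param detected logical: subject found in this sample.
#' @param skipped logical: sample skipped by the tracker.
#' @return data.frame of class `maze_track`.
#' @export
maze_track <- function(time_s, x_cm, y_cm,
                       detected = rep(TRUE, length(time_s)),
                       skipped = rep(FALSE, length(time_s))) {
  stopifnot(length(x_cm) == length(time_s), length(y_cm) == length(time_s))
  if (length(time_s) && any(diff(time_s) <= 0)) {
    stop("track samples must be strictly time-ordered", call. = FALSE)
  }
  structure(
    data.frame(time_s = as.numeric(time_s), x_cm = as.numeric(x_cm),
               y_cm = as.numeric(y_cm), detected = as.logical(detected),
               skipped = as.logical(skipped)),
    class = c("maze_track", "data.frame")
  )
}

#' Assign maze zones to tracked points
#'
#' Classifies points as `CENTER`, `ARM_<i>`, `ARM_END_<i>` or
#' `OUT_OF_MAZE`. Arm i occupies the rectangle of width `arm_width`
#' extending radially from the central-arena radius to radius + arm
#' length along the arm's axis (angle 2*pi*i/n). The distal
#' `end_zone_length` of an arm is its end zone. Boundary tie-breaks: an
#' arm beats the centre (entry triggers fire at first touch) and the end
#' zone beats the rest of the arm.
#'
#' @param x,y coordinates (cm), vectorised.
#' @param config a `maze_config`.
#' @return character vector of zone labels.
#' @export
assign_zone <- function(x, y, config) {
  n <- config$n_arms
  rc <- config$center_diameter / 2
  L <- config$arm_length
  w2 <- config$arm_width / 2
  ez <- config$end_zone_length
  zone <- rep(NA_character_, length(x))
  r2 <- x^2 + y^2
  for (i in seq_len(n) - 1L) {
    th <- 2 * pi * i / n
    xr <- x * cos(th) + y * sin(th)
    yr <- -x * sin(th) + y * cos(th)
    inarm <- is.na(zone) & xr >= rc & xr <= rc + L & abs(yr) <= w2
    inend <- inarm & xr >= rc + L - ez
    zone[inend] <- paste0("ARM_END_", i)
    zone[inarm & !inend] <- paste0("ARM_", i)
  }
  zone[is.na(zone) & r2 <= rc^2] <- "CENTER"
  zone[is.na(zone)] <- "OUT_OF_MAZE"
  zone[is.na(x) | is.na(y)] <- NA_character_
  zone
}

zone_arm <- function(zone) {
  arm <- rep(NA_integer_, length(zone))
  is_arm <- grepl("^ARM_", zone)
  arm[is_arm] <- as.integer(sub("^ARM_(END_)?", "", zone[is_arm]))
  arm
}

#' Per-trial tracking quality control
#'
#' A trial passes QC iff both the percentage of samples in which the
#' subject was not found and the percentage of skipped samples are
#' strictly below 1%.
#'
#' @param track a `maze_track`.
#' @param threshold_pct QC threshold in percent (default 1, strict `<`).
#' @return list of class `trial_qc`: `pct_not_found`, `pct_skipped`,
#'   `passed`.
#' @export
trial_qc <- function(track, threshold_pct = 1) {
  n <- nrow(track)
  if (n == 0L) stop("empty track", call. = FALSE)
  pnf <- 100 * sum(!track$detected) / n
  psk <- 100 * sum(track$skipped) / n
  structure(list(pct_not_found = pnf, pct_skipped = psk,
                 passed = pnf < threshold_pct && psk < threshold_pct),
            class = "trial_qc")
}

#' @export
print.trial_qc <- function(x, ...) {
  cat(sprintf("<trial_qc> not found %.3f%%, skipped %.3f%% -> %s\n",
              x$pct_not_found, x$pct_skipped,
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Mean running speed
#'
#' Total path length over pairs of raw-consecutive detected samples,
#' divided by the elapsed time spanned by those pairs. No smoothing.
#'
#' @param track a `maze_track`.
#' @return speed in cm/s.
#' @export
mean_speed <- function(track) {
  d <- track[track$detected & !is.na(track$x_cm), , drop = FALSE]
  if (nrow(d) < 2L) stop("mean_speed needs at least 2 detected samples", call. = FALSE)
  det_idx <- which(track$detected & !is.na(track$x_cm))
  consec <- diff(det_idx) == 1L
  if (!any(consec)) stop("no consecutive detected sample pairs", call. = FALSE)
  i <- det_idx[c(consec, FALSE)]
  dx <- track$x_cm[i + 1L] - track$x_cm[i]
  dy <- track$y_cm[i + 1L] - track$y_cm[i]
  dt <- track$time_s[i + 1L] - track$time_s[i]
  sum(sqrt(dx^2 + dy^2)) / sum(dt)
}

#' Extract arm visits and maze events from a track
#'
#' Segments the detected samples into zone dwells. `ENTER_ARM` is
#' emitted at the first sample inside an arm after a non-arm zone,
#' `REACH_END` at the first end-zone sample of the visit, `EXIT_ARM` at
#' the first sample outside the arm, and `ENTER_CENTER` at the first
#' centre sample after a non-centre zone (or at track start).
#' Undetected gaps no longer than `gap_max` seconds with the same zone
#' on both sides are bridged; longer gaps split visits, with the exit
#' stamped one nominal sample interval after the last detected sample.
#' Intervals are half-open `[t_enter, t_exit)`.
#'
#' @param track a `maze_track`.
#' @param config a `maze_config`.
#' @param gap_max maximum undetected gap (s) bridged within one zone.
#' @return list with `visits` (data.frame `arm`, `t_enter`, `t_exit`,
#'   `reached_end`, `t_reach_end`) and `events` (data.frame `time`,
#'   `kind`, `arm`), exclusive of session start/end markers.
#' @export
visits_from_track <- function(track, config, gap_max = 0.5) {
  if (nrow(track) == 0L) stop("empty track", call. = FALSE)
  if (nrow(track) < 2L) stop("track shorter than one sample interval", call. = FALSE)
  det <- which(track$detected & !is.na(track$x_cm))
  if (length(det) < 1L) stop("no detected samples", call. = FALSE)
  t <- track$time_s[det]
  dt_nom <- stats::median(diff(track$time_s))
  zone <- assign_zone(track$x_cm[det], track$y_cm[det], config)
  arm <- zone_arm(zone)
  grp <- ifelse(is.na(arm), ifelse(zone == "CENTER", "C", "O"), paste0("A", arm))

  # segment boundaries: zone-group change, or undetected gap > gap_max
  nseg_break <- c(TRUE, grp[-1] != grp[-length(grp)] | diff(t) > gap_max)
  seg_id <- cumsum(nseg_break)
  nseg <- max(seg_id)
  first <- match(seq_len(nseg), seg_id)
  last <- length(seg_id) + 1L - match(seq_len(nseg), rev(seg_id))

  acc <- new_visit_event_acc()
  prev_grp <- ""
  for (s in seq_len(nseg)) {
    f <- first[s]; l <- last[s]
    g <- grp[f]
    t_enter <- t[f]
    t_exit <- if (s < nseg && grp[first[s + 1L]] != g) t[first[s + 1L]] else
      t[l] + dt_nom
    if (startsWith(g, "A")) {
      a <- arm[f]
      end_idx <- f - 1L + which(zone[f:l] == paste0("ARM_END_", a))
      reached <- length(end_idx) > 0L
      t_reach <- if (reached) t[end_idx[1L]] else NA_real_
      acc$visit(a, t_enter, t_exit, reached, t_reach)
    } else if (g == "C" && prev_grp != "C") {
      acc$ev(t_enter, "ENTER_CENTER", NA_integer_)
    }
    prev_grp <- g
  }
  acc$result()
}

#' Wrap visit events into a full session event log
#'
#' Prepends `SESSION_START` at `t0` and appends `SESSION_END` at
#' `t_end`, yielding a log suitable for [replay_contingencies()].
#' @param events event data.frame from [visits_from_track()].
#' @param t0 session start time (s).
#' @param t_end session end time (s).
#' @return event data.frame.
#' @export
session_events <- function(events, t0 = 0, t_end) {
  rbind(maze_event(t0, "SESSION_START"), events, maze_event(t_end, "SESSION_END"))
}

#' Read / write tracking CSV
#'
#' Fixed dialect: columns `time_s`, `x_cm`, `y_cm`, `detected`,
#' `skipped` (logical as 0/1).
#' @param path file path.
#' @param track a `maze_track`.
#' @return `read_track_csv` returns a `maze_track`.
#' @export
read_track_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_cm", "y_cm", "detected", "skipped")
  if (!all(need %in% names(d))) {
    stop("malformed tracking CSV ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  maze_track(d$time_s, d$x_cm, d$y_cm, as.logical(d$detected), as.logical(d$skipped))
}

#' @rdname read_track_csv
#' @export
write_track_csv <- function(track, path) {
  out <- track
  out$detected <- as.integer(out$detected)
  out$skipped <- as.integer(out$skipped)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
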