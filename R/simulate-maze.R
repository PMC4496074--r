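#' Agent parameters for the maze exploration simulator
#'
#' The simulator is a semi-Markov walk over maze zones: the agent
#' alternates centre dwells and arm visits, choosing among open arms by
#' a softmax over role utilities
#' `u(arm) = valence_bias * v(role) - ambiguity_aversion * w(role) * novelty(arm)`
#' with valence `v` = +1 / -1 for positive / negative arms and +0.5 /
#' -0.5 for near-positive / near-negative arms. The novelty term decays
#' with the number of visits to an arm (`1 / (1 + visits)`) and applies
#' only to the ambiguous arms, weighted asymmetrically (`w`): the
#' near-negative arms carry more of the aversion, emulating the
#' conflict between exploratory drive and neophobia tilted by the
#' adjacent negative cue. Dwell times are exponential; arm dwell means
#' are modulated by `exp(dwell_gain * u)` so preferred arms also hold
#' the agent longer.
#'
#' @param valence_bias preference weight for positive over negative
#'   arms, in `[-1, 1]`.
#' @param ambiguity_aversion reluctance to enter unvisited ambiguous
#'   arms (>= 0).
#' @param activity_rate arm transitions per minute (> 0).
#' @param speed_mean target running speed, cm/s.
#' @param end_reach_prob probability of reaching the arm end per visit.
#' @param learning_rate per-session increment of the effective valence
#'   bias during training.
#' @param choice_sharpness softmax inverse temperature.
#' @param dwell_gain modulation of arm dwell time by utility.
#' @param novelty_weights aversion weights for the two ambiguous roles.
#' @param circler if `TRUE` the agent circles in the central arena for
#'   the whole session and never enters an arm (exclusion-flag
#'   exerciser).
#' @param seed integer RNG seed.
#' @return object of class `agent_params`.
#' @export
agent_params <- function(valence_bias = 0.2,
                         ambiguity_aversion = 0.5,
                         activity_rate = 5,
                         speed_mean = 10,
                         end_reach_prob = 0.85,
                         learning_rate = 0.06,
                         choice_sharpness = 1.5,
                         dwell_gain = 0.4,
                         novelty_weights = c(NEAR_POSITIVE = 0.7, NEAR_NEGATIVE = 1.3),
                         circler = FALSE,
                         seed = 1L) {
  stopifnot(valence_bias >= -1, valence_bias <= 1,
            ambiguity_aversion >= 0, activity_rate > 0,
            end_reach_prob >= 0, end_reach_prob <= 1)
  structure(
    list(valence_bias = valence_bias, ambiguity_aversion = ambiguity_aversion,
         activity_rate = activity_rate, speed_mean = speed_mean,
         end_reach_prob = end_reach_prob, learning_rate = learning_rate,
         choice_sharpness = choice_sharpness, dwell_gain = dwell_gain,
         novelty_weights = novelty_weights, circler = circler,
         seed = as.integer(seed)),
    class = "agent_params"
  )
}

ROLE_VALENCE <- c(POSITIVE = 1, NEGATIVE = -1,
                  NEAR_POSITIVE = 0.5, NEAR_NEGATIVE = -0.5)

# run code with an isolated, seeded RNG stream, restoring global state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + as.double(index) * 9973) %% 2147483629)
}

#' Simulate one maze session with known ground truth
#'
#' Generates a session as a sequence of zone dwells aligned to the
#' tracking sample grid, then derives (a) the ground-truth visit table,
#' (b) the session event log, (c) the actuator log obtained by replaying
#' the events through [contingency_step()], and optionally (d) a
#' tracking export whose per-sample zones reproduce the dwell sequence
#' exactly, so that [visits_from_track()] recovers the ground truth
#' bit-for-bit on gap-free tracks.
#'
#' @param params an `agent_params`.
#' @param mode `"TRAINING"` or `"TEST"`.
#' @param config a `maze_config`.
#' @param session_index 1-based session number; the effective valence
#'   bias is `valence_bias + learning_rate * (session_index - 1)`,
#'   clamped to `[-1, 1]`.
#' @param sample_rate tracking sample rate, samples/s.
#' @param make_track generate the tracking export (set `FALSE` for fast
#'   visit-level simulation).
#' @param p_not_found,p_skipped per-sample probabilities of tracker
#'   dropout flags (default 0; non-zero values exercise the QC rule).
#' @return list of class `sim_session`: `track` (or `NULL`), `visits`,
#'   `events` (including session start/end), `actuator_log`, `state`
#'   (final contingency state), `pellets`, `effective_bias`, `mode`.
#' @export
simulate_session <- function(params, mode = "TRAINING",
                             config = default_maze_config(),
                             session_index = 1L,
                             sample_rate = 10,
                             make_track = TRUE,
                             p_not_found = 0, p_skipped = 0) {
  mode <- match.arg(mode, c("TRAINING", "TEST"))
  stopifnot(inherits(params, "agent_params"))
  with_local_seed(derive_seed(params$seed, session_index), {
    dt <- 1 / sample_rate
    n <- as.integer(round(config$session_duration * sample_rate))
    tt <- (seq_len(n) - 1L) * dt
    dt_nom <- stats::median(diff(tt))

    b_eff <- max(-1, min(1, params$valence_bias +
                           params$learning_rate * (session_index - 1L)))
    arms_open <- open_arms(mode, config)
    roles <- arm_role(arms_open, config)
    visit_count <- stats::setNames(rep(0L, length(arms_open)), arms_open)

    cycle_s <- 60 / params$activity_rate
    c_mean <- 0.4 * cycle_s
    a_mean <- 0.6 * cycle_s

    # segments in integer sample units: list(zone = "C" | arm index, k0, k1, kreach)
    segs <- list()
    k <- 0L
    snap <- function(x, lo = 1L) max(lo, as.integer(ceiling(x / dt)))
    if (params$circler) {
      segs[[1L]] <- list(zone = "C", k0 = 0L, k1 = n, kreach = NA_integer_)
      k <- n
    }
    while (k < n) {
      dc <- snap(stats::rexp(1, 1 / c_mean))
      k1 <- min(k + dc, n)
      segs[[length(segs) + 1L]] <- list(zone = "C", k0 = k, k1 = k1,
                                        kreach = NA_integer_)
      k <- k1
      if (k >= n) break

      nov <- ifelse(roles %in% c("NEAR_POSITIVE", "NEAR_NEGATIVE"),
                    params$novelty_weights[roles] / (1 + visit_count), 0)
      u <- b_eff * ROLE_VALENCE[roles] - params$ambiguity_aversion * nov
      p <- exp(params$choice_sharpness * (u - max(u)))
      pick <- sample(seq_along(arms_open), 1L, prob = p)
      a <- arms_open[pick]
      visit_count[pick] <- visit_count[pick] + 1L

      dwell_mult <- min(3, max(1 / 3, exp(params$dwell_gain * u[pick])))
      da <- snap(stats::rexp(1, 1 / (a_mean * dwell_mult)), lo = 2L)
      k1 <- min(k + da, n)
      kreach <- NA_integer_
      if (k1 - k >= 2L && stats::runif(1) < params$end_reach_prob) {
        kreach <- k + max(1L, as.integer(round((k1 - k) * 0.4)))
      }
      segs[[length(segs) + 1L]] <- list(zone = a, k0 = k, k1 = k1, kreach = kreach)
      k <- k1
    }

    gt <- segments_to_truth(segs, tt, dt_nom, n)
    events <- session_events(gt$events, t0 = 0, t_end = config$session_duration)
    replay <- replay_contingencies(events, config, mode)

    track <- NULL
    if (make_track) {
      track <- track_from_segments(segs, tt, config, params$speed_mean)
      if (p_not_found > 0) {
        drop <- stats::runif(n) < p_not_found
        track$detected[drop] <- FALSE
        track$x_cm[drop] <- NA_real_
        track$y_cm[drop] <- NA_real_
      }
      if (p_skipped > 0) {
        track$skipped <- stats::runif(n) < p_skipped
      }
    }

    structure(
      list(track = track, visits = gt$visits, events = events,
           actuator_log = replay$log, state = replay$state,
           pellets = replay$state$pellets_dispensed,
           effective_bias = b_eff, mode = mode, session_index = session_index),
      class = "sim_session"
    )
  })
}

# ground-truth visits + event list using the same timing conventions as
# visits_from_track (enter at first sample, exit at next segment's first
# sample, end-of-track exit one nominal interval after the last sample)
segments_to_truth <- function(segs, tt, dt_nom, n) {
  acc <- new_visit_event_acc()
  t_of <- function(k) if (k >= n) tt[n] + dt_nom else tt[k + 1L]
  prev_center <- FALSE
  for (s in segs) {
    t_enter <- tt[s$k0 + 1L]
    t_exit <- t_of(s$k1)
    if (identical(s$zone, "C")) {
      if (!prev_center) acc$ev(t_enter, "ENTER_CENTER", NA_integer_)
      prev_center <- TRUE
    } else {
      reached <- !is.na(s$kreach)
      t_reach <- if (reached) tt[s$kreach + 1L] else NA_real_
      acc$visit(s$zone, t_enter, t_exit, reached, t_reach)
      prev_center <- FALSE
    }
  }
  acc$result()
}

# shared accumulator for visit tables and their event streams, so the
# simulator's ground truth and visits_from_track build byte-identical
# structures
new_visit_event_acc <- function() {
  v_arm <- integer(0); v_en <- numeric(0); v_ex <- numeric(0)
  v_re <- logical(0); v_tr <- numeric(0)
  e_t <- numeric(0); e_k <- character(0); e_a <- integer(0)
  ev <- function(time, kind, arm) {
    e_t <<- c(e_t, time); e_k <<- c(e_k, kind); e_a <<- c(e_a, arm)
  }
  visit <- function(arm, t_enter, t_exit, reached, t_reach) {
    v_arm <<- c(v_arm, arm); v_en <<- c(v_en, t_enter); v_ex <<- c(v_ex, t_exit)
    v_re <<- c(v_re, reached); v_tr <<- c(v_tr, t_reach)
    ev(t_enter, "ENTER_ARM", arm)
    if (reached) ev(t_reach, "REACH_END", arm)
    ev(t_exit, "EXIT_ARM", arm)
  }
  result <- function() {
    list(visits = quick_df(list(arm = v_arm, t_enter = v_en, t_exit = v_ex,
                                reached_end = v_re, t_reach_end = v_tr),
                           length(v_arm)),
         events = quick_df(list(time = e_t, kind = e_k, arm = e_a),
                           length(e_t)))
  }
  list(ev = ev, visit = visit, result = result)
}

# per-sample positions consistent with the segment zones, with margins so
# zone classification is unambiguous
track_from_segments <- function(segs, tt, config, speed_mean) {
  n <- length(tt)
  dt <- stats::median(diff(tt))
  rc <- config$center_diameter / 2
  L <- config$arm_length
  w2 <- config$arm_width / 2
  ez <- config$end_zone_length
  x <- numeric(n); y <- numeric(n)
  step_sd <- max(0.2, speed_mean * dt / sqrt(2))
  for (s in segs) {
    idx <- (s$k0 + 1L):s$k1
    m <- length(idx)
    if (identical(s$zone, "C")) {
      # bounded correlated walk inside the central disc
      px <- cumsum(stats::rnorm(m, 0, step_sd))
      py <- cumsum(stats::rnorm(m, 0, step_sd))
      r <- sqrt(px^2 + py^2)
      over <- r > (rc - 1.5)
      scale <- ifelse(over, (rc - 1.5) / r, 1)
      x[idx] <- px * scale
      y[idx] <- py * scale
    } else {
      th <- 2 * pi * s$zone / config$n_arms
      lo <- rc + 0.5
      hi_prox <- rc + L - ez - 0.5
      hi_end <- rc + L - 0.5
      radial <- numeric(m)
      if (!is.na(s$kreach)) {
        mr <- s$kreach - s$k0            # samples before reaching the end zone
        ramp <- if (mr > 0) seq(lo, hi_prox, length.out = mr + 1L)[seq_len(mr)]
          else numeric(0)
        inend <- m - mr
        wiggle <- pmin(hi_end, pmax(rc + L - ez + 0.5,
          (rc + L - ez + 1) + cumsum(stats::rnorm(inend, 0, step_sd))))
        radial <- c(ramp, wiggle)
      } else {
        radial <- pmin(hi_prox, pmax(lo,
          (lo + hi_prox) / 2 + cumsum(stats::rnorm(m, 0, step_sd))))
      }
      lat <- pmin(w2 - 0.8, pmax(-(w2 - 0.8),
        cumsum(stats::rnorm(m, 0, step_sd / 3))))
      x[idx] <- radial * cos(th) - lat * sin(th)
      y[idx] <- radial * sin(th) + lat * cos(th)
    }
  }
  maze_track(tt, x, y)
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %s #%d: %d visits, %d pellets, effective bias %.2f\n",
              x$mode, x$session_index, nrow(x$visits), x$pellets,
              x$effective_bias))
  invisible(x)
}
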