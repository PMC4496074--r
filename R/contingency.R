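#' Maze event kinds and actuator actions
#' @keywords internal
EVENT_KINDS <- c("SESSION_START", "ENTER_ARM", "REACH_END", "EXIT_ARM",
                 "ENTER_CENTER", "SESSION_END")

#' @keywords internal
ACTUATOR_ACTIONS <- c("LIGHT_ON", "LIGHT_OFF", "NOISE_ON", "NOISE_OFF",
                      "DISPENSE_PELLET")

# data.frame constructor without the validation overhead of data.frame();
# columns must be equal-length atomic vectors
quick_df <- function(cols, n = length(cols[[1L]])) {
  structure(cols, class = "data.frame", row.names = .set_row_names(n))
}

#' Create a maze event table
#'
#' @param time event times in seconds from session start.
#' @param kind events: `SESSION_START`, `ENTER_ARM`, `REACH_END`,
#'   `EXIT_ARM`, `ENTER_CENTER`, `SESSION_END`.
#' @param arm 0-based arm indices, `NA` for arm-less events.
#' @return a data.frame with columns `time`, `kind`, `arm`.
#' @export
maze_event <- function(time, kind, arm = NA_integer_) {
  stopifnot(all(kind %in% EVENT_KINDS))
  n <- max(length(time), length(kind), length(arm))
  quick_df(list(time = rep_len(as.numeric(time), n),
                kind = rep_len(as.character(kind), n),
                arm = rep_len(as.integer(arm), n)), n)
}

#' Initial contingency state
#'
#' The session contingency automaton starts before `SESSION_START`:
#' light off, noise off, no pellets, subject location unknown.
#'
#' @return an object of class `contingency_state`: fields `light_on`,
#'   `noise_on`, `noise_source_arm`, `center_timer_start`,
#'   `pellets_dispensed`, `clock`, plus internal bookkeeping (`location`:
#'   `NA`, `"CENTER"` or arm index as character; `reached_this_visit`;
#'   `pending_center_timer`; `started`; `ended`).
#' @export
initial_contingency_state <- function() {
  structure(
    list(
      light_on = FALSE,
      noise_on = FALSE,
      noise_source_arm = NA_integer_,
      center_timer_start = NA_real_,
      pellets_dispensed = 0L,
      clock = 0,
      location = NA_character_,
      reached_this_visit = FALSE,
      pending_center_timer = FALSE,
      started = FALSE,
      ended = FALSE
    ),
    class = "contingency_state"
  )
}

protocol_error <- function(event, msg) {
  stop(sprintf("protocol error at t=%g [%s arm=%s]: %s",
               event$time, event$kind,
               ifelse(is.na(event$arm), "-", event$arm), msg),
       call. = FALSE)
}

#' Advance the session contingency state machine by one event
#'
#' Implements the operant contingencies of the maze session. A session
#' starts with the overhead light on. Reaching the end of a positive arm
#' turns the light off and dispenses one food pellet (once per visit);
#' the light stays off until the subject either enters a negative arm or
#' exits a positive arm and then dwells in the central arena for the
#' configured `center_timeout` (20 s). Reaching the end of a negative arm
#' triggers white noise, which stays on until that arm is exited. When
#' the light is on (after a negative-arm entry), it stays on until the
#' end of a positive arm is reached. Ambiguous arms trigger nothing; in
#' `TRAINING` mode events on ambiguous arms are protocol errors because
#' those arms are physically closed.
#'
#' The centre timer is armed at `ENTER_CENTER` following `EXIT_ARM` of a
#' positive arm with the light off, cancelled by any subsequent
#' `ENTER_ARM`, and on expiry emits `LIGHT_ON` stamped at the expiry
#' time (checked lazily when the next event arrives).
#'
#' @param state a `contingency_state`.
#' @param event a one-row event data.frame (see [maze_event()]).
#' @param config a `maze_config`.
#' @param mode `"TRAINING"` or `"TEST"`.
#' @return list with elements `state` (updated) and `actions` (data.frame
#'   `time`, `action`; zero rows if nothing actuated).
#' @export
contingency_step <- function(state, event, config, mode = "TEST") {
  mode <- match.arg(mode, c("TRAINING", "TEST"))
  stopifnot(inherits(state, "contingency_state"), nrow(event) == 1L)
  if (!event$kind %in% EVENT_KINDS) {
    protocol_error(event, "unknown event kind")
  }
  if (state$ended) protocol_error(event, "event after SESSION_END")
  if (event$time < state$clock) {
    protocol_error(event, sprintf("events out of order (clock at %g)", state$clock))
  }
  a_time <- numeric(0); a_act <- character(0)
  act <- function(time, action) {
    a_time <<- c(a_time, time)
    a_act <<- c(a_act, action)
  }

  # lazy centre-timer expiry: fires before processing any event at/after expiry
  if (!is.na(state$center_timer_start)) {
    expiry <- state$center_timer_start + config$center_timeout
    cancels <- event$kind == "ENTER_ARM" && event$time < expiry
    if (!cancels && event$time >= expiry) {
      if (!state$light_on) {
        act(expiry, "LIGHT_ON")
        state$light_on <- TRUE
      }
      state$center_timer_start <- NA_real_
    }
  }

  arm <- event$arm
  has_arm <- !is.na(arm)
  if (has_arm) {
    if (arm < 0L || arm >= config$n_arms) protocol_error(event, "arm index out of range")
    role <- arm_role(arm, config)
    if (mode == "TRAINING" && role %in% c("NEAR_POSITIVE", "NEAR_NEGATIVE")) {
      protocol_error(event, "ambiguous arms are closed in TRAINING mode")
    }
  }

  switch(event$kind,
    SESSION_START = {
      if (state$started) protocol_error(event, "duplicate SESSION_START")
      state$started <- TRUE
      state$light_on <- TRUE
      act(event$time, "LIGHT_ON")
    },
    ENTER_ARM = {
      if (!state$started) protocol_error(event, "session not started")
      if (!has_arm) protocol_error(event, "ENTER_ARM requires an arm")
      if (!is.na(state$location) && state$location != "CENTER") {
        protocol_error(event, paste0("ENTER_ARM while still in arm ", state$location))
      }
      state$center_timer_start <- NA_real_
      state$pending_center_timer <- FALSE
      state$location <- as.character(arm)
      state$reached_this_visit <- FALSE
      if (role == "NEGATIVE" && !state$light_on) {
        state$light_on <- TRUE
        act(event$time, "LIGHT_ON")
      }
    },
    REACH_END = {
      if (!has_arm) protocol_error(event, "REACH_END requires an arm")
      if (is.na(state$location) || state$location != as.character(arm)) {
        protocol_error(event, "REACH_END without prior ENTER_ARM of the same arm")
      }
      if (!state$reached_this_visit) {
        state$reached_this_visit <- TRUE
        if (role == "POSITIVE") {
          if (state$light_on) {
            state$light_on <- FALSE
            act(event$time, "LIGHT_OFF")
          }
          state$pellets_dispensed <- state$pellets_dispensed + 1L
          act(event$time, "DISPENSE_PELLET")
        } else if (role == "NEGATIVE") {
          state$noise_on <- TRUE
          state$noise_source_arm <- arm
          act(event$time, "NOISE_ON")
        }
        # ambiguous arms: no contingencies
      }
    },
    EXIT_ARM = {
      if (!has_arm) protocol_error(event, "EXIT_ARM requires an arm")
      if (is.na(state$location) || state$location != as.character(arm)) {
        protocol_error(event, "EXIT_ARM without matching ENTER_ARM")
      }
      if (state$noise_on && !is.na(state$noise_source_arm) &&
          state$noise_source_arm == arm) {
        state$noise_on <- FALSE
        state$noise_source_arm <- NA_integer_
        act(event$time, "NOISE_OFF")
      }
      if (role == "POSITIVE" && !state$light_on) {
        state$pending_center_timer <- TRUE
      }
      state$location <- "CENTER"
      state$reached_this_visit <- FALSE
    },
    ENTER_CENTER = {
      if (!state$started) protocol_error(event, "session not started")
      if (!is.na(state$location) && !state$location %in% "CENTER") {
        protocol_error(event, "ENTER_CENTER while inside an arm (missing EXIT_ARM)")
      }
      state$location <- "CENTER"
      if (state$pending_center_timer && !state$light_on) {
        state$center_timer_start <- event$time
      }
      state$pending_center_timer <- FALSE
    },
    SESSION_END = {
      if (!state$started) protocol_error(event, "session not started")
      state$ended <- TRUE
    }
  )

  state$clock <- event$time
  list(state = state,
       actions = quick_df(list(time = a_time, action = a_act), length(a_time)))
}

#' Replay an event log through the contingency engine
#'
#' Pure fold of [contingency_step()] over a time-ordered event log,
#' accumulating the actuator log. Replaying the same sequence always
#' yields identical state and log.
#'
#' @param events data.frame with columns `time`, `kind`, `arm`.
#' @param config a `maze_config`.
#' @param mode `"TRAINING"` or `"TEST"`.
#' @param state starting state (defaults to [initial_contingency_state()]).
#' @return list with `state` (final `contingency_state`) and `log`
#'   (data.frame `time`, `action`).
#' @export
replay_contingencies <- function(events, config, mode = "TEST",
                                 state = initial_contingency_state()) {
  stopifnot(is.data.frame(events), all(c("time", "kind", "arm") %in% names(events)))
  ev_time <- events$time; ev_kind <- events$kind; ev_arm <- events$arm
  l_time <- vector("list", nrow(events)); l_act <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    row <- quick_df(list(time = ev_time[i], kind = ev_kind[i], arm = ev_arm[i]), 1L)
    step <- contingency_step(state, row, config, mode)
    state <- step$state
    l_time[[i]] <- step$actions$time
    l_act[[i]] <- step$actions$action
  }
  log <- quick_df(list(time = as.numeric(unlist(l_time)),
                       action = as.character(unlist(l_act))))
  list(state = state, log = log)
}
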