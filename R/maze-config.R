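#' Arm role labels
#'
#' The eight arms of the maze carry one of four roles: two trained
#' positive arms (darkness + food pellet), two trained negative arms
#' (light + white noise), and four ambiguous arms opened only at test,
#' labelled near-positive or near-negative by adjacency to the
#' reference arms.
#' @keywords internal
ARM_ROLES <- c("POSITIVE", "NEGATIVE", "NEAR_POSITIVE", "NEAR_NEGATIVE")

#' Maze configuration
#'
#' Geometry, arm-role layout and contingency parameters of the eight-arm
#' radial maze. Arms are indexed 0-7 counter-clockwise with arm 0 along
#' the +x axis and the maze centroid at the origin; all lengths are in cm.
#'
#' @param n_arms number of arms (8).
#' @param arm_length arm length in cm.
#' @param arm_width arm width in cm.
#' @param center_diameter diameter of the central arena in cm.
#' @param end_zone_length length of the distal trigger zone of each arm, cm.
#'   Must lie in (0, arm_length].
#' @param arm_roles character vector of length `n_arms`: role of arm i at
#'   position i+1. Roles are `POSITIVE`, `NEGATIVE`, `NEAR_POSITIVE`,
#'   `NEAR_NEGATIVE`, exactly two arms each; the positive pair must be
#'   adjacent, the negative pair adjacent and diametrically opposite the
#'   positive pair, and each near-positive (near-negative) arm adjacent to
#'   a positive (negative) arm.
#' @param session_duration session length in seconds.
#' @param center_timeout central-arena dwell (s) after leaving a positive
#'   arm with the light off before the light reverts to on.
#' @param pellet_mass reward pellet mass in mg (descriptive only).
#' @param light_intensity overhead light intensity in lux (descriptive only).
#'
#' @return An object of class `maze_config`.
#' @seealso [default_maze_config()]
#' @export
maze_config <- function(n_arms = 8L,
                        arm_length = 46,
                        arm_width = 9,
                        center_diameter = 28,
                        end_zone_length = 10,
                        arm_roles = default_arm_roles(),
                        session_duration = 600,
                        center_timeout = 20,
                        pellet_mass = 20,
                        light_intensity = 400) {
  n_arms <- as.integer(n_arms)
  stopifnot(n_arms >= 4L, arm_length > 0, arm_width > 0, center_diameter > 0)
  if (!(end_zone_length > 0 && end_zone_length <= arm_length)) {
    stop("end_zone_length must lie in (0, arm_length]", call. = FALSE)
  }
  cfg <- structure(
    list(
      n_arms = n_arms,
      arm_length = arm_length,
      arm_width = arm_width,
      center_diameter = center_diameter,
      end_zone_length = end_zone_length,
      arm_roles = as.character(arm_roles),
      session_duration = session_duration,
      center_timeout = center_timeout,
      pellet_mass = pellet_mass,
      light_intensity = light_intensity
    ),
    class = "maze_config"
  )
  validate_maze_config(cfg)
  cfg
}

#' Default arm-role layout
#'
#' Positive arms at indices 0 and 1, near-positive at 7 and 2 (each
#' flanking a positive arm), near-negative at 3 and 6, negative at 4 and 5
#' (adjacent pair diametrically opposite the positive pair).
#' @return character vector of length 8 (role of arm i at position i+1).
#' @export
default_arm_roles <- function() {
  c("POSITIVE", "POSITIVE", "NEAR_POSITIVE", "NEAR_NEGATIVE",
    "NEGATIVE", "NEGATIVE", "NEAR_NEGATIVE", "NEAR_POSITIVE")
}

#' Default maze configuration
#'
#' The published apparatus: eight arms of 46 x 9 cm around a 28 cm
#' central arena, 10-minute sessions, 20-s centre timeout, 20 mg pellets,
#' 400 lux overhead light, and the standard role layout
#' (see [default_arm_roles()]).
#'
#' @return A `maze_config`.
#' @export
default_maze_config <- function() maze_config()

validate_maze_config <- function(cfg) {
  n <- cfg$n_arms
  roles <- cfg$arm_roles
  if (length(roles) != n) {
    stop("arm_roles must have one entry per arm", call. = FALSE)
  }
  if (!all(roles %in% ARM_ROLES)) {
    stop("unknown arm role: ", paste(setdiff(roles, ARM_ROLES), collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(roles, levels = ARM_ROLES))
  if (!all(counts == n / 4)) {
    stop("each role must be assigned to exactly ", n / 4, " arms", call. = FALSE)
  }
  adjacent <- function(i, j) (abs(i - j) %% n) %in% c(1L, n - 1L)
  idx <- function(role) which(roles == role) - 1L
  pos <- idx("POSITIVE"); neg <- idx("NEGATIVE")
  np <- idx("NEAR_POSITIVE"); nn <- idx("NEAR_NEGATIVE")
  if (n == 8L) {
    if (!adjacent(pos[1], pos[2])) {
      stop("the two POSITIVE arms must be adjacent", call. = FALSE)
    }
    if (!adjacent(neg[1], neg[2])) {
      stop("the two NEGATIVE arms must be adjacent", call. = FALSE)
    }
    if (!setequal((pos + 4L) %% n, neg)) {
      stop("NEGATIVE pair must be diametrically opposite the POSITIVE pair",
           call. = FALSE)
    }
    for (a in np) {
      if (!any(vapply(pos, adjacent, logical(1), i = a))) {
        stop("each NEAR_POSITIVE arm must be adjacent to a POSITIVE arm",
             call. = FALSE)
      }
    }
    for (a in nn) {
      if (!any(vapply(neg, adjacent, logical(1), i = a))) {
        stop("each NEAR_NEGATIVE arm must be adjacent to a NEGATIVE arm",
             call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

#' Role of a given arm
#' @param arm arm index (0-based) or vector thereof.
#' @param config a `maze_config`.
#' @return character vector of roles.
#' @export
arm_role <- function(arm, config) {
  stopifnot(all(arm >= 0L & arm < config$n_arms))
  config$arm_roles[arm + 1L]
}

#' Arms carrying a role
#' @param role one of `POSITIVE`, `NEGATIVE`, `NEAR_POSITIVE`, `NEAR_NEGATIVE`.
#' @param config a `maze_config`.
#' @return integer vector of 0-based arm indices.
#' @export
arms_with_role <- function(role, config) {
  role <- match.arg(role, ARM_ROLES)
  which(config$arm_roles == role) - 1L
}

#' Arms open in a given session mode
#'
#' Training closes the four ambiguous arms; the test session opens all
#' eight.
#' @param mode `"TRAINING"` or `"TEST"`.
#' @param config a `maze_config`.
#' @return integer vector of 0-based open arm indices.
#' @export
open_arms <- function(mode, config) {
  mode <- match.arg(mode, c("TRAINING", "TEST"))
  if (mode == "TRAINING") {
    sort(c(arms_with_role("POSITIVE", config), arms_with_role("NEGATIVE", config)))
  } else {
    seq_len(config$n_arms) - 1L
  }
}

#' @export
print.maze_config <- function(x, ...) {
  cat("<maze_config>\n")
  cat(sprintf("  %d arms, %g x %g cm, central arena %g cm diameter\n",
              x$n_arms, x$arm_length, x$arm_width, x$center_diameter))
  cat(sprintf("  end zone %g cm, session %g s, center timeout %g s\n",
              x$end_zone_length, x$session_duration, x$center_timeout))
  cat("  roles:", paste(sprintf("%d=%s", seq_along(x$arm_roles) - 1L,
                                abbreviate(x$arm_roles, 7)), collapse = " "), "\n")
  invisible(x)
}

#' Write / read a maze configuration as JSON
#'
#' Human-readable round-trippable configuration file (roles by arm index
#' 0-7 counter-clockwise, geometry, timeouts).
#' @param config a `maze_config`.
#' @param path file path.
#' @return `read_maze_config` returns a `maze_config`.
#' @export
write_maze_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_maze_config
#' @export
read_maze_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(maze_config, raw)
}
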