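# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: geometry via ray-casting point-in-polygon, occupancy via
# per-sample tallies, bouts via an explicit maximal-run scan, one-zero via
# per-slot overlap accumulation.

# ray-casting point-in-polygon (boundary points may fall either side; the
# callers sample away from exact polygon edges except where testing the
# documented tie-break, which is asserted separately)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

arm_polygon <- function(i, config, from, to) {
  th <- 2 * pi * i / config$n_arms
  w2 <- config$arm_width / 2
  cx <- c(from, to, to, from)
  cy <- c(-w2, -w2, w2, w2)
  list(x = cx * cos(th) - cy * sin(th), y = cx * sin(th) + cy * cos(th))
}

oracle_zone <- function(x, y, config) {
  rc <- config$center_diameter / 2
  L <- config$arm_length
  ez <- config$end_zone_length
  for (i in seq_len(config$n_arms) - 1L) {
    pe <- arm_polygon(i, config, rc + L - ez, rc + L)
    if (point_in_polygon(x, y, pe$x, pe$y)) return(paste0("ARM_END_", i))
  }
  for (i in seq_len(config$n_arms) - 1L) {
    pa <- arm_polygon(i, config, rc, rc + L - ez)
    if (point_in_polygon(x, y, pa$x, pa$y)) return(paste0("ARM_", i))
  }
  if (x^2 + y^2 <= rc^2) return("CENTER")
  "OUT_OF_MAZE"
}

# per-sample occupancy tally: seconds in each arm = sample count * dt
oracle_arm_occupancy <- function(track, config) {
  det <- track$detected & !is.na(track$x_cm)
  zone <- mazecbt::assign_zone(track$x_cm[det], track$y_cm[det], config)
  arm <- suppressWarnings(as.integer(sub("^ARM_(END_)?", "", zone)))
  dt <- stats::median(diff(track$time_s))
  vapply(seq_len(config$n_arms) - 1L,
         function(a) sum(arm == a, na.rm = TRUE) * dt, numeric(1))
}

# exhaustive scan: all maximal same-form runs with gaps <= gap_max, then
# the qualification rule applied run by run
oracle_bouts <- function(stream, gap_max = 3, barmouth_min = 10, min_reps = 3) {
  forms <- c("BAR_MOUTHING", "CIRCLING", "CAGE_TOP_TWIRLING", "BACK_FLIPPING")
  rep_forms <- c("CIRCLING", "CAGE_TOP_TWIRLING", "BACK_FLIPPING")
  out <- list()
  for (f in forms) {
    iv <- stream[stream$behaviour == f, , drop = FALSE]
    iv <- iv[order(iv$start_s), , drop = FALSE]
    i <- 1L
    while (i <= nrow(iv)) {
      j <- i
      while (j < nrow(iv) && iv$start_s[j + 1L] - iv$end_s[j] <= gap_max) {
        j <- j + 1L
      }
      reps <- j - i + 1L
      dur <- sum(iv$end_s[i:j] - iv$start_s[i:j])
      ok <- if (f %in% rep_forms) reps >= min_reps else dur >= barmouth_min
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          form = f, start_s = iv$start_s[i], end_s = iv$end_s[j],
          repetitions = reps, duration = dur, stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(form = character(0), start_s = numeric(0),
                      end_s = numeric(0), repetitions = integer(0),
                      duration = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start_s), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-slot overlap accumulation oracle for one-zero scoring
oracle_onezero <- function(stream, bouts, design, twitch_max = 5) {
  slots <- mazecbt::schedule_observations(design)
  ov <- function(a0, a1, b0, b1) max(0, min(a1, b1) - max(a0, b0))
  act <- stream[stream$behaviour != "INACTIVE", , drop = FALSE]
  act <- act[!(act$behaviour == "ACTIVE" &
                 act$end_s - act$start_s <= twitch_max), , drop = FALSE]
  n <- nrow(slots)
  active <- integer(n); stereo <- integer(n)
  for (k in seq_len(n)) {
    s0 <- slots$slot_start[k]; s1 <- slots$slot_end[k]
    a <- 0
    for (r in seq_len(nrow(act))) {
      a <- a + ov(act$start_s[r], act$end_s[r], s0, s1)
    }
    active[k] <- as.integer(a > 0)
    b <- 0
    for (r in seq_len(nrow(bouts))) {
      b <- b + ov(bouts$start_s[r], bouts$end_s[r], s0, s1)
    }
    stereo[k] <- as.integer(b > 0 && a > 0)
  }
  list(active = active, stereotypic = stereo)
}

# random behaviour stream with labels drawn across all categories
random_stream <- function(n_intervals, seed, mouse_id = "MX") {
  set.seed(seed)
  labs <- sample(c("INACTIVE", "ACTIVE", "BAR_MOUTHING", "CIRCLING",
                   "CAGE_TOP_TWIRLING", "BACK_FLIPPING"),
                 n_intervals, replace = TRUE,
                 prob = c(3, 4, 2, 1, 1, 1))
  durs <- round(runif(n_intervals, 0.5, 15), 2)
  gaps <- round(rexp(n_intervals, 1 / 2), 2)  # occasional >3 s gaps
  starts <- cumsum(c(0, durs[-n_intervals] + gaps[-n_intervals]))
  behavior_stream(labs, starts, starts + durs, mouse_id = mouse_id)
}
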