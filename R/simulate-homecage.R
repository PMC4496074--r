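#' Simulate a home-cage behaviour stream
#'
#' Alternating-renewal process: inactive and active phases with
#' exponential durations (defaults chosen so mice are active about 73%
#' of the time). Within active phases, stereotypy runs of the given
#' form are inserted until roughly `propensity` of the phase is spent
#' stereotyping; run lengths and repetition counts are drawn to
#' straddle the bout-qualification thresholds (10 s summed duration for
#' bar-mouthing, 3 repetitions for the repetition-scored forms, pauses
#' within runs <= 3 s). Brief twitches (activity <= 5 s) are sprinkled
#' into inactive phases. The stream fully covers `[0, duration]`, or —
#' when `windows` is given — each requested window, which keeps large
#' multi-day designs cheap by simulating only the observed hours.
#'
#' The generator records its own ground truth: the attribute
#' `ground_truth` holds the exact proportion of active (non-twitch)
#' time spent in qualifying stereotypy, computable without the
#' downstream bout classifier.
#'
#' @param propensity target fraction of active time spent stereotyping,
#'   in `[0, 0.8]`.
#' @param form stereotypy form label.
#' @param duration stream length (s); must cover the observation design.
#' @param seed integer RNG seed.
#' @param active_mean,inactive_mean mean phase lengths (s).
#' @param mouse_id identifier.
#' @param windows optional data.frame with columns `start`, `end`:
#'   disjoint time blocks to simulate instead of `[0, duration]`
#'   (e.g. [observed_windows()] of a design).
#' @return a `behavior_stream` with attribute `ground_truth` (list:
#'   `stereotypy_time`, `active_time`, `proportion`).
#' @export
simulate_homecage <- function(propensity, form = "BAR_MOUTHING",
                              duration = 86400 + 7 * 3600, seed = 1L,
                              active_mean = 300, inactive_mean = 110,
                              mouse_id = NA_character_, windows = NULL) {
  stopifnot(propensity >= 0, propensity <= 0.8)
  form <- match.arg(form, STEREOTYPY_FORMS)
  if (is.null(windows)) windows <- data.frame(start = 0, end = duration)
  stopifnot(all(windows$end > windows$start))
  with_local_seed(derive_seed(seed, 424243L), {
    n_beh <- character(0); n_s <- numeric(0); n_e <- numeric(0)
    add <- function(behaviour, s, e) {
      n_beh <<- c(n_beh, behaviour); n_s <<- c(n_s, s); n_e <<- c(n_e, e)
    }
    gt_stereo <- 0
    for (w in seq_len(nrow(windows))) {
    t <- windows$start[w]
    duration <- windows$end[w]
    active_phase <- stats::runif(1) < active_mean / (active_mean + inactive_mean)
    while (t < duration) {
      if (active_phase) {
        len <- max(30, stats::rexp(1, 1 / active_mean))
        end <- min(t + len, duration)
        # stereotypy is clumped: one contiguous block of runs per phase,
        # occupying roughly `propensity` of the phase, placed at a
        # random offset; runs inside the block are separated by > 3 s
        # (and > 5 s, so the separators are not twitches)
        budget <- propensity * (end - t) * stats::runif(1, 0.85, 1.15)
        p <- t
        if (budget > 2 && end - t > 40) {
          bstart <- t + stats::runif(1, 0, max(0, (end - t) - budget * 1.5 - 10))
          if (bstart > p) add("ACTIVE", p, bstart)
          p <- bstart
          acc <- 0
          while (acc < budget && p < end - 15) {
            run <- draw_stereotypy_run(form, p)
            if (run$end > end) break
            add(rep(form, run$n), run$starts, run$ends)
            if (run$n > 1L) {
              add(rep("ACTIVE", run$n - 1L), run$ends[-run$n], run$starts[-1L])
            }
            if (run$qualifies) gt_stereo <- gt_stereo + run$movement_time
            acc <- acc + run$movement_time
            p <- run$end
            sep <- stats::runif(1, 5.5, 8)  # separates runs, not a twitch
            if (p + sep < end) add("ACTIVE", p, p + sep)
            p <- min(end, p + sep)
          }
        }
        if (p < end) add("ACTIVE", p, end)
      } else {
        len <- max(30, stats::rexp(1, 1 / inactive_mean))
        end <- min(t + len, duration)
        if (end - t > 20 && stats::runif(1) < 0.5) {
          # a brief twitch inside the inactive phase (still inactive by rule)
          tw <- stats::runif(1, 1, 4)
          ts <- stats::runif(1, t + 5, end - 5 - tw)
          add("INACTIVE", t, ts)
          add("ACTIVE", ts, ts + tw)
          add("INACTIVE", ts + tw, end)
        } else {
          add("INACTIVE", t, end)
        }
      }
      t <- end
      active_phase <- !active_phase
    }
    }
    # active time = non-inactive time excluding twitches (activity <= 5 s),
    # matching the one-zero layer's twitch rule
    dur <- n_e - n_s
    gt_active <- sum(dur[n_beh != "INACTIVE" & !(n_beh == "ACTIVE" & dur <= 5)])
    stream <- behavior_stream(n_beh, n_s, n_e, mouse_id = mouse_id)
    attr(stream, "ground_truth") <- list(
      stereotypy_time = gt_stereo, active_time = gt_active,
      proportion = if (gt_active > 0) gt_stereo / gt_active else NA_real_)
    stream
  })
}

# one run of same-form intervals with pauses <= 3 s; qualification known
# by construction
draw_stereotypy_run <- function(form, start) {
  if (form == "BAR_MOUTHING") {
    # summed duration straddles the 10-s threshold
    n_iv <- 1L + stats::rpois(1, 1.2)
    durs <- stats::runif(n_iv, 2.5, 9)
    gaps <- if (n_iv > 1L) stats::runif(n_iv - 1L, 0.5, 2.5) else numeric(0)
    qualifies <- sum(durs) >= 10
  } else {
    # repetition count straddles the >= 3 threshold
    n_iv <- sample(1:6, 1L, prob = c(1, 1.5, 2, 2, 1.5, 1))
    durs <- stats::runif(n_iv, 1, 3)
    gaps <- if (n_iv > 1L) stats::runif(n_iv - 1L, 0.5, 2.5) else numeric(0)
    qualifies <- n_iv >= 3L
  }
  starts <- start + cumsum(c(0, durs[-n_iv] + gaps))
  ends <- starts + durs
  list(starts = starts, ends = ends, n = n_iv,
       end = ends[n_iv], movement_time = sum(durs), qualifies = qualifies)
}

#' Simulate a study cohort design
#'
#' Builds the study manifest: `n_mice` female mice from `n_litters`
#' litters, housed in pairs so that each cage holds mice from two
#' different litters, with the two cage mates randomly assigned to tail
#' vs cupped handling. Each mouse receives a stereotypy propensity and
#' form (roughly a quarter of mice non-stereotypic; among stereotypers
#' the forms are weighted 13:4:3 bar-mouthing : cage-top twirling :
#' back-flipping, with back-flippers drawn at higher propensities), and
#' maze agent parameters whose valence bias and ambiguity aversion
#' increase with propensity — the planted cohort-level effect that
#' higher-stereotypy mice occupy positive and reference arms more and
#' avoid (especially near-negative) ambiguous arms.
#'
#' @param n_mice number of mice (even).
#' @param n_litters number of litters.
#' @param seed integer RNG seed.
#' @param include_circler add one extra agent that only circles in the
#'   centre (flagged for exclusion, never analysed).
#' @return object of class `cohort_design`: `manifest` (data.frame
#'   `mouse_id`, `cage`, `litter`, `handling`, `stereotypy_propensity`,
#'   `stereotypy_form`, `excluded`, `exclusion_reason`) and `params`
#'   (named list of `agent_params`).
#' @export
cohort_design <- function(n_mice = 24L, n_litters = 4L, seed = 1L,
                          include_circler = FALSE) {
  stopifnot(n_mice %% 2L == 0L, n_mice %% n_litters == 0L)
  with_local_seed(derive_seed(seed, 77L), {
    litter <- rep(paste0("L", seq_len(n_litters)), each = n_mice / n_litters)
    half <- n_mice / 2L
    # pair each mouse of the first half with one from the second half;
    # re-draw until every cage holds two different litters
    mate1 <- seq_len(half)
    repeat {
      mate2 <- half + sample(half)
      if (all(litter[mate1] != litter[mate2])) break
    }
    mouse_of_cage <- rbind(mate1, mate2)
    mouse_id <- sprintf("M%02d", seq_len(n_mice))
    cage <- character(n_mice)
    for (cg in seq_len(half)) cage[mouse_of_cage[, cg]] <- sprintf("C%02d", cg)
    handling <- character(n_mice)
    for (cg in seq_len(half)) {
      hh <- sample(c("TAIL", "CUPPED"))
      handling[mouse_of_cage[, cg]] <- hh
    }

    stereotyper <- stats::runif(n_mice) < 0.76
    sform <- rep(NA_character_, n_mice)
    sform[stereotyper] <- sample(c("BAR_MOUTHING", "CAGE_TOP_TWIRLING", "BACK_FLIPPING"),
                                 sum(stereotyper), replace = TRUE,
                                 prob = c(13, 4, 3))
    propensity <- numeric(n_mice)
    for (i in which(stereotyper)) {
      base <- stats::rbeta(1, 2, 5) * 0.5
      propensity[i] <- min(0.8, if (sform[i] == "BACK_FLIPPING") base + 0.2 else base)
    }

    # propensity links on the sqrt scale (the covariate scale of the
    # analysis models), strong enough that the planted cohort effects
    # yield F statistics of the same order as a well-powered study
    params <- lapply(seq_len(n_mice), function(i) {
      agent_params(
        valence_bias = max(-1, min(1, 0.08 + 0.55 * sqrt(propensity[i]) +
                                     stats::rnorm(1, 0, 0.05))),
        ambiguity_aversion = max(0, 0.2 + 1.8 * sqrt(propensity[i]) +
                                   stats::rnorm(1, 0, 0.08)),
        activity_rate = max(2, stats::rnorm(1, 5.2, 0.8)),
        speed_mean = max(4, stats::rnorm(1, 10, 1.5)),
        learning_rate = 0.06,
        seed = derive_seed(seed, 1000L + i))
    })
    names(params) <- mouse_id

    manifest <- data.frame(
      mouse_id = mouse_id, cage = cage, litter = litter, handling = handling,
      stereotypy_propensity = propensity, stereotypy_form = sform,
      excluded = FALSE, exclusion_reason = "", stringsAsFactors = FALSE)

    if (include_circler) {
      manifest <- rbind(manifest, data.frame(
        mouse_id = "M_CIRCLER", cage = "C_EXTRA", litter = "L1",
        handling = "TAIL", stereotypy_propensity = 0,
        stereotypy_form = "CIRCLING", excluded = TRUE,
        exclusion_reason = "circling in central arena; never performed the test",
        stringsAsFactors = FALSE))
      params$M_CIRCLER <- agent_params(circler = TRUE,
                                       seed = derive_seed(seed, 999983L))
    }
    structure(list(manifest = manifest, params = params, seed = seed),
              class = "cohort_design")
  })
}

#' @export
print.cohort_design <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<cohort_design> %d mice, %d cages, %d litters; %d stereotypers\n",
              nrow(m), length(unique(m$cage)), length(unique(m$litter)),
              sum(m$stereotypy_propensity > 0)))
  invisible(x)
}

#' Direct score-table generator for statistical calibration
#'
#' Generates per-mouse outcome tables straight from the linear
#' mixed-model data-generating process (litter and cage random
#' intercepts, within-cage handling assignment, an independent
#' stereotypy-level covariate, Gaussian residuals) without simulating
#' maze behaviour. Used to calibrate the type-I error and power of
#' [fit_mixed_model()].
#'
#' @param n_mice,n_litters cohort size.
#' @param handling_effect fixed effect of tail vs cupped handling on
#'   the outcome (0 for null calibration).
#' @param stereotypy_effect coefficient of `sqrt(stereotypy_level)`.
#' @param litter_sd,cage_sd,resid_sd variance components (SD scale).
#' @param seed integer RNG seed.
#' @return data.frame `mouse_id`, `litter`, `cage`, `handling`,
#'   `stereotypy_level`, `outcome`.
#' @export
simulate_score_cohort <- function(n_mice = 24L, n_litters = 4L,
                                  handling_effect = 0,
                                  stereotypy_effect = 0,
                                  litter_sd = 0.3, cage_sd = 0.3,
                                  resid_sd = 1, seed = 1L) {
  with_local_seed(derive_seed(seed, 5151L), {
    half <- n_mice / 2L
    cage <- rep(sprintf("C%02d", seq_len(half)), each = 2L)
    litter <- sample(rep(paste0("L", seq_len(n_litters)), length.out = n_mice))
    handling <- as.vector(vapply(seq_len(half),
                                 function(i) sample(c("TAIL", "CUPPED")),
                                 character(2)))
    level <- ifelse(stats::runif(n_mice) < 0.25, 0, stats::runif(n_mice, 0, 0.4))
    le <- stats::rnorm(n_litters, 0, litter_sd)[as.integer(factor(litter))]
    ce <- stats::rnorm(half, 0, cage_sd)[as.integer(factor(cage))]
    outcome <- handling_effect * (handling == "TAIL") +
      stereotypy_effect * sqrt(level) + le + ce + stats::rnorm(n_mice, 0, resid_sd)
    data.frame(mouse_id = sprintf("M%02d", seq_len(n_mice)), litter = litter,
               cage = cage, handling = handling, stereotypy_level = level,
               outcome = outcome, stringsAsFactors = FALSE)
  })
}
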