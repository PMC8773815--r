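#' Horizontal bias trajectory parameters
#'
#' Anchors of the population-level time course of the horizontal gaze bias
#' during free exploration: an early leftward peak (pseudoneglect), a later
#' rightward peak, and a return towards the centre at the end of the trial.
#' Defaults place a -50 px leftward peak at 1 s, a +30 px rightward peak at
#' 3.5 s and a centred finish.
#'
#' @param left_amplitude Early leftward peak in centred px (negative).
#' @param right_amplitude Mid rightward peak in centred px.
#' @param t_left_peak,t_right_peak Peak times in ms,
#'   `0 < t_left_peak < t_right_peak < total_ms`.
#' @param return_level Late value in centred px (~0).
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(left_amplitude = -50, right_amplitude = 30,
                              t_left_peak = 1000, t_right_peak = 3500,
                              return_level = 0) {
  if (!(0 < t_left_peak && t_left_peak < t_right_peak)) {
    stop("need 0 < t_left_peak < t_right_peak", call. = FALSE)
  }
  structure(list(left_amplitude = left_amplitude,
                 right_amplitude = right_amplitude,
                 t_left_peak = t_left_peak, t_right_peak = t_right_peak,
                 return_level = return_level),
            class = "trajectory_params")
}

#' Mean gaze position at time t under the bias trajectory
#'
#' Piecewise smooth interpolation (half-cosine easing between anchors) of
#' the trajectory defined by [trajectory_params()]: exactly 0 at t = 0, the
#' left amplitude at the left peak, the right amplitude at the right peak,
#' and the return level at `total_ms`; continuous in between. Only the
#' anchor constraints are contractual - the interpolant is an
#' implementation choice.
#'
#' @param t Time(s) in ms, within `[0, total_ms]`.
#' @param params A [trajectory_params()].
#' @param total_ms Trial duration in ms.
#' @return Mean centred horizontal position(s) in px.
#' @export
trajectory_template <- function(t, params = trajectory_params(),
                                total_ms = 7000) {
  if (params$t_right_peak >= total_ms) {
    stop("t_right_peak must be < total_ms", call. = FALSE)
  }
  if (any(t < 0 | t > total_ms)) {
    stop("t must lie within [0, total_ms]", call. = FALSE)
  }
  knots_t <- c(0, params$t_left_peak, params$t_right_peak, total_ms)
  knots_x <- c(0, params$left_amplitude, params$right_amplitude,
               params$return_level)
  seg <- findInterval(t, knots_t, rightmost.closed = TRUE)
  s <- (t - knots_t[seg]) / (knots_t[seg + 1] - knots_t[seg])
  ease <- (1 - cospi(s)) / 2
  knots_x[seg] + (knots_x[seg + 1] - knots_x[seg]) * ease
}

#' Injected condition-by-timepoint effect
#'
#' Describes a horizontal shift confined to one stimulation, one timepoint
#' and a half-open time window - the ground-truth effect the pipeline
#' should recover.
#'
#' @param stimulation,timepoint Condition cell receiving the shift.
#' @param window Half-open ms interval `c(from, to)`.
#' @param shift_px Shift in centred px (negative = leftward).
#' @return An object of class `injected_effect`.
#' @export
injected_effect <- function(stimulation = "FEF", timepoint = "T1",
                            window = c(5700, 5900), shift_px = -40) {
  stopifnot(stimulation %in% STIMULATION_LEVELS,
            timepoint %in% TIMEPOINT_LEVELS,
            length(window) == 2, window[1] < window[2])
  structure(list(stimulation = stimulation, timepoint = timepoint,
                 window = window, shift_px = shift_px),
            class = "injected_effect")
}

#' Configuration of the synthetic scanpath generator
#'
#' Defaults reproduce the shape of a 22-participant, three-stimulation
#' (FEF/PPC/SHAM), three-timepoint (T0/T1/T2), 25-pictures-per-block
#' free-exploration experiment: sequential fixations whose durations are
#' gamma-distributed (shape 4) with a 300 ms mean, giving roughly 22-23
#' fixations per 7-s trial; a common bias trajectory; a per-participant
#' horizontal bias (SD 40 px); and per-fixation horizontal noise
#' (SD 100 px).
#'
#' @param n_participants Number of participants.
#' @param stimulations Subset of FEF/PPC/SHAM.
#' @param timepoints Subset of T0/T1/T2.
#' @param pictures_per_block Pictures viewed per condition cell.
#' @param trajectory A [trajectory_params()].
#' @param subject_bias_sd SD of the per-participant constant horizontal
#'   bias, px.
#' @param fixation_noise_sd SD of the zero-mean per-fixation horizontal
#'   noise, px.
#' @param mean_fixation_ms Mean fixation duration, ms.
#' @param duration_shape Gamma shape of the fixation durations.
#' @param effect An [injected_effect()] or `NULL`.
#' @param seed Integer seed; a single global seed drives a hierarchical
#'   participant-then-trial stream, so adding participants does not perturb
#'   existing ones.
#' @param geometry A [screen_geometry()].
#' @param grid A [bin_grid()] (supplies the trial duration).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 22,
                              stimulations = STIMULATION_LEVELS,
                              timepoints = TIMEPOINT_LEVELS,
                              pictures_per_block = 25,
                              trajectory = trajectory_params(),
                              subject_bias_sd = 40,
                              fixation_noise_sd = 100,
                              mean_fixation_ms = 300,
                              duration_shape = 4,
                              effect = NULL,
                              seed = 1,
                              geometry = screen_geometry(),
                              grid = bin_grid()) {
  stopifnot(n_participants >= 1, pictures_per_block >= 1,
            mean_fixation_ms > 0, duration_shape > 0,
            subject_bias_sd >= 0, fixation_noise_sd >= 0,
            all(stimulations %in% STIMULATION_LEVELS),
            all(timepoints %in% TIMEPOINT_LEVELS))
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "injected_effect"))
    if (effect$window[1] < 0 || effect$window[2] > grid$total_ms) {
      stop("effect window must lie within [0, total_ms)", call. = FALSE)
    }
  }
  structure(list(n_participants = n_participants,
                 stimulations = stimulations, timepoints = timepoints,
                 pictures_per_block = pictures_per_block,
                 trajectory = trajectory,
                 subject_bias_sd = subject_bias_sd,
                 fixation_noise_sd = fixation_noise_sd,
                 mean_fixation_ms = mean_fixation_ms,
                 duration_shape = duration_shape,
                 effect = effect, seed = seed,
                 geometry = geometry, grid = grid),
            class = "simulation_config")
}

# draws one trial from the current RNG state
trial_core <- function(config, participant, stimulation, timepoint, picture,
                       subject_bias) {
  total <- config$grid$total_ms
  scale <- config$mean_fixation_ms / config$duration_shape
  expected <- ceiling(total / config$mean_fixation_ms)
  durations <- stats::rgamma(2 * expected + 10,
                             shape = config$duration_shape, scale = scale)
  while (sum(durations) < total) {
    durations <- c(durations,
                   stats::rgamma(expected, shape = config$duration_shape,
                                 scale = scale))
  }
  starts <- cumsum(c(0, durations))
  keep <- which(starts < total)
  starts <- starts[keep]
  durations <- pmin(durations[keep], total - starts)
  m <- trajectory_template(starts, config$trajectory, total)
  eff <- config$effect
  x_centered <- m + subject_bias +
    stats::rnorm(length(starts), sd = config$fixation_noise_sd)
  if (!is.null(eff) && identical(eff$stimulation, stimulation) &&
      identical(eff$timepoint, timepoint)) {
    in_win <- starts >= eff$window[1] & starts < eff$window[2]
    x_centered[in_win] <- x_centered[in_win] + eff$shift_px
  }
  y <- stats::runif(length(starts), 0, config$geometry$height_px)
  nf <- length(starts)
  list(participant = rep(participant, nf),
       stimulation = rep(stimulation, nf),
       timepoint = rep(timepoint, nf),
       picture = rep(picture, nf),
       start_ms = starts, duration_ms = durations,
       x_px = uncenter_x(x_centered, config$geometry), y_px = y)
}

#' Simulate one free-exploration trial
#'
#' Draws a single trial from the current RNG state (seed it yourself, or
#' use [simulate_dataset()] for the full seeded design): fixation start
#' times from sequential gamma durations truncated at the trial end, each
#' fixation's horizontal position equal to the trajectory mean at its start
#' time plus the subject bias, the injected effect shift when the
#' condition and start time match, and zero-mean noise; vertical positions
#' uniform over the screen height.
#'
#' @param config A [simulation_config()].
#' @param participant,stimulation,timepoint,picture Identifiers for the
#'   emitted fixations.
#' @param subject_bias Constant horizontal bias of this participant, px.
#' @return A [fixation_table()] with this trial's fixations.
#' @export
simulate_trial <- function(config, participant = "P1",
                           stimulation = "SHAM", timepoint = "T0",
                           picture = "pic1", subject_bias = 0) {
  stopifnot(inherits(config, "simulation_config"))
  fixation_table(as.data.frame(trial_core(config, participant, stimulation,
                                          timepoint, picture, subject_bias),
                               stringsAsFactors = FALSE),
                 geometry = config$geometry, provenance = "simulate_trial")
}

#' Simulate a full factorial free-exploration dataset
#'
#' Generates trials for every participant x stimulation x timepoint x
#' picture combination. The per-participant bias is drawn once per
#' participant. Randomness uses L'Ecuyer-CMRG streams derived from the
#' global seed, one stream per participant and one substream per trial, so
#' the data of the first k participants are identical regardless of
#' `n_participants`; the caller's RNG state is left untouched.
#'
#' @param config A [simulation_config()].
#' @return A [fixation_table()] carrying the config as attribute
#'   `sim_config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  trials <- expand.grid(picture = seq_len(config$pictures_per_block),
                        timepoint = config$timepoints,
                        stimulation = config$stimulations,
                        stringsAsFactors = FALSE)
  out <- vector("list", config$n_participants)
  with_preserved_rng({
    RNGkind("L'Ecuyer-CMRG")
    set.seed(config$seed)
    stream <- .Random.seed
    for (p in seq_len(config$n_participants)) {
      stream <- parallel::nextRNGStream(stream)
      pid <- sprintf("P%02d", p)
      assign(".Random.seed", stream, envir = globalenv())
      bias <- stats::rnorm(1, sd = config$subject_bias_sd)
      tstate <- stream
      rows <- vector("list", nrow(trials))
      for (q in seq_len(nrow(trials))) {
        tstate <- parallel::nextRNGSubStream(tstate)
        assign(".Random.seed", tstate, envir = globalenv())
        rows[[q]] <- trial_core(config, pid, trials$stimulation[q],
                                trials$timepoint[q],
                                sprintf("%s_%s_pic%02d",
                                        trials$stimulation[q],
                                        trials$timepoint[q],
                                        trials$picture[q]),
                                bias)
      }
      out[[p]] <- data.table::rbindlist(rows)
    }
  })
  fixation_table(data.table::setDF(data.table::rbindlist(out)),
                 geometry = config$geometry,
                 provenance = sprintf("simulate_dataset(seed = %d)",
                                      config$seed)) -> tab
  attr(tab, "sim_config") <- config
  tab
}
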