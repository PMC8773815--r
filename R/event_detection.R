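#' Velocity/acceleration thresholds for event detection
#'
#' Defaults follow the standard cognitive-research setup: a sample belongs
#' to a saccade when its angular velocity exceeds 30 deg/s or its angular
#' acceleration exceeds 8000 deg/s^2.
#'
#' @param velocity_deg_s Saccade velocity threshold, degrees/second.
#' @param acceleration_deg_s2 Saccade acceleration threshold,
#'   degrees/second^2.
#' @param min_fixation_ms Optional minimum fixation duration filter in ms;
#'   `NULL` (the default) keeps all fixations.
#' @return An object of class `event_thresholds`.
#' @export
event_thresholds <- function(velocity_deg_s = 30,
                             acceleration_deg_s2 = 8000,
                             min_fixation_ms = NULL) {
  if (velocity_deg_s <= 0 || acceleration_deg_s2 <= 0) {
    stop("thresholds must be strictly positive", call. = FALSE)
  }
  if (!is.null(min_fixation_ms) && min_fixation_ms <= 0) {
    stop("min_fixation_ms must be strictly positive when given", call. = FALSE)
  }
  structure(list(velocity_deg_s = velocity_deg_s,
                 acceleration_deg_s2 = acceleration_deg_s2,
                 min_fixation_ms = min_fixation_ms),
            class = "event_thresholds")
}

#' Parse raw gaze samples into fixations and saccades
#'
#' Classifies each valid sample as saccadic when its instantaneous angular
#' velocity or acceleration (central finite differences over the sample
#' grid, one-sided at run boundaries; pixel displacements converted to
#' degrees through the linear geometry mapping) exceeds the thresholds.
#' Maximal runs of non-saccadic samples become fixations whose start is the
#' first sample time, whose duration is the number of member samples times
#' the sampling interval, and whose position is the mean of member samples.
#' Invalid (track-loss) samples split events.
#'
#' @param samples Data frame with columns `t_ms`, `x_px`, `y_px` and
#'   optionally logical `valid` (default all valid); `t_ms` must be strictly
#'   increasing on a constant grid.
#' @param geometry A [screen_geometry()].
#' @param thresholds An [event_thresholds()].
#' @param meta Optional named list giving `participant`, `stimulation`,
#'   `timepoint`, `picture` for the emitted fixations (defaults are
#'   placeholders).
#' @param dt_tolerance Maximum relative deviation of inter-sample intervals
#'   from their median before sampling is declared non-uniform.
#' @return A list with elements `fixations` (a [fixation_table()]),
#'   `saccades` (data frame `start_ms`, `end_ms`, `duration_ms`) and
#'   `dt_ms`, the sampling interval.
#' @export
detect_events <- function(samples, geometry = screen_geometry(),
                          thresholds = event_thresholds(),
                          meta = list(), dt_tolerance = 1e-3) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("t_ms", "x_px", "y_px") %in% names(samples)))
  if (is.null(samples$valid)) samples$valid <- TRUE
  n <- nrow(samples)
  if (sum(samples$valid) < 3) {
    stop("detect_events needs at least 3 valid samples", call. = FALSE)
  }
  dts <- diff(samples$t_ms)
  if (any(dts <= 0)) stop("sample times must be strictly increasing", call. = FALSE)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > dt_tolerance * dt)) {
    stop("non-uniform sampling interval (beyond tolerance)", call. = FALSE)
  }

  xd <- px_to_deg(samples$x_px, geometry)
  yd <- px_to_deg(samples$y_px, geometry)

  # Per maximal run of valid samples: finite-difference velocity and
  # acceleration; runs shorter than 3 samples are left unclassified (gap).
  is_sac <- rep(NA, n)
  runs <- rle(samples$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  dt_s <- dt / 1000
  for (r in seq_along(runs$values)) {
    if (!runs$values[r] || runs$lengths[r] < 3) next
    idx <- starts[r]:ends[r]
    vx <- fd_gradient(xd[idx], dt_s)
    vy <- fd_gradient(yd[idx], dt_s)
    speed <- sqrt(vx^2 + vy^2)
    accel <- abs(fd_gradient(speed, dt_s))
    is_sac[idx] <- speed > thresholds$velocity_deg_s |
      accel > thresholds$acceleration_deg_s2
  }

  flag <- ifelse(is.na(is_sac), "gap", ifelse(is_sac, "saccade", "fixation"))
  ev <- rle(flag)
  ev_end <- cumsum(ev$lengths)
  ev_start <- ev_end - ev$lengths + 1

  fix_rows <- list()
  sac_rows <- list()
  for (e in seq_along(ev$values)) {
    idx <- ev_start[e]:ev_end[e]
    t0 <- samples$t_ms[idx[1]]
    dur <- length(idx) * dt
    if (ev$values[e] == "fixation") {
      fix_rows[[length(fix_rows) + 1]] <- data.frame(
        start_ms = t0, duration_ms = dur,
        x_px = mean(samples$x_px[idx]), y_px = mean(samples$y_px[idx]))
    } else if (ev$values[e] == "saccade") {
      sac_rows[[length(sac_rows) + 1]] <- data.frame(
        start_ms = t0, end_ms = t0 + dur, duration_ms = dur)
    }
  }

  fix <- if (length(fix_rows)) do.call(rbind, fix_rows) else
    data.frame(start_ms = numeric(), duration_ms = numeric(),
               x_px = numeric(), y_px = numeric())
  if (!is.null(thresholds$min_fixation_ms)) {
    fix <- fix[fix$duration_ms >= thresholds$min_fixation_ms, , drop = FALSE]
  }
  defaults <- list(participant = "P0", stimulation = "SHAM",
                   timepoint = "T0", picture = "pic0")
  meta <- utils::modifyList(defaults, meta)
  if (nrow(fix) > 0) {
    fix <- cbind(participant = meta$participant, stimulation = meta$stimulation,
                 timepoint = meta$timepoint, picture = meta$picture, fix)
  } else {
    fix <- data.frame(participant = character(), stimulation = character(),
                      timepoint = character(), picture = character(), fix)
  }
  sac <- if (length(sac_rows)) do.call(rbind, sac_rows) else
    data.frame(start_ms = numeric(), end_ms = numeric(), duration_ms = numeric())
  list(fixations = fixation_table(fix, geometry = geometry,
                                  provenance = "detect_events"),
       saccades = sac, dt_ms = dt)
}

# central differences in the interior, one-sided at the ends
fd_gradient <- function(v, dt) {
  n <- length(v)
  g <- numeric(n)
  if (n == 1) return(g)
  g[1] <- (v[2] - v[1]) / dt
  g[n] <- (v[n] - v[n - 1]) / dt
  if (n > 2) g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  g
}

#' Exclude fixations falling outside the picture area
#'
#' A fixation is excluded when its mean position lies strictly outside the
#' picture rectangle; fixations exactly on the boundary are kept (the
#' picture area is treated as a closed region).
#'
#' @param table A [fixation_table()].
#' @param bounds Picture rectangle `c(xmin, xmax, ymin, ymax)` in screen
#'   pixels; defaults to the full screen of the table's geometry.
#' @return List with `kept` (filtered [fixation_table()]) and
#'   `excluded_fraction` (proportion of fixations removed).
#' @export
filter_out_of_bounds <- function(table, bounds = NULL) {
  stopifnot(inherits(table, "fixation_table"))
  if (nrow(table) == 0) stop("cannot filter an empty fixation table", call. = FALSE)
  g <- attr(table, "geometry")
  if (is.null(bounds)) bounds <- c(0, g$width_px, 0, g$height_px)
  stopifnot(length(bounds) == 4)
  inside <- table$x_px >= bounds[1] & table$x_px <= bounds[2] &
    table$y_px >= bounds[3] & table$y_px <= bounds[4]
  kept <- fixation_table(as.data.frame(table)[inside, , drop = FALSE],
                         geometry = g, provenance = attr(table, "provenance"))
  list(kept = kept, excluded_fraction = mean(!inside))
}

#' Summarise fixation counts per cell and per picture
#'
#' @param table A [fixation_table()].
#' @return List with `cells` (fixation counts per participant, stimulation
#'   and timepoint), `per_picture` (counts per participant, condition and
#'   picture) and `per_picture_stats` (mean, sd and range of the per-picture
#'   counts).
#' @export
fixation_summary <- function(table) {
  stopifnot(inherits(table, "fixation_table"))
  if (nrow(table) == 0) stop("cannot summarise an empty fixation table", call. = FALSE)
  dt <- data.table::as.data.table(as.data.frame(table))
  cells <- dt[, list(n_fixations = .N),
              by = c("participant", "stimulation", "timepoint")]
  per_pic <- dt[, list(n_fixations = .N),
                by = c("participant", "stimulation", "timepoint", "picture")]
  stats_ <- list(mean = mean(per_pic$n_fixations),
                 sd = stats::sd(per_pic$n_fixations),
                 range = range(per_pic$n_fixations))
  list(cells = data.table::setDF(cells),
       per_picture = data.table::setDF(per_pic),
       per_picture_stats = stats_)
}
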