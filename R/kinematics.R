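#' Wrap angles to (-pi, pi]
#'
#' @param a Numeric vector of angles in radians.
#' @return Angles wrapped into the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(a) {
  w <- a %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Kinematic series of one track
#'
#' Derives speed, heading, tangential acceleration and turning rate from a
#' position time series, exactly as an observer of recorded tracks would:
#' `speed[t]` is the length of the displacement from `t - 1` to `t` divided
#' by `dt`; `heading[t]` is the four-quadrant angle of that displacement
#' (mathematical convention, counter-clockwise positive); `accel[t] =
#' (speed[t + 1] - speed[t]) / dt` and `turn_rate[t]` is the wrapped
#' heading difference `heading[t + 1] - heading[t]` over `dt`. Responses
#' are forward differences: the response attributed to time `t` is the
#' change occurring between `t` and `t + 1`, so it can be binned against
#' the configuration observed at `t`.
#'
#' A zero-length displacement leaves the heading undefined; the previous
#' heading is carried forward and the step is flagged in
#' `heading_degenerate`.
#'
#' @param xy A data frame with numeric columns `x` and `y`, one row per
#'   time step, at least 3 rows.
#' @param dt Seconds per time step.
#' @return A tibble with columns `t`, `speed` (a.u./s), `heading` (rad),
#'   `accel` (a.u./s^2), `turn_rate` (rad/s, counter-clockwise positive)
#'   and `heading_degenerate`; quantities undefined at the boundaries are
#'   `NA`.
#' @export
kinematic_series <- function(xy, dt) {
  if (nrow(xy) < 3) {
    rlang::abort("Position series must have at least 3 steps.",
                 class = "flockdual_invalid_input")
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    rlang::abort("`dt` must be a single positive number.",
                 class = "flockdual_invalid_input")
  }
  n <- nrow(xy)
  dx <- diff(xy$x)
  dy <- diff(xy$y)
  step_len <- sqrt(dx^2 + dy^2)
  speed <- c(NA_real_, step_len / dt)
  heading <- c(NA_real_, atan2(dy, dx))
  degenerate <- c(NA, step_len == 0)
  # heading undefined on a zero-length step: carry the last defined value
  if (any(degenerate[-1])) {
    for (i in which(degenerate[-1]) + 1L) {
      heading[i] <- if (i > 2) heading[i - 1] else NA_real_
    }
  }
  accel <- c((speed[-1] - speed[-n]) / dt, NA_real_)
  turn_rate <- c(wrap_angle(heading[-1] - heading[-n]) / dt, NA_real_)
  tibble::tibble(t = seq_len(n), speed = speed, heading = heading,
                 accel = accel, turn_rate = turn_rate,
                 heading_degenerate = degenerate)
}

#' Relative geometry of a neighbour in the focal frame
#'
#' Computes, at each aligned time step, the neighbour's distance and
#' position/orientation relative to the focal individual's heading.
#' Reported angles are right-positive (the field's plotting convention):
#' `theta` is 0 when the neighbour is dead ahead and positive when it is to
#' the focal's right; `phi` is 0 when headings are parallel and positive
#' when the neighbour is oriented to the right of the focal's heading.
#' Internally `theta = wrap(psi_focal - atan2(dy, dx))` and
#' `phi = wrap(psi_focal - psi_neighbour)`, which negates the
#' mathematical (counter-clockwise positive) convention at this layer only.
#' Signed decompositions are `d_fb = d * cos(theta)` (positive = neighbour
#' ahead) and `d_lat = d * sin(theta)` (positive = neighbour to the right).
#'
#' @param focal,neighbour Data frames with columns `x`, `y`, `heading`
#'   (radians, mathematical convention), aligned row-by-row.
#' @return A tibble with columns `d`, `theta`, `phi`, `d_fb`, `d_lat`.
#'   Steps where the two positions coincide (direction undefined) or where
#'   a heading is missing have `NA` angles and are excluded from any later
#'   binning.
#' @export
pair_geometry <- function(focal, neighbour) {
  if (nrow(focal) != nrow(neighbour)) {
    rlang::abort("`focal` and `neighbour` must be aligned (equal rows).",
                 class = "flockdual_invalid_input")
  }
  dx <- neighbour$x - focal$x
  dy <- neighbour$y - focal$y
  d <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx)
  theta <- wrap_angle(focal$heading - bearing)
  theta[d == 0] <- NA_real_
  phi <- wrap_angle(focal$heading - neighbour$heading)
  tibble::tibble(d = d, theta = theta, phi = phi,
                 d_fb = d * cos(theta), d_lat = d * sin(theta))
}

#' Pairwise observation table of an experiment
#'
#' The workhorse that turns recorded tracks into the long table of
#' (focal, neighbour, time) observations all response maps are built from.
#' For every trajectory and every ordered pair of individuals it joins the
#' focal's movement responses at `t` (tangential acceleration and turning,
#' both forward differences over `t` to `t + 1`) with the relative geometry
#' of the neighbour observed at `t`. Headings are estimated from recorded
#' displacements, never from the ideal path — exactly what an observer of
#' real tracks can do.
#'
#' The `turn` column is the turning response in the right-positive
#' reporting convention (positive = turning to the right), so a response
#' toward a neighbour at `theta > 0` has `turn > 0`.
#'
#' @param tracks A tracks tibble (from [simulate_flock()],
#'   [simulate_flights()] or [read_tracks()]) with columns `trajectory_id`,
#'   `t`, `individual_id`, `x`, `y`.
#' @param dt Seconds per time step.
#' @return A tibble with one row per (trajectory, t, focal, neighbour):
#'   `trajectory_id`, `t`, `focal_id`, `neighbour_id`, `focal_offset`,
#'   `neighbour_offset` (if offsets are present), `d`, `theta`, `phi`,
#'   `d_fb`, `d_lat`, `turn` (rad/s, right-positive), `accel` (a.u./s^2).
#'   Rows with undefined geometry or responses are dropped.
#' @export
pair_observations <- function(tracks, dt = 0.2) {
  has_offset <- "offset" %in% names(tracks)
  kin <- tracks |>
    dplyr::group_by(.data$trajectory_id, .data$individual_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$t)
      k <- kinematic_series(df[, c("x", "y")], dt)
      df$heading <- k$heading
      df$accel <- k$accel
      df$turn_rate <- k$turn_rate
      df$heading_degenerate <- k$heading_degenerate
      df
    }) |>
    dplyr::ungroup()

  foc_cols <- c("trajectory_id", "t", "individual_id", "x", "y", "heading",
                "accel", "turn_rate", "heading_degenerate",
                if (has_offset) "offset")
  foc <- kin[, foc_cols]
  names(foc) <- c("trajectory_id", "t", "focal_id", "x_f", "y_f",
                  "heading_f", "accel", "turn_rate", "degen_f",
                  if (has_offset) "focal_offset")
  nb_cols <- c("trajectory_id", "t", "individual_id", "x", "y", "heading",
               if (has_offset) "offset")
  nb <- kin[, nb_cols]
  names(nb) <- c("trajectory_id", "t", "neighbour_id", "x_n", "y_n",
                 "heading_n", if (has_offset) "neighbour_offset")

  obs <- dplyr::inner_join(foc, nb, by = c("trajectory_id", "t"),
                           relationship = "many-to-many") |>
    dplyr::filter(.data$focal_id != .data$neighbour_id)

  geom <- pair_geometry(
    tibble::tibble(x = obs$x_f, y = obs$y_f, heading = obs$heading_f),
    tibble::tibble(x = obs$x_n, y = obs$y_n, heading = obs$heading_n)
  )
  obs |>
    dplyr::mutate(
      d = geom$d, theta = geom$theta, phi = geom$phi,
      d_fb = geom$d_fb, d_lat = geom$d_lat,
      turn = -.data$turn_rate  # right-positive reporting convention
    ) |>
    dplyr::filter(
      !is.na(.data$theta), !is.na(.data$phi), !is.na(.data$turn),
      !is.na(.data$accel), !.data$degen_f
    ) |>
    dplyr::select(dplyr::any_of(c(
      "trajectory_id", "t", "focal_id", "neighbour_id",
      "focal_offset", "neighbour_offset",
      "d", "theta", "phi", "d_fb", "d_lat", "turn", "accel"
    )))
}
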