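#' Simulation configuration
#'
#' Collects every generative parameter of a simulated "flight": a group of
#' individuals that ride one common correlated-random trajectory while
#' holding fixed mutual target positions, observed through temporally
#' autocorrelated positional noise. Defaults are the study conditions:
#' flights of 2^12 steps, base speed 5 a.u./step modulated by +/- 0.2,
#' turning amplitude 0.02 rad/step, path correlation cut-off 300 steps,
#' displacement noise cut-off 20 steps rescaled to standard deviation
#' `spacing / 2`, target spacing 5 a.u., and 5 steps per second of time
#' (`dt = 0.2` s).
#'
#' @param n_steps Trajectory length in time steps.
#' @param base_speed Mean speed S0, a.u. per step.
#' @param speed_amplitude Speed modulation amplitude s, a.u. per step;
#'   must be smaller than `base_speed` so speed stays positive.
#' @param turn_amplitude Turning amplitude a, radians per step.
#' @param path_cutoff Correlation cut-off period C_T of the common path
#'   noise, steps.
#' @param displacement_cutoff Correlation cut-off period C_D of the
#'   positional displacement noise, steps.
#' @param spacing Target inter-individual distance r, a.u.
#' @param configuration `"front_back"` (placement segment parallel to the
#'   direction of motion, angle 0) or `"side_by_side"` (perpendicular,
#'   angle pi/2).
#' @param configuration_angle Orientation of the placement segment relative
#'   to the step direction, radians; overrides `configuration` when given.
#' @param n_individuals 2 or 3.
#' @param displacement_std Standard deviation of each displacement-noise
#'   component, a.u.; defaults to `spacing / 2`. Zero disables the noise.
#' @param dt Seconds per time step.
#' @param seed Integer seed for the flight.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_steps = 4096,
                       base_speed = 5,
                       speed_amplitude = 0.2,
                       turn_amplitude = 0.02,
                       path_cutoff = 300,
                       displacement_cutoff = 20,
                       spacing = 5,
                       configuration = c("front_back", "side_by_side"),
                       configuration_angle = NULL,
                       n_individuals = 2,
                       displacement_std = spacing / 2,
                       dt = 0.2,
                       seed = 1L) {
  configuration <- rlang::arg_match(configuration)
  if (is.null(configuration_angle)) {
    configuration_angle <- switch(configuration,
                                  front_back = 0,
                                  side_by_side = pi / 2)
  }
  cfg <- list(
    n_steps = as.integer(n_steps),
    base_speed = base_speed,
    speed_amplitude = speed_amplitude,
    turn_amplitude = turn_amplitude,
    path_cutoff = path_cutoff,
    displacement_cutoff = displacement_cutoff,
    spacing = spacing,
    configuration = configuration,
    configuration_angle = configuration_angle,
    n_individuals = as.integer(n_individuals),
    displacement_std = displacement_std,
    dt = dt,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  problems <- character()
  if (cfg$n_steps < 2) problems <- c(problems, "n_steps must be >= 2")
  if (cfg$speed_amplitude < 0) problems <- c(problems, "speed_amplitude must be >= 0")
  if (cfg$base_speed <= cfg$speed_amplitude) {
    problems <- c(problems, "base_speed must exceed speed_amplitude (speed must stay positive)")
  }
  if (cfg$turn_amplitude < 0) problems <- c(problems, "turn_amplitude must be >= 0")
  if (cfg$path_cutoff <= 0) problems <- c(problems, "path_cutoff must be > 0")
  if (cfg$displacement_cutoff <= 0) problems <- c(problems, "displacement_cutoff must be > 0")
  if (cfg$spacing <= 0) problems <- c(problems, "spacing must be > 0")
  if (!cfg$n_individuals %in% c(2L, 3L)) {
    problems <- c(problems, "n_individuals must be 2 or 3")
  }
  if (cfg$displacement_std < 0) problems <- c(problems, "displacement_std must be >= 0")
  if (cfg$dt <= 0) problems <- c(problems, "dt must be > 0")
  if (length(problems) > 0) {
    rlang::abort(paste0("Invalid simulation configuration:\n",
                        paste0("- ", problems, collapse = "\n")),
                 class = "flockdual_invalid_config")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Generate the common correlated-random path
#'
#' Builds the shared trajectory all individuals ride. Speeds are
#' `S(t) = S0 + s * eps1(t) / max|eps1|` and turning angles
#' `T(t) = a * eps2(t) / max|eps2|`, with `eps1`, `eps2` independent
#' low-pass-filtered uniform sequences (cut-off `path_cutoff`). Headings
#' accumulate the turnings (initial heading 0, mathematical convention,
#' counter-clockwise positive) and positions integrate speed along heading
#' from the origin. Consumes the current RNG stream; seed upstream.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `t`, `speed`, `turn`, `heading`, `x`, `y`;
#'   row `t` to `t + 1` is a step of length `speed[t]` in direction
#'   `heading[t]`.
#' @export
generate_common_path <- function(config) {
  validate_sim_config(config)
  n <- config$n_steps
  eps1 <- correlated_sequence(n, config$path_cutoff, "uniform_half")
  eps2 <- correlated_sequence(n, config$path_cutoff, "uniform_half")
  speed <- if (config$speed_amplitude == 0) {
    rep(config$base_speed, n)
  } else {
    config$base_speed + config$speed_amplitude * normalize_by_max_abs(eps1)
  }
  turn <- if (config$turn_amplitude == 0) {
    rep(0, n)
  } else {
    config$turn_amplitude * normalize_by_max_abs(eps2)
  }
  heading <- c(0, cumsum(turn[-n]))
  x <- c(0, cumsum(speed[-n] * cos(heading[-n])))
  y <- c(0, cumsum(speed[-n] * sin(heading[-n])))
  tibble::tibble(t = seq_len(n), speed = speed, turn = turn,
                 heading = heading, x = x, y = y)
}

# Offsets along the placement segment: equally spaced at `spacing`,
# centred on the path point so all individuals are statistically
# interchangeable relative to the common path.
segment_offsets <- function(n_individuals, spacing) {
  switch(as.character(n_individuals),
         `2` = c(-spacing / 2, spacing / 2),
         `3` = c(-spacing, 0, spacing),
         rlang::abort("`n_individuals` must be 2 or 3.",
                      class = "flockdual_invalid_input"))
}

#' Place individuals at fixed offsets along the moving placement segment
#'
#' At each step `t` a segment through the path point is drawn at angle
#' `configuration_angle` relative to the direction of the step from `t` to
#' `t + 1` (the final step reuses the preceding direction), and individuals
#' sit at equally spaced points on it, `spacing` apart, symmetric about the
#' path. Which individual occupies which offset is drawn uniformly at
#' random once per flight and held constant, so roles (front/back or
#' left/right) never switch within a flight. Positive offsets point ahead
#' in the front-back configuration and to the left in the side-by-side
#' configuration. Consumes the current RNG stream.
#'
#' @param path Tibble from [generate_common_path()].
#' @param config A [sim_config()].
#' @return A tibble with columns `individual_id`, `t`, `x_ideal`, `y_ideal`,
#'   `offset` (signed position along the segment, a.u., constant per
#'   individual).
#' @export
place_individuals <- function(path, config) {
  n <- nrow(path)
  if (n < 2) {
    rlang::abort("`path` must have at least 2 steps.",
                 class = "flockdual_invalid_input")
  }
  offsets <- segment_offsets(config$n_individuals, config$spacing)
  assigned <- sample(offsets)  # permutation: individual k -> assigned[k]
  seg_dir <- path$heading
  seg_dir[n] <- seg_dir[n - 1]  # defining step t -> t+1 absent at the end
  ux <- cos(seg_dir + config$configuration_angle)
  uy <- sin(seg_dir + config$configuration_angle)
  purrr::map_dfr(seq_len(config$n_individuals), function(k) {
    tibble::tibble(
      individual_id = k,
      t = path$t,
      x_ideal = path$x + assigned[k] * ux,
      y_ideal = path$y + assigned[k] * uy,
      offset = assigned[k]
    )
  })
}

#' Add autocorrelated recording noise to ideal tracks
#'
#' For each individual independently, the x and y components of the
#' displacement `eta(t)` are independent low-pass-filtered standard-normal
#' sequences (cut-off `displacement_cutoff`), each rescaled after filtering
#' to sample standard deviation `displacement_std`. Recorded positions are
#' `ideal + eta`. There is no cross-correlation between individuals.
#' Consumes the current RNG stream (x series then y series, in individual
#' order).
#'
#' @param ideal Tibble from [place_individuals()].
#' @param config A [sim_config()].
#' @return `ideal` with added columns `x`, `y` (recorded positions).
#' @export
add_recording_noise <- function(ideal, config) {
  n <- config$n_steps
  noise_component <- function() {
    if (config$displacement_std == 0) return(rep(0, n))
    eta <- correlated_sequence(n, config$displacement_cutoff, "standard_normal")
    rescale_to_std(as.numeric(eta), config$displacement_std)
  }
  ideal |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_modify(function(df, key) {
      df$x <- df$x_ideal + noise_component()
      df$y <- df$y_ideal + noise_component()
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("individual_id", "t", "x", "y", "x_ideal", "y_ideal",
                  "offset")
}

#' Simulate one flight
#'
#' Composes path generation, placement, and recording noise into one
#' complete flight, fully determined by `config$seed`. Sub-streams are
#' consumed in a fixed order (path speed noise, path turning noise, offset
#' assignment, then per-individual x and y displacement series), so the
#' whole flight is reproducible from the one seed.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per (step, individual): columns
#'   `trajectory_id`, `t`, `individual_id`, `x`, `y` (recorded),
#'   `x_ideal`, `y_ideal`, `offset`. The configuration is attached as
#'   attribute `"config"`.
#' @examples
#' tracks <- simulate_flock(sim_config(n_steps = 64, seed = 42))
#' dplyr::count(tracks, individual_id)
#' @export
simulate_flock <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  path <- generate_common_path(config)
  ideal <- place_individuals(path, config)
  tracks <- add_recording_noise(ideal, config)
  tracks <- dplyr::mutate(tracks, trajectory_id = 1L, .before = 1)
  attr(tracks, "config") <- config
  tracks
}

#' Simulate a collection of flights
#'
#' Runs [simulate_flock()] `n_flights` times with per-flight seeds derived
#' deterministically from `config$seed`, so an entire experiment is
#' reproducible from one master seed. Offset assignments (who is in front,
#' who is on the left) are redrawn independently every flight.
#'
#' @param config A [sim_config()]; `config$seed` acts as the master seed.
#' @param n_flights Number of flights.
#' @return A tibble as in [simulate_flock()] with `trajectory_id` in
#'   `1:n_flights`; flight seeds attached as attribute `"flight_seeds"`.
#' @export
simulate_flights <- function(config, n_flights = 100) {
  set.seed(config$seed)
  flight_seeds <- sample.int(.Machine$integer.max, n_flights)
  out <- purrr::map_dfr(seq_len(n_flights), function(i) {
    cfg_i <- config
    cfg_i$seed <- flight_seeds[i]
    fl <- simulate_flock(cfg_i)
    fl$trajectory_id <- i
    fl
  })
  attr(out, "config") <- config
  attr(out, "flight_seeds") <- flight_seeds
  out
}
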