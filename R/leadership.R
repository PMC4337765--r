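#' Directional correlation delay between two heading series
#'
#' Finds the lag `tau` in `[-max_lag, max_lag]` that maximizes the mean
#' cosine of the heading difference `cos(psi_i(t) - psi_j(t + tau))`,
#' averaged over the overlapping index range (no wrapping or padding).
#' Positive `tau*` means the focal individual `i` anticipates its partner:
#' the partner's headings best match the focal's earlier ones. Ties are
#' broken toward the smallest `|tau|`, then toward positive `tau`.
#'
#' @param heading_i,heading_j Equal-length numeric vectors of headings in
#'   radians (`NA`s allowed at the boundaries; pairs with an `NA` are
#'   excluded from each lag's average). Length must exceed `2 * max_lag`.
#' @param max_lag Maximum absolute lag searched, in time steps.
#' @return Integer `tau*` with the maximized mean cosine in attribute
#'   `"max_correlation"` and the full lag profile in attribute `"profile"`
#'   (a tibble with columns `tau`, `correlation`).
#' @examples
#' psi <- cumsum(rnorm(300, sd = 0.1))
#' directional_correlation_delay(psi, dplyr::lag(psi, 3), max_lag = 10)
#' @export
directional_correlation_delay <- function(heading_i, heading_j,
                                          max_lag = 50) {
  n <- length(heading_i)
  if (length(heading_j) != n) {
    rlang::abort("Heading series must have equal length.",
                 class = "flockdual_invalid_input")
  }
  if (max_lag < 1) {
    rlang::abort("`max_lag` must be >= 1.",
                 class = "flockdual_invalid_input")
  }
  if (n <= 2 * max_lag) {
    rlang::abort("Series too short for the requested `max_lag`.",
                 class = "flockdual_invalid_input")
  }
  taus <- -max_lag:max_lag
  corr <- vapply(taus, function(tau) {
    if (tau >= 0) {
      a <- heading_i[seq_len(n - tau)]
      b <- heading_j[seq_len(n - tau) + tau]
    } else {
      a <- heading_i[seq_len(n + tau) - tau]
      b <- heading_j[seq_len(n + tau)]
    }
    mean(cos(a - b), na.rm = TRUE)
  }, numeric(1))
  # ties: smallest |tau| first, then positive before negative
  pref <- order(abs(taus), -taus)
  best <- pref[which.max(corr[pref] >= max(corr))]
  tau_star <- taus[best]
  structure(tau_star,
            max_correlation = corr[best],
            profile = tibble::tibble(tau = taus, correlation = corr))
}

#' Leadership experiment: delays by position in the pair
#'
#' Simulates `n_flights` two-individual flights, computes the directional
#' correlation delay of each individual as focal, and labels each value by
#' the focal's role: `front`/`back` in the front-back configuration (sign
#' of the offset along the direction of motion), `left`/`right` side by
#' side. The distribution of `tau*` by role is the leadership signature:
#' a front individual that "appears to change direction first" has
#' positive delays.
#'
#' @param config A two-individual [sim_config()]; `config$seed` is the
#'   master seed.
#' @param n_flights Number of flights (120 in the study conditions).
#' @param max_lag Maximum absolute lag searched, steps.
#' @return A tibble of class `"delay_table"`: `trajectory_id`,
#'   `focal_role`, `tau_star` (steps), `max_correlation`.
#' @export
delay_experiment <- function(config, n_flights = 120, max_lag = 50) {
  if (config$n_individuals != 2L) {
    rlang::abort("The delay experiment uses two-individual flights.",
                 class = "flockdual_invalid_input")
  }
  tracks <- simulate_flights(config, n_flights)
  delay_table(tracks, configuration = config$configuration,
              dt = config$dt, max_lag = max_lag)
}

#' Directional delays from an existing track table
#'
#' @param tracks Two-individual tracks tibble with columns
#'   `trajectory_id`, `t`, `individual_id`, `x`, `y`, `offset`.
#' @param configuration `"front_back"` or `"side_by_side"`; controls role
#'   labels (`front`/`back` vs `left`/`right`).
#' @param dt Seconds per time step (kinematics only; delays are in steps).
#' @param max_lag Maximum absolute lag searched, steps.
#' @return A tibble of class `"delay_table"` (see [delay_experiment()]).
#' @export
delay_table <- function(tracks,
                        configuration = c("front_back", "side_by_side"),
                        dt = 0.2, max_lag = 50) {
  configuration <- rlang::arg_match(configuration)
  role_of <- function(offset) {
    if (configuration == "front_back") {
      ifelse(offset > 0, "front", "back")
    } else {
      ifelse(offset > 0, "left", "right")
    }
  }
  out <- tracks |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::group_map(function(df, key) {
      ids <- sort(unique(df$individual_id))
      kin <- lapply(ids, function(id) {
        sub <- df[df$individual_id == id, ]
        k <- kinematic_series(sub[, c("x", "y")], dt)
        list(heading = k$heading, offset = sub$offset[1])
      })
      purrr::map_dfr(1:2, function(i) {
        j <- 3 - i
        ts <- directional_correlation_delay(kin[[i]]$heading,
                                            kin[[j]]$heading, max_lag)
        tibble::tibble(
          trajectory_id = key$trajectory_id,
          focal_role = role_of(kin[[i]]$offset),
          tau_star = as.integer(ts),
          max_correlation = attr(ts, "max_correlation")
        )
      })
    }) |>
    purrr::list_rbind()
  structure(out, class = c("delay_table", class(tibble::tibble())),
            configuration = configuration, max_lag = max_lag)
}
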