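#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy polar_response_map
#' @export
tidy.polar_response_map <- function(x, ...) tibble::as_tibble(x)

#' @method tidy theta_phi_map
#' @export
tidy.theta_phi_map <- function(x, ...) tibble::as_tibble(x)

#' @method tidy fb_profile
#' @export
tidy.fb_profile <- function(x, ...) tibble::as_tibble(x)

#' @method tidy neighbour_pair_map
#' @export
tidy.neighbour_pair_map <- function(x, ...) tibble::as_tibble(x)

#' @method tidy delay_table
#' @export
tidy.delay_table <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a polar force map
#' @param x A `"polar_response_map"`.
#' @param ... Unused.
#' @return A tibble with observation, drop and reliable-cell counts.
#' @method glance polar_response_map
#' @export
glance.polar_response_map <- function(x, ...) {
  tibble::tibble(n_obs = attr(x, "n_obs"),
                 n_dropped = attr(x, "n_dropped"),
                 n_cells = nrow(x),
                 n_reliable = sum(x$reliable))
}

#' One-row summary of an attraction-versus-alignment map
#' @param x A `"theta_phi_map"`.
#' @param ... Unused.
#' @return A tibble with counts and the two modulation indices.
#' @method glance theta_phi_map
#' @export
glance.theta_phi_map <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_obs = attr(x, "n_obs"),
                   n_dropped = attr(x, "n_dropped"),
                   r_min = attr(x, "r_min")),
    modulation_indices(x)
  )
}

#' One-row summary of a front-back response profile
#' @param x An `"fb_profile"`.
#' @param ... Unused.
#' @return A tibble with counts, the response kind, and the sign-change
#'   location on the neighbour-ahead branch.
#' @method glance fb_profile
#' @export
glance.fb_profile <- function(x, ...) {
  cr <- acceleration_sign_crossing(x)
  tibble::tibble(n_obs = attr(x, "n_obs"),
                 n_dropped = attr(x, "n_dropped"),
                 response = attr(x, "response"),
                 crossing = cr$crossing)
}

#' One-row summary of a two-neighbour response map
#' @param x A `"neighbour_pair_map"`.
#' @param ... Unused.
#' @return A tibble with the response kind, ordering rule and modulation
#'   range over reliable cells.
#' @method glance neighbour_pair_map
#' @export
glance.neighbour_pair_map <- function(x, ...) {
  tibble::tibble(response = attr(x, "response"),
                 ordering = attr(x, "ordering"),
                 modulation = map_modulation(x))
}

#' Per-role summary of a delay table
#' @param x A `"delay_table"`.
#' @param ... Unused.
#' @return A tibble with one row per focal role: mean, median and
#'   interquartile range of `tau*` and the share of flights with
#'   `|tau*| = 1`.
#' @method glance delay_table
#' @export
glance.delay_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$focal_role) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_tau = mean(.data$tau_star),
      median_tau = stats::median(.data$tau_star),
      iqr_tau = stats::IQR(.data$tau_star),
      share_abs_1 = mean(abs(.data$tau_star) == 1),
      .groups = "drop")
}
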