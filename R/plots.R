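# Quick-look plots. Conventions follow the analysis layer: angles are
# right-positive and the focal individual heads "up the page", so a
# neighbour at theta = 0 is plotted at the top.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot polar_response_map
#' @export
autoplot.polar_response_map <- function(object,
                                        fill = c("mean_turn",
                                                 "mean_accel", "n"),
                                        ...) {
  fill <- rlang::arg_match(fill)
  df <- tibble::as_tibble(object)
  df[[fill]][!df$reliable & fill != "n"] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta_mid, y = .data$r_mid,
                                   fill = .data[[fill]])) +
    ggplot2::geom_tile(width = df$theta_hi - df$theta_lo,
                       height = df$r_hi - df$r_lo) +
    ggplot2::coord_polar(theta = "x", start = pi) +
    ggplot2::scale_x_continuous(limits = c(-pi, pi),
                                breaks = c(-pi / 2, 0, pi / 2),
                                labels = c("left", "ahead", "right")) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey85") +
    ggplot2::labs(x = NULL, y = "distance (a.u.)", fill = fill,
                  title = "Apparent response vs neighbour position") +
    ggplot2::theme_minimal()
}

#' @method autoplot theta_phi_map
#' @export
autoplot.theta_phi_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mean_turn[!df$reliable] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta_mid, y = .data$phi_mid,
                                   fill = .data$mean_turn)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey85") +
    ggplot2::labs(x = "relative direction \u03d1 (rad, right +)",
                  y = "relative bearing \u03c6 (rad, right +)",
                  fill = "turning (rad/s)",
                  title = "Attraction vs alignment turning map") +
    ggplot2::theme_minimal()
}

#' @method autoplot fb_profile
#' @export
autoplot.fb_profile <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$n > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$mean_response)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(alpha = .data$reliable)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$reliable)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = "front-back distance to neighbour (a.u., + = ahead)",
                  y = paste0("mean ", attr(object, "response")),
                  title = "Response vs signed front-back distance") +
    ggplot2::theme_minimal()
}

#' @method autoplot neighbour_pair_map
#' @export
autoplot.neighbour_pair_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d1_mid, y = .data$d2_mid,
                                   fill = .data$mean_response)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "white") +
    ggplot2::labs(x = "front-back distance, neighbour 1 (a.u.)",
                  y = "front-back distance, neighbour 2 (a.u.)",
                  fill = attr(object, "response"),
                  title = paste0("Two-neighbour response (",
                                 attr(object, "ordering"), ")")) +
    ggplot2::theme_minimal()
}

#' @method autoplot delay_table
#' @export
autoplot.delay_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$focal_role, y = .data$tau_star)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "focal position", y = "tau* (steps)",
                  title = "Directional correlation delay by position") +
    ggplot2::theme_minimal()
}
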