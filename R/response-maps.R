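# Bin assignment on half-open (left, right] intervals, matching the
# (-pi, pi] angle wrap. Returns NA outside the edge range.
bin_index <- function(x, edges) {
  i <- findInterval(x, edges, left.open = TRUE, rightmost.closed = FALSE)
  i[x <= edges[1] | x > edges[length(edges)]] <- NA_integer_
  i
}

bin_mid <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

new_response_map <- function(cells, subclass, n_obs, n_dropped, min_count,
                             ...) {
  structure(cells,
            class = c(subclass, class(tibble::tibble())),
            n_obs = n_obs, n_dropped = n_dropped, min_count = min_count,
            ...)
}

#' Polar force map of turning and acceleration responses
#'
#' Bins pairwise observations by the neighbour's position in the focal
#' frame — distance and right-positive relative direction `theta` (0 =
#' dead ahead) — and averages the focal's turning and tangential
#' acceleration responses per cell. This is the classic "force map" that
#' individual-level studies of schooling and flocking reconstruct from
#' tracked trajectories.
#'
#' Observations beyond the outermost radial edge are dropped and counted
#' (attribute `n_dropped`). Cells with fewer than `min_count` observations
#' are flagged `reliable = FALSE` and should not be read as structure.
#'
#' @param obs Observation table from [pair_observations()].
#' @param radial_edges Increasing numeric vector of distance bin edges,
#'   a.u. Default: 8 bins out to 20 a.u.
#' @param angular_edges Increasing numeric vector of angle bin edges over
#'   (-pi, pi]. Default: 12 bins.
#' @param min_count Minimum per-cell count for a reliable mean.
#' @return A tibble of class `"polar_response_map"`, one row per cell:
#'   `r_lo`, `r_hi`, `r_mid`, `theta_lo`, `theta_hi`, `theta_mid`, `n`,
#'   `mean_turn` (rad/s, right-positive), `mean_accel` (a.u./s^2),
#'   `reliable`. Empty cells have `n = 0` and `NA` means.
#' @export
polar_response_map <- function(obs,
                               radial_edges = seq(0, 20, by = 2.5),
                               angular_edges = seq(-pi, pi, length.out = 13),
                               min_count = 100) {
  stopifnot(all(diff(radial_edges) > 0), all(diff(angular_edges) > 0))
  ri <- bin_index(obs$d, radial_edges)
  ai <- bin_index(obs$theta, angular_edges)
  # theta = -pi wraps to the pi end of the first bin's mirror; the wrap
  # convention (-pi, pi] makes -pi unreachable, so only d can drop rows
  keep <- !is.na(ri) & !is.na(ai)
  cells <- tibble::tibble(ri = ri[keep], ai = ai[keep],
                          turn = obs$turn[keep], accel = obs$accel[keep]) |>
    dplyr::group_by(.data$ri, .data$ai) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_turn = mean(.data$turn),
                     mean_accel = mean(.data$accel),
                     .groups = "drop")
  grid <- tidyr::expand_grid(ri = seq_along(radial_edges[-1]),
                             ai = seq_along(angular_edges[-1]))
  cells <- grid |>
    dplyr::left_join(cells, by = c("ri", "ai")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      r_lo = radial_edges[.data$ri], r_hi = radial_edges[.data$ri + 1],
      r_mid = bin_mid(radial_edges)[.data$ri],
      theta_lo = angular_edges[.data$ai],
      theta_hi = angular_edges[.data$ai + 1],
      theta_mid = bin_mid(angular_edges)[.data$ai],
      reliable = .data$n >= min_count
    ) |>
    dplyr::select("r_lo", "r_hi", "r_mid", "theta_lo", "theta_hi",
                  "theta_mid", "n", "mean_turn", "mean_accel", "reliable")
  new_response_map(cells, "polar_response_map",
                   n_obs = nrow(obs), n_dropped = sum(!keep),
                   min_count = min_count)
}

#' Response profile along the signed front-back distance
#'
#' Bins observations by the signed front-back distance of the neighbour
#' (`d_fb`, positive = neighbour ahead) and averages the chosen response
#' per bin. The acceleration profile exposes the repulsion-to-attraction
#' boundary: acceleration is negative when a neighbour ahead is closer
#' than the target spacing and positive beyond it.
#'
#' @param obs Observation table from [pair_observations()].
#' @param edges Increasing bin edges for `d_fb`, a.u. Default 1 a.u. bins
#'   over \[-15, 15\].
#' @param response `"accel"` or `"turn"`.
#' @param min_count Minimum per-bin count for a reliable mean.
#' @return A tibble of class `"fb_profile"`: `lo`, `hi`, `mid`, `n`,
#'   `mean_response`, `reliable`, with the response kind in attribute
#'   `"response"`.
#' @export
fb_response_profile <- function(obs, edges = seq(-15, 15, by = 1),
                                response = c("accel", "turn"),
                                min_count = 100) {
  response <- rlang::arg_match(response)
  stopifnot(all(diff(edges) > 0))
  bi <- bin_index(obs$d_fb, edges)
  keep <- !is.na(bi)
  prof <- tibble::tibble(bi = bi[keep], y = obs[[response]][keep]) |>
    dplyr::group_by(.data$bi) |>
    dplyr::summarise(n = dplyr::n(), mean_response = mean(.data$y),
                     .groups = "drop")
  prof <- tibble::tibble(bi = seq_along(edges[-1])) |>
    dplyr::left_join(prof, by = "bi") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      lo = edges[.data$bi], hi = edges[.data$bi + 1],
      mid = bin_mid(edges)[.data$bi],
      reliable = .data$n >= min_count
    ) |>
    dplyr::select("lo", "hi", "mid", "n", "mean_response", "reliable")
  new_response_map(prof, "fb_profile",
                   n_obs = nrow(obs), n_dropped = sum(!keep),
                   min_count = min_count, response = response)
}

#' Sign-change location of the acceleration profile on the ahead branch
#'
#' Walks the reliable bins of a front-back response profile outward along
#' the neighbour-ahead branch (`mid > 0`) and locates the first sign change
#' of the mean response by linear interpolation between the two adjacent
#' bin centres of opposite sign. In the front-back configuration this is
#' the boundary between the (apparent) repulsion and attraction zones.
#'
#' @param profile An `"fb_profile"` from [fb_response_profile()].
#' @return A one-row tibble with `crossing` (a.u., `NA` if no sign change
#'   exists on the branch — reported as absent, not an error) and
#'   `n_bins_used`.
#' @export
acceleration_sign_crossing <- function(profile) {
  branch <- profile |>
    dplyr::filter(.data$mid > 0, .data$reliable,
                  !is.na(.data$mean_response)) |>
    dplyr::arrange(.data$mid)
  crossing <- NA_real_
  if (nrow(branch) >= 2) {
    y <- branch$mean_response
    x <- branch$mid
    flips <- which(sign(y[-length(y)]) * sign(y[-1]) < 0)
    if (length(flips) > 0) {
      i <- flips[1]
      crossing <- x[i] + (x[i + 1] - x[i]) * y[i] / (y[i] - y[i + 1])
    } else if (any(y == 0)) {
      crossing <- x[which(y == 0)[1]]
    }
  }
  tibble::tibble(crossing = crossing, n_bins_used = nrow(branch))
}

#' Attraction-versus-alignment turning map
#'
#' Bins the turning response by the neighbour's relative direction `theta`
#' (attraction axis) and relative bearing `phi` (alignment axis), both
#' right-positive, restricted to observations with the neighbour in the
#' attraction zone (`d > r_min`). Modulation along `theta` reveals an
#' apparent attraction rule; modulation along `phi` an apparent alignment
#' rule.
#'
#' @param obs Observation table from [pair_observations()].
#' @param r_min Attraction-zone cutoff, a.u.; only observations with
#'   `d > r_min` contribute.
#' @param n_bins Number of bins per axis over (-pi, pi].
#' @param min_count Minimum per-cell count for a reliable mean.
#' @return A tibble of class `"theta_phi_map"`, one row per cell:
#'   `theta_lo`, `theta_hi`, `theta_mid`, `phi_lo`, `phi_hi`, `phi_mid`,
#'   `n`, `mean_turn`, `reliable`.
#' @export
theta_phi_map <- function(obs, r_min = 5, n_bins = 12, min_count = 100) {
  if (r_min < 0) {
    rlang::abort("`r_min` must be >= 0.", class = "flockdual_invalid_input")
  }
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  zone <- dplyr::filter(obs, .data$d > r_min)
  ti <- bin_index(zone$theta, edges)
  pi_ <- bin_index(zone$phi, edges)
  keep <- !is.na(ti) & !is.na(pi_)
  cells <- tibble::tibble(ti = ti[keep], pi_ = pi_[keep],
                          turn = zone$turn[keep]) |>
    dplyr::group_by(.data$ti, .data$pi_) |>
    dplyr::summarise(n = dplyr::n(), mean_turn = mean(.data$turn),
                     .groups = "drop")
  cells <- tidyr::expand_grid(ti = seq_len(n_bins), pi_ = seq_len(n_bins)) |>
    dplyr::left_join(cells, by = c("ti", "pi_")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      theta_lo = edges[.data$ti], theta_hi = edges[.data$ti + 1],
      theta_mid = bin_mid(edges)[.data$ti],
      phi_lo = edges[.data$pi_], phi_hi = edges[.data$pi_ + 1],
      phi_mid = bin_mid(edges)[.data$pi_],
      reliable = .data$n >= min_count
    ) |>
    dplyr::select("theta_lo", "theta_hi", "theta_mid",
                  "phi_lo", "phi_hi", "phi_mid",
                  "n", "mean_turn", "reliable")
  new_response_map(cells, "theta_phi_map",
                   n_obs = nrow(zone), n_dropped = sum(!keep),
                   min_count = min_count, r_min = r_min)
}

#' Modulation indices of a turning map
#'
#' Quantifies how strongly the mean turning response is modulated along
#' the attraction (`theta`) and alignment (`phi`) axes. The index along an
#' axis is conditional: within each bin of the other axis, the range
#' (max - min) of the per-cell mean turning across the axis of interest,
#' then count-weighted-averaged over those bins. Conditioning matters
#' because the sign of the alignment response inverts between
#' neighbour-ahead and neighbour-behind rows, so a plain marginal over
#' `theta` cancels real `phi` structure. Only reliable cells (count at
#' least the map's `min_count`) enter — unreliable cells are never
#' silently averaged, so a handful of rare, noisy configurations cannot
#' masquerade as modulation.
#'
#' Because the overall amplitude of apparent responses scales with how
#' quickly the positional noise reverts, comparisons across noise regimes
#' should use `phi_share`, the `phi` index as a fraction of the `theta`
#' index, which is invariant to that overall scale (it is what a reader
#' of a per-panel-normalized map perceives).
#'
#' @param map A `"theta_phi_map"`.
#' @return A one-row tibble with `theta_modulation`, `phi_modulation`
#'   (rad/s) and `phi_share` (dimensionless).
#' @export
modulation_indices <- function(map) {
  conditional_range <- function(along_mid, cond_mid) {
    rel <- map[map$reliable, ]
    rows <- split(rel, rel[[cond_mid]])
    rows <- rows[vapply(rows, nrow, integer(1)) >= 2]
    if (length(rows) == 0) return(NA_real_)
    w <- vapply(rows, function(r) sum(r$n), numeric(1))
    rg <- vapply(rows, function(r) diff(range(r$mean_turn)), numeric(1))
    sum(w * rg) / sum(w)
  }
  th <- conditional_range("theta_mid", "phi_mid")
  ph <- conditional_range("phi_mid", "theta_mid")
  tibble::tibble(theta_modulation = th,
                 phi_modulation = ph,
                 phi_share = ph / th)
}

#' Observed responses to two neighbours
#'
#' For three individuals moving in a front-back configuration, draws one
#' focal individual uniformly at random per flight (consumes the current
#' RNG stream) and bins the focal's response by the signed front-back
#' distances to its two neighbours. Neighbour ordering onto the two axes
#' is either `"nearest"` (axis 1 = neighbour with the smaller |d_fb| at
#' each observation) or `"random"` (per-observation coin flip, which makes
#' the map symmetric in its axes in expectation).
#'
#' @param obs Observation table from [pair_observations()] on a
#'   three-individual track set.
#' @param edges Increasing bin edges shared by both axes, a.u.
#' @param response `"turn"` or `"accel"`.
#' @param ordering `"nearest"` or `"random"`.
#' @param min_count Minimum per-cell count for a reliable mean.
#' @return A tibble of class `"neighbour_pair_map"`, one row per cell:
#'   `d1_lo`, `d1_hi`, `d1_mid`, `d2_lo`, `d2_hi`, `d2_mid`, `n`,
#'   `mean_response`, `reliable`. Cells never observed have `n = 0` and
#'   `NA` mean (missing values).
#' @export
multi_neighbour_observed <- function(obs,
                                     edges = seq(-15, 15, by = 1),
                                     response = c("turn", "accel"),
                                     ordering = c("nearest", "random"),
                                     min_count = 100) {
  response <- rlang::arg_match(response)
  ordering <- rlang::arg_match(ordering)
  if (length(unique(obs$neighbour_id)) != 3 &&
      length(unique(obs$focal_id)) != 3) {
    rlang::abort("A three-individual observation table is required.",
                 class = "flockdual_invalid_input")
  }
  # one focal per flight, drawn uniformly
  focal_pick <- obs |>
    dplyr::distinct(.data$trajectory_id) |>
    dplyr::mutate(picked = sample(sort(unique(obs$focal_id)),
                                  dplyr::n(), replace = TRUE))
  wide <- obs |>
    dplyr::inner_join(focal_pick, by = "trajectory_id") |>
    dplyr::filter(.data$focal_id == .data$picked) |>
    dplyr::group_by(.data$trajectory_id, .data$t) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::arrange(.data$neighbour_id, .by_group = TRUE) |>
    dplyr::summarise(
      da = .data$d_fb[1], db = .data$d_fb[2],
      y = .data[[response]][1],
      .groups = "drop")
  if (ordering == "nearest") {
    swap <- abs(wide$db) < abs(wide$da)
  } else {
    swap <- stats::runif(nrow(wide)) < 0.5
  }
  d1 <- ifelse(swap, wide$db, wide$da)
  d2 <- ifelse(swap, wide$da, wide$db)
  i1 <- bin_index(d1, edges)
  i2 <- bin_index(d2, edges)
  keep <- !is.na(i1) & !is.na(i2)
  cells <- tibble::tibble(i1 = i1[keep], i2 = i2[keep], y = wide$y[keep]) |>
    dplyr::group_by(.data$i1, .data$i2) |>
    dplyr::summarise(n = dplyr::n(), mean_response = mean(.data$y),
                     .groups = "drop")
  nb <- length(edges) - 1
  cells <- tidyr::expand_grid(i1 = seq_len(nb), i2 = seq_len(nb)) |>
    dplyr::left_join(cells, by = c("i1", "i2")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      d1_lo = edges[.data$i1], d1_hi = edges[.data$i1 + 1],
      d1_mid = bin_mid(edges)[.data$i1],
      d2_lo = edges[.data$i2], d2_hi = edges[.data$i2 + 1],
      d2_mid = bin_mid(edges)[.data$i2],
      reliable = .data$n >= min_count
    ) |>
    dplyr::select("d1_lo", "d1_hi", "d1_mid", "d2_lo", "d2_hi", "d2_mid",
                  "n", "mean_response", "reliable")
  new_response_map(cells, "neighbour_pair_map",
                   n_obs = nrow(wide), n_dropped = sum(!keep),
                   min_count = min_count, response = response,
                   ordering = ordering, edges = edges)
}

#' Predict two-neighbour responses from the pairwise profile
#'
#' Builds the response surface expected if the focal combined two
#' independent pairwise interactions by averaging them:
#' `predicted(d1, d2) = (profile(d1) + profile(d2)) / 2`, where `profile`
#' is the single-neighbour response profile versus signed front-back
#' distance estimated from two-individual simulations on the same bins.
#'
#' @param profile An `"fb_profile"` (from [fb_response_profile()]) whose
#'   bin edges match `edges` exactly.
#' @param edges Bin edges of the target grid; must equal the profile's.
#' @return A tibble of class `"neighbour_pair_map"` with `mean_response`
#'   holding the predicted surface; symmetric in its two axes.
#' @export
predict_from_pairwise <- function(profile, edges = seq(-15, 15, by = 1)) {
  prof_edges <- sort(unique(c(profile$lo, profile$hi)))
  if (!isTRUE(all.equal(prof_edges, as.numeric(edges)))) {
    rlang::abort("Profile bin edges must match the target grid exactly.",
                 class = "flockdual_invalid_input")
  }
  nb <- length(edges) - 1
  p <- profile$mean_response[order(profile$mid)]
  cells <- tidyr::expand_grid(i1 = seq_len(nb), i2 = seq_len(nb)) |>
    dplyr::mutate(
      n = NA_integer_,
      mean_response = (p[.data$i1] + p[.data$i2]) / 2,
      d1_lo = edges[.data$i1], d1_hi = edges[.data$i1 + 1],
      d1_mid = bin_mid(edges)[.data$i1],
      d2_lo = edges[.data$i2], d2_hi = edges[.data$i2 + 1],
      d2_mid = bin_mid(edges)[.data$i2],
      reliable = !is.na(.data$mean_response)
    ) |>
    dplyr::select("d1_lo", "d1_hi", "d1_mid", "d2_lo", "d2_hi", "d2_mid",
                  "n", "mean_response", "reliable")
  new_response_map(cells, "neighbour_pair_map",
                   n_obs = NA_integer_, n_dropped = NA_integer_,
                   min_count = attr(profile, "min_count"),
                   response = attr(profile, "response"),
                   ordering = "predicted", edges = edges)
}

#' Modulation range of a two-neighbour response map
#'
#' Max minus min of the per-cell mean response over reliable cells; the
#' summary used to compare observed maps with pairwise-average predictions.
#'
#' @param map A `"neighbour_pair_map"`.
#' @return A single number (rad/s or a.u./s^2 depending on the response).
#' @export
map_modulation <- function(map) {
  vals <- map$mean_response[map$reliable & !is.na(map$mean_response)]
  if (length(vals) == 0) return(NA_real_)
  diff(range(vals))
}
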