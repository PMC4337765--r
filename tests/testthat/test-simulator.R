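test_that("degenerate noise gives a straight constant-speed path", {
  cfg <- quick_config(speed_amplitude = 0, turn_amplitude = 0)
  set.seed(cfg$seed)
  path <- generate_common_path(cfg)
  expect_equal(path$speed, rep(5, cfg$n_steps))
  expect_equal(path$heading, rep(0, cfg$n_steps))
  expect_equal(path$y, rep(0, cfg$n_steps))
  expect_equal(diff(path$x), rep(5, cfg$n_steps - 1))
})

test_that("speeds stay within S0 +/- s and turnings within +/- a", {
  cfg <- quick_config(n_steps = 2048L)
  set.seed(cfg$seed)
  path <- generate_common_path(cfg)
  expect_true(all(path$speed >= 4.8 & path$speed <= 5.2))
  expect_true(all(abs(path$turn) <= 0.02 + 1e-15))
  # amplitude 1 is attained by the max-abs normalization
  expect_equal(max(abs(path$speed - 5)), 0.2, tolerance = 1e-12)
})

test_that("vectorized headings and positions match a step-by-step loop", {
  cfg <- quick_config(n_steps = 200L)
  set.seed(cfg$seed)
  path <- generate_common_path(cfg)
  n <- nrow(path)
  h <- numeric(n); x <- numeric(n); y <- numeric(n)
  for (t in 1:(n - 1)) {
    h[t + 1] <- h[t] + path$turn[t]
    x[t + 1] <- x[t] + path$speed[t] * cos(h[t])
    y[t + 1] <- y[t] + path$speed[t] * sin(h[t])
  }
  expect_equal(path$heading, h, tolerance = 1e-10)
  expect_equal(path$x, x, tolerance = 1e-10)
  expect_equal(path$y, y, tolerance = 1e-10)
})

test_that("front-back placement puts the pair exactly r apart along the step direction", {
  cfg <- quick_config(configuration = "front_back")
  set.seed(cfg$seed)
  path <- generate_common_path(cfg)
  ideal <- place_individuals(path, cfg)
  wide <- tidyr::pivot_wider(ideal, id_cols = "t",
                             names_from = "individual_id",
                             values_from = c("x_ideal", "y_ideal"))
  dx <- wide$x_ideal_2 - wide$x_ideal_1
  dy <- wide$y_ideal_2 - wide$y_ideal_1
  expect_equal(sqrt(dx^2 + dy^2), rep(5, nrow(wide)), tolerance = 1e-10)
  # displacement is parallel to the step direction at every interior step
  n <- cfg$n_steps
  seg <- path$heading
  seg[n] <- seg[n - 1]
  cross <- dx * sin(seg) - dy * cos(seg)
  expect_lt(max(abs(cross)), 1e-10)
})

test_that("side-by-side placement on a straight path gives parallel tracks r apart", {
  cfg <- quick_config(speed_amplitude = 0, turn_amplitude = 0,
                      configuration = "side_by_side")
  set.seed(cfg$seed)
  path <- generate_common_path(cfg)
  ideal <- place_individuals(path, cfg)
  for (k in 1:2) {
    yk <- ideal$y_ideal[ideal$individual_id == k]
    expect_equal(yk, rep(yk[1], length(yk)))  # straight, parallel to +x
    expect_equal(abs(yk[1]), 2.5)
  }
})

test_that("offset assignment is uniform across flights", {
  cfg <- quick_config(n_steps = 16L)
  n_flights <- 400
  tr <- simulate_flights(cfg, n_flights)
  first_offsets <- tr |>
    dplyr::filter(.data$individual_id == 1, .data$t == 1) |>
    dplyr::pull(.data$offset)
  expect_equal(mean(first_offsets > 0), 0.5, tolerance = 0.1)
})

test_that("zero displacement noise leaves recorded equal to ideal and d = r exactly", {
  cfg <- quick_config(displacement_std = 0)
  tr <- simulate_flock(cfg)
  expect_equal(tr$x, tr$x_ideal)
  expect_equal(tr$y, tr$y_ideal)
  wide <- tidyr::pivot_wider(tr, id_cols = "t",
                             names_from = "individual_id",
                             values_from = c("x", "y"))
  d <- sqrt((wide$x_2 - wide$x_1)^2 + (wide$y_2 - wide$y_1)^2)
  expect_equal(d, rep(5, nrow(wide)), tolerance = 1e-10)
})

test_that("recorded minus ideal has the configured std and no cross-correlation", {
  cfg <- sim_config(n_steps = 2048L, seed = 55L)
  tr <- simulate_flights(cfg, 20)
  eta <- tr |>
    dplyr::mutate(ex = .data$x - .data$x_ideal,
                  ey = .data$y - .data$y_ideal)
  # rescaling is per flight, per component, so each flight is exact
  per_flight <- eta |>
    dplyr::group_by(.data$trajectory_id, .data$individual_id) |>
    dplyr::summarise(sx = sd(.data$ex), sy = sd(.data$ey),
                     .groups = "drop")
  expect_true(all(abs(per_flight$sx - 2.5) < 1e-10))
  expect_true(all(abs(per_flight$sy - 2.5) < 1e-10))
  wide <- eta |>
    dplyr::select("trajectory_id", "t", "individual_id", "ex") |>
    tidyr::pivot_wider(names_from = "individual_id",
                       values_from = "ex", names_prefix = "i")
  expect_lt(abs(cor(wide$i1, wide$i2)), 0.05)
})

test_that("same seed reproduces a flight bit-for-bit", {
  cfg <- quick_config()
  a <- simulate_flock(cfg)
  b <- simulate_flock(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("near-white noise shows regression to the mean of the relative position", {
  cfg <- sim_config(n_steps = 2048L, displacement_cutoff = 1,
                    seed = 31L)
  tr <- simulate_flights(cfg, 10)
  rel <- tr |>
    dplyr::select("trajectory_id", "t", "individual_id", "x", "y",
                  "x_ideal", "y_ideal") |>
    tidyr::pivot_wider(names_from = "individual_id",
                       values_from = c("x", "y", "x_ideal", "y_ideal")) |>
    dplyr::mutate(devx = (.data$x_2 - .data$x_1) -
                    (.data$x_ideal_2 - .data$x_ideal_1),
                  devy = (.data$y_2 - .data$y_1) -
                    (.data$y_ideal_2 - .data$y_ideal_1)) |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::mutate(dxn = dplyr::lead(.data$devx) - .data$devx,
                  dyn = dplyr::lead(.data$devy) - .data$devy) |>
    dplyr::ungroup() |>
    tidyr::drop_na()
  slope_x <- coef(lm(dxn ~ devx, data = rel))[2]
  slope_y <- coef(lm(dyn ~ devy, data = rel))[2]
  expect_lt(slope_x, 0)
  expect_lt(slope_y, 0)
})

test_that("longer displacement cut-off increases noise persistence", {
  ac_for <- function(cd) {
    mean(vapply(1:20, function(i) {
      cfg <- sim_config(n_steps = 1024L, displacement_cutoff = cd,
                        seed = 700L + i)
      tr <- simulate_flock(cfg)
      e1 <- tr$x[tr$individual_id == 1] - tr$x_ideal[tr$individual_id == 1]
      lag_autocor(e1, 1)
    }, numeric(1)))
  }
  expect_gt(ac_for(100), ac_for(20))
})

test_that("configuration validation catches bad fields", {
  expect_error(sim_config(n_individuals = 4),
               class = "flockdual_invalid_config")
  expect_error(sim_config(base_speed = 0.1, speed_amplitude = 0.2),
               class = "flockdual_invalid_config")
  expect_error(sim_config(path_cutoff = -1),
               class = "flockdual_invalid_config")
})
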