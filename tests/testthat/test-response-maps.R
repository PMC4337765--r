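fake_obs <- function(d, theta, phi = 0, turn = 0, accel = 0) {
  tibble::tibble(d = d, theta = theta, phi = phi,
                 d_fb = d * cos(theta), d_lat = d * sin(theta),
                 turn = turn, accel = accel)
}

test_that("a single observation lands in exactly one polar cell", {
  obs <- fake_obs(d = 7, theta = 0.3, turn = 0.5, accel = -0.2)
  m <- polar_response_map(obs, min_count = 1)
  expect_equal(sum(m$n), 1)
  hit <- m[m$n == 1, ]
  expect_true(hit$r_lo < 7 & 7 <= hit$r_hi)
  expect_true(hit$theta_lo < 0.3 & 0.3 <= hit$theta_hi)
  expect_equal(hit$mean_turn, 0.5)
  expect_equal(hit$mean_accel, -0.2)
  expect_true(all(is.na(m$mean_turn[m$n == 0])))
})

test_that("binned cell means match an explicit per-observation loop", {
  set.seed(21)
  obs <- fake_obs(d = runif(500, 0, 22), theta = runif(500, -pi, pi),
                  turn = rnorm(500), accel = rnorm(500))
  m <- polar_response_map(obs, min_count = 1)
  for (i in sample(which(m$n > 0), 10)) {
    expect_equal(m$mean_turn[i],
                 polar_cell_mean_oracle(obs, m$r_lo[i], m$r_hi[i],
                                        m$theta_lo[i], m$theta_hi[i],
                                        "turn"),
                 tolerance = 1e-12)
    expect_equal(m$mean_accel[i],
                 polar_cell_mean_oracle(obs, m$r_lo[i], m$r_hi[i],
                                        m$theta_lo[i], m$theta_hi[i],
                                        "accel"),
                 tolerance = 1e-12)
  }
})

test_that("counts are conserved: cells plus dropped equals observations", {
  set.seed(22)
  obs <- fake_obs(d = runif(300, 0, 40), theta = runif(300, -pi, pi))
  m <- polar_response_map(obs)
  expect_equal(sum(m$n) + attr(m, "n_dropped"), nrow(obs))
  p <- fb_response_profile(fake_obs(d = runif(300, 0, 40),
                                    theta = runif(300, -pi, pi)))
  expect_equal(sum(p$n) + attr(p, "n_dropped"), 300)
})

test_that("sign crossing is interpolated at the bin boundary", {
  prof <- structure(
    tibble::tibble(lo = c(0, 2.5, 5, 7.5), hi = c(2.5, 5, 7.5, 10),
                   mid = c(1.25, 3.75, 6.25, 8.75),
                   n = rep(1000L, 4),
                   mean_response = c(-1, -1, 1, 1),
                   reliable = TRUE),
    class = c("fb_profile", class(tibble::tibble())),
    response = "accel", min_count = 100)
  expect_equal(acceleration_sign_crossing(prof)$crossing, 5)
})

test_that("absence of a sign change is reported as NA, not an error", {
  prof <- structure(
    tibble::tibble(lo = c(0, 5), hi = c(5, 10), mid = c(2.5, 7.5),
                   n = c(500L, 500L), mean_response = c(0.4, 0.9),
                   reliable = TRUE),
    class = c("fb_profile", class(tibble::tibble())),
    response = "accel", min_count = 100)
  expect_true(is.na(acceleration_sign_crossing(prof)$crossing))
})

test_that("theta-phi map honours the attraction-zone cutoff", {
  obs <- fake_obs(d = c(3, 6), theta = c(0.1, 0.1), phi = c(0.2, 0.2),
                  turn = c(100, 1))
  m <- theta_phi_map(obs, r_min = 5, min_count = 1)
  expect_equal(sum(m$n), 1)  # the d = 3 observation is excluded
  expect_equal(m$mean_turn[m$n == 1], 1)
})

test_that("pairwise-average prediction has the closed form and is symmetric", {
  edges <- seq(-15, 15, by = 10)
  mids <- c(-10, 0, 10)
  prof0 <- structure(
    tibble::tibble(lo = edges[-4], hi = edges[-1], mid = mids,
                   n = 1000L, mean_response = 0, reliable = TRUE),
    class = c("fb_profile", class(tibble::tibble())),
    response = "turn", min_count = 100)
  pred0 <- predict_from_pairwise(prof0, edges)
  expect_true(all(pred0$mean_response == 0))

  prof_id <- prof0
  prof_id$mean_response <- mids  # profile(d) = d
  pred <- predict_from_pairwise(prof_id, edges)
  expect_equal(pred$mean_response, (pred$d1_mid + pred$d2_mid) / 2)
  swapped <- pred[order(pred$d2_mid, pred$d1_mid), ]
  expect_equal(swapped$mean_response,
               pred[order(pred$d1_mid, pred$d2_mid), ]$mean_response)
  expect_error(predict_from_pairwise(prof_id, seq(-15, 15, by = 5)),
               class = "flockdual_invalid_input")
})

test_that("two-neighbour maps are symmetric under randomized ordering and conserve counts", {
  cfg <- sim_config(n_steps = 1024L, n_individuals = 3, seed = 77L)
  tr <- simulate_flights(cfg, 6)
  obs <- pair_observations(tr, dt = cfg$dt)
  set.seed(5)
  m <- multi_neighbour_observed(obs, response = "turn",
                                ordering = "random", min_count = 5)
  expect_equal(sum(m$n) + attr(m, "n_dropped"), attr(m, "n_obs"))
  # with per-observation random axis assignment the mass above and below
  # the diagonal must balance
  above <- sum(m$n[m$d1_mid > m$d2_mid])
  below <- sum(m$n[m$d1_mid < m$d2_mid])
  expect_gt(above + below, 0)
  expect_lt(abs(above - below) / (above + below), 0.05)
})

test_that("without noise all mass sits at the ideal offsets", {
  cfg <- sim_config(n_steps = 256L, n_individuals = 3,
                    displacement_std = 0, seed = 13L)
  tr <- simulate_flights(cfg, 3)
  obs <- pair_observations(tr, dt = cfg$dt)
  # measured front-back distances sit at the ideal offsets up to the
  # small heading-estimation error on a gently curving path
  expect_true(all(vapply(obs$d_fb, function(v) {
    min(abs(v - c(-10, -5, 5, 10))) < 0.5
  }, logical(1))))
  set.seed(2)
  m <- multi_neighbour_observed(obs, response = "turn", min_count = 1)
  filled <- m[m$n > 0, ]
  # populated cells all touch one of the ideal offsets
  near <- function(lo, hi) {
    any(vapply(c(-10, -5, 5, 10),
               function(v) lo - 0.5 < v && v <= hi + 0.5, logical(1)))
  }
  expect_true(all(mapply(near, filled$d1_lo, filled$d1_hi)))
  expect_true(all(mapply(near, filled$d2_lo, filled$d2_hi)))
})

test_that("mirror reflection negates angles and turning responses", {
  cfg <- quick_config(n_steps = 256L)
  tr <- simulate_flock(cfg)
  obs <- pair_observations(tr, dt = cfg$dt)
  mirrored <- dplyr::mutate(tr, y = -.data$y, y_ideal = -.data$y_ideal)
  obs_m <- pair_observations(mirrored, dt = cfg$dt)
  expect_equal(obs_m$theta, -obs$theta, tolerance = 1e-10)
  expect_equal(obs_m$phi, -obs$phi, tolerance = 1e-10)
  expect_equal(obs_m$turn, -obs$turn, tolerance = 1e-10)
  expect_equal(obs_m$accel, obs$accel, tolerance = 1e-10)
  expect_equal(obs_m$d_lat, -obs$d_lat, tolerance = 1e-10)
})
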