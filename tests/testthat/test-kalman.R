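# Independent scalar Kalman oracle, written directly from the textbook
# recursion (predict with known input, scalar gain update), used to
# cross-check kalman_step().
oracle_step <- function(x, P, u, z, Q, R, dt) {
  x_minus <- x + u
  P_minus <- P + dt * dt * Q
  K <- P_minus / (P_minus + R)
  x_new <- x_minus + K * (z - x_minus)
  P_new <- (1 - K) * P_minus
  list(x = x_new, P = P_new, K = K)
}

test_that("direction_input scales the unit direction by v*dt", {
  u <- direction_input(c(3, 0, 4), v_m_s = 1.9, dt_s = 0.001)
  expect_equal(sqrt(sum(u^2)), 1.9 * 0.001 * 1000)
  expect_equal(u / sqrt(sum(u^2)), c(0.6, 0, 0.8))
  # magnitude of j_hat cancels
  expect_equal(direction_input(c(300, 0, 400)), u)
  expect_error(direction_input(c(0, 0, 0)), "nonzero")
})

test_that("kalman_step matches the independent scalar oracle to 1e-12", {
  set.seed(99)
  Q <- c(2, 0.5, 1.3); R <- c(4, 9, 0.1); dt <- 0.001
  state <- list(x_hat_mm = c(10, -5, 3), P = Q)
  ox <- state$x_hat_mm; oP <- state$P
  for (t in 1:50) {
    u <- rnorm(3); z <- rnorm(3, mean = ox)
    state <- kalman_step(state, u, z, Q, R, dt_s = dt)
    o <- Map(oracle_step, ox, oP, u, z, Q, R, dt)
    ox <- vapply(o, `[[`, numeric(1), "x")
    oP <- vapply(o, `[[`, numeric(1), "P")
    oK <- vapply(o, `[[`, numeric(1), "K")
    expect_equal(state$x_hat_mm, ox, tolerance = 1e-12)
    expect_equal(state$P, oP, tolerance = 1e-12)
    expect_equal(state$K, oK, tolerance = 1e-12)
  }
})

test_that("the gain converges to the scalar Riccati fixed point", {
  Q <- 3; R <- 7; dt <- 0.001
  q <- dt^2 * Q
  # steady state of P- = (1-K)P- + q with K = P-/(P- + R):
  # P-^2 = q P- + q R  =>  P- = (q + sqrt(q^2 + 4 q R)) / 2
  P_minus_star <- (q + sqrt(q^2 + 4 * q * R)) / 2
  K_star <- P_minus_star / (P_minus_star + R)
  state <- list(x_hat_mm = c(0, 0, 0), P = rep(Q, 3))
  # with dt^2 Q tiny the linear convergence factor is (1-K*)^2 ~ 0.9987,
  # so reaching 1e-6 takes tens of thousands of iterations
  for (t in 1:40000) {
    state <- kalman_step(state, c(0, 0, 0), c(0, 0, 0), Q, R, dt_s = dt)
  }
  expect_equal(unname(state$K), rep(K_star, 3), tolerance = 1e-6)
})

test_that("gain limits: infinite R ignores observations, zero R trusts them", {
  st <- list(x_hat_mm = c(1, 1, 1), P = c(1, 1, 1))
  s_inf <- kalman_step(st, c(1, 0, 0), c(50, 50, 50), Q = 1, R = Inf)
  expect_equal(s_inf$K, c(0, 0, 0))
  expect_equal(s_inf$x_hat_mm, c(2, 1, 1))   # pure dead reckoning
  s_zero <- kalman_step(st, c(1, 0, 0), c(50, 50, 50), Q = 1, R = 0)
  expect_equal(s_zero$K, c(1, 1, 1))
  expect_equal(s_zero$x_hat_mm, c(50, 50, 50))
  expect_error(kalman_step(list(x_hat_mm = c(0, 0, 0), P = c(0, 0, 0)),
                           c(0, 0, 0), c(0, 0, 0), Q = 0, R = 0),
               "indeterminate")
})

test_that("track_source runs the recursion over a series with truth attached", {
  n <- 25
  set.seed(5)
  truth <- t(vapply(seq_len(n), function(s) c(s * 1.9, 0, 0), numeric(3)))
  series <- tibble::tibble(
    rx_mm = truth[, 1] + rnorm(n, sd = 5),
    ry_mm = truth[, 2] + rnorm(n, sd = 5),
    rz_mm = truth[, 3] + rnorm(n, sd = 5),
    jx = 1, jy = 0, jz = 0,
    true_x_mm = truth[, 1], true_y_mm = truth[, 2], true_z_mm = truth[, 3])
  cfg <- track_config(x0_mm = c(0, 0, 0), Q = 1, R = 25)
  tr <- track_source(series, cfg)
  expect_s3_class(tr, "source_track")
  expect_equal(nrow(tr), n)
  expect_true(all(tr$Kx >= 0 & tr$Kx <= 1))
  g <- glance(tr)
  expect_lt(g$mde_filt_mm, g$mde_raw_mm)
  expect_error(track_source(series[0, ], cfg), "empty")
  expect_error(track_source(tibble::tibble(rx_mm = 1), cfg), "needs columns")
})

test_that("track_config validates speed, step and variances", {
  expect_error(track_config(c(0, 0, 0), v_m_s = 0), "positive")
  expect_error(track_config(c(0, 0, 0), dt_s = -1), "positive")
  expect_error(track_config(c(0, 0, 0), Q = -1), ">= 0")
  cfg <- track_config(c(1, 2, 3), Q = 2, R = c(1, 2, 3))
  expect_equal(cfg$Q, c(2, 2, 2))
  expect_equal(cfg$R, c(1, 2, 3))
})

test_that("Q calibration uses the per-axis study error components", {
  study <- tibble::tibble(
    est_x_mm = c(1, 2, 3, 4), true_x_mm = c(1, 1, 1, 1),
    est_y_mm = c(0, 0, 0, 0), true_y_mm = c(0, 0, 0, 0),
    est_z_mm = c(2, 4, 6, 8), true_z_mm = c(0, 0, 0, 0),
    le_mm = c(1, 2, 3, 4))
  Q <- estimate_Q(study)
  expect_equal(Q, c(var(c(0, 1, 2, 3)), 0, var(c(2, 4, 6, 8))))
  expect_equal(estimate_Q(study, per_axis = FALSE), var(c(1, 2, 3, 4)))
  expect_error(estimate_Q(study[1, ]), "at least 2")
})

test_that("R calibration measures localization spread across sub-dictionaries", {
  lfm <- small_lfm()
  N <- nrow(lfm$points)
  size <- max(2L, N - 2L)
  R <- estimate_R(lfm, n_subsets = 4, subset_size = size,
                  n_probes = min(5L, N), seed = 3)
  expect_length(R, 3)
  expect_true(all(is.finite(R) & R >= 0))
  expect_error(estimate_R(lfm, subset_size = N + 1), "exceeds")
  # reproducible under the same seed
  expect_identical(R, estimate_R(lfm, n_subsets = 4, subset_size = size,
                                 n_probes = min(5L, N), seed = 3))
})

test_that("tracking integrates with synthesized observations on the phantom", {
  m <- small_model()
  lfm <- small_lfm()
  spec <- small_spec()
  start <- (spec$heart_center - 1) * spec$pitch_mm
  traj <- make_trajectory(m, start, directions = c(1, 0, 0), n_steps = 3)
  obs <- synthesize_observations(traj, lfm, m, snr_db = Inf, seed = 1)
  expect_equal(nrow(obs), 3)
  cfg <- track_config(start, Q = 4, R = 4)
  tr <- track_source(obs, cfg)
  expect_equal(nrow(tr), 3)
  expect_true(all(is.finite(c(tr$fx_mm, tr$fy_mm, tr$fz_mm))))
})
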