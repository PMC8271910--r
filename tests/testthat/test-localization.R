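test_that("noise injection hits the prescribed SNR and is reproducible", {
  phi <- sin(1:2000)
  noisy <- add_noise(phi, 10, seed = 7)
  expect_equal(attr(noisy, "snr_db"), 10)
  v_target <- mean(phi^2) * 10^(-1)
  expect_equal(var(noisy - phi), v_target, tolerance = 0.15)
  expect_identical(add_noise(phi, 10, seed = 7), noisy)
  expect_identical(as.numeric(add_noise(phi, Inf)), phi)
  expect_error(add_noise(numeric(9), 10), "zero signal")
})

test_that("noise injection restores the caller's RNG state", {
  phi <- sin(1:9) + 10
  set.seed(123)
  before <- .Random.seed
  invisible(add_noise(phi, 20, seed = 42))
  expect_identical(.Random.seed, before)
})

test_that("OMP recovers axis-aligned dictionary atoms exactly", {
  lfm <- small_lfm()
  N <- nrow(lfm$points)
  for (case in list(c(1L, 1L), c(min(3L, N), 2L), c(min(2L, N), 3L))) {
    p <- case[1]; a <- case[2]
    col <- lfm$L[, (a - 1) * N + p]
    est <- omp_localize(lfm, col * 2.5)  # amplitude 2.5 in base direction a
    expect_equal(est$grid_index, p)
    expect_equal(est$correlation, 1, tolerance = 1e-12)
    want <- numeric(3); want[a] <- 2.5
    expect_equal(est$j_hat, want, tolerance = 1e-8)
    expect_lt(est$residual / sqrt(sum(col^2)), 1e-10)
  }
})

test_that("anti-aligned sources select their location via |corr| with signed j", {
  lfm <- small_lfm()
  N <- nrow(lfm$points)
  col <- lfm$L[, N + 1]                 # y-direction column of point 1
  est <- omp_localize(lfm, -col)
  expect_equal(est$grid_index, 1L)
  expect_equal(est$j_hat, c(0, -1, 0), tolerance = 1e-8)
})

test_that("correlation ties break toward the lowest grid-point index", {
  L <- cbind(diag(3), diag(3), diag(3))  # two identical points
  L <- L[, c(1, 1, 2, 2, 3, 3)]          # x1==x2, y1==y2, z1==z2
  pts <- tibble::tibble(point = 1:2, i = 1:2, j = 1L, k = 1L,
                        x_mm = c(0, 2), y_mm = 0, z_mm = 0)
  fake <- structure(list(L = L, points = pts, electrodes = NULL),
                    class = "lead_field")
  est <- omp_localize(fake, c(1, 0, 0))
  expect_equal(est$grid_index, 1L)
})

test_that("degenerate inputs are rejected", {
  lfm <- small_lfm()
  expect_error(omp_localize(lfm, numeric(9)), "identically zero")
  expect_error(omp_localize(lfm, 1:3), "length")
})

test_that("subspace selection recovers oblique on-grid sources exactly", {
  m <- small_model()
  lfm <- small_lfm()
  study <- run_dipole_study(m, lfm, n_dipoles = 20, snr_db = Inf,
                            seed = 11, on_grid = TRUE,
                            selection = "subspace")
  expect_true(all(study$le_mm == 0))
  expect_true(all(study$de_deg < 1e-3))
})

test_that("error metrics behave at the extremes", {
  expect_equal(localization_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(localization_error(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(direction_error(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(direction_error(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(direction_error(c(1, 0, 0), c(0, 1, 0)), 90)
  # clamped against round-off: nearly parallel vectors do not NaN
  expect_false(is.nan(direction_error(c(1, 1e-17, 0), c(1, 0, 0))))
  expect_error(direction_error(c(0, 0, 0), c(1, 0, 0)), "zero vector")
})

test_that("dipole studies are reproducible and leave the RNG untouched", {
  m <- small_model()
  lfm <- small_lfm()
  set.seed(555)
  before <- .Random.seed
  s1 <- run_dipole_study(m, lfm, n_dipoles = 5, snr_db = 20, seed = 3)
  expect_identical(.Random.seed, before)
  s2 <- run_dipole_study(m, lfm, n_dipoles = 5, snr_db = 20, seed = 3)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_equal(nrow(s1), 5)
  expect_true(all(s1$le_mm >= 0))
  expect_true(all(s1$de_deg >= 0 & s1$de_deg <= 180))
})

test_that("noise-free localization error never exceeds noisy error on average", {
  m <- small_model()
  lfm <- small_lfm()
  dip <- make_test_dipoles(m, 6, seed = 2)
  clean <- run_dipole_study(m, lfm, dipoles = dip, snr_db = Inf, seed = 2)
  noisy <- run_dipole_study(m, lfm, dipoles = dip, snr_db = 0, seed = 2)
  expect_lte(mean(clean$le_mm), mean(noisy$le_mm) + 1e-9)
})

test_that("the SNR sweep returns one row per level and dipole", {
  m <- small_model()
  lfm <- small_lfm()
  sw <- run_snr_sweep(m, lfm, n_dipoles = 3, snr_grid = c(10, Inf),
                      n_noise = 25, seed = 4)
  expect_s3_class(sw, "snr_sweep")
  expect_equal(nrow(sw), 6)
  expect_equal(sw$n_noise[is.infinite(sw$snr_db)], rep(1L, 3))
  expect_equal(sw$n_noise[sw$snr_db == 10], rep(25L, 3))
  g <- glance(sw)
  expect_equal(nrow(g), 2)
  expect_true(all(c("snr_db", "mean_le_mm") %in% names(g)))
})
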