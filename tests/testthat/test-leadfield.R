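test_that("source points lie deep in the cardiac tissue on a regular lattice", {
  m <- small_model()
  g <- small_grid()
  expect_s3_class(g, "source_grid")
  expect_gt(nrow(g), 0)
  hm <- heart_mask(m)
  d <- dim(hm)
  for (p in seq_len(nrow(g))) {
    i <- g$i[p]; j <- g$j[p]; k <- g$k[p]
    expect_true(hm[i, j, k])
    # all six face-neighbours are cardiac too
    expect_true(hm[i - 1, j, k] && hm[i + 1, j, k] &&
                  hm[i, j - 1, k] && hm[i, j + 1, k] &&
                  hm[i, j, k - 1] && hm[i, j, k + 1])
  }
  # deterministic ascending z, y, x scan order
  expect_identical(order(g$k, g$j, g$i), seq_len(nrow(g)))
  expect_equal(attr(g, "spacing_mm"), 6)
  # positions are the anode-node world coordinates
  expect_equal(g$x_mm, (g$i - 1) * m$pitch_mm + m$origin_mm[1])
})

test_that("lattice spacing subsamples the eligible voxels", {
  m <- default_model()
  g2 <- select_source_points(m, 2)   # every eligible voxel
  g6 <- select_source_points(m, 6)
  expect_gt(nrow(g2), nrow(g6))
  # the 6 mm lattice is a subset of the eligible set
  key <- function(g) paste(g$i, g$j, g$k)
  expect_true(all(key(g6) %in% key(g2)))
})

test_that("LFM columns reproduce independent forward solves", {
  lfm <- small_lfm()
  g <- small_grid()
  el <- small_electrodes()
  sys <- small_system()
  N <- nrow(g)
  expect_equal(dim(lfm$L), c(nrow(el), 3 * N))
  p <- min(2L, N)
  for (a in 1:3) {
    axis <- c("+x", "+y", "+z")[a]
    src <- dipole_source(c(g$i[p], g$j[p], g$k[p]), axis)
    fld <- solve_spfd(sys, src, method = "direct", factor = small_factor())
    phi <- electrode_potentials(fld, el)
    # the column is the potential divided by the anode current density;
    # a unit-direction source through the column gives back the potential
    col <- lfm$L[, (a - 1) * N + p]
    expect_gt(abs(sum(col * phi)) / sqrt(sum(col^2) * sum(phi^2)), 1 - 1e-12)
  }
})

test_that("an LFM survives a save/load round trip bit for bit", {
  lfm <- small_lfm()
  stem <- file.path(tempdir(), "lfm_roundtrip")
  save_lfm(lfm, stem)
  on.exit(unlink(paste0(stem, c(".csv", ".json"))), add = TRUE)
  back <- load_lfm(stem, model = small_model())
  expect_identical(back$L, lfm$L)
  expect_equal(as.data.frame(back$points), as.data.frame(lfm$points))
  expect_equal(as.data.frame(back$electrodes), as.data.frame(lfm$electrodes))
  expect_equal(back$provenance$model_hash, lfm$provenance$model_hash)
  expect_equal(attr(back$points, "spacing_mm"), attr(lfm$points, "spacing_mm"))
})

test_that("loading an LFM against a different conductor fails unless forced", {
  lfm <- small_lfm()
  stem <- file.path(tempdir(), "lfm_stale")
  save_lfm(lfm, stem)
  on.exit(unlink(paste0(stem, c(".csv", ".json"))), add = TRUE)
  other <- homogenize(small_model())
  expect_error(load_lfm(stem, model = other), "hash mismatch")
  expect_s3_class(load_lfm(stem, model = other, force = TRUE), "lead_field")
  expect_error(load_lfm(file.path(tempdir(), "no_such_stem")), "no lead field")
})

test_that("tissue inhomogeneity changes the lead field", {
  m <- small_model()
  h <- homogenize(m)
  g <- small_grid()
  el <- small_electrodes()
  lfm_h <- build_lfm(h, el, g)
  rel <- norm(lfm_h$L - small_lfm()$L, "F") / norm(small_lfm()$L, "F")
  expect_gt(rel, 0.01)
})

test_that("electrode sets validate their columns and roles", {
  expect_error(electrode_set(data.frame(x_mm = 1)), "needs columns")
  df <- data.frame(role = c("V1", "V1"), x_mm = 1:2, y_mm = 1:2, z_mm = 1:2)
  expect_error(electrode_set(df), "unique")
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(role = "V1", x_mm = 1, y_mm = 2, z_mm = 3), path,
            row.names = FALSE)
  on.exit(unlink(path), add = TRUE)
  es <- electrode_set(path)
  expect_s3_class(es, "electrode_set")
  expect_equal(es$z_mm, 3)
})
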