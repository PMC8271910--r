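tt_mini <- function() {
  new_tissue_table(c(0L, 4L, 25L, 32L, 33L),
                   c("Air", "Blood", "Heart", "Lung", "Muscle"),
                   c(0, 0.7, 0.05, 0.2, 0.2))
}

mini_model <- function() {
  labs <- array(0L, dim = c(8, 8, 8))
  labs[2:7, 2:7, 2:7] <- 33L
  labs[4:5, 4:5, 4:5] <- 25L
  voxel_model(labs, 2, tt_mini(), heart_label = 25L, lung_label = 32L)
}

test_that("voxel_model validates labels, pitch and dimensionality", {
  expect_error(voxel_model(matrix(0L, 2, 2), 2, tt_mini()), "3-D")
  expect_error(voxel_model(array(0L, c(2, 2, 2)), -1, tt_mini()), "positive")
  labs <- array(99L, dim = c(2, 2, 2))
  expect_error(voxel_model(labs, 2, tt_mini()), "absent from the tissue table")
})

test_that("conductivity assignment is an exact per-voxel lookup", {
  m <- mini_model()
  sig <- assign_conductivity(m)
  expect_equal(dim(sig), dim(m$labels))
  expect_true(all(sig[m$labels == 0L] == 0))
  expect_true(all(sig[m$labels == 33L] == 0.2))
  expect_true(all(sig[m$labels == 25L] == 0.05))
})

test_that("homogenize keeps the body surface and sets sigma to 2/3 muscle", {
  m <- mini_model()
  h <- homogenize(m)
  sig <- assign_conductivity(h)
  expect_equal(sig == 0, assign_conductivity(m) == 0)  # identical air mask
  vals <- unique(sig[sig > 0])
  expect_length(vals, 1)
  expect_equal(vals, 2 / 3 * 0.2)
  expect_true(is.na(h$heart_label))
})

test_that("homogenize requires a Muscle entry", {
  tt <- new_tissue_table(c(0L, 1L), c("Air", "Fat"), c(0, 0.05))
  labs <- array(c(0L, 1L), dim = c(2, 2, 2))
  m <- voxel_model(labs, 2, tt)
  expect_error(homogenize(m), "Muscle")
})

test_that("heart transforms: identity, volume scaling and vacancy fill", {
  # the 40^3 model: at 24^3 a 10% scale moves the cardiac boundary by
  # less than half a voxel and nearest-neighbour resampling is a no-op
  m <- default_model()
  expect_identical(transform_heart(m, 0, 100)$labels, m$labels)

  n0 <- sum(m$labels == m$heart_label)
  up <- transform_heart(m, 0, 110)
  dn <- transform_heart(m, 0, 90)
  expect_gt(sum(up$labels == m$heart_label), n0)
  expect_lt(sum(dn$labels == m$heart_label), n0)
  # shrinking vacates cardiac volume, which must become lung
  vacated <- m$labels == m$heart_label & dn$labels != m$heart_label
  expect_true(all(dn$labels[vacated] == m$lung_label))
  # the body surface is untouched
  expect_equal(dn$labels == 0L, m$labels == 0L)
  expect_equal(up$labels == 0L, m$labels == 0L)
})

test_that("rotation preserves cardiac volume approximately and warns off-range", {
  m <- default_model()
  r <- transform_heart(m, 10, 100)
  n0 <- sum(m$labels == m$heart_label)
  expect_equal(sum(r$labels == m$heart_label) / n0, 1, tolerance = 0.1)
  expect_warning(transform_heart(m, 15, 100), "outside the nominal")
  expect_warning(transform_heart(m, 0, 80), "outside the nominal")
})

test_that("transforms that push the heart into air are rejected", {
  labs <- array(0L, dim = c(12, 12, 12))
  labs[2:11, 2:11, 2:11] <- 33L
  labs[3:9, 3:9, 3:9] <- 25L   # heart almost touching the surface
  labs[5:7, 5:7, 5:7] <- 4L
  m <- voxel_model(labs, 2, tt_mini(), heart_label = 25L, blood_label = 4L,
                   lung_label = 32L)
  expect_error(suppressWarnings(transform_heart(m, 0, 160)),
               "outside the body surface")
})

test_that("raw and text model formats round-trip exactly", {
  m <- mini_model()
  for (ext in c("raw", "json")) {
    path <- file.path(withr_tempdir <- tempfile(), paste0("model.", ext))
    dir.create(dirname(path), recursive = TRUE)
    save_model(m, path)
    m2 <- load_model(path)
    expect_identical(m2$labels, m$labels)
    expect_equal(m2$pitch_mm, m$pitch_mm)
    expect_equal(m2$heart_label, m$heart_label)
    expect_equal(as.data.frame(m2$tissues), as.data.frame(m$tissues))
    unlink(dirname(path), recursive = TRUE)
  }
})

test_that("model loading reports missing files and format clearly", {
  expect_error(load_model(tempfile(fileext = ".json")), "not found")
  expect_error(load_model("model.xyz"), "cannot infer")
})
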