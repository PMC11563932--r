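test_that("phantom volume bookkeeping matches the request within 2%", {
  for (case in list(list(v = 700, h = 1, gen = 0),
                    list(v = 700, h = 1, gen = 4),
                    list(v = 120, h = 2, gen = 2))) {
    ph <- build_thorax_phantom(case$v, case$h, case$gen, seed = 1)
    got_mL <- ph$lung_voxels * ph$voxel_size^3 / 1000
    expect_lt(abs(got_mL - case$v) / case$v, 0.02,
              label = sprintf("volume error for %g mL at %g mm", case$v,
                              case$h))
  }
})

test_that("labels partition the grid and the air tree stays inside the lung", {
  ph <- build_thorax_phantom(200, 1, 4, seed = 3)
  labs <- sort(unique(as.vector(ph$label_grid)))
  expect_true(all(labs %in% seq_along(ph$material_table)))
  expect_silent(lungpdt:::validate_phantom(ph))
  # bronchial voxels lie strictly inside the calibrated lung envelope
  idx <- which(ph$label_grid == ph$labels[["bronchial_air"]], arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  cc <- (idx - 0.5) * ph$voxel_size
  q <- (pmax(cc[, 1] - ph$flat_face_x, 0) / ph$semi_axes[1])^2 +
    ((cc[, 2] - ph$center[2]) / ph$semi_axes[2])^2 +
    ((cc[, 3] - ph$center[3]) / ph$semi_axes[3])^2
  expect_true(all(q < 1))
  expect_true(all(cc[, 1] > ph$flat_face_x))
})

test_that("phantom construction is deterministic for a fixed seed", {
  a <- build_thorax_phantom(100, 2, 3, seed = 9)
  b <- build_thorax_phantom(100, 2, 3, seed = 9)
  expect_identical(a$label_grid, b$label_grid)
  c <- build_thorax_phantom(100, 2, 3, seed = 10)
  expect_false(identical(a$label_grid, c$label_grid))
})

test_that("unresolvable airway generations fail naming the limiting one", {
  # at 5 mm voxels, generation-4 airways (5 * 0.79^3 ~ 2.5 mm radius) are
  # the first whose diameter drops below one voxel
  expect_error(build_thorax_phantom(700, 5, 8, seed = 1), "generation 4")
  expect_error(build_thorax_phantom(700, 5, 8, seed = 1), "too coarse")
})

test_that("disc sources split power equally and never overlap", {
  ph <- build_thorax_phantom(700, 2, 0, seed = 1)
  srcs <- place_disc_sources(ph, 3, 50, 2430, 665)
  expect_length(srcs, 3)
  expect_equal(vapply(srcs, function(s) s$emitted_power, 0),
               rep(810, 3))
  ctrs <- t(vapply(srcs, function(s) s$center, numeric(3)))
  dd <- as.matrix(dist(ctrs))
  expect_gte(min(dd[upper.tri(dd)]), 50)
  for (s in srcs)
    expect_equal(sqrt(sum(s$inward_normal^2)), 1, tolerance = 1e-9)

  one <- place_disc_sources(ph, 1, 50, 1234, 630)
  expect_equal(one[[1]]$emitted_power, 1234)

  small <- build_thorax_phantom(40, 2, 0, seed = 1)
  expect_error(place_disc_sources(small, 8, 50, 1000, 665), "too small")
})

test_that("detectors land at the requested depths inside lung parenchyma", {
  ph <- build_thorax_phantom(700, 1, 0, seed = 1)
  srcs <- place_disc_sources(ph, 1, 50, 810, 665)
  depths <- c(5, 10, 15, 20)
  probes <- place_detectors(ph, depths, srcs[[1]])
  expect_length(probes, 4)
  got <- vapply(probes, function(p)
    sqrt(sum((p$position - srcs[[1]]$surface_point)^2)), 0)
  expect_true(all(abs(got - depths) <= ph$voxel_size))
  expect_error(place_detectors(ph, c(0, 5), srcs[[1]]), "ill-defined")
  expect_error(place_detectors(ph, 500, srcs[[1]]), "500")
})

test_that("detectors inside air voxels are rejected with the label named", {
  ph <- homogeneous_phantom(30, 1)
  src <- point_source(c(15, 15, 5), 100)
  ph$label_grid[15:16, 15:16, 9:11] <- 3L  # bronchial air pocket on the axis
  expect_error(place_detectors(ph, 5, src), "bronchial_air")
})

test_that("phantoms survive a NIfTI + YAML round trip", {
  ph <- build_thorax_phantom(60, 2, 2, seed = 4)
  prefix <- file.path(tempdir(), "ph_roundtrip")
  write_phantom(ph, prefix)
  back <- read_phantom(prefix)
  expect_identical(back$label_grid, ph$label_grid)
  expect_equal(back$voxel_size, ph$voxel_size)
  expect_equal(back$lung_voxels, ph$lung_voxels)
  expect_equal(back$material_table[[2]]$absorption_coeff,
               ph$material_table[[2]]$absorption_coeff)
  unlink(paste0(prefix, c(".nii", ".yaml")))
})
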