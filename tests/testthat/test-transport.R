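test_that("Henyey-Greenstein sampling has the right mean cosine", {
  inc <- c(0, 0, 1)
  n <- 1e6
  for (g in c(0, 0.5, 0.93)) {
    dirs <- sample_scatter_direction(g, inc, n = n, seed = 5)
    mu <- dirs %*% inc
    se <- sd(mu) / sqrt(n)
    expect_lt(abs(mean(mu) - g), 3 * se,
              label = sprintf("HG mean cosine at g = %g", g))
    norms <- sqrt(rowSums(dirs^2))
    expect_lt(max(abs(norms - 1)), 1e-9)
  }
  # isotropic limit: deflection cosine uniform on [-1, 1]
  mu0 <- sample_scatter_direction(0, inc, n = n, seed = 6) %*% inc
  expect_lt(abs(mean(mu0)), 3 / sqrt(3 * n))
  expect_equal(mean(mu0 > 0), 0.5, tolerance = 0.005)
  # forward limit passes the direction through
  inc2 <- c(1, 2, 2) / 3
  expect_equal(sample_scatter_direction(1, inc2, n = 10, seed = 1),
               matrix(inc2, 10, 3, byrow = TRUE), tolerance = 1e-12)
})

test_that("disc launches are uniform on the face and Lambertian", {
  src <- disc_source(center = c(10, 20, 30), inward_normal = c(0, 1, 0),
                     radius = 25, emitted_power = 810)
  n <- 2e5
  pk <- launch_packets(src, n = n, seed = 2)
  rel <- sweep(pk$position, 2, src$center)
  expect_lt(max(abs(rel %*% src$inward_normal)), 1e-9)  # in the disc plane
  rad <- sqrt(rowSums(rel^2))
  expect_lte(max(rad), 25)
  expect_equal(mean(rad <= 25 / sqrt(2)), 0.5, tolerance = 0.01)  # uniform
  ct <- pk$direction %*% src$inward_normal
  expect_true(all(ct >= 0))
  # cosine-weighted hemisphere: E[cos] = 2/3
  expect_lt(abs(mean(ct) - 2 / 3), 3 * sd(ct) / sqrt(n))
  expect_true(all(pk$weight == 1))
})

test_that("the weight ledger balances and responds to absorption", {
  ph <- homogeneous_phantom(40, 2)
  src <- point_source(rep(20, 3), 100)
  raw <- simulate_fluence(ph, src, transport_config(5000, seed = 3))
  expect_lt(ledger_imbalance(raw), 1e-9)
  expect_gt(raw$ledger$absorbed, 0)

  # absorption-free medium: nothing absorbed, everything escapes
  ph0 <- homogeneous_phantom(40, 2,
                             material_optical_properties(0, 0.965, 0, 1.36,
                                                         TRUE))
  raw0 <- simulate_fluence(ph0, src, transport_config(5000, seed = 3))
  expect_identical(raw0$ledger$absorbed, 0)
  expect_equal(raw0$ledger$escaped + raw0$ledger$rouletted,
               raw0$ledger$launched, tolerance = 1e-12)
  expect_lt(ledger_imbalance(raw0), 1e-9)
})

test_that("simulation is deterministic for a fixed seed", {
  ph <- homogeneous_phantom(30, 2)
  src <- point_source(rep(15, 3), 100)
  a <- simulate_fluence(ph, src, transport_config(3000, seed = 11))
  b <- simulate_fluence(ph, src, transport_config(3000, seed = 11))
  expect_identical(a$grid, b$grid)
  expect_identical(a$ledger, b$ledger)
  c <- simulate_fluence(ph, src, transport_config(3000, seed = 12))
  expect_false(identical(a$grid, c$grid))
})

test_that("normalization is linear in power and refuses to run twice", {
  ph <- homogeneous_phantom(30, 2)
  src <- point_source(rep(15, 3), 100)
  raw <- simulate_fluence(ph, src, transport_config(2000, seed = 8))
  m1 <- normalize_fluence(raw, total_power_mW = 100)
  m2 <- normalize_fluence(raw, total_power_mW = 200)
  expect_equal(m2$grid, 2 * m1$grid)
  expect_error(normalize_fluence(m1), "already normalized")
  # raw zeros map to zeros
  raw0 <- raw
  raw0$grid[] <- 0
  expect_true(all(normalize_fluence(raw0)$grid == 0))
  # unit check: raw weight*mm -> mW/cm^2 via power/n/voxel_volume * 100
  v <- which(raw$grid > 0)[1]
  expect_equal(m1$grid[v],
               raw$grid[v] * (100 / raw$n_packets) / raw$voxel_size^3 * 100)
})

test_that("max_steps terminations are counted in the roulette imbalance", {
  ph <- homogeneous_phantom(40, 2)
  src <- point_source(rep(20, 3), 100)
  raw <- simulate_fluence(ph, src,
                          transport_config(2000, seed = 4, max_steps = 5))
  expect_gt(raw$ledger$max_step_weight, 0)
  expect_lt(ledger_imbalance(raw), 1e-9)
})

test_that("reduced-scattering transport matches full (mu_s, g) transport", {
  # similarity relation: (mu_s' = 0.965, g = 0) vs
  # (mu_s = 0.965 / 0.07, g = 0.93), compared on spherical-shell sums
  side <- 60
  src <- point_source(rep(side / 2, 3), 1000)
  ph_red <- homogeneous_phantom(side, 1, lung_properties(reduced = TRUE))
  ph_full <- homogeneous_phantom(side, 1, lung_properties(reduced = FALSE))
  n <- 2e4
  map_red <- normalize_fluence(
    simulate_fluence(ph_red, src, transport_config(n, seed = 21)))
  map_full <- normalize_fluence(
    simulate_fluence(ph_full, src, transport_config(n, seed = 22)))
  cc <- (seq_len(dim(map_red$grid)[1]) - 0.5) * 1 - side / 2
  r <- sqrt(outer(outer(cc^2, cc^2, `+`), cc^2, `+`))
  for (shell in list(c(3, 5), c(5, 8), c(8, 12))) {
    sel <- r >= shell[1] & r < shell[2]
    a <- mean(map_red$grid[sel])
    b <- mean(map_full$grid[sel])
    expect_lt(abs(a - b) / a, 0.1,
              label = sprintf("similarity shell %g-%g mm", shell[1],
                              shell[2]))
  }
})

test_that("mirror-symmetric sources produce a mirror-symmetric map", {
  ph <- homogeneous_phantom(60, 2)
  srcs <- list(point_source(c(20, 30, 30), 500),
               point_source(c(40, 30, 30), 500))
  map <- normalize_fluence(
    simulate_fluence(ph, srcs, transport_config(3e4, seed = 13)))
  flipped <- map$grid[rev(seq_len(dim(map$grid)[1])), , ]
  # aggregate halves (per-voxel values are too noisy at this packet count)
  nx <- dim(map$grid)[1]
  left <- sum(map$grid[1:(nx / 2), , ])
  right <- sum(map$grid[(nx / 2 + 1):nx, , ])
  expect_equal(left / right, 1, tolerance = 0.03)
  expect_equal(sum(abs(flipped - map$grid)) / sum(map$grid) < 0.5, TRUE)
})

test_that("Fresnel boundaries only matter when the index changes", {
  ph <- homogeneous_phantom(30, 2)  # uniform n: flag must change nothing
  src <- point_source(rep(15, 3), 100)
  a <- simulate_fluence(ph, src, transport_config(2000, seed = 5))
  b <- simulate_fluence(ph, src,
                        transport_config(2000, seed = 5,
                                         fresnel_at_air_interfaces = TRUE))
  expect_identical(a$grid, b$grid)

  # air pocket (n = 1) inside tissue (n = 1.36): flag changes the result
  ph$label_grid[6:9, 6:9, 6:9] <- 3L
  c1 <- simulate_fluence(ph, src, transport_config(2000, seed = 5))
  c2 <- simulate_fluence(ph, src,
                         transport_config(2000, seed = 5,
                                          fresnel_at_air_interfaces = TRUE))
  expect_false(identical(c1$grid, c2$grid))
  expect_lt(ledger_imbalance(c2), 1e-9)
})
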