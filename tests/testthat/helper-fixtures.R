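# shared fixtures built in code

# fluence map wrapper around a plain array, for dosimetry unit tests
manual_fluence_map <- function(grid, voxel_size = 1, mode = "normalized") {
  structure(list(grid = grid, voxel_size = voxel_size,
                 n_packets = 1, total_power_mW = 1, mode = mode,
                 ledger = list(launched = 1, absorbed = 1, escaped = 0,
                               rouletted = 0)),
            class = "fluence_map")
}

# analytic infinite-medium point-source field sampled on a voxel grid
oracle_field_map <- function(side_mm = 41, voxel_size = 1,
                             power_mW = 1000, props = lung_properties()) {
  n <- ceiling(side_mm / voxel_size)
  ctr <- rep(n * voxel_size / 2, 3)
  cc <- (seq_len(n) - 0.5) * voxel_size
  r2 <- outer(outer((cc - ctr[1])^2, (cc - ctr[2])^2, `+`),
              (cc - ctr[3])^2, `+`)
  r <- sqrt(pmax(r2, (voxel_size / 4)^2))
  map <- manual_fluence_map(array(point_source_fluence(props, power_mW, r),
                                  dim = c(n, n, n)), voxel_size)
  map$center <- ctr
  map
}

lung_mu_eff_mm <- sqrt(3 * 0.0473 * (0.0473 + 0.965))  # 0.37901 per mm
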