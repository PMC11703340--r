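test_that("percolation fraction handles channels, blobs and mixtures", {
  ch <- generate_phantom("straight_channel", list(n = 24, width = 4,
                                                  n_channels = 1))
  expect_equal(percolation_fraction(ch, 3), 100)

  blob <- array(0L, c(20, 20, 20))
  blob[8:12, 8:12, 8:12] <- 1L
  expect_equal(percolation_fraction(blob, 3), 0)

  # one spanning channel plus one interior blob: exact voxel ratio
  mixed <- ch$grid
  mixed[15:18, 15:18, 8:11] <- 1L
  n_chan <- sum(ch$grid)
  expect_equal(percolation_fraction(mixed, 3),
               100 * n_chan / (n_chan + 64), tolerance = 1e-12)
  expect_error(percolation_fraction(array(0L, c(4, 4, 4)), 3), "empty")
})

test_that("homogeneous and straight-channel limits are exact", {
  blk <- array(1L, c(12, 12, 12))
  r <- tortuosity(blk, 3)
  expect_equal(r$tortuosity_factor, 1, tolerance = 1e-9)
  expect_equal(r$d_eff_ratio, 1, tolerance = 1e-9)
  expect_true(r$converged)

  ch <- generate_phantom("straight_channel", list(n = 32, width = 4,
                                                  n_channels = 2))
  tru <- attr(ch, "analytic_truth")
  r2 <- tortuosity(ch, 3)
  expect_equal(r2$tortuosity_factor, 1, tolerance = 1e-6)
  expect_equal(r2$d_eff_ratio, tru$volume_fraction / 100,
               tolerance = 1e-6)
})

test_that("serpentine tortuosity approximates the squared path-length ratio", {
  sp <- generate_phantom("serpentine_channel", list(n = 40, width = 4))
  tru <- attr(sp, "analytic_truth")
  r <- tortuosity(sp, 3, lateral = "insulating")
  expect_equal(r$tortuosity_factor, tru$tortuosity_estimate,
               tolerance = 0.10)
  # 1D resistor-chain oracle: R = centreline length / cross-section, and
  # D_eff/D = L/(R A_grid), so tau = eps * R * A_grid / L
  eps <- sum(sp$grid) / length(sp$grid)
  R_chain <- tru$centreline_length / tru$width^2
  tau_oracle <- eps * R_chain * prod(dim(sp$grid)[1:2]) / tru$gap
  expect_equal(r$tortuosity_factor, tau_oracle, tolerance = 0.10)
})

test_that("iterative and direct solves agree to tight tolerance", {
  f <- generate_foam_volume(c(16, 16, 16), 90, seed = 3,
                            node_spacing = 8, max_radius = 5)
  rc <- tortuosity(f, 3, method = "cg")
  rd <- tortuosity(f, 3, method = "direct")
  expect_lt(abs(rc$d_eff_ratio - rd$d_eff_ratio), 1e-8)
  expect_lt(abs(rc$tortuosity_factor - rd$tortuosity_factor), 1e-6)
})

test_that("effective diffusivity never exceeds the volume fraction", {
  cases <- list(
    generate_phantom("straight_channel", list(n = 24, width = 3,
                                              n_channels = 2))$grid,
    generate_phantom("serpentine_channel", list(n = 32, width = 4))$grid,
    generate_foam_volume(c(24, 24, 24), 92, seed = 5, node_spacing = 10,
                         max_radius = 5)$grid,
    array(1L, c(10, 10, 10)))
  for (g in cases) {
    r <- tortuosity(g, 3)
    expect_lte(r$d_eff_ratio, r$volume_fraction / 100 + 1e-9)
    expect_gte(r$tortuosity_factor, 1 - 1e-9)
    expect_true(r$converged)
  }
})

test_that("flux is invariant to swapping inlet and outlet", {
  sp <- generate_phantom("serpentine_channel", list(n = 32, width = 4))
  g <- sp$grid
  r1 <- tortuosity(g, 3)
  gflip <- g[, , dim(g)[3]:1]
  r2 <- tortuosity(gflip, 3)
  expect_lt(abs(r1$d_eff_ratio - r2$d_eff_ratio), 1e-9)
})

test_that("adding phase voxels never increases the tortuosity factor", {
  base <- generate_phantom("serpentine_channel", list(n = 32, width = 4))
  g <- base$grid
  taus <- numeric(5)
  taus[1] <- tortuosity(g, 3)$tortuosity_factor
  grow <- g
  # nested sequence: widen the channel plane, then add straight channels
  grow[, 13:20, ] <- pmax(grow[, 13:20, ], g[, 13:16, ])
  taus[2] <- tortuosity(grow, 3)$tortuosity_factor
  grow2 <- grow; grow2[3:6, 3:6, ] <- 1L
  taus[3] <- tortuosity(grow2, 3)$tortuosity_factor
  grow3 <- grow2; grow3[26:29, 26:29, ] <- 1L
  taus[4] <- tortuosity(grow3, 3)$tortuosity_factor
  grow4 <- grow3; grow4[, , ] <- 1L
  taus[5] <- tortuosity(grow4, 3)$tortuosity_factor
  expect_true(all(diff(taus) <= 1e-9))
  expect_equal(taus[5], 1, tolerance = 1e-9)
})

test_that("non-percolating phases are refused", {
  blob <- array(0L, c(16, 16, 16))
  blob[6:10, 6:10, 6:10] <- 1L
  expect_error(tortuosity(blob, 3), "percolate")
})

test_that("field context preserves provenance and refuses unconverged input", {
  ch <- generate_phantom("straight_channel", list(n = 16, width = 3,
                                                  n_channels = 1))
  r <- tortuosity(ch, 3)
  ctx <- field_context(r, volume_id = "phantom-01")
  json <- jsonlite::toJSON(ctx, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$tortuosity_factor, ctx$tortuosity_factor)
  expect_identical(back$volume_id, "phantom-01")
  expect_identical(back$axis, 3L)
  bad <- r
  bad$converged <- FALSE
  expect_error(field_context(bad), "unconverged")
})
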