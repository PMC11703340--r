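test_that("decay series generator matches the closed form", {
  # t = 0 gives A + y0; the asymptote is y0
  expect_equal(generate_decay_series(2, 5, 3, times = 1e-12)$y, 5,
               tolerance = 1e-9)
  expect_equal(generate_decay_series(2, 5, 3, times = 1e6)$y, 3,
               tolerance = 1e-9)
  tt <- seq(2, 16, by = 2)
  s <- generate_decay_series(2.5, 8, 5.0, tt)
  expect_equal(s$y, 2.5 * exp(-tt / 8) + 5.0, tolerance = 1e-12)
  expect_error(generate_decay_series(2, -1, 3, tt), "tau")
  expect_error(generate_decay_series(2, 5, 3, c(2, 2, 3)), "increasing")
})

test_that("pure spring gives exactly elastic stress and zero phase truth", {
  m <- prony_material(50e3)
  sim <- simulate_dma_protocol(m, dma_protocol(), seed = 1)
  expect_equal(sim$trace$stress_Pa, 50e3 * sim$trace$strain,
               tolerance = 1e-12)
  expect_equal(sim$analytic_truth$phase_shift, 0)
  expect_equal(sim$analytic_truth$dynamic_modulus, 50e3)
})

test_that("single-arm relaxation follows the standard-linear-solid closed form", {
  m <- sls_material()
  # near-step loading: one-sample ramp so the step response applies
  p <- dma_protocol(precondition_cycles = 0, rest_duration = 0,
                    ramp_duration = 0.002, relaxation_duration = 120,
                    dynamic_cycles = 0)
  sim <- simulate_dma_protocol(m, p, seed = 1)
  hold <- sim$trace[sim$trace$segment == "relaxation", ]
  t_rel <- hold$time_s - hold$time_s[1]
  expected <- 0.12 * (20e3 + 40e3 * exp(-t_rel / 10))
  expect_equal(hold$stress_Pa, expected, tolerance = 5e-3)
})

test_that("time-domain simulation matches the frequency-domain oracle", {
  m <- sls_material()
  sim <- simulate_dma_protocol(m, dma_protocol(), seed = 1)
  dyn <- dynamic_modulus_and_phase(sim$trace)
  oracle <- prony_dynamic_modulus(m, dma_protocol()$dynamic_frequency)
  expect_equal(dyn$dynamic_modulus_Pa, oracle$dynamic_modulus,
               tolerance = 0.01)
  expect_equal(dyn$phase_shift_rad, oracle$phase, tolerance = 0.01)
})

test_that("simulator is linear in the strain amplitude", {
  m <- prony_material(15e3, data.frame(modulus = c(30e3, 10e3),
                                       tau = c(12, 3)))
  p1 <- dma_protocol()
  p2 <- dma_protocol(precondition_peak_strain = 0.28,
                     ramp_target_strain = 0.24,
                     dynamic_amplitude = 0.02,
                     dynamic_strain_velocity = 0.20)
  s1 <- simulate_dma_protocol(m, p1, seed = 1)
  s2 <- simulate_dma_protocol(m, p2, seed = 1)
  expect_equal(s2$trace$stress_Pa, 2 * s1$trace$stress_Pa,
               tolerance = 1e-9)
})

test_that("noise-free relaxation stress is non-increasing during the hold", {
  for (m in material_grid(5, seed = 7, noise = FALSE)) {
    sim <- simulate_dma_protocol(m, dma_protocol(), seed = 1)
    hold <- sim$trace$stress_Pa[sim$trace$segment == "relaxation"]
    expect_true(all(diff(hold) <= 1e-9))
  }
})

test_that("foam generator hits the target porosity and is deterministic", {
  foam <- generate_foam_volume(c(128, 128, 128), 97, seed = 11)
  por <- attr(foam, "realized_porosity")
  expect_gte(por, 96.5)
  expect_lte(por, 97.5)
  expect_equal(porosity(foam)$porosity, por)
  foam2 <- generate_foam_volume(c(128, 128, 128), 97, seed = 11)
  expect_identical(foam$grid, foam2$grid)
  # approaching full porosity the grid empties
  empty <- generate_foam_volume(c(32, 32, 32), 99.999, seed = 1)
  expect_equal(sum(empty$grid), 0)
  expect_equal(porosity(empty)$porosity, 100)
})

test_that("seeded cells are disjoint, attached, and volume-consistent", {
  foam <- generate_foam_volume(c(80, 80, 80), 97, seed = 3)
  same <- seed_cells_in_foam(foam, 0, seed = 1)
  expect_identical(same$grid[same$grid != 2L], foam$grid[same$grid != 2L])
  expect_equal(sum(same$grid == 2L), 0)

  lab <- seed_cells_in_foam(foam, 7, radius_range_um = c(10, 14),
                            seed = 5)
  cells <- array(0L, dim(lab$grid))
  cells[lab$grid == 2L] <- 1L
  expect_equal(count_objects(cells), 7)
  radii_vox <- attr(lab, "cell_radii_um") / lab$voxel_size_um
  expect_equal(sum(cells), sum(4 / 3 * pi * radii_vox^3),
               tolerance = 0.05)
  # cells never overwrite foam
  expect_true(all(foam$grid[lab$grid == 2L] == 0L))
})

test_that("phantom analytic truths are self-consistent", {
  sp <- generate_phantom("sphere", list(radius = 20))
  tru <- attr(sp, "analytic_truth")
  expect_equal(sum(sp$grid), tru$volume_voxels, tolerance = 0.02)
  expect_equal(surface_area_voxels(sp), tru$surface_voxels2,
               tolerance = 0.05)
  expect_identical(connectivity_density(sp)$euler_characteristic, 1L)

  to <- generate_phantom("torus", list(major = 16, minor = 8))
  expect_identical(connectivity_density(to)$euler_characteristic, 0L)
  expect_equal(sum(to$grid), attr(to, "analytic_truth")$volume_voxels,
               tolerance = 0.03)

  sl <- generate_phantom("slab", list(side = 50, thickness = 15))
  expect_equal(attr(sl, "analytic_truth")$thickness_voxels, 15)
  expect_error(generate_phantom("straight_channel",
                                list(n = 10, width = 9, n_channels = 3)),
               "bounds")
})
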