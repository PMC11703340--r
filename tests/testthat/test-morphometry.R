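test_that("threshold windows binarize inclusively and recover generated phases", {
  g <- array(70L, c(4, 4, 4))
  vol <- voxel_volume(g, 2.43, kind = "grayscale")
  expect_equal(sum(binarize(vol, 25, 115)$grid), 64)
  expect_equal(sum(binarize(vol, 115, 255)$grid), 0)

  # synthetic two-level volume: foam at 80, cells at 200
  foam <- generate_foam_volume(c(40, 40, 40), 96, seed = 2)
  lab <- seed_cells_in_foam(foam, 3, radius_range_um = c(8, 10), seed = 3)
  gray <- array(0L, dim(lab$grid))
  gray[lab$grid == 1L] <- 80L
  gray[lab$grid == 2L] <- 200L
  gv <- voxel_volume(gray, 2.43, kind = "grayscale")
  expect_identical(binarize(gv, 25, 114)$grid,
                   array(as.integer(lab$grid == 1L), dim(gray)))
  expect_identical(binarize(gv, 115, 255)$grid,
                   array(as.integer(lab$grid == 2L), dim(gray)))
  expect_error(binarize(gv, 120, 20), "lo <= hi")
})

test_that("porosity complements the phase fraction exactly", {
  g <- array(0L, c(10, 10, 10))
  expect_equal(porosity(g)$porosity, 100)
  g[1:5, , ] <- 1L
  p <- porosity(g)
  expect_equal(p$porosity, 50)
  expect_identical(p$porosity + p$phase_fraction, 100)
  vol <- voxel_volume(g, 2.43, kind = "binary")
  expect_identical(porosity(vol)$phase_fraction,
                   object_metrics(vol)$obj_v_tv)
})

test_that("object metrics match closed forms for cube and sphere", {
  s <- 50L
  cube <- array(0L, c(58, 58, 58))
  cube[5:54, 5:54, 5:54] <- 1L
  vol <- voxel_volume(cube, 2.43, kind = "binary")
  om <- object_metrics(vol)
  expect_equal(om$obj_v_mm3, (s * 2.43e-3)^3, tolerance = 1e-12)
  expect_equal(om$obj_s_mm2, 6 * (s * 2.43e-3)^2, tolerance = 0.05)

  sp <- generate_phantom("sphere", list(radius = 20), voxel_size_um = 2.43)
  oms <- object_metrics(sp)
  expect_equal(oms$obj_s_obj_v, 3 / (20 * 2.43e-3), tolerance = 0.05)

  full <- voxel_volume(array(1L, c(8, 8, 8)), 1, kind = "binary")
  expect_equal(object_metrics(full)$obj_v_tv, 100)
  empty <- voxel_volume(array(0L, c(8, 8, 8)), 1, kind = "binary")
  expect_equal(object_metrics(empty)$obj_v_tv, 0)
  expect_true(is.na(object_metrics(empty)$obj_s_obj_v))
})

test_that("Euler-based connectivity density distinguishes ball, torus, handles", {
  sp <- generate_phantom("sphere", list(radius = 12), voxel_size_um = 1e3)
  cd <- connectivity_density(sp)
  expect_identical(cd$euler_characteristic, 1L)
  expect_identical(cd$connectivity, 0L)
  expect_equal(cd$conn_dn_mm3, 0)

  to <- generate_phantom("torus", list(major = 12, minor = 4),
                         voxel_size_um = 1e3)
  cdt <- connectivity_density(to)
  expect_identical(cdt$euler_characteristic, 0L)
  expect_identical(cdt$connectivity, 1L)
  tv <- prod(dim(to$grid))
  expect_equal(cdt$conn_dn_mm3, 1 / tv, tolerance = 1e-12)

  # k fused tori form a genus-k handlebody: connectivity k
  for (k in 2:3) {
    hc <- voxel_volume(handle_chain(k), 1e3, kind = "binary")
    expect_identical(connectivity_density(hc)$connectivity, k)
    expect_equal(count_objects(hc), 1)
  }
})

test_that("Euler characteristic is additive over disjoint phantoms", {
  blobs <- generate_phantom("disjoint_blobs", list(k = 5, radius = 4))
  expect_identical(connectivity_density(blobs)$euler_characteristic, 5L)
  expect_identical(attr(blobs, "analytic_truth")$euler, 5)
})

test_that("object counts agree with a brute-force flood fill", {
  blobs <- generate_phantom("disjoint_blobs", list(k = 7, radius = 3))
  expect_equal(count_objects(blobs), 7)
  expect_equal(count_objects(array(0L, c(5, 5, 5))), 0)
  withr::with_seed(8, {
    g <- array(as.integer(stats::runif(32^3) < 0.08), c(32, 32, 32))
  })
  expect_equal(count_objects(g), flood_fill_count(g))
})

test_that("local thickness matches slab and cylinder truths", {
  sl <- generate_phantom("slab", list(side = 50, thickness = 15),
                         voxel_size_um = 2)
  th <- structure_thickness(sl)
  # away from the lateral rim the map is exactly the slab thickness
  d <- dim(sl$grid)
  interior <- th$map[15:(d[1] - 14), 15:(d[2] - 14), ]
  interior <- interior[interior > 0]
  expect_lt(abs(mean(interior) / 2 - 15), 0.5)

  cy <- generate_phantom("cylinder", list(radius = 9.5, length = 60),
                         voxel_size_um = 1)
  thc <- structure_thickness(cy)
  dz <- dim(cy$grid)[3]
  central <- thc$map[, , (dz %/% 4):(3 * dz %/% 4)]
  gcen <- cy$grid[, , (dz %/% 4):(3 * dz %/% 4)]
  expect_equal(mean(central[gcen != 0]), 19, tolerance = 0.05)

  single <- array(0L, c(7, 7, 7)); single[4, 4, 4] <- 1L
  ts <- structure_thickness(voxel_volume(single, 5, kind = "binary"))
  expect_equal(ts$mean_um, 5)
  expect_error(structure_thickness(
    voxel_volume(array(0L, c(4, 4, 4)), 1, kind = "binary")), "empty")
})

test_that("metrics are invariant under axis permutation and reflection", {
  to <- generate_phantom("torus", list(major = 10, minor = 4),
                         voxel_size_um = 10)
  g <- to$grid
  perms <- list(aperm(g, c(2, 3, 1)), aperm(g, c(3, 1, 2)),
                g[dim(g)[1]:1, , ])
  base_sa <- surface_area_voxels(g)
  for (gp in perms) {
    vol <- voxel_volume(gp, 10, kind = "binary")
    expect_identical(euler_chi <- connectivity_density(vol)$euler_characteristic,
                     0L)
    expect_identical(sum(gp), sum(g))
    expect_equal(count_objects(vol), 1)
    expect_equal(surface_area_voxels(gp), base_sa, tolerance = 0.005)
  }
})

test_that("sliced stacks restack to the sampled planes bit-exactly", {
  foam <- generate_foam_volume(c(24, 24, 40), 95, seed = 6,
                               node_spacing = 10, max_radius = 5)
  out <- withr::local_tempdir()
  man <- slice_stack(foam, axis = 3, interval_um = 2 * 2.43, out_dir = out)
  expect_equal(man$planes, seq(1, 40, by = 2))
  for (i in seq_along(man$planes)) {
    img <- tiff::readTIFF(file.path(out, man$files[i]))
    phase <- 1L - as.integer(round(img * 255) / 255)
    expect_identical(array(phase, dim(img)),
                     array(foam$grid[, , man$planes[i]], dim(img)))
  }
  # one slice per plane when the interval equals the voxel size
  man1 <- slice_stack(foam, axis = 3, interval_um = 2.43,
                      out_dir = withr::local_tempdir())
  expect_length(man1$planes, 40)
  expect_error(slice_stack(foam, 3, 1.0, out), "voxel")
})
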