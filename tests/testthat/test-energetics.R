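test_that("eight preconditioning cycles give eight loops ending at 2,4,...,16 s", {
  sim <- simulate_dma_protocol(sls_material(), dma_protocol(), seed = 1)
  loops <- extract_hysteresis_loops(sim$trace)
  expect_length(loops, 8)
  expect_equal(vapply(loops, function(l) l$cycle_end_time, numeric(1)),
               seq(2, 16, by = 2), tolerance = 1e-9)
  # partition identity: arcs re-concatenated reproduce the cycle samples
  idx <- which(sim$trace$segment == "precondition:3")
  l <- loops[[3]]
  rebuilt <- c(l$loading$stress, l$unloading$stress[-1])
  expect_identical(rebuilt, sim$trace$stress_Pa[idx])
})

test_that("elastic loops dissipate nothing", {
  sim <- simulate_dma_protocol(prony_material(50e3), dma_protocol(),
                               seed = 1)
  loops <- extract_hysteresis_loops(sim$trace)
  for (l in loops) {
    expect_lt(abs(l$dissipated_kJ_m3), 1e-9)
    expect_gte(l$strain_energy_kJ_m3, 0)
  }
  # peak of the elastic loop is E * peak strain
  expect_equal(loops[[1]]$max_stress_Pa, 50e3 * 0.14, tolerance = 1e-4)
})

test_that("trapezoid loop area matches the analytic ellipse", {
  cyc <- ellipse_cycle(samples_per_cycle = 200)
  loop <- hysteresis_loop(cyc$strain, cyc$stress, cyc$time)
  analytic <- pi * 4000 * 0.07 * sin(0.2) / 1000
  expect_equal(loop$dissipated_kJ_m3, analytic, tolerance = 0.005)
  expect_equal(analytic, 0.1747, tolerance = 1e-3)
  expect_lte(loop$dissipated_kJ_m3, loop$strain_energy_kJ_m3)

  # trapezoid error decreases with at least second-order convergence
  err <- vapply(c(100, 200, 400), function(nn) {
    cc <- ellipse_cycle(samples_per_cycle = nn)
    abs(hysteresis_loop(cc$strain, cc$stress, cc$time)$dissipated_kJ_m3 -
          analytic)
  }, numeric(1))
  order_obs <- log2(err[1] / err[2])
  expect_gte(order_obs, 1.8)
  expect_gte(log2(err[2] / err[3]), 1.8)
})

test_that("max stress equals the brute-force cycle maximum", {
  sim <- simulate_dma_protocol(sls_material(35), dma_protocol(), seed = 4)
  loops <- extract_hysteresis_loops(sim$trace)
  idx <- which(sim$trace$segment == "precondition:5")
  expect_equal(loops[[5]]$max_stress_Pa, max(sim$trace$stress_Pa[idx]))
  zero <- hysteresis_loop(c(0, 0.1, 0.2, 0.1, 0), rep(0, 5), 0:4)
  expect_equal(max_stress(zero), 0)
})

test_that("energy decay series normalizes by the cycle-1 peak stress", {
  sim <- simulate_dma_protocol(sls_material(), dma_protocol(), seed = 1)
  loops <- extract_hysteresis_loops(sim$trace)
  raw <- energy_decay_series(loops)
  norm <- energy_decay_series(loops, normalize_by = "cycle1_max_stress")
  expect_equal(raw$t, seq(2, 16, by = 2), tolerance = 1e-9)
  expect_equal(norm$y, raw$y / (loops[[1]]$max_stress_Pa / 1000),
               tolerance = 1e-12)
  expect_error(energy_decay_series(loops[1:2]), "3 loops")
})

test_that("decay fit recovers noiseless parameters to machine precision", {
  tt <- seq(2, 16, by = 2)
  s <- generate_decay_series(2.5, 8, 5.0, tt)
  fit <- fit_energy_decay(s)
  expect_equal(fit$A, 2.5, tolerance = 1e-6)
  expect_equal(fit$tau, 8, tolerance = 1e-6)
  expect_equal(fit$y0, 5.0, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-9)
  # the adjusted series is e^(-t/tau): value e^-1 at t = tau
  adj <- stats::approx(fit$adjusted_series$t, fit$adjusted_series$y,
                       xout = fit$tau)$y
  expect_equal(adj, exp(-1), tolerance = 1e-3)
})

test_that("flat series yield a degenerate fit with unidentifiable tau", {
  s <- data.frame(t = seq(2, 16, 2), y = rep(5, 8))
  fit <- fit_energy_decay(s)
  expect_equal(fit$A, 0)
  expect_equal(fit$y0, 5)
  expect_false(fit$tau_identifiable)
})

test_that("normalized and adjusted series satisfy their defining algebra", {
  s <- generate_decay_series(2.5, 8, 5.0, seq(2, 16, 2), noise_sd = 0.05,
                             seed = 2)
  fit <- fit_energy_decay(s)
  expect_equal(fit$normalized_series$y * fit$A, fit$fitted_series$y,
               tolerance = 1e-12)
  expect_equal(fit$adjusted_series$y * fit$A + fit$y0,
               fit$fitted_series$y, tolerance = 1e-12)
  expect_true(all(fit$adjusted_series$y > 0 &
                    fit$adjusted_series$y <= 1))
  expect_true(all(diff(fit$adjusted_series$y) < 0))
})

test_that("decay fit is scale-equivariant", {
  s <- generate_decay_series(2.5, 8, 5.0, seq(2, 16, 2), noise_sd = 0.05,
                             seed = 3)
  f1 <- fit_energy_decay(s)
  s2 <- s
  s2$y <- 100 * s$y
  f2 <- fit_energy_decay(s2)
  expect_equal(f2$A, 100 * f1$A, tolerance = 1e-6)
  expect_equal(f2$y0, 100 * f1$y0, tolerance = 1e-6)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-6)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
})

test_that("fitted y0 matches the independently simulated steady state", {
  m <- sls_material()
  p50 <- dma_protocol(precondition_cycles = 50)
  sim50 <- simulate_dma_protocol(m, p50, seed = 1)
  loops <- extract_hysteresis_loops(sim50$trace)
  steady <- loops[[50]]$dissipated_kJ_m3
  fit <- fit_energy_decay(energy_decay_series(loops[1:8]))
  expect_equal(fit$y0, steady, tolerance = 0.05)
})

test_that("first-cycle dissipation exceeds the eighth for viscoelastic cohorts", {
  mats <- material_grid(4, seed = 21)
  loops_by <- lapply(seq_along(mats), function(i)
    extract_hysteresis_loops(
      simulate_dma_protocol(mats[[i]], dma_protocol(), seed = i)$trace))
  names(loops_by) <- paste0("s", seq_along(mats))
  pairs <- compare_first_last(loops_by)
  expect_true(all(pairs$cycle1_kJ_m3 > pairs$cycle8_kJ_m3))

  # specimens with fewer than 8 cycles are excluded with a warning
  short <- loops_by
  short$s1 <- short$s1[1:7]
  expect_warning(res <- compare_first_last(short), "s1")
  expect_equal(nrow(res), 3)
})
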