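elastic_sim <- function(E = 50e3, seed = 1) {
  simulate_dma_protocol(prony_material(E), dma_protocol(), seed = seed)
}

test_that("elastic traces give exact endpoints", {
  sim <- elastic_sim()
  ep <- dma_endpoints(sim$trace)
  expect_equal(ep$compressive_modulus_Pa, 50e3, tolerance = 1e-6)
  expect_equal(ep$equilibrium_modulus_Pa, 50e3, tolerance = 1e-9)
  expect_equal(ep$stress_relaxation_percent, 0, tolerance = 1e-9)
  expect_equal(ep$dynamic_modulus_Pa, 50e3, tolerance = 1e-9)
  expect_equal(ep$phase_shift_rad, 0, tolerance = 1e-9)
})

test_that("compressive modulus matches a dense-sampling tangent oracle", {
  m <- sls_material()
  sim <- simulate_dma_protocol(m, dma_protocol(), seed = 1)
  got <- compressive_linear_modulus(sim$trace)
  # oracle: independent finite differences on a 10x-sampled noise-free
  # trace, restricted by the same relative strain-rate floor
  p10 <- dma_protocol(sample_rate = 5000)
  dense <- simulate_dma_protocol(m, p10, seed = 1)
  labs <- dense$trace$segment
  idx <- which(labs == "precondition:8")
  eps <- dense$trace$strain[idx]
  sig <- dense$trace$stress_Pa[idx]
  arc <- seq_len(which.max(eps))
  span <- eps[arc][-(1:2)] - eps[arc][-c(length(arc) - 1, length(arc))]
  dsde <- (sig[arc][-(1:2)] -
             sig[arc][-c(length(arc) - 1, length(arc))]) / span
  dsde[span < 0.2 * max(span)] <- -Inf
  expect_equal(got$modulus_Pa, max(dsde), tolerance = 0.02)
})

test_that("short loading arcs are rejected", {
  strain <- c(seq(0, 0.1, length.out = 11), seq(0.09, 0.01, length.out = 9))
  tr <- stress_strain_trace(seq_along(strain) * 0.01, 1e4 * strain, strain,
                            rep("precondition:1", 20))
  expect_error(compressive_linear_modulus(tr), "12 samples")
})

test_that("equilibrium modulus converges to the long-time stiffness", {
  sim <- simulate_dma_protocol(sls_material(), dma_protocol(), seed = 1)
  eq <- equilibrium_modulus(sim$trace)
  expect_equal(eq$modulus_Pa, 20e3, tolerance = 0.002)
  expect_equal(eq$held_strain, 0.12, tolerance = 1e-9)
})

test_that("stress relaxation matches the step-response closed form", {
  # ramp-and-hold input: cyclic preconditioning leaves viscoelastic memory
  # that the step formula does not model
  m <- sls_material()
  p <- dma_protocol(precondition_cycles = 0)
  sim <- simulate_dma_protocol(m, p, seed = 1)
  rel <- stress_relaxation_percent(sim$trace)
  expect_equal(rel$relaxation_percent, 100 * 40 / 60, tolerance = 0.03)
  expect_lt(abs(rel$relaxation_percent - 100 * 40 / 60), 2)

  flat <- sim$trace
  flat$stress_Pa <- -flat$stress_Pa
  expect_error(stress_relaxation_percent(flat), "positive")
})

test_that("constructed signals recover an exact phase lag", {
  f <- 1.5
  tt <- seq(0, 4 / f, by = 1 / (500))
  w <- 2 * pi * f
  tr <- stress_strain_trace(tt,
                            4000 + 1000 * sin(w * tt + 0.3),
                            0.12 + 0.01 * sin(w * tt),
                            rep("dynamic", length(tt)))
  dyn <- dynamic_modulus_and_phase(tr, n_cycles = 3, frequency = f)
  expect_equal(dyn$phase_shift_rad, 0.3, tolerance = 1e-6)
  expect_equal(dyn$dynamic_modulus_Pa, 1e5, tolerance = 1e-6)
})

test_that("endpoints are invariant to time shifts and scale with stress units", {
  m <- sls_material()
  sim <- simulate_dma_protocol(m, dma_protocol(), seed = 3)
  tr <- sim$trace
  ep <- dma_endpoints(tr)
  shifted <- stress_strain_trace(tr$time_s + 37.5, tr$stress_Pa, tr$strain,
                                 tr$segment,
                                 protocol = attr(tr, "protocol"))
  eps <- dma_endpoints(shifted)
  expect_equal(eps$phase_shift_rad, ep$phase_shift_rad, tolerance = 1e-9)
  expect_equal(eps$dynamic_modulus_Pa, ep$dynamic_modulus_Pa,
               tolerance = 1e-9)

  scaled <- stress_strain_trace(tr$time_s, 1000 * tr$stress_Pa, tr$strain,
                                tr$segment,
                                protocol = attr(tr, "protocol"))
  epk <- dma_endpoints(scaled)
  expect_equal(epk$dynamic_modulus_Pa, 1000 * ep$dynamic_modulus_Pa,
               tolerance = 1e-9)
  expect_equal(epk$equilibrium_modulus_Pa,
               1000 * ep$equilibrium_modulus_Pa, tolerance = 1e-9)
  expect_equal(epk$stress_relaxation_percent,
               ep$stress_relaxation_percent, tolerance = 1e-9)
  expect_equal(epk$phase_shift_rad, ep$phase_shift_rad, tolerance = 1e-9)
})

test_that("dynamic modulus dominates the equilibrium modulus", {
  for (m in material_grid(5, seed = 9, noise = FALSE)) {
    sim <- simulate_dma_protocol(m, dma_protocol(), seed = 2)
    ep <- dma_endpoints(sim$trace)
    expect_gt(ep$dynamic_modulus_Pa, ep$equilibrium_modulus_Pa)
  }
})
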