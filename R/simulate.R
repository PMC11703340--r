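#' Simulate a DMA bioreactor trace for a Prony material
#'
#' Builds the full strain schedule of a [dma_protocol()] (offset-sinusoid
#' preconditioning \eqn{\varepsilon(t) = \tfrac{1}{2}\varepsilon_{peak}
#' (1 - \cos 2\pi f t)}, zero-hold rest, linear ramp, constant hold,
#' sinusoidal dynamic segment), computes the stress as the hereditary
#' Boltzmann-superposition response of the material via an exact exponential
#' recursive update per Maxwell arm, and adds seeded Gaussian stress noise
#' (`material$noise_sd`).
#'
#' The returned object carries an `analytic_truth` record computed from the
#' material parameters alone (no signal processing): the equilibrium
#' modulus, the dynamic modulus and phase shift at the protocol's dynamic
#' frequency from the Prony storage/loss closed forms, and the step-response
#' stress-relaxation percentage.
#'
#' @param material A [prony_material()].
#' @param protocol A [dma_protocol()].
#' @param seed Integer seed for the stress noise.
#' @param geometry A [specimen_geometry()] used to derive the force and
#'   displacement channels of the bioreactor record.
#' @return A list of class `simulated_trace` with elements `trace`
#'   (a `stress_strain_trace`), `record` (time/force/displacement
#'   `data.frame` as the bioreactor would log), `material`, `protocol`,
#'   `geometry`, `seed` and `analytic_truth`.
#' @examples
#' m <- prony_material(20e3, data.frame(modulus = 40e3, tau = 10))
#' sim <- simulate_dma_protocol(m, dma_protocol(), seed = 1)
#' head(sim$trace)
#' sim$analytic_truth
#' @export
simulate_dma_protocol <- function(material, protocol, seed = 1L,
                                  geometry = specimen_geometry()) {
  stopifnot(inherits(material, "prony_material"),
            inherits(protocol, "dma_protocol"))
  p <- protocol
  dt <- 1 / p$sample_rate

  seg_n <- function(duration) max(0L, round(duration * p$sample_rate))
  n_pre <- seg_n(p$precondition_cycles / p$precondition_frequency)
  n_rest <- seg_n(p$rest_duration)
  n_ramp <- seg_n(p$ramp_duration)
  n_hold <- seg_n(p$relaxation_duration)
  n_dyn <- seg_n(p$dynamic_cycles / p$dynamic_frequency)
  n <- n_pre + n_rest + n_ramp + n_hold + n_dyn
  if (n < 12L) stop("protocol produces too few samples")
  if (n_pre > 0L && n_pre / p$precondition_cycles < 24L)
    stop("fewer than 12 samples per preconditioning loading arc")

  tt <- (seq_len(n) - 1L) * dt
  strain <- numeric(n)
  segment <- character(n)

  off <- 0L
  if (n_pre > 0L) {
    i <- seq_len(n_pre)
    tloc <- tt[i]
    strain[i] <- 0.5 * p$precondition_peak_strain *
      (1 - cos(2 * pi * p$precondition_frequency * tloc))
    cyc <- pmin(p$precondition_cycles,
                floor(tloc * p$precondition_frequency) + 1L)
    segment[i] <- paste0("precondition:", cyc)
    off <- n_pre
  }
  if (n_rest > 0L) {
    i <- off + seq_len(n_rest)
    strain[i] <- 0
    segment[i] <- "rest"
    off <- off + n_rest
  }
  t_ramp0 <- tt[off + 1L]
  if (n_ramp > 0L) {
    i <- off + seq_len(n_ramp)
    strain[i] <- pmin(1, (tt[i] - t_ramp0) / p$ramp_duration) *
      p$ramp_target_strain
    segment[i] <- "ramp"
    off <- off + n_ramp
  }
  if (n_hold > 0L) {
    i <- off + seq_len(n_hold)
    strain[i] <- p$ramp_target_strain
    segment[i] <- "relaxation"
    off <- off + n_hold
  }
  if (n_dyn > 0L) {
    i <- off + seq_len(n_dyn)
    t0 <- tt[off + 1L]
    strain[i] <- p$ramp_target_strain +
      p$dynamic_amplitude * sin(2 * pi * p$dynamic_frequency * (tt[i] - t0))
    segment[i] <- "dynamic"
  }

  stress <- prony_stress_response(material, strain, dt)
  if (material$noise_sd > 0) {
    noise <- withr::with_seed(seed, stats::rnorm(n, 0, material$noise_sd))
    stress <- stress + noise
  }

  trace <- stress_strain_trace(tt, stress, strain, segment,
                               protocol = protocol)
  record <- data.frame(
    time_s = tt,
    force_N = stress * geometry$cross_section_area * 1e-6,
    displacement_mm = strain * geometry$thickness)

  truth <- list(
    equilibrium_modulus = material$equilibrium_modulus,
    relaxation_percent = prony_step_relaxation_percent(material))
  dyn <- prony_dynamic_modulus(material, p$dynamic_frequency)
  truth$dynamic_modulus <- dyn$dynamic_modulus
  truth$phase_shift <- dyn$phase
  truth$storage_modulus <- dyn$storage
  truth$loss_modulus <- dyn$loss

  structure(list(trace = trace, record = record, material = material,
                 protocol = protocol, geometry = geometry, seed = seed,
                 analytic_truth = truth),
            class = "simulated_trace")
}

#' Generate a noisy exponential-decay series
#'
#' Samples \eqn{y(t) = A e^{-t/\tau} + y_0} at the given times and adds
#' seeded Gaussian noise.  This is the generator for validating the
#' energy-dissipation decay fit.
#'
#' @param A Amplitude (same units as y).
#' @param tau Decay constant, s. Must be > 0.
#' @param y0 Steady-state offset.
#' @param times Strictly increasing sample times, s.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return `data.frame` with columns `t` and `y`.
#' @export
generate_decay_series <- function(A, tau, y0, times, noise_sd = 0,
                                  seed = 1L) {
  if (tau <= 0) stop("tau must be > 0")
  if (length(times) == 0L) stop("times must be non-empty")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  y <- A * exp(-times / tau) + y0
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  data.frame(t = times, y = y)
}

#' Simulate a thickness-probe approach ramp
#'
#' Emulates the preload step of the bioreactor protocol: the platen starts at
#' a known gap above the stage and advances at constant speed; force is zero
#' until it contacts the specimen, then rises linearly with indentation
#' (contact stiffness `stiffness_N_mm`).  Used to validate
#' [determine_thickness()].
#'
#' @param thickness_mm True specimen thickness, mm.
#' @param initial_gap_mm Platen gap at the start of the approach, mm.
#' @param stiffness_N_mm Contact stiffness, N/mm.
#' @param speed_mm_s Approach speed, mm/s.
#' @param sample_rate Sampling rate, Hz.
#' @param max_force_N Force at which the approach stops, N.
#' @param noise_sd Force noise sd, N.
#' @param seed Integer seed for the force noise.
#' @return `data.frame` with `time_s`, `force_N`, `displacement_mm` and the
#'   initial gap attached as attribute `initial_gap_mm`.
#' @export
simulate_thickness_probe <- function(thickness_mm, initial_gap_mm = 2,
                                     stiffness_N_mm = 0.5,
                                     speed_mm_s = 0.01, sample_rate = 100,
                                     max_force_N = 0.05, noise_sd = 0,
                                     seed = 1L) {
  stopifnot(initial_gap_mm > thickness_mm, thickness_mm > 0)
  contact_travel <- initial_gap_mm - thickness_mm
  total_travel <- contact_travel + max_force_N / stiffness_N_mm
  n <- ceiling(total_travel / speed_mm_s * sample_rate) + 1L
  tt <- (seq_len(n) - 1L) / sample_rate
  disp <- pmin(tt * speed_mm_s, total_travel)
  force <- pmax(0, disp - contact_travel) * stiffness_N_mm
  if (noise_sd > 0)
    force <- pmax(0, force +
                    withr::with_seed(seed, stats::rnorm(n, 0, noise_sd)))
  out <- data.frame(time_s = tt, force_N = force, displacement_mm = disp)
  attr(out, "initial_gap_mm") <- initial_gap_mm
  out
}
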