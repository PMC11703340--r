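#' Prony-series viscoelastic material
#'
#' A generalized Maxwell (Prony-series) solid: an equilibrium spring of
#' modulus `equilibrium_modulus` in parallel with zero or more Maxwell arms,
#' each an elastic modulus `modulus` in series with a dashpot giving
#' relaxation time `tau`.  The relaxation modulus is
#' \deqn{E(t) = E_\infty + \sum_i E_i e^{-t/\tau_i}.}
#' This is the ground truth used by the trace simulator and by the
#' closed-form frequency- and time-domain oracles.
#'
#' @param equilibrium_modulus Long-time (equilibrium) modulus, Pa. Must be > 0.
#' @param arms `data.frame` with columns `modulus` (Pa, >= 0) and `tau`
#'   (seconds, > 0), one row per Maxwell arm. `NULL` or zero rows gives a
#'   pure elastic spring.
#' @param noise_sd Standard deviation of additive Gaussian stress noise (Pa)
#'   applied by the simulator. Must be >= 0.
#' @return An object of class `prony_material`.
#' @examples
#' m <- prony_material(20e3, arms = data.frame(modulus = 40e3, tau = 10))
#' prony_dynamic_modulus(m, frequency = 10 / (2 * pi))
#' @export
prony_material <- function(equilibrium_modulus, arms = NULL, noise_sd = 0) {
  stopifnot(is.numeric(equilibrium_modulus), length(equilibrium_modulus) == 1L)
  if (!is.finite(equilibrium_modulus) || equilibrium_modulus <= 0)
    stop("equilibrium_modulus must be a positive finite number")
  if (is.null(arms)) {
    arms <- data.frame(modulus = numeric(0), tau = numeric(0))
  }
  arms <- as.data.frame(arms)
  if (!all(c("modulus", "tau") %in% names(arms)))
    stop("arms must have columns 'modulus' and 'tau'")
  if (nrow(arms) > 0) {
    if (any(!is.finite(arms$modulus)) || any(!is.finite(arms$tau)))
      stop("non-finite arm parameters")
    if (any(arms$modulus < 0)) stop("arm moduli must be >= 0")
    if (any(arms$tau <= 0)) stop("arm relaxation times must be > 0")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(equilibrium_modulus = equilibrium_modulus,
         arms = arms[, c("modulus", "tau")],
         noise_sd = noise_sd),
    class = "prony_material")
}

#' @export
print.prony_material <- function(x, ...) {
  cat(sprintf("Prony material: E_inf = %.4g Pa, %d arm(s), noise sd = %.3g Pa\n",
              x$equilibrium_modulus, nrow(x$arms), x$noise_sd))
  if (nrow(x$arms) > 0) print(x$arms)
  invisible(x)
}

#' Relaxation modulus of a Prony material
#'
#' Closed form \eqn{E(t) = E_\infty + \sum_i E_i e^{-t/\tau_i}} used as the
#' time-domain oracle for step-strain relaxation.
#'
#' @param material A [prony_material()].
#' @param t Times in seconds (vector).
#' @return Relaxation modulus in Pa at each time.
#' @export
prony_relaxation_modulus <- function(material, t) {
  E <- rep(material$equilibrium_modulus, length(t))
  for (i in seq_len(nrow(material$arms)))
    E <- E + material$arms$modulus[i] * exp(-t / material$arms$tau[i])
  E
}

#' Storage/loss moduli and dynamic modulus of a Prony material
#'
#' Frequency-domain closed forms for steady-state sinusoidal loading at
#' angular frequency \eqn{\omega = 2\pi f}:
#' \deqn{E'(\omega) = E_\infty + \sum_i E_i \frac{\omega^2\tau_i^2}{1+\omega^2\tau_i^2},
#'       \quad
#'       E''(\omega) = \sum_i E_i \frac{\omega\tau_i}{1+\omega^2\tau_i^2},}
#' with \eqn{|E^*| = \sqrt{E'^2 + E''^2}} and phase lag
#' \eqn{\delta = \mathrm{atan2}(E'', E')}.  This is the independent oracle
#' against which time-domain simulation and endpoint extraction are checked.
#'
#' @param material A [prony_material()].
#' @param frequency Loading frequency in Hz.
#' @return List with `storage`, `loss` (Pa), `dynamic_modulus` (Pa, |E*|),
#'   `phase` (radians) and `tan_delta`.
#' @export
prony_dynamic_modulus <- function(material, frequency) {
  stopifnot(frequency > 0)
  w <- 2 * pi * frequency
  Ep <- material$equilibrium_modulus
  Epp <- 0
  for (i in seq_len(nrow(material$arms))) {
    wt <- w * material$arms$tau[i]
    Ep <- Ep + material$arms$modulus[i] * wt^2 / (1 + wt^2)
    Epp <- Epp + material$arms$modulus[i] * wt / (1 + wt^2)
  }
  list(storage = Ep, loss = Epp,
       dynamic_modulus = sqrt(Ep^2 + Epp^2),
       phase = atan2(Epp, Ep),
       tan_delta = Epp / Ep)
}

#' Step-response stress relaxation percentage
#'
#' For an ideal step to a held strain, the peak stress is
#' \eqn{\varepsilon (E_\infty + \sum_i E_i)} and the equilibrium stress
#' \eqn{\varepsilon E_\infty}, so the relaxation percentage is independent of
#' strain: \eqn{100 \sum_i E_i / (E_\infty + \sum_i E_i)}.
#'
#' @param material A [prony_material()].
#' @return Percentage in `[0, 100)`.
#' @export
prony_step_relaxation_percent <- function(material) {
  Es <- sum(material$arms$modulus)
  100 * Es / (material$equilibrium_modulus + Es)
}

#' DMA loading protocol specification
#'
#' Encodes the unconfined-compression testing schedule: sinusoidal cyclic
#' preconditioning to a peak strain, a rest, a ramp to a held strain, a
#' stress-relaxation hold, and a small-amplitude sinusoidal dynamic segment.
#' The dynamic frequency is derived from the commanded peak strain velocity:
#' for \eqn{\varepsilon(t) = \varepsilon_{hold} + a\sin(\omega t)} the peak
#' velocity is \eqn{a\omega}, so `dynamic_frequency =
#' dynamic_strain_velocity / (2 * pi * dynamic_amplitude)`.
#'
#' Defaults encode the study conditions this package targets:
#' preconditioning to 14% peak strain at 0.5 Hz for 8 cycles, 5 s rest, ramp
#' to 12% strain at 10%/s (1.2 s), 120 s relaxation, then 1% amplitude at a
#' strain velocity of 10%/s (about 1.59 Hz) for 10 cycles.
#'
#' @param precondition_peak_strain Peak preconditioning strain (0-1).
#' @param precondition_frequency Preconditioning frequency, Hz.
#' @param precondition_cycles Number of preconditioning cycles (0 allowed,
#'   giving a ramp-and-hold test).
#' @param rest_duration Rest after preconditioning, s.
#' @param ramp_target_strain Held strain reached by the ramp (0-1).
#' @param ramp_duration Ramp duration, s. Default ramps at
#'   `dynamic_strain_velocity` per second.
#' @param relaxation_duration Stress-relaxation hold, s.
#' @param dynamic_amplitude Dynamic strain amplitude (0-1).
#' @param dynamic_strain_velocity Peak dynamic strain velocity, 1/s.
#' @param dynamic_cycles Number of dynamic cycles.
#' @param sample_rate Sampling rate, Hz. At least 50 samples must span one
#'   preconditioning cycle.
#' @return An object of class `dma_protocol`.
#' @export
dma_protocol <- function(precondition_peak_strain = 0.14,
                         precondition_frequency = 0.5,
                         precondition_cycles = 8,
                         rest_duration = 5,
                         ramp_target_strain = 0.12,
                         ramp_duration = NULL,
                         relaxation_duration = 120,
                         dynamic_amplitude = 0.01,
                         dynamic_strain_velocity = 0.10,
                         dynamic_cycles = 10,
                         sample_rate = 500) {
  if (is.null(ramp_duration))
    ramp_duration <- ramp_target_strain / dynamic_strain_velocity
  strains <- c(precondition_peak_strain, ramp_target_strain, dynamic_amplitude)
  if (any(strains <= 0) || any(strains >= 1))
    stop("all strains must lie in (0, 1)")
  if (precondition_frequency <= 0 || sample_rate <= 0)
    stop("frequencies must be positive")
  if (precondition_cycles < 0 || dynamic_cycles < 0)
    stop("cycle counts must be >= 0")
  if (precondition_cycles > 0 &&
      sample_rate / precondition_frequency < 50)
    stop("sample_rate must give at least 50 samples per preconditioning cycle")
  dynamic_frequency <- dynamic_strain_velocity / (2 * pi * dynamic_amplitude)
  if (dynamic_cycles > 0 && sample_rate / dynamic_frequency < 24)
    stop("sample_rate too low for the dynamic segment")
  structure(
    list(precondition_peak_strain = precondition_peak_strain,
         precondition_frequency = precondition_frequency,
         precondition_cycles = precondition_cycles,
         rest_duration = rest_duration,
         ramp_target_strain = ramp_target_strain,
         ramp_duration = ramp_duration,
         relaxation_duration = relaxation_duration,
         dynamic_amplitude = dynamic_amplitude,
         dynamic_strain_velocity = dynamic_strain_velocity,
         dynamic_cycles = dynamic_cycles,
         dynamic_frequency = dynamic_frequency,
         sample_rate = sample_rate),
    class = "dma_protocol")
}

#' @export
print.dma_protocol <- function(x, ...) {
  cat(sprintf(paste0(
    "DMA protocol: %d cycles to %.0f%% @ %.3g Hz | rest %.3g s | ",
    "ramp to %.0f%% in %.3g s | hold %.3g s | %d dynamic cycles, ",
    "%.1f%% amplitude @ %.4g Hz | %g Hz sampling\n"),
    x$precondition_cycles, 100 * x$precondition_peak_strain,
    x$precondition_frequency, x$rest_duration,
    100 * x$ramp_target_strain, x$ramp_duration, x$relaxation_duration,
    x$dynamic_cycles, 100 * x$dynamic_amplitude, x$dynamic_frequency,
    x$sample_rate))
  invisible(x)
}

# Hereditary (Boltzmann superposition) stress response of a Prony material
# to a sampled strain history on a uniform time grid, using the exact
# exponential recursive update per arm (piecewise-linear strain between
# samples; unconditionally stable).  Internal work-horse of the simulator.
prony_stress_response <- function(material, strain, dt) {
  n <- length(strain)
  stress <- material$equilibrium_modulus * strain
  if (n < 2L) return(stress)
  de <- diff(strain)
  for (i in seq_len(nrow(material$arms))) {
    Ei <- material$arms$modulus[i]
    taui <- material$arms$tau[i]
    a <- exp(-dt / taui)
    b <- Ei * taui / dt * (1 - a)
    q <- stats::filter(b * de, a, method = "recursive")
    stress <- stress + c(0, as.numeric(q))
  }
  stress
}
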