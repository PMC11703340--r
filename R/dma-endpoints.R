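#' Compressive linear modulus from the last preconditioning cycle
#'
#' Computes the numerical derivative dS/dE (central differences) of the
#' stress-strain curve over the loading arc of the final preconditioning
#' cycle, locates its maximum (first occurrence on ties), and returns the
#' ordinary-least-squares slope of the 12 data points surrounding the peak
#' (6 before and 6 after, window shifted inward - never shrunk - at arc
#' boundaries).
#'
#' Because the sinusoidal loading arc has vanishing strain rate at its
#' turning points, raw difference quotients there divide by near-zero
#' strain increments and explode under measurement noise.  Two standard
#' guards are applied: samples whose local strain increment falls below
#' `min_rate_fraction` of the arc maximum are excluded from the derivative,
#' and the peak is located on a short running-mean of the derivative
#' (`smooth_window` samples); the least-squares fit itself uses the raw
#' samples.
#'
#' @param trace A `stress_strain_trace` with labelled preconditioning cycles.
#' @param min_rate_fraction Strain-rate floor as a fraction of the arc
#'   maximum.
#' @param smooth_window Running-mean length for peak location (samples).
#' @return List with `modulus_Pa`, `peak_index` (index into the loading
#'   arc), `fit_window` (indices used for the fit) and `r_squared` of the
#'   linear fit.
#' @export
compressive_linear_modulus <- function(trace, min_rate_fraction = 0.2,
                                       smooth_window = 11L) {
  labs <- trace$segment
  pre <- grep("^precondition:", labs)
  if (length(pre) == 0L) stop("no preconditioning segment in trace")
  last_cycle <- labs[pre[length(pre)]]
  idx <- which(labs == last_cycle)
  strain <- trace$strain[idx]
  stress <- trace$stress_Pa[idx]
  imax <- which.max(strain)
  if (imax < 12L) stop("loading arc shorter than 12 samples")
  eps <- strain[1:imax]
  sig <- stress[1:imax]
  m <- imax
  # central differences on the arc interior, restricted to samples with a
  # meaningful strain rate
  span <- eps[3:m] - eps[1:(m - 2)]
  admissible <- span >= min_rate_fraction * max(span)
  if (sum(admissible) < 12L) admissible <- span >= 0
  dsde <- (sig[3:m] - sig[1:(m - 2)]) / span
  if (any(!is.finite(dsde[admissible])))
    stop("non-finite derivative on loading arc")
  dsde[!admissible] <- -Inf
  w <- min(smooth_window, sum(admissible))
  sm <- stats::filter(ifelse(is.finite(dsde), dsde, NA), rep(1 / w, w),
                      sides = 2)
  sm[!is.finite(sm)] <- -Inf
  pk <- which.max(sm) + 1L  # index into the arc
  # 6 points before and 6 after the peak, shifted inward at boundaries
  lo <- pk - 6L
  hi <- pk + 6L
  if (lo < 1L) { hi <- hi - lo + 1L; lo <- 1L }
  if (hi > m) { lo <- lo - (hi - m); hi <- m }
  win <- setdiff(lo:hi, pk)
  fit <- stats::lm.fit(cbind(1, eps[win]), sig[win])
  slope <- fit$coefficients[2]
  ssr <- sum(fit$residuals^2)
  sst <- sum((sig[win] - mean(sig[win]))^2)
  list(modulus_Pa = unname(slope), peak_index = pk,
       fit_window = win,
       r_squared = if (sst > 0) 1 - ssr / sst else NA_real_)
}

#' Equilibrium modulus after stress relaxation
#'
#' The equilibrium stress is the mean stress over the final `tail_window`
#' seconds of the relaxation hold; the modulus divides it by the held
#' strain read from the trace (not hard-coded).
#'
#' @param trace A `stress_strain_trace` with a `relaxation` segment.
#' @param tail_window Averaging window at the end of the hold, s.
#' @return List with `modulus_Pa`, `equilibrium_stress_Pa`, `held_strain`.
#' @export
equilibrium_modulus <- function(trace, tail_window = 10) {
  idx <- which(trace$segment == "relaxation")
  if (length(idx) == 0L) stop("no relaxation segment in trace")
  t_end <- trace$time_s[idx[length(idx)]]
  dur <- t_end - trace$time_s[idx[1]]
  if (dur < tail_window)
    stop("relaxation segment shorter than the tail window")
  tail_idx <- idx[trace$time_s[idx] >= t_end - tail_window]
  sig_eq <- mean(trace$stress_Pa[tail_idx])
  eps_hold <- mean(trace$strain[tail_idx])
  if (eps_hold <= 0) stop("held strain must be positive")
  list(modulus_Pa = sig_eq / eps_hold,
       equilibrium_stress_Pa = sig_eq,
       held_strain = eps_hold)
}

#' Stress relaxation percentage
#'
#' Compares the maximum stress reached directly after the compression ramp
#' (searched over the ramp plus the first `peak_window` seconds of the
#' hold) with the equilibrium stress: `100 (sigma_peak - sigma_eq) /
#' sigma_peak`.
#'
#' @param trace A `stress_strain_trace` with `ramp` and `relaxation`
#'   segments.
#' @param tail_window Equilibrium averaging window, s.
#' @param peak_window Portion of the hold searched for the peak, s.
#' @return List with `relaxation_percent`, `peak_stress_Pa`,
#'   `equilibrium_stress_Pa`.
#' @export
stress_relaxation_percent <- function(trace, tail_window = 10,
                                      peak_window = 1) {
  ramp <- which(trace$segment == "ramp")
  relax <- which(trace$segment == "relaxation")
  if (length(ramp) == 0L || length(relax) == 0L)
    stop("trace must contain ramp and relaxation segments")
  t0 <- trace$time_s[relax[1]]
  early <- relax[trace$time_s[relax] <= t0 + peak_window]
  sig_peak <- max(trace$stress_Pa[c(ramp, early)])
  if (sig_peak <= 0) stop("peak stress must be positive")
  eq <- equilibrium_modulus(trace, tail_window)
  list(relaxation_percent =
         100 * (sig_peak - eq$equilibrium_stress_Pa) / sig_peak,
       peak_stress_Pa = sig_peak,
       equilibrium_stress_Pa = eq$equilibrium_stress_Pa)
}

# Linear least-squares sinusoid fit at a known angular frequency:
# y = c + a sin(wt) + b cos(wt).  Returns amplitude sqrt(a^2+b^2) and phase
# atan2(b, a) (so y = c + A sin(wt + phase)), wrapped to (-pi, pi].
fit_sinusoid_known_freq <- function(t, y, omega) {
  X <- cbind(1, sin(omega * t), cos(omega * t))
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  amp <- sqrt(co[2]^2 + co[3]^2)
  phase <- atan2(co[3], co[2])
  list(mean_level = unname(co[1]), amplitude = unname(amp),
       phase = unname(phase), angular_frequency = omega,
       residual_rms = sqrt(mean(fit$residuals^2)))
}

#' Dynamic modulus and phase shift from the dynamic segment
#'
#' Fits stress and strain over the last `n_cycles` dynamic cycles with
#' `y = c + a sin(wt) + b cos(wt)` by linear least squares at the known
#' protocol frequency.  The dynamic modulus is the stress amplitude over
#' the strain amplitude; the phase shift is the stress phase minus the
#' strain phase, wrapped into `[0, pi)`.
#'
#' @param trace A `stress_strain_trace` whose `dynamic` segment holds at
#'   least `n_cycles` full cycles; the protocol attribute (or `frequency`)
#'   supplies the loading frequency.
#' @param n_cycles Number of trailing cycles to fit.
#' @param frequency Loading frequency, Hz; defaults to the trace protocol's
#'   dynamic frequency.
#' @return List with `dynamic_modulus_Pa`, `phase_shift_rad`, `stress_fit`
#'   and `strain_fit` (each a sinusoid-fit record).
#' @export
dynamic_modulus_and_phase <- function(trace, n_cycles = 3,
                                      frequency = NULL) {
  if (is.null(frequency)) {
    p <- attr(trace, "protocol")
    if (is.null(p)) stop("frequency not given and trace has no protocol")
    frequency <- p$dynamic_frequency
  }
  idx <- which(trace$segment == "dynamic")
  if (length(idx) == 0L) stop("no dynamic segment in trace")
  t_end <- trace$time_s[idx[length(idx)]]
  t_start <- trace$time_s[idx[1]]
  span <- n_cycles / frequency
  if (t_end - t_start < span * (1 - 1e-6))
    stop("dynamic segment holds fewer than ", n_cycles, " cycles")
  sel <- idx[trace$time_s[idx] >= t_end - span]
  omega <- 2 * pi * frequency
  sfit <- fit_sinusoid_known_freq(trace$time_s[sel], trace$stress_Pa[sel],
                                  omega)
  efit <- fit_sinusoid_known_freq(trace$time_s[sel], trace$strain[sel],
                                  omega)
  if (efit$amplitude < 1e-12) stop("strain amplitude is zero")
  delta <- (sfit$phase - efit$phase) %% (2 * pi)
  if (delta >= pi) delta <- delta - 2 * pi  # wrap to (-pi, pi]
  delta <- delta %% pi                      # passive lag in [0, pi)
  list(dynamic_modulus_Pa = sfit$amplitude / efit$amplitude,
       phase_shift_rad = delta,
       stress_fit = sfit, strain_fit = efit)
}

#' All five DMA endpoints of a labelled trace
#'
#' Convenience wrapper returning the compressive linear modulus,
#' equilibrium modulus, stress relaxation percentage, dynamic modulus and
#' phase shift, with per-fit diagnostics.
#'
#' @inheritParams dynamic_modulus_and_phase
#' @inheritParams stress_relaxation_percent
#' @return List of class `dma_endpoints`.
#' @export
dma_endpoints <- function(trace, tail_window = 10, peak_window = 1,
                          n_cycles = 3, frequency = NULL) {
  comp <- compressive_linear_modulus(trace)
  eq <- equilibrium_modulus(trace, tail_window)
  rel <- stress_relaxation_percent(trace, tail_window, peak_window)
  dyn <- dynamic_modulus_and_phase(trace, n_cycles, frequency)
  structure(list(
    compressive_modulus_Pa = comp$modulus_Pa,
    equilibrium_modulus_Pa = eq$modulus_Pa,
    stress_relaxation_percent = rel$relaxation_percent,
    dynamic_modulus_Pa = dyn$dynamic_modulus_Pa,
    phase_shift_rad = dyn$phase_shift_rad,
    diagnostics = list(compressive = comp, equilibrium = eq,
                       relaxation = rel, dynamic = dyn)),
    class = "dma_endpoints")
}

#' @export
print.dma_endpoints <- function(x, ...) {
  cat(sprintf(paste0(
    "DMA endpoints:\n",
    "  compressive modulus : %10.4g Pa\n",
    "  equilibrium modulus : %10.4g Pa\n",
    "  stress relaxation   : %10.4g %%\n",
    "  dynamic modulus     : %10.4g Pa\n",
    "  phase shift         : %10.4g rad\n"),
    x$compressive_modulus_Pa, x$equilibrium_modulus_Pa,
    x$stress_relaxation_percent, x$dynamic_modulus_Pa,
    x$phase_shift_rad))
  invisible(x)
}
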