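#' Extract hysteresis loops from the preconditioning cycles
#'
#' Each labelled preconditioning cycle is split at its strain maximum into a
#' loading arc (cycle start through the peak) and an unloading arc (peak
#' through cycle end), and the per-cycle dissipated and strain energies are
#' computed by trapezoidal integration (see [loop_energies()]).
#'
#' @param trace A `stress_strain_trace` with labelled preconditioning
#'   cycles.
#' @return List of `hysteresis_loop` objects, one per cycle, each with
#'   `cycle_index`, `loading` / `unloading` arcs (`data.frame`s of strain,
#'   stress, time), `dissipated_kJ_m3`, `strain_energy_kJ_m3`,
#'   `max_stress_Pa` and `cycle_end_time`.
#' @export
extract_hysteresis_loops <- function(trace) {
  labs <- trace$segment
  cycles <- unique(labs[grepl("^precondition:", labs)])
  if (length(cycles) == 0L) stop("no labelled preconditioning cycle")
  ord <- order(as.integer(sub("^precondition:", "", cycles)))
  lapply(cycles[ord], function(lab) {
    idx <- which(labs == lab)
    hysteresis_loop(strain = trace$strain[idx],
                    stress = trace$stress_Pa[idx],
                    time = trace$time_s[idx],
                    cycle_index = as.integer(sub("^precondition:", "", lab)),
                    dt = diff(trace$time_s[idx[1:2]]))
  })
}

#' Build a hysteresis loop from one compression cycle
#'
#' @param strain,stress,time Samples of one cycle in time order, starting
#'   near the strain minimum.
#' @param cycle_index 1-based cycle number.
#' @param dt Sample spacing (used to extrapolate the cycle end time).
#' @return A `hysteresis_loop`.
#' @export
hysteresis_loop <- function(strain, stress, time, cycle_index = 1L,
                            dt = NULL) {
  stopifnot(length(strain) == length(stress),
            length(strain) == length(time), length(strain) >= 4L)
  imax <- which.max(strain)
  if (imax == 1L || imax == length(strain))
    stop("cycle has monotone strain: no loading/unloading turning point")
  loading <- data.frame(strain = strain[1:imax], stress = stress[1:imax],
                        time = time[1:imax])
  unloading <- data.frame(strain = strain[imax:length(strain)],
                          stress = stress[imax:length(strain)],
                          time = time[imax:length(strain)])
  loop <- structure(
    list(cycle_index = cycle_index, loading = loading,
         unloading = unloading,
         cycle_end_time = if (is.null(dt)) time[length(time)]
                          else time[length(time)] + dt,
         strain = strain, stress = stress),
    class = "hysteresis_loop")
  en <- loop_energies(loop)
  loop$dissipated_kJ_m3 <- en$dissipated_kJ_m3
  loop$strain_energy_kJ_m3 <- en$strain_energy_kJ_m3
  loop$max_stress_Pa <- max_stress(loop)
  loop
}

# trapezoid rule for integral of y dx (x need not be monotone: signed)
trapz_signed <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Dissipated and strain energy of a hysteresis loop
#'
#' The dissipated energy density is the closed cycle integral
#' \eqn{\oint \sigma\, d\varepsilon} by the trapezoid rule (the loop is
#' closed by a final segment back to its first sample), reported positive;
#' a value below -1e-9 kJ/m^3 raises an error since it indicates an
#' orientation bug rather than noise.  The strain energy is the trapezoid
#' area under the loading arc.  Stress in Pa and dimensionless strain give
#' J/m^3; results are reported in kJ/m^3.
#'
#' @param loop A `hysteresis_loop`.
#' @return List with `dissipated_kJ_m3` and `strain_energy_kJ_m3`.
#' @export
loop_energies <- function(loop) {
  if (nrow(loop$loading) < 2L || nrow(loop$unloading) < 2L)
    stop("degenerate loop arcs")
  eps <- c(loop$strain, loop$strain[1])
  sig <- c(loop$stress, loop$stress[1])
  dissipated <- trapz_signed(eps, sig) / 1000
  if (dissipated < -1e-9)
    stop("negative dissipated energy (", dissipated,
         " kJ/m^3): loop orientation bug")
  strain_energy <- trapz_signed(loop$loading$strain,
                                loop$loading$stress) / 1000
  list(dissipated_kJ_m3 = abs(dissipated),
       strain_energy_kJ_m3 = strain_energy)
}

#' Peak stress of a hysteresis loop
#'
#' @param loop A `hysteresis_loop`.
#' @return Maximum stress over both arcs, Pa.
#' @export
max_stress <- function(loop) {
  if (length(loop$stress) == 0L) stop("empty loop")
  max(loop$stress)
}

#' Energy-dissipation decay series over preconditioning cycles
#'
#' One point per cycle: `t` is the cycle end time and `y` the dissipated
#' energy, optionally normalized by the cycle-1 peak stress (in kPa, so the
#' normalized series is in kJ/m^3 per kPa).
#'
#' @param loops List of `hysteresis_loop`s from
#'   [extract_hysteresis_loops()].
#' @param normalize_by `"none"` or `"cycle1_max_stress"`.
#' @return `data.frame` with columns `t`, `y` and attribute `units`.
#' @export
energy_decay_series <- function(loops,
                                normalize_by = c("none",
                                                 "cycle1_max_stress")) {
  normalize_by <- match.arg(normalize_by)
  if (length(loops) < 3L) stop("need at least 3 loops")
  t <- vapply(loops, function(l) l$cycle_end_time, numeric(1))
  y <- vapply(loops, function(l) l$dissipated_kJ_m3, numeric(1))
  units <- "kJ/m^3"
  if (normalize_by == "cycle1_max_stress") {
    ms <- loops[[1]]$max_stress_Pa / 1000
    if (ms == 0) stop("cycle-1 max stress is zero; cannot normalize")
    y <- y / ms
    units <- "kJ/m^3 per kPa"
  }
  out <- data.frame(t = t, y = y)
  attr(out, "units") <- units
  out
}

#' Fit the exponential-decay energy model
#'
#' Bounded nonlinear least squares for \eqn{y_{fit} = A e^{-t/\tau} + y_0}
#' with \eqn{A \ge 0, \tau > 0} (Levenberg-Marquardt via minpack.lm), with
#' three deterministic restarts of the decay-constant initializer
#' (`tau0 x {0.3, 1, 3}`, `tau0` = a third of the time span).  Diagnostics:
#' `rmse = sqrt(SSE/n)`, `r_squared`, the regression F statistic against
#' the constant model with `df = (2, n-3)` and its p-value.  The fitted,
#' normalized (`y_fit / A`) and adjusted (`(y_fit - y0)/A = e^{-t/tau}`)
#' series are attached.
#'
#' A flat series (amplitude indistinguishable from zero) returns `A = 0`,
#' `y0 = mean(y)` and `tau = NA` flagged unidentifiable.
#'
#' @param series `data.frame` with columns `t` and `y`.
#' @return Object of class `decay_fit`.
#' @export
fit_energy_decay <- function(series) {
  t <- series$t
  y <- series$y
  if (length(t) < 4L) stop("need at least 4 points")
  if (any(!is.finite(y))) stop("non-finite y values")

  y0_0 <- min(y)
  A_0 <- max(y[1] - y0_0, 1e-12)
  span <- diff(range(t))
  sst <- sum((y - mean(y))^2)
  flat <- sst < (1e-14 * max(1, mean(y)^2)) * length(y)

  best <- NULL
  if (!flat) {
    for (mult in c(0.3, 1, 3)) {
      st <- list(A = A_0, tau = span / 3 * mult, y0 = y0_0)
      fit <- try(minpack.lm::nlsLM(
        y ~ A * exp(-t / tau) + y0,
        data = data.frame(t = t, y = y),
        start = st,
        lower = c(A = 0, tau = 1e-9, y0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      sse <- sum(stats::residuals(fit)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(fit = fit, sse = sse)
    }
    if (is.null(best))
      stop("decay fit did not converge after bounded restarts")
  }

  if (flat || unname(stats::coef(best$fit)["A"]) < 1e-10 * max(abs(y), 1e-300)) {
    A <- 0; tau <- NA_real_; y0 <- mean(y)
    yfit <- rep(y0, length(t))
    tau_identifiable <- FALSE
  } else {
    co <- stats::coef(best$fit)
    A <- unname(co["A"]); tau <- unname(co["tau"]); y0 <- unname(co["y0"])
    yfit <- A * exp(-t / tau) + y0
    tau_identifiable <- TRUE
  }
  n <- length(y)
  sse <- sum((y - yfit)^2)
  rmse <- sqrt(sse / n)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  if (tau_identifiable && sse > 0) {
    fstat <- ((sst - sse) / 2) / (sse / (n - 3))
    pval <- stats::pf(fstat, 2, n - 3, lower.tail = FALSE)
  } else if (tau_identifiable) {
    fstat <- Inf; pval <- 0
  } else {
    fstat <- NA_real_; pval <- NA_real_
  }
  structure(list(
    A = A, tau = tau, y0 = y0,
    rmse = rmse, r_squared = r2, f_statistic = fstat, p_value = pval,
    tau_identifiable = tau_identifiable,
    fitted_series = data.frame(t = t, y = yfit),
    normalized_series = if (A > 0) data.frame(t = t, y = yfit / A) else NULL,
    adjusted_series = if (A > 0 && tau_identifiable)
      data.frame(t = t, y = (yfit - y0) / A) else NULL),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit: A = %.4g, tau = %.4g s, y0 = %.4g\n  RMSE = %.3g, R^2 = %.4f, F = %.3g (p = %.3g)\n",
    x$A, x$tau, x$y0, x$rmse, x$r_squared, x$f_statistic, x$p_value))
  invisible(x)
}

#' Pair cycle-1 and cycle-8 dissipated energies across specimens
#'
#' Builds the per-specimen pair table for the paired t-test comparing the
#' first and eighth preconditioning cycles.  Specimens with fewer than 8
#' cycles are excluded with a warning.
#'
#' @param loops_by_specimen Named list; each element the loop list of one
#'   specimen (from [extract_hysteresis_loops()]).
#' @return `data.frame` with columns `specimen`, `cycle1_kJ_m3`,
#'   `cycle8_kJ_m3`.
#' @export
compare_first_last <- function(loops_by_specimen) {
  keep <- vapply(loops_by_specimen, function(l) length(l) >= 8L, logical(1))
  if (any(!keep))
    warning("excluding specimens with < 8 cycles: ",
            paste(names(loops_by_specimen)[!keep], collapse = ", "))
  loops_by_specimen <- loops_by_specimen[keep]
  if (length(loops_by_specimen) == 0L)
    stop("no specimen has 8 preconditioning cycles")
  data.frame(
    specimen = names(loops_by_specimen),
    cycle1_kJ_m3 = vapply(loops_by_specimen,
                          function(l) l[[1]]$dissipated_kJ_m3, numeric(1)),
    cycle8_kJ_m3 = vapply(loops_by_specimen,
                          function(l) l[[8]]$dissipated_kJ_m3, numeric(1)),
    row.names = NULL)
}
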