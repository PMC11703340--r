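#' Specimen geometry for stress/strain conversion
#'
#' Cylindrical unconfined-compression specimen. The cross-section area is
#' derived from the diameter (`pi d^2 / 4`); a 10 mm round is the default
#' punch size for the foam scaffolds this package targets.
#'
#' @param diameter_mm Specimen diameter, mm.
#' @param thickness_mm Specimen thickness, mm (from [determine_thickness()]
#'   or measured directly).
#' @return Object of class `specimen_geometry` with fields `diameter`,
#'   `thickness` and `cross_section_area` (mm^2).
#' @export
specimen_geometry <- function(diameter_mm = 10, thickness_mm = 1) {
  stopifnot(diameter_mm > 0, thickness_mm > 0)
  structure(list(diameter = diameter_mm,
                 thickness = thickness_mm,
                 cross_section_area = pi * diameter_mm^2 / 4),
            class = "specimen_geometry")
}

#' Construct and validate a stress-strain trace
#'
#' The labelled stress-strain signal all DMA operations consume. Segment
#' labels come from `{precondition:k, rest, ramp, relaxation, dynamic}` and
#' must partition the trace contiguously in protocol order.
#'
#' @param time_s Strictly increasing times, s.
#' @param stress_Pa Engineering stress, Pa (compression positive).
#' @param strain Engineering strain (compression positive, >= 0).
#' @param segment Per-sample segment label.
#' @param protocol Optional [dma_protocol()] attached as an attribute (used
#'   by the dynamic-segment fit to know the loading frequency).
#' @return `data.frame` of class `stress_strain_trace`.
#' @export
stress_strain_trace <- function(time_s, stress_Pa, strain, segment,
                                protocol = NULL) {
  n <- length(time_s)
  stopifnot(length(stress_Pa) == n, length(strain) == n,
            length(segment) == n, n >= 2L)
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(stress_Pa)) || any(!is.finite(strain)))
    stop("non-finite stress or strain")
  if (any(strain < -1e-12)) stop("strain must be >= 0 throughout")
  runs <- rle(segment)
  if (anyDuplicated(runs$values))
    stop("segment labels must be contiguous (a label recurs after ending)")
  out <- data.frame(time_s = time_s, stress_Pa = stress_Pa,
                    strain = pmax(strain, 0), segment = segment)
  class(out) <- c("stress_strain_trace", "data.frame")
  attr(out, "protocol") <- protocol
  out
}

#' Write / read a bioreactor trace as delimited text
#'
#' Traces are exchanged as comma-separated text with header
#' `time_s,force_N,displacement_mm`; simulator-emitted files additionally
#' carry `stress_Pa` and `strain` columns, which round-trip unchanged.
#'
#' @param record `data.frame` with at least `time_s`, `force_N`,
#'   `displacement_mm`.
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   validated record.
#' @export
write_trace <- function(record, path) {
  data.table::fwrite(as.data.frame(record), path)
  invisible(path)
}

#' @rdname write_trace
#' @param column_mapping Optional named list mapping canonical names
#'   (`time`, `force`, `displacement`) to the column names present in the
#'   file, e.g. `list(time = "t", force = "load")`.
#' @export
read_trace <- function(path, column_mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, data.table = FALSE)
  canon <- c(time = "time_s", force = "force_N",
             displacement = "displacement_mm")
  if (!is.null(column_mapping)) {
    for (key in names(column_mapping)) {
      src <- column_mapping[[key]]
      if (!src %in% names(dt))
        stop("mapped column '", src, "' not present in ", path)
      names(dt)[names(dt) == src] <- canon[[key]]
    }
  }
  missing <- setdiff(unname(canon), names(dt))
  if (length(missing) > 0)
    stop("missing columns: ", paste(missing, collapse = ", "))
  for (col in unname(canon)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(dt[[col]]))))
    if (length(bad) > 0)
      stop("non-numeric value in column '", col, "' at row ", bad[1])
  }
  dtime <- diff(dt$time_s)
  if (any(dtime <= 0)) {
    row <- which(dtime <= 0)[1] + 1L
    stop("time not strictly increasing at row ", row)
  }
  dt
}

#' Determine specimen thickness from the preload contact
#'
#' Finds the first sample at which the measured force enters the preload
#' window (0.02-0.03 N by default) and reports the platen gap at that
#' instant as the specimen thickness.  If the force jumps over the window
#' between consecutive samples, the crossing is linearly interpolated and a
#' warning is raised.  All subsequent displacement should be referenced to
#' the returned contact datum.
#'
#' @param record Trace record with `time_s`, `force_N`, `displacement_mm`.
#' @param preload_window Force window `c(lo, hi)` in N.
#' @param initial_gap_mm Platen gap at zero displacement, mm. Defaults to
#'   the `initial_gap_mm` attribute of `record` if present.
#' @return List with `thickness_mm`, `contact_index` (first in-window
#'   sample), `datum_displacement_mm`.
#' @export
determine_thickness <- function(record, preload_window = c(0.02, 0.03),
                                initial_gap_mm = NULL) {
  if (preload_window[1] > preload_window[2])
    stop("preload window must satisfy lo <= hi")
  if (is.null(initial_gap_mm))
    initial_gap_mm <- attr(record, "initial_gap_mm")
  if (is.null(initial_gap_mm))
    stop("initial platen gap required to convert displacement to thickness")
  f <- record$force_N
  if (max(f) < preload_window[1])
    stop("no contact: force never reaches ", preload_window[1], " N")
  idx <- which(f >= preload_window[1])[1]
  if (f[idx] > preload_window[2]) {
    warning("force jumps over the preload window; interpolating the crossing")
  }
  if (idx > 1L && f[idx] > preload_window[1]) {
    frac <- (preload_window[1] - f[idx - 1L]) / (f[idx] - f[idx - 1L])
    disp <- record$displacement_mm[idx - 1L] +
      frac * (record$displacement_mm[idx] - record$displacement_mm[idx - 1L])
  } else {
    disp <- record$displacement_mm[idx]
  }
  list(thickness_mm = initial_gap_mm - disp,
       contact_index = idx,
       datum_displacement_mm = disp)
}

#' Convert a force-displacement record to engineering stress-strain
#'
#' Stress is force over the undeformed cross-section (`F/A`, Pa with force
#' in N and area in mm^2); strain is compressive displacement over the
#' contact-datum thickness.  Segments are labelled by aligning the known
#' protocol schedule to the time axis (the first sample is taken as the
#' start of preconditioning).
#'
#' @param record Trace record (`time_s`, `force_N`, `displacement_mm`).
#' @param geometry A [specimen_geometry()] with the datum thickness set.
#' @param protocol A [dma_protocol()] describing the schedule, used for
#'   segment labelling.
#' @param datum_displacement_mm Displacement at contact; subtracted before
#'   the strain conversion.
#' @return A `stress_strain_trace`.
#' @export
to_stress_strain <- function(record, geometry, protocol,
                             datum_displacement_mm = 0) {
  stopifnot(inherits(geometry, "specimen_geometry"),
            inherits(protocol, "dma_protocol"))
  if (geometry$thickness <= 0) stop("thickness must be positive")
  stress <- record$force_N / geometry$cross_section_area * 1e6
  strain <- (record$displacement_mm - datum_displacement_mm) /
    geometry$thickness
  if (any(strain > 1)) stop("strain exceeds 1; check thickness datum")
  t_rel <- record$time_s - record$time_s[1]
  segment <- label_protocol_segments(t_rel, protocol)
  stress_strain_trace(record$time_s, stress, strain, segment,
                      protocol = protocol)
}

# Label samples by the protocol schedule: segment boundaries are the
# cumulative durations of preconditioning, rest, ramp, relaxation and the
# dynamic tail, applied to time measured from the trace start.
label_protocol_segments <- function(t_rel, protocol) {
  p <- protocol
  d_pre <- if (p$precondition_cycles > 0)
    p$precondition_cycles / p$precondition_frequency else 0
  bounds <- cumsum(c(d_pre, p$rest_duration, p$ramp_duration,
                     p$relaxation_duration,
                     if (p$dynamic_cycles > 0)
                       p$dynamic_cycles / p$dynamic_frequency else 0))
  eps <- 1e-9
  segment <- character(length(t_rel))
  pre <- t_rel < bounds[1] - eps
  if (any(pre)) {
    cyc <- pmin(p$precondition_cycles,
                floor(t_rel[pre] * p$precondition_frequency) + 1L)
    segment[pre] <- paste0("precondition:", cyc)
  }
  segment[t_rel >= bounds[1] - eps & t_rel < bounds[2] - eps] <- "rest"
  segment[t_rel >= bounds[2] - eps & t_rel < bounds[3] - eps] <- "ramp"
  segment[t_rel >= bounds[3] - eps & t_rel < bounds[4] - eps] <- "relaxation"
  segment[t_rel >= bounds[4] - eps] <- "dynamic"
  segment
}

#' Write a stress-strain trace as delimited text
#'
#' Columns `time_s,stress_Pa,strain,segment`.
#' @param trace A `stress_strain_trace`.
#' @param path File path.
#' @export
write_stress_strain <- function(trace, path) {
  data.table::fwrite(as.data.frame(trace), path)
  invisible(path)
}
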