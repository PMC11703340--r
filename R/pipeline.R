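#' Default end-to-end run configuration
#'
#' A desk-scale cohort emulating the study design: four stimulation groups
#' of viscoelastic specimens (stiffer, less-relaxing materials at higher
#' stimulation amplitudes), the full DMA protocol, and one foam volume with
#' seeded cells for morphometry and transport.
#'
#' @param seed Global seed; per-specimen sub-seeds are derived as
#'   `(seed * 1000 + specimen_counter) mod (2^31 - 1)` in the order
#'   specimens are listed, so appending a specimen never perturbs existing
#'   ones.
#' @param n_per_group Specimens per group.
#' @return Configuration list for [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, n_per_group = 5L) {
  arm <- function(E1, tau) data.frame(modulus = E1, tau = tau)
  list(
    seed = seed,
    protocol = list(),
    materials = list(
      `0mV`  = list(equilibrium_modulus = 20e3, arms = arm(45e3, 10),
                    noise_sd = 35),
      `20mV` = list(equilibrium_modulus = 13e3, arms = arm(45e3, 9),
                    noise_sd = 35),
      `40mV` = list(equilibrium_modulus = 22e3, arms = arm(48e3, 9),
                    noise_sd = 35),
      `60mV` = list(equilibrium_modulus = 26e3, arms = arm(53e3, 8),
                    noise_sd = 35)),
    groups = stats::setNames(
      lapply(c("0mV", "20mV", "40mV", "60mV"),
             function(m) list(material = m, n = n_per_group)),
      c("0mV", "20mV", "40mV", "60mV")),
    volume = list(shape = c(64L, 64L, 64L), target_porosity = 97,
                  voxel_size_um = 2.43, n_cells = 8),
    stimulus = list(vpp_mV = 60, frequency_Hz = 1000,
                    electrode_distance_mm = 3.17))
}

#' Run the full simulate-analyze-report pipeline
#'
#' Simulates one DMA trace per specimen, extracts the five DMA endpoints
#' and the hysteresis-loop energies with their exponential-decay fit,
#' generates the foam volume with seeded cells, runs morphometry and the
#' tortuosity solve, estimates the effective stimulation field, and
#' assembles the cohort report.  A manifest records the package version,
#' all derived seeds and the MD5 hashes of every written file.
#'
#' @param config Configuration list as from [default_run_config()], or a
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory; created if needed.
#' @return List with `report` (the [build_report()] bundle), `manifest`,
#'   and `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("scafmech_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  protocol <- do.call(dma_protocol, config$protocol %||% list())

  materials <- lapply(config$materials, function(m)
    prony_material(m$equilibrium_modulus,
                   as.data.frame(m$arms),
                   m$noise_sd %||% 0))

  endpoints <- NULL
  loops_by_specimen <- list()
  decay_fits <- list()
  counter <- 0L
  seeds_used <- integer(0)
  for (grp in names(config$groups)) {
    gspec <- config$groups[[grp]]
    if (!gspec$material %in% names(materials))
      stop("group '", grp, "' references unknown material '",
           gspec$material, "'")
    mat <- materials[[gspec$material]]
    for (i in seq_len(gspec$n)) {
      counter <- counter + 1L
      sub_seed <- as.integer((seed * 1000 + counter) %% (2^31 - 1))
      seeds_used <- c(seeds_used, sub_seed)
      sim <- simulate_dma_protocol(mat, protocol, seed = sub_seed)
      sid <- sprintf("%s_s%02d", grp, i)
      write_trace(cbind(sim$record,
                        stress_Pa = sim$trace$stress_Pa,
                        strain = sim$trace$strain),
                  file.path(out_dir, paste0(sid, "_trace.csv")))
      ep <- dma_endpoints(sim$trace)
      endpoints <- rbind(endpoints, data.frame(
        sample_id = sid, group = grp,
        compressive_modulus_Pa = ep$compressive_modulus_Pa,
        equilibrium_modulus_Pa = ep$equilibrium_modulus_Pa,
        stress_relaxation_percent = ep$stress_relaxation_percent,
        dynamic_modulus_Pa = ep$dynamic_modulus_Pa,
        phase_shift_rad = ep$phase_shift_rad))
      loops <- extract_hysteresis_loops(sim$trace)
      loops_by_specimen[[sid]] <- loops
      decay_fits[[sid]] <- fit_energy_decay(energy_decay_series(loops))
    }
  }
  pairs <- compare_first_last(loops_by_specimen)

  morph <- NULL; trans <- NULL; field <- NULL
  if (!is.null(config$volume)) {
    v <- config$volume
    vol_seed <- as.integer((seed * 1000 + 901L) %% (2^31 - 1))
    foam <- generate_foam_volume(v$shape, v$target_porosity,
                                 v$voxel_size_um %||% 2.43,
                                 seed = vol_seed)
    labelled <- seed_cells_in_foam(foam, v$n_cells %||% 0,
                                   seed = vol_seed + 1L)
    write_volume(labelled, file.path(out_dir, "volume.tif"))
    morph <- morphometry(labelled, phase = 1L)
    trans <- tortuosity(phase_grid(labelled, 1L), axis = 3L)
    if (!is.null(config$stimulus)) {
      s <- config$stimulus
      wf <- generate_waveform(stimulus_spec(s$vpp_mV, s$frequency_Hz))
      field <- effective_field(rms_voltage(wf),
                               s$electrode_distance_mm %||% 3.17,
                               trans$tortuosity_factor)
    }
  }

  report <- build_report(endpoints, energy_pairs = pairs,
                         decay_fits = decay_fits, morphometry = morph,
                         transport = trans, field = field)
  paths <- write_report(report, out_dir)

  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(package_version = as.character(
                     utils::packageVersion("scafmech")),
                   seed = seed,
                   specimen_seeds = seeds_used,
                   files = data.frame(file = basename(files),
                                      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, manifest = manifest, out_dir = out_dir))
}
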