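#' Default structured configuration
#'
#' A nested list mirroring the YAML configuration consumed by the command
#' line interface, with all model defaults (Sputnik1 pump and power-law
#' parameters, baseline heart-failure cardiovascular conditions, the
#' modulation sweep grids).
#'
#' @return A named nested list with sections `pump` (`mech`, `hyd`),
#'   `power_law`, `geometry`, `cvs`, `profile`, `sweep`, `simulation`.
#' @export
default_config <- function() {
  list(
    pump = list(
      mech = unclass(mech_params()),
      hyd = unclass(hydraulic_params())),
    power_law = unclass(power_law_params()),
    geometry = unclass(impeller_geometry()),
    cvs = unclass(cvs_params()),
    profile = list(mean_speed = 7500, amplitude = 1000, duty = 0.5,
                   phase = 0, cutoff = 20),
    sweep = list(means = c(6500, 7500, 8500),
                 amplitudes = seq(500, 3000, by = 500),
                 cutoffs = c(20, 5, 2), duty_step = 0.05,
                 phase_step = 0.05),
    simulation = list(dt = 4e-4, cycles = 16))
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()]:
#' any key not present in the file keeps its default.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return A configuration list as [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("reading configuration files requires the 'yaml' package")
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  merge_lists(cfg, user)
}

#' Build parameter objects from a configuration
#'
#' @param cfg a configuration list as returned by [read_config()].
#' @return A list with elements `mech`, `hyd`, `params` (power law),
#'   `geometry`, `cvs`, `dt`, `cycles`.
#' @export
config_params <- function(cfg = default_config()) {
  list(mech = do.call(mech_params, cfg$pump$mech),
       hyd = do.call(hydraulic_params, cfg$pump$hyd),
       params = do.call(power_law_params, cfg$power_law),
       geometry = do.call(impeller_geometry, cfg$geometry),
       cvs = do.call(cvs_params, cfg$cvs),
       dt = cfg$simulation$dt, cycles = cfg$simulation$cycles)
}
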