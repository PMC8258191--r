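#' Default processing configuration
#'
#' All numeric constants of the estimation chain in one list: the mean
#' weighing error subtracted from every record, the control standard
#' deviation and its multiplier defining the reliability threshold, the
#' assumed formalin mass-loss fraction, and the sampling geometry (net
#' mouth area, dilution volume, pipette volume). The small-mesozooplankton
#' size threshold and the allometry performance band are included because
#' downstream modules share them.
#'
#' @details Units: masses in mg, volumes in ml, areas in m\eqn{^2}, lengths
#'   in \eqn{\mu}m. `control_sd` defaults to 0.043/4 = 0.01075 mg, the value
#'   implied by a reliability threshold of 0.043 mg at a multiplier of 4.
#'   `reliable_on` selects whether the threshold is compared against the
#'   error-corrected gain (default) or the raw gain.
#'
#' @param ... named overrides of any default entry.
#' @return A named list of class `"zoo_config"`.
#' @examples
#' cfg <- default_config()
#' cfg$formalin_loss
#' default_config(sd_multiplier = 3)$sd_multiplier
#' @export
default_config <- function(...) {
  cfg <- list(
    mean_control_error = 0.016,   # mg
    control_sd         = 0.01075, # mg; 0.043 / 4
    sd_multiplier      = 4,
    formalin_loss      = 0.40,
    net_area           = 0.25,    # m^2
    dilution_ml        = 200,
    pipette_ml         = 2,
    smz_threshold_um   = 1000,
    band_lower         = 80,      # percent
    band_upper         = 120,     # percent
    reliable_on        = "corrected"
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  class(cfg) <- "zoo_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$formalin_loss), cfg$formalin_loss >= 0, cfg$formalin_loss < 1,
    cfg$net_area > 0, cfg$dilution_ml > 0, cfg$pipette_ml > 0,
    cfg$sd_multiplier >= 0, cfg$control_sd >= 0,
    cfg$reliable_on %in% c("corrected", "raw")
  )
  invisible(cfg)
}

#' Read or write a processing configuration as YAML
#'
#' @param path file path.
#' @param cfg a configuration list from [default_config()].
#' @return `read_config()` returns a `"zoo_config"` list; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
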