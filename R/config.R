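#' Default fhdx configuration
#'
#' Loads the configuration shipped with the package: criterion thresholds and
#' point tables for the six FH diagnostic criteria, the statin/ezetimibe
#' treatment-intensity factor table, Friedewald reporting rules, and variant
#' classification rules. All lipid values are mmol/L and all LDL-C / total
#' cholesterol threshold comparisons are strict (`>`).
#'
#' @return A named list of class `fh_config`.
#' @seealso [fh_read_config()] to load an edited copy.
#' @export
#' @examples
#' cfg <- fh_default_config()
#' names(cfg)
fh_default_config <- function() {
  path <- system.file("extdata", "fh-config.yaml", package = "fhdx")
  fh_read_config(path)
}

#' Read an fhdx configuration file
#'
#' Reads a YAML (or JSON) configuration with the same schema as the shipped
#' default (see `system.file("extdata", "fh-config.yaml", package = "fhdx")`).
#' Keys missing from the file are filled in from the shipped default, so a
#' config may override only the entries it cares about.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A named list of class `fh_config`.
#' @export
fh_read_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  default_path <- system.file("extdata", "fh-config.yaml", package = "fhdx")
  if (nzchar(default_path) && normalizePath(path) != normalizePath(default_path)) {
    cfg <- modify_defaults(yaml::read_yaml(default_path), cfg)
  }
  validate_config(cfg)
  structure(cfg, class = c("fh_config", "list"))
}

# recursively overlay `new` onto `base`
modify_defaults <- function(base, new) {
  for (k in names(new)) {
    if (is.list(new[[k]]) && is.list(base[[k]]) && !is.null(names(new[[k]]))) {
      base[[k]] <- modify_defaults(base[[k]], new[[k]])
    } else {
      base[[k]] <- new[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  required <- c(
    "dlcnc", "simon_broome", "medped", "jfhmc", "hk_panel",
    "intensity_criterion", "friedewald", "correction_factors"
  )
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("config is missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  band <- cfg$intensity_criterion$reduction_band
  if (length(band) != 2 || band[1] >= band[2] || band[1] < 0 || band[2] > 1) {
    stop("intensity_criterion$reduction_band must be an increasing interval in [0, 1]",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Write a configuration to a file
#'
#' Serialises a configuration (for example to echo the exact settings of a
#' run into its output directory, so the run is reproducible from config +
#' seed alone).
#'
#' @param cfg An `fh_config` list.
#' @param path Output path; extension picks the format (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
fh_write_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}

# Resolve a config argument: NULL -> shipped default, path -> read it.
as_fh_config <- function(config) {
  if (is.null(config)) {
    return(fh_default_config())
  }
  if (is.character(config) && length(config) == 1) {
    return(fh_read_config(config))
  }
  if (inherits(config, "fh_config") || is.list(config)) {
    return(config)
  }
  stop("`config` must be NULL, a path, or an fh_config list", call. = FALSE)
}

#' Round percentages half-up
#'
#' Rounds on the percent scale with ties going away from zero (half-up), the
#' convention used for all reported percentages (e.g. 33.25 -> 33.3 at one
#' decimal). Base `round()` rounds half to even, which would disagree with
#' published roundings on exact ties.
#'
#' @param x Numeric vector of percentages.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' percent_half_up(84.615)       # 84.6
#' percent_half_up(33.3333)      # 33.3
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname round_half_up
#' @param fraction Numeric vector of fractions (0-1) to render as percentages.
#' @export
percent_half_up <- function(fraction, digits = 1) {
  round_half_up(100 * fraction, digits)
}
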