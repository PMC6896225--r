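# Per-command configuration registries: every known key with its default
# and expected type. Unknown keys are rejected by name; shared keys keep
# the field names of the corresponding classes.
configRegistry <- function() {
  sim <- list(
    temperature = 303, gamma = 500, dt = 0.04, epsilon = 2.5, leafletK = 5,
    cutoff = 0.6
  )
  ring <- list(
    nProtomers = 14L, outerRadius = 2.6, innerRadius = 1.7,
    beadsPerColumn = 3L, columnZSpan = 3.2, box = c(24, 18, 12)
  )
  plug <- list(nLoop = 7L, nNC = 10L, bulkDensity = 1.5)
  common <- list(rngSeed = 1L, outputDir = ".", logLevel = "info")
  list(
    fixtures = c(ring, plug, list(separation = 5), common),
    assemble = c(sim, ring, plug, list(
      separation = 5, weakK = 10, weakMaxDuration = 300, checkInterval = 1,
      convergenceThreshold = 5,
      strongStages = list(c(10, 200), c(100, 200), c(1000, 200)),
      assembledThreshold = 5, saveEvery = 20), common),
    density = c(list(select = "lipid", spacing = 1, sigma = 1), common),
    symavg = c(list(order = 14L), common),
    rscc = c(list(maskLevel = 0.8), common),
    count = c(list(zExtent = 2), common),
    residence = c(list(zExtent = 2, includeCensored = FALSE), common),
    extrude = c(list(zExtent = 2, debounce = 10L), common),
    contacts = c(list(cutoff = 4.0), common),
    zprofile = c(list(select = "lipid_head", binWidth = 0.1), common),
    displace = c(list(zExtent = 2), common)
  )
}

#' Parse a YAML run configuration
#'
#' Reads a YAML mapping for the given command, applies the documented
#' defaults (e.g. contact cutoff 4 Angstrom, mask level 0.8) and rejects
#' unknown keys and type mismatches by name. An empty file yields the
#' full default configuration.
#'
#' @param path YAML file.
#' @param command one of the CLI subcommand names.
#' @return a named list of configuration values, with attributes
#'   `command`.
#' @export
parseRunConfig <- function(path, command = "assemble") {
  reg <- configRegistry()
  if (!command %in% names(reg))
    rwStop("rw_config_error", sprintf("unknown command '%s'", command))
  defaults <- reg[[command]]
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user))
    rwStop("rw_config_error", "configuration must be a YAML mapping")
  for (k in names(user)) {
    if (!k %in% names(defaults))
      rwStop("rw_config_error", sprintf("unknown configuration key '%s'", k))
    def <- defaults[[k]]
    val <- user[[k]]
    if (is.numeric(def) && !is.numeric(val))
      rwStop("rw_config_error",
             sprintf("key '%s' must be numeric, got %s", k, class(val)[1]))
    if (is.character(def) && !is.character(val))
      rwStop("rw_config_error",
             sprintf("key '%s' must be character, got %s", k, class(val)[1]))
    if (is.logical(def) && !is.logical(val))
      rwStop("rw_config_error",
             sprintf("key '%s' must be logical, got %s", k, class(val)[1]))
    if (is.numeric(def) && length(def) > 1 && length(val) != length(def))
      rwStop("rw_config_error",
             sprintf("key '%s' must have %d values", k, length(def)))
    defaults[[k]] <- val
  }
  structure(defaults, command = command)
}
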