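#' Run configuration
#'
#' Builds and validates the configuration consumed by the command-line
#' interface: calibration, method parameters, sweep grids, filter-chain
#' overrides, voting rule, and seed. Values resolve in three layers:
#' built-in defaults (the standard filter bounds 5 / 50 / 50 / 6000 /
#' 1.73 and `min_votes = 2`), then a YAML config file, then explicit
#' arguments / command-line flags.
#'
#' @param path Optional YAML file with any subset of the config keys
#'   (`pixel_size_um`, `method`, `threshold`, `radius`,
#'   `ratio_threshold_grid` / `phasor_radius_grid` as `lo:hi:n` strings or
#'   numeric vectors, `min_votes`, `seed`, `phasor_bins`, and the
#'   `filters:` block `min_area_um2`, `isolated_max_area_um2`,
#'   `isolation_distance_um`, `max_area_um2`, `hole_fill_max_um2`).
#' @param ... Named overrides applied on top of the file.
#' @return A validated `cmh_config` list.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    pixel_size_um = NULL,
    method = NULL,
    threshold = NULL,
    radius = NULL,
    ratio_threshold_grid = ratio_threshold_grid(),
    phasor_radius_grid = phasor_radius_grid(),
    phasor_bins = 256,
    min_votes = 2,
    seed = 1,
    filters = list(min_area_um2 = 5, isolated_max_area_um2 = 50,
                   isolation_distance_um = 50, max_area_um2 = 6000,
                   hole_fill_max_um2 = 1.73))
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  over <- list(...)
  over <- over[!vapply(over, is.null, logical(1))]
  cfg <- utils::modifyList(cfg, over)
  for (g in c("ratio_threshold_grid", "phasor_radius_grid")) {
    cfg[[g]] <- parse_grid(cfg[[g]])
  }
  if (!is.null(cfg$pixel_size_um)) check_pixel_size(cfg$pixel_size_um)
  if (!is.null(cfg$method) &&
      !cfg$method %in% c("ratiometric", "phasor", "truth")) {
    stop("unknown method: ", cfg$method, call. = FALSE)
  }
  structure(cfg, class = "cmh_config")
}

# accept "lo:hi:n" strings (geometric for thresholds? no: linear seq) or vectors
parse_grid <- function(g) {
  if (is.character(g)) {
    parts <- as.numeric(strsplit(g, ":", fixed = TRUE)[[1]])
    if (length(parts) != 3 || anyNA(parts)) {
      stop("grid spec must be lo:hi:n", call. = FALSE)
    }
    g <- seq(parts[1], parts[2], length.out = parts[3])
  }
  as.numeric(g)
}

chain_from_config <- function(cfg, method) {
  f <- cfg$filters
  filter_chain_spec(method,
                    min_area_um2 = f$min_area_um2,
                    isolated_max_area_um2 = f$isolated_max_area_um2,
                    isolation_distance_um = f$isolation_distance_um,
                    max_area_um2 = f$max_area_um2,
                    hole_fill_max_um2 = f$hole_fill_max_um2)
}

# provenance record written next to CLI outputs
write_provenance <- function(cfg, path, extra = list()) {
  rec <- c(list(package = "cmhseg",
                version = as.character(utils::packageVersion("cmhseg")),
                r_version = as.character(getRversion()),
                timestamp = format(Sys.time(), tz = "UTC")),
           extra,
           list(config = unclass(cfg)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
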