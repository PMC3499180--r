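# Simulation configuration: defaults, validation (all problems reported at
# once), YAML round-trip.

.gp_config_defaults <- function() {
  k <- gp_constants()
  list(load = NULL,                 # MPa, tension positive — required
       duration = k$duration,       # days
       columns = k$columns,
       spacing = k$column_spacing,  # um
       lateral_per_column = 1L,
       reserve_rows = 2L,
       bone_rows = 2L,
       steady_geometry = TRUE,
       support = "confined",
       interpolate = FALSE,
       snapshot_every = 0L,         # steps between VTK snapshots; 0 = none
       verbose = FALSE,
       out_dir = NULL)
}

#' Build a simulation configuration
#'
#' Fills defaults (23-day duration, 20 columns at 40 um spacing on the
#' 800 um domain, steady-geometry mode, confined support, no snapshots) and
#' validates every field, reporting all problems in one error.
#'
#' @param load Sustained axial stress difference, MPa, tension positive
#'   (required).  One of +0.1, 0.0, -0.1, -0.2 unless `interpolate = TRUE`.
#' @param ... Overrides for the remaining fields: `duration`, `columns`,
#'   `spacing`, `lateral_per_column`, `reserve_rows`, `bone_rows`,
#'   `steady_geometry`, `support`, `interpolate`, `snapshot_every`,
#'   `verbose`, `out_dir`.
#' @return An object of class `gp_config`.
#' @seealso [parse_config()] to read a configuration file.
#' @export
#' @examples
#' gp_config(load = -0.1)
gp_config <- function(load, ...) {
  .build_config(c(list(load = load), list(...)))
}

#' Parse a simulation configuration from a YAML file
#'
#' Reads a flat-key YAML file (keys as in [gp_config()]), applies defaults
#' and validates.  Unknown keys and out-of-range values are all reported in
#' a single error.
#'
#' @param path Path to the YAML file.
#' @param ... Overrides applied on top of the file.
#' @return A `gp_config`.
#' @export
parse_config <- function(path, ...) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  over <- list(...)
  vals[names(over)] <- over
  .build_config(vals)
}

#' Write a configuration to a YAML file
#'
#' @param config A `gp_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "gp_config"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

.build_config <- function(vals) {
  defaults <- .gp_config_defaults()
  problems <- character()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) {
    problems <- c(problems,
                  paste0("unknown configuration key(s): ",
                         paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  known <- intersect(names(vals), names(defaults))
  cfg[known] <- vals[known]

  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)

  chk(num1(cfg$load),
      "'load' (sustained stress difference, MPa) is required and must be a single number")
  chk(num1(cfg$duration) && cfg$duration >= 0,
      "'duration' must be a non-negative number of days")
  chk(num1(cfg$columns) && cfg$columns >= 1 && cfg$columns == round(cfg$columns),
      "'columns' must be a positive integer")
  chk(num1(cfg$spacing) && cfg$spacing > 0, "'spacing' must be positive (um)")
  chk(num1(cfg$lateral_per_column) && cfg$lateral_per_column >= 1 &&
        cfg$lateral_per_column == round(cfg$lateral_per_column),
      "'lateral_per_column' must be a positive integer")
  chk(num1(cfg$reserve_rows) && cfg$reserve_rows >= 1,
      "'reserve_rows' must be a positive integer")
  chk(num1(cfg$bone_rows) && cfg$bone_rows >= 1,
      "'bone_rows' must be a positive integer")
  chk(isTRUE(cfg$steady_geometry) || isFALSE(cfg$steady_geometry),
      "'steady_geometry' must be TRUE or FALSE")
  chk(is.character(cfg$support) && length(cfg$support) == 1 &&
        cfg$support %in% c("confined", "simple"),
      "'support' must be \"confined\" or \"simple\"")
  chk(isTRUE(cfg$interpolate) || isFALSE(cfg$interpolate),
      "'interpolate' must be TRUE or FALSE")
  chk(num1(cfg$snapshot_every) && cfg$snapshot_every >= 0 &&
        cfg$snapshot_every == round(cfg$snapshot_every),
      "'snapshot_every' must be a non-negative integer (steps)")
  chk(isTRUE(cfg$verbose) || isFALSE(cfg$verbose),
      "'verbose' must be TRUE or FALSE")
  chk(is.null(cfg$out_dir) ||
        (is.character(cfg$out_dir) && length(cfg$out_dir) == 1),
      "'out_dir' must be a single path or omitted")
  if (num1(cfg$load) && isFALSE(cfg$interpolate)) {
    tab <- gp_load_cases()$delta_sigma_n
    chk(any(abs(tab - cfg$load) < 1e-9),
        paste0("'load' = ", cfg$load, " MPa is not a tabulated case (",
               paste(sprintf("%+.1f", tab), collapse = ", "),
               "); set interpolate: true to allow intermediate loads"))
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  for (f in c("columns", "lateral_per_column", "reserve_rows", "bone_rows",
              "snapshot_every")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  structure(cfg, class = "gp_config")
}

#' @export
print.gp_config <- function(x, ...) {
  cat("Growth simulation configuration:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "<unset>" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
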