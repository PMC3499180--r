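# Result export (CSV time series, VTK snapshots, run manifest) and the
# four-case validation suite.

#' Export simulation results
#'
#' Writes the per-step time series as an RFC 4180 CSV, any stored mesh
#' snapshots (plus the final mesh) as VTK `.vtu` files with tissue, zone,
#' column and axial-stress cell data, and a plain-text run manifest listing
#' every output with its MD5 checksum alongside the configuration echo and
#' package version.  CSV output is byte-identical across repeated runs of
#' the same configuration.  The output directory is checked for
#' writability up front.
#'
#' @param result A `gp_simulation` (possibly from a partial run).
#' @param dir Output directory (created if missing).
#' @param basename Stem for output file names.
#' @return Invisibly, a character vector of the files written.
#' @export
export_results <- function(result, dir, basename = "growthplate") {
  stopifnot(inherits(result, "gp_simulation"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  if (file.access(dir, mode = 2) != 0) {
    stop("output directory is not writable: ", dir, call. = FALSE)
  }
  files <- character()

  csv <- file.path(dir, paste0(basename, "_series.csv"))
  series <- result$series
  for (cn in names(series)) series[[cn]] <- sprintf("%.10g", series[[cn]])
  write.csv(series, csv, row.names = FALSE, quote = FALSE)
  files <- c(files, csv)

  for (sn in result$snapshots) {
    vtu <- file.path(dir, sprintf("%s_step%04d.vtu", basename, sn$step))
    cd <- list(zone = as.integer(sn$mesh$elem_zone),
               tissue = as.integer(factor(sn$mesh$elem_tissue,
                                          levels = gp_tissues()$tissue)),
               column = as.integer(ifelse(is.na(sn$mesh$elem_column), -1L,
                                          sn$mesh$elem_column)))
    if (!is.null(sn$sigma_n)) cd$sigma_n <- sn$sigma_n
    write_vtu(sn$mesh, vtu, cell_data = cd)
    files <- c(files, vtu)
  }

  manifest <- file.path(dir, paste0(basename, "_manifest.txt"))
  md5 <- tools::md5sum(files)
  cfg <- unclass(result$config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  cfg_lines <- strsplit(yaml::as.yaml(cfg), "\n", fixed = TRUE)[[1]]
  lines <- c(
    "growthplate run manifest",
    paste0("package_version: ", as.character(packageVersion("growthplate"))),
    paste0("written: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    "configuration:",
    paste0("  ", cfg_lines),
    "outputs:",
    sprintf("  %s  md5=%s  bytes=%d", basename(files), md5,
            file.size(files)))
  writeLines(lines, manifest)
  files <- c(files, manifest)
  invisible(files)
}

#' Run the four-case 23-day validation suite
#'
#' Simulates all four tabulated sustained-load cases (+0.1, 0.0, -0.1,
#' -0.2 MPa) for the standard 23-day period and compares the simulated mean
#' growth rate with the experimentally derived rate for each case.  A case
#' passes when its relative error stays within the 3.73% band.
#'
#' @param duration Simulated period, days.
#' @param tolerance_pct Pass threshold on the relative error, percent.
#' @param ... Further configuration overrides passed to every case.
#' @return A data frame (class `gp_validation`) with columns
#'   `delta_sigma_n`, `g_sim`, `g_stokes`, `error_pct`, `pass`, and an
#'   attribute `pass` (all cases within tolerance).  The simulation objects
#'   are attached as attribute `runs`.
#' @export
run_validation_suite <- function(duration = gp_constants()$duration,
                                 tolerance_pct = 3.73, ...) {
  loads <- gp_load_cases()$delta_sigma_n
  runs <- lapply(loads, function(l) {
    simulate_growth(gp_config(load = l, duration = duration, ...))
  })
  out <- data.frame(
    delta_sigma_n = loads,
    g_sim = vapply(runs, function(r) r$mean_g, 0),
    g_stokes = vapply(runs, function(r) r$load_case$g_stokes, 0))
  out$error_pct <- 100 * abs(out$g_sim - out$g_stokes) / out$g_stokes
  out$pass <- out$error_pct <= tolerance_pct
  attr(out, "pass") <- all(out$pass)
  attr(out, "runs") <- runs
  attr(out, "tolerance_pct") <- tolerance_pct
  class(out) <- c("gp_validation", "data.frame")
  out
}

#' @export
print.gp_validation <- function(x, ...) {
  cat("Growth-rate validation (", attr(x, "tolerance_pct"),
      "% tolerance):\n", sep = "")
  df <- as.data.frame(x)
  df$g_sim <- sprintf("%.1f", df$g_sim)
  df$error_pct <- sprintf("%.2f", df$error_pct)
  print(df, row.names = FALSE)
  cat(if (attr(x, "pass")) "PASS: all load cases within tolerance\n"
      else "FAIL: at least one load case outside tolerance\n")
  invisible(x)
}
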