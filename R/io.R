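# Delimited-text formats: header line naming columns with unit suffixes,
# '.' decimal, comma or tab delimited, UTF-8.

KNOWN_HEADERS <- list(
  rehydration_curve = c("time_min", "moisture_g_per_g"),
  cpmg_decay = c("echo_ms", "amplitude")
)

#' Read a rehydration curve or CPMG decay from delimited text
#'
#' Accepts comma- or tab-delimited files with a header line naming the
#' columns with their units: `time_min, moisture_g_per_g` for rehydration
#' curves or `echo_ms, amplitude` for CPMG decays.  The time axis must be
#' strictly increasing; violations are reported with the offending line
#' number, as are non-numeric cells and unknown column/unit tags.
#'
#' @param path file to read.
#' @return A [rehydration_curve()] or [cpmg_decay()], by header.
#' @export
load_timeseries <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("file needs a header and at least one row",
                              call. = FALSE)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  header <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  kind <- NULL
  for (k in names(KNOWN_HEADERS)) {
    if (identical(header, KNOWN_HEADERS[[k]])) kind <- k
  }
  if (is.null(kind)) {
    stop(sprintf("unrecognised header/unit tags: '%s'",
                 paste(header, collapse = ", ")), call. = FALSE)
  }
  n <- length(lines) - 1
  tvals <- numeric(n); yvals <- numeric(n)
  for (r in seq_len(n)) {
    cells <- trimws(strsplit(lines[r + 1], sep, fixed = TRUE)[[1]])
    if (length(cells) != 2) {
      stop(sprintf("line %d: expected 2 columns, found %d", r + 1,
                   length(cells)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      stop(sprintf("line %d: non-numeric cell '%s'", r + 1,
                   cells[which(is.na(vals))[1]]), call. = FALSE)
    }
    tvals[r] <- vals[1]; yvals[r] <- vals[2]
  }
  bad <- which(diff(tvals) <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-monotone time axis at line %d (t = %g after t = %g)",
                 bad[1] + 2, tvals[bad[1] + 1], tvals[bad[1]]), call. = FALSE)
  }
  if (kind == "rehydration_curve") rehydration_curve(tvals, yvals)
  else cpmg_decay(tvals, yvals)
}

#' Write a rehydration curve or CPMG decay as delimited text
#'
#' @param x a [rehydration_curve()] or [cpmg_decay()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a kinetic fit report as key-value text
#'
#' @param fit a [fit_kinetics()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "kinetic_fit"))
  lines <- c(
    sprintf("model: %s", fit$model),
    sprintf("param_%s: %.10g", names(fit$params), unlist(fit$params)),
    sprintf("M0_g_per_g: %.10g", fit$M0),
    sprintf("Me_g_per_g: %.10g", fit$Me),
    sprintf("r_squared: %.10g", fit$r_squared),
    sprintf("sse: %.10g", fit$sse),
    sprintf("converged: %s", tolower(fit$converged)),
    sprintf("n_iter: %d", fit$n_iter)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a field snapshot as a legacy VTK structured-points file
#'
#' Cell data: water volume fraction `phi`, pressure `p`, and the
#' cell-averaged velocity vector; suitable for ParaView and other standard
#' visualisation tools.
#'
#' @param snapshot one element of `run_capillary_filling()$snapshots` (or a
#'   `twophase_state`).
#' @param domain the [build_domain()] grid.
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(snapshot, domain, path) {
  Nr <- domain$Nr; Nz <- domain$Nz; h <- domain$h
  phi <- snapshot$phi; p <- snapshot$p
  ur <- snapshot$ur; uz <- snapshot$uz
  ucell <- (ur[seq_len(Nr), , drop = FALSE] +
              ur[seq_len(Nr) + 1, , drop = FALSE]) / 2
  wcell <- (uz[, seq_len(Nz), drop = FALSE] +
              uz[, seq_len(Nz) + 1, drop = FALSE]) / 2
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    sprintf("axisymmetric two-phase state t=%.6e s", snapshot$t %||% NA),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 2", Nr + 1, Nz + 1),
    "ORIGIN 0 0 0",
    sprintf("SPACING %.6e %.6e %.6e", h, h, h),
    sprintf("CELL_DATA %d", Nr * Nz),
    "SCALARS phi double 1",
    "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6e", as.vector(phi)), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6e", as.vector(p)), con)
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.6e %.6e 0", as.vector(ucell), as.vector(wcell)), con)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Every pipeline run records its configuration, seed and package version
#' so that results can be reproduced exactly.
#'
#' @param config named list of run parameters (must be JSON-serialisable).
#' @param seed the RNG seed used by the run.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  manifest <- list(
    package = "gelrehyd",
    version = as.character(utils::packageVersion("gelrehyd")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
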