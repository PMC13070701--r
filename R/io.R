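#' Read a plain-text CEST profile
#'
#' Accepts the column format customary in relaxation-dispersion work:
#' whitespace- or comma-delimited numeric columns, `#` starting a comment,
#' column 1 the saturation-carrier position (absolute ppm by default),
#' column 2 the normalized intensity, optional column 3 a per-point
#' intensity uncertainty; further columns are ignored. Rows are sorted by
#' offset; duplicate offsets are averaged with a warning. Malformed numerics
#' are rejected with the offending line number rather than coerced.
#'
#' @param path file to read.
#' @param residue_id,b1_Hz metadata attached to the profile.
#' @param offsets_relative_hz if `TRUE`, column 1 holds offsets in Hz
#'   relative to the carrier and is converted to ppm on load (requires
#'   `larmor_MHz`).
#' @param larmor_MHz Larmor frequency used for the Hz -> ppm conversion.
#' @return a [cest_profile()].
#' @export
read_cest_profile <- function(path, residue_id, b1_Hz,
                              offsets_relative_hz = FALSE,
                              larmor_MHz = NULL) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(stripped)))
  if (length(keep) < 3)
    stop(sprintf("%s: fewer than 3 data rows", path))
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(stripped[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || any(is.na(vals[1:min(3, length(vals))])))
      stop(sprintf("%s: non-numeric or incomplete data on line %d: '%s'",
                   path, i, lines[i]), call. = FALSE)
    vals
  })
  ncol_min <- min(vapply(rows, length, integer(1)))
  off <- vapply(rows, `[[`, numeric(1), 1)
  inten <- vapply(rows, `[[`, numeric(1), 2)
  sig <- if (ncol_min >= 3) vapply(rows, `[[`, numeric(1), 3) else NULL
  bad <- which(inten < -1.5 | inten > 1.5)
  if (length(bad))
    stop(sprintf("%s: intensity outside [-1.5, 1.5] on line %d (value %g)",
                 path, keep[bad[1]], inten[bad[1]]))
  if (offsets_relative_hz) {
    if (is.null(larmor_MHz))
      stop("offsets_relative_hz = TRUE requires larmor_MHz")
    off <- off / larmor_MHz
  }
  if (anyDuplicated(off)) {
    warning(sprintf("%s: duplicate offsets averaged", path))
    agg_i <- tapply(inten, off, mean)
    agg_s <- if (!is.null(sig)) tapply(sig, off, mean)
    off <- as.numeric(names(agg_i))
    inten <- as.numeric(agg_i)
    sig <- if (!is.null(sig)) as.numeric(agg_s)
  }
  cest_profile(residue_id, b1_Hz, off, inten, sig)
}

#' Write a CEST profile to a plain-text file
#'
#' Columns `offset_ppm intensity [sigma]`, 6 significant digits, readable
#' back with [read_cest_profile()] without loss at that precision.
#' @param profile a [cest_profile()].
#' @param path output file.
#' @export
write_cest_profile <- function(profile, path) {
  has_sig <- !all(is.na(profile$sigmas))
  hdr <- sprintf("# residue %s, B1 %g Hz: offset_ppm intensity%s",
                 profile$residue_id, profile$b1_Hz,
                 if (has_sig) " sigma" else "")
  body <- if (has_sig)
    sprintf("%s %s %s", fmt6(profile$offsets_ppm), fmt6(profile$intensities),
            fmt6(profile$sigmas))
  else sprintf("%s %s", fmt6(profile$offsets_ppm), fmt6(profile$intensities))
  writeLines(c(hdr, body), path)
  invisible(path)
}

fmt6 <- function(x) sprintf("%.6g", x)

config_template <- function() list(
  format_version = 1L,
  acquisition = list(larmor_MHz = NULL, T_sat = NULL, b1_fields = NULL,
                     b1_frac_sigma = 0, b1_grid_points = 11L),
  fit = list(method = "baldwin", share_kinetics = TRUE, mc_iterations = 0L,
             seed = 1L),
  profiles = list(),
  output_dir = "results",
  offsets_relative_hz = FALSE)

#' Read and validate a project configuration
#'
#' The configuration is one YAML file (schema version 1) holding the
#' acquisition constants, fit settings, the file manifest binding each
#' profile file to its residue and RF field, and the output directory.
#' Required keys are `acquisition` (`larmor_MHz`, `T_sat`, `b1_fields`) and
#' `profiles`; missing keys are enumerated in one message; unknown keys are
#' rejected with a nearest-match suggestion. Manifest B1 values must be a
#' subset of `acquisition$b1_fields`.
#'
#' @param path YAML configuration file.
#' @return list of class `cest_config` with elements `acquisition`
#'   (an [acquisition()]), `fit` (a [fit_spec()]), `manifest` (data.frame
#'   `file`, `residue`, `b1_Hz`), `output_dir`, `offsets_relative_hz`,
#'   `format_version`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  tmpl <- config_template()
  check_keys(names(raw), names(tmpl), "top-level")
  missing <- character(0)
  if (is.null(raw$acquisition)) missing <- c(missing, "acquisition")
  else {
    check_keys(names(raw$acquisition), names(tmpl$acquisition), "acquisition")
    for (k in c("larmor_MHz", "T_sat", "b1_fields"))
      if (is.null(raw$acquisition[[k]]))
        missing <- c(missing, paste0("acquisition$", k))
  }
  if (is.null(raw$profiles) || !length(raw$profiles))
    missing <- c(missing, "profiles (file manifest)")
  if (length(missing))
    stop("config is missing required keys: ", paste(missing, collapse = ", "))
  if (!is.null(raw$fit)) check_keys(names(raw$fit), names(tmpl$fit), "fit")

  acq_in <- modifyList(tmpl$acquisition, raw$acquisition)
  acq <- acquisition(acq_in$larmor_MHz, acq_in$T_sat,
                     unlist(acq_in$b1_fields),
                     acq_in$b1_frac_sigma, acq_in$b1_grid_points)
  fit_in <- modifyList(tmpl$fit, if (is.null(raw$fit)) list() else raw$fit)
  spec <- fit_spec(method = fit_in$method,
                   share_kinetics = fit_in$share_kinetics,
                   mc_iterations = fit_in$mc_iterations, seed = fit_in$seed)
  base <- dirname(normalizePath(path))
  manifest <- do.call(rbind, lapply(seq_along(raw$profiles), function(i) {
    e <- raw$profiles[[i]]
    check_keys(names(e), c("file", "residue", "b1_Hz"),
               sprintf("profiles[%d]", i))
    if (is.null(e$file) || is.null(e$residue) || is.null(e$b1_Hz))
      stop(sprintf("profiles[%d] needs file, residue and b1_Hz", i))
    # manifest entries are interpreted relative to the config file, so a
    # project directory is relocatable as a unit
    f <- if (startsWith(e$file, "/")) e$file else file.path(base, e$file)
    data.frame(file = f, residue = as.character(e$residue),
               b1_Hz = as.numeric(e$b1_Hz))
  }))
  if (!all(manifest$b1_Hz %in% acq$b1_fields))
    stop("manifest B1 values must be a subset of acquisition$b1_fields")
  structure(list(
    format_version = if (is.null(raw$format_version)) 1L
                     else as.integer(raw$format_version),
    acquisition = acq, fit = spec, manifest = manifest,
    output_dir = if (is.null(raw$output_dir)) tmpl$output_dir
                 else raw$output_dir,
    offsets_relative_hz = isTRUE(raw$offsets_relative_hz)
  ), class = "cest_config")
}

check_keys <- function(got, allowed, where) {
  unknown <- setdiff(got, allowed)
  if (length(unknown)) {
    hints <- vapply(unknown, function(u) {
      d <- utils::adist(u, allowed)
      if (min(d) <= 3) sprintf(" (did you mean '%s'?)", allowed[which.min(d)])
      else ""
    }, character(1))
    stop(sprintf("unknown %s config key(s): %s", where,
                 paste0("'", unknown, "'", hints, collapse = ", ")),
         call. = FALSE)
  }
}

#' Save a project configuration
#'
#' Canonical YAML serialization; [read_config()] of the saved file
#' reproduces every field, and the file is the input of [config_hash()].
#' @param config a `cest_config` (from [read_config()] or built in code).
#' @param path output YAML file.
#' @export
save_config <- function(config, path) {
  acq <- config$acquisition
  out <- list(
    format_version = config$format_version,
    acquisition = list(larmor_MHz = acq$larmor_MHz, T_sat = acq$T_sat,
                       b1_fields = acq$b1_fields,
                       b1_frac_sigma = acq$b1_frac_sigma,
                       b1_grid_points = acq$b1_grid_points),
    fit = list(method = config$fit$method,
               share_kinetics = config$fit$share_kinetics,
               mc_iterations = config$fit$mc_iterations,
               seed = config$fit$seed),
    profiles = lapply(seq_len(nrow(config$manifest)), function(i)
      list(file = config$manifest$file[i],
           residue = config$manifest$residue[i],
           b1_Hz = config$manifest$b1_Hz[i])),
    output_dir = config$output_dir,
    offsets_relative_hz = config$offsets_relative_hz)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Hash of the semantic content of a configuration
#'
#' MD5 of a canonical serialization of every field that influences the
#' fitted numbers: acquisition constants, fit settings, the manifest
#' bindings (file basenames, residues, fields) and the offset convention.
#' Storage locations (directories, `output_dir`) are excluded, so moving a
#' project or redirecting its output does not change the hash.
#' @param config a `cest_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  acq <- config$acquisition
  sem <- list(
    format_version = config$format_version,
    acquisition = acq[c("larmor_MHz", "T_sat", "b1_fields", "b1_frac_sigma",
                        "b1_grid_points")],
    fit = config$fit[c("method", "share_kinetics", "mc_iterations", "seed")],
    manifest = list(file = basename(config$manifest$file),
                    residue = config$manifest$residue,
                    b1_Hz = config$manifest$b1_Hz),
    offsets_relative_hz = config$offsets_relative_hz)
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(sem, tf, precision = 15)
  unname(tools::md5sum(tf))
}

#' Write a fit report
#'
#' A tab-delimited table of global and per-residue parameters with
#' uncertainties, preceded by comment lines carrying the method, reduced
#' chi-square, problem size and (optionally) the configuration hash.
#' Regenerating the report from the same fit result is byte-identical.
#'
#' @param result a [joint_fit()] result.
#' @param path output file.
#' @param config_hash optional hash string from [config_hash()].
#' @export
write_report <- function(result, path, config_hash = NULL) {
  hdr <- c("# cestfit fit report",
           sprintf("# method: %s", result$method),
           sprintf("# reduced_chisq: %s", fmt6(result$red_chisq)),
           sprintf("# n_data: %d", result$n_data),
           sprintf("# n_params: %d", result$n_params))
  if (!is.null(config_hash))
    hdr <- c(hdr, sprintf("# config_hash: %s", config_hash))
  if (length(result$flags))
    hdr <- c(hdr, sprintf("# flag: %s", result$flags))
  fmt_row <- function(scope, residue, param, value, se)
    sprintf("%s\t%s\t%s\t%s\t%s", scope, residue, param, fmt6(value),
            ifelse(is.na(se), "NA", fmt6(se)))
  lines <- c(hdr, "scope\tresidue\tparameter\tvalue\tstderr")
  g <- result$global
  if (nrow(g))
    lines <- c(lines, fmt_row("global", "-", g$param, g$value, g$se))
  pr <- result$per_residue
  if (nrow(pr))
    lines <- c(lines, fmt_row("residue", pr$residue, pr$param, pr$value,
                              pr$se))
  if (!is.null(result$mc))
    lines <- c(lines, sprintf("mc\t-\t%s\t%s\tNA", result$mc$param,
                              fmt6(result$mc$mc_sd)))
  writeLines(lines, path)
  invisible(path)
}

#' Write observed and fitted curves
#'
#' One file per (residue, field): columns `offset_ppm I_obs sigma I_fit`
#' (the sigma column is dropped when no uncertainties are attached).
#'
#' @param result a [joint_fit()] result.
#' @param dir output directory (created if needed).
#' @return character vector of the files written.
#' @export
write_curves <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(result$curves, function(cv) {
    path <- file.path(dir, sprintf("%s_%gHz_fit.txt", cv$residue[1],
                                   cv$b1_Hz[1]))
    has_sig <- !all(is.na(cv$sigma))
    hdr <- sprintf("# residue %s, B1 %g Hz: offset_ppm I_obs%s I_fit",
                   cv$residue[1], cv$b1_Hz[1], if (has_sig) " sigma" else "")
    body <- if (has_sig)
      sprintf("%s %s %s %s", fmt6(cv$offset_ppm), fmt6(cv$I_obs),
              fmt6(cv$sigma), fmt6(cv$I_fit))
    else sprintf("%s %s %s", fmt6(cv$offset_ppm), fmt6(cv$I_obs),
                 fmt6(cv$I_fit))
    writeLines(c(hdr, body), path)
    path
  }, character(1))
  invisible(paths)
}
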