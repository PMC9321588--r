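#' Write a compartment model to a directory of text files
#'
#' Mirrors the classic CFD-to-solver text-file handoff: the convective and
#' turbulent flux matrices as MatrixMarket coordinate files (`conv.mtx`,
#' `turb.mtx`, kg/s, 1-based indices) and the compartment table as
#' `compartments.csv` (index, volume m^3, center coordinates, residence
#' time s) with unit annotations in comment headers. A `manifest.yaml`
#' records the layout, geometry and file checksums.
#'
#' @param model A `compartment_model`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_flux_matrices <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(model$phi_conv, "generalMatrix"), file.path(dir, "conv.mtx"))
  Matrix::writeMM(methods::as(model$phi_turb, "generalMatrix"), file.path(dir, "turb.mtx"))
  tab <- compartment_table(model)
  csv <- file.path(dir, "compartments.csv")
  con <- file(csv, "w")
  writeLines(c("# compartment table: volume [m^3], y/r [m], theta [rad], tau [s]",
               sprintf("# layout %s, density %g kg/m^3", model$layout$code,
                       model$geometry$density)), con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  geo <- model$geometry
  manifest <- list(
    layout = model$layout$code,
    divisions = as.integer(model$layout$divisions),
    n_compartments = model$n_compartments,
    geometry = list(diameter = geo$diameter, liquid_height = geo$liquid_height,
                    impeller_diameter = geo$impeller_diameter,
                    clearance = geo$clearance,
                    impeller_spacing = geo$impeller_spacing,
                    n_impellers = geo$n_impellers,
                    stir_rpm = geo$stir_rpm, density = geo$density),
    units = list(flux = "kg/s", volume = "m^3", tau = "s"),
    checksums = as.list(tools::md5sum(c(file.path(dir, "conv.mtx"),
                                        file.path(dir, "turb.mtx"), csv)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a compartment model from a directory of text files
#'
#' Reconstructs the model written by [write_flux_matrices()] (or produced
#' externally in the same schema), recomputing residence times and
#' destination tables, and runs the invariant checks: positive diagonals
#' are rejected, and non-conservative columns beyond
#' `1e-9 * max(|entry|)` raise a warning with the worst imbalance.
#'
#' @param dir Directory holding `conv.mtx`, `turb.mtx`, `compartments.csv`
#'   and `manifest.yaml`.
#' @return A `compartment_model`.
#' @export
read_flux_matrices <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  phi_c <- methods::as(Matrix::readMM(file.path(dir, "conv.mtx")), "CsparseMatrix")
  phi_t <- methods::as(Matrix::readMM(file.path(dir, "turb.mtx")), "CsparseMatrix")
  tab <- utils::read.csv(file.path(dir, "compartments.csv"), comment.char = "#")
  nc <- nrow(tab)
  if (any(dim(phi_c) != nc) || any(dim(phi_t) != nc)) {
    abort_lagcm("matrix dimensions do not match the compartment table",
                class = "lagcm_io_error")
  }
  geo <- do.call(tank_geometry, manifest$geometry)
  model <- compartment_model_from_matrices(
    phi_c, phi_t, volumes = tab$volume, geometry = geo,
    centers = tibble::tibble(compartment = tab$compartment,
                             y = tab$y, r = tab$r, theta = tab$theta),
    code = manifest$layout)
  model$layout$divisions <- as.integer(manifest$divisions)
  closure <- max(abs(Matrix::colSums(model$phi)))
  scale <- max(abs(model$phi@x), 0)
  if (scale > 0 && closure > 1e-9 * scale) {
    warning(sprintf("flux matrices are non-conservative: worst column imbalance %.3g kg/s",
                    closure))
  }
  model
}

#' Write / read a flow field as flat CSV tables
#'
#' Plain-text schema for exchanging gridded flow fields: `cells.csv`
#' (cell, ia, ir, ik, y, r, theta, volume) and `faces.csv` (face, cell_a,
#' cell_b, orientation, area, flux, kt), plus `geometry.yaml`. Externally
#' produced (e.g. CFD-exported) fields in this schema can be ingested with
#' [read_flow_field()].
#'
#' @param field A `flow_field`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_flow_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(field$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(field$faces, file.path(dir, "faces.csv"), row.names = FALSE)
  geo <- field$geometry
  yaml::write_yaml(list(
    dims = as.integer(field$dims),
    geometry = list(diameter = geo$diameter, liquid_height = geo$liquid_height,
                    impeller_diameter = geo$impeller_diameter,
                    clearance = geo$clearance,
                    impeller_spacing = geo$impeller_spacing,
                    n_impellers = geo$n_impellers,
                    stir_rpm = geo$stir_rpm, density = geo$density),
    units = list(volume = "m^3", flux = "kg/s", area = "m^2", kt = "m^2/s^2")
  ), file.path(dir, "field.yaml"))
  invisible(dir)
}

#' @rdname write_flow_field
#' @param dir Directory holding `cells.csv`, `faces.csv`, `field.yaml`.
#' @export
read_flow_field <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "field.yaml"))
  structure(
    list(geometry = do.call(tank_geometry, meta$geometry),
         dims = as.integer(meta$dims),
         cells = tibble::as_tibble(utils::read.csv(file.path(dir, "cells.csv"))),
         faces = tibble::as_tibble(utils::read.csv(file.path(dir, "faces.csv")))),
    class = "flow_field"
  )
}

#' Load a simulation configuration from a YAML file
#'
#' The file may contain any subset of the [sim_config()] arguments (the
#' rest take the documented defaults: `n_parcels = 1000`,
#' `rel_tol = 0.001`, `dt_max = 0.03 s`) plus an optional nested `feed`
#' block with [feed_spec()] arguments. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  feed_args <- raw$feed %||% list()
  raw$feed <- NULL
  bad <- setdiff(names(raw), setdiff(names(formals(sim_config)), "feed"))
  bad_feed <- setdiff(names(feed_args), names(formals(feed_spec)))
  if (length(bad) || length(bad_feed)) {
    abort_lagcm(sprintf("unknown configuration keys: %s",
                        paste(c(bad, paste0("feed.", bad_feed)), collapse = ", ")),
                class = "lagcm_config_error")
  }
  for (nm in c("injection", "probe")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (is.data.frame(feed_args$profile)) feed_args$profile <- feed_args$profile
  raw$feed <- do.call(feed_spec, feed_args)
  do.call(sim_config, raw)
}

#' Save a simulation configuration as YAML
#'
#' @param config A `sim_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$feed <- unclass(x$feed)
  if (!is.null(x$feed$profile)) {
    abort_lagcm("configs with feed profile functions cannot be serialized; embed the breakpoint table instead",
                class = "lagcm_config_error")
  }
  x$feed$profile <- NULL
  x$injection <- as.list(x$injection)
  x$probe <- as.list(x$probe)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' @param config A `sim_config`.
#' @param model A `compartment_model`.
#' @param inputs Named character vector of input file paths to checksum.
#' @return A list (config hash, seed, layout code, package version, input
#'   checksums, timestamp) suitable for [yaml::write_yaml()].
#' @export
run_manifest <- function(config, model, inputs = character(0)) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = config$seed,
    layout = model$layout$code,
    package_version = as.character(utils::packageVersion("lagcm")),
    input_checksums = as.list(tools::md5sum(inputs)),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}
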