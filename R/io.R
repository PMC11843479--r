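#' Write / read a complex B-scan stack container
#'
#' Stacks are stored as a single self-describing, endianness-portable
#' serialized container holding the complex data cube together with the
#' acquisition metadata (`k0`, `dk`, `dx_um`, `dz_um`, frame times and the
#' full system description). `read_stack` validates the schema and refuses
#' files with missing metadata, so round trips are bit-exact.
#'
#' @param stack An [oct_stack].
#' @param path File path (conventionally `.rds`).
#' @return `write_stack` returns `path` invisibly; `read_stack` returns the
#'   [oct_stack].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "oct_stack"))
  sys <- stack$system
  obj <- list(format = "oct-stack", version = 1L,
              k0 = sys$k0, dk = sys$dk,
              dx_um = sys$dx_um, dz_um = sys$dz_um,
              times = stack$times,
              system = unclass(sys)[c("lambda0_um", "axial_fwhm_um",
                                      "lateral_fwhm_um", "n_k", "n_x",
                                      "dx_um", "dz_um", "guard_frac")],
              data = stack$data)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  obj <- readRDS(path)
  required <- c("format", "k0", "dk", "dx_um", "dz_um", "system", "data")
  missing <- setdiff(required, names(obj))
  if (!is.list(obj) || length(missing)) {
    stop("not a valid stack container: missing ",
         paste(missing, collapse = ", "))
  }
  if (!identical(obj$format, "oct-stack")) {
    stop("not a valid stack container: unknown format")
  }
  system <- do.call(oct_system, obj$system)
  oct_stack(obj$data, system, obj$times)
}

#' Write / read a scatterer field as CSV
#'
#' Plain-text interchange for scatterer fields: columns `x_um`, `z_um`,
#' `r`.
#'
#' @param field A [scatterer_field].
#' @param path CSV file path.
#' @return `write_field_csv` returns `path` invisibly; `read_field_csv` the
#'   [scatterer_field].
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "scatterer_field"))
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  required <- c("x_um", "z_um", "r")
  if (!all(required %in% names(df))) {
    stop("field CSV must have columns x_um, z_um, r")
  }
  scatterer_field(df$x_um, df$z_um, df$r)
}

#' Write / read an OCT system configuration as YAML
#'
#' Persists the constructor parameters of an [oct_system]; derived
#' quantities (k grid, spectrum, beam radius) are rebuilt on read.
#'
#' @param system An [oct_system].
#' @param path YAML file path.
#' @return `write_system_yaml` returns `path` invisibly; `read_system_yaml`
#'   the [oct_system].
#' @export
write_system_yaml <- function(system, path) {
  stopifnot(inherits(system, "oct_system"))
  yaml::write_yaml(unclass(system)[c("lambda0_um", "axial_fwhm_um",
                                     "lateral_fwhm_um", "n_k", "n_x",
                                     "dx_um", "dz_um", "guard_frac")],
                   path)
  invisible(path)
}

#' @rdname write_system_yaml
#' @export
read_system_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("lambda0_um", "axial_fwhm_um", "lateral_fwhm_um", "n_k",
                "n_x", "dx_um", "dz_um")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("system config missing fields: ", paste(missing, collapse = ", "))
  }
  do.call(oct_system, cfg)
}

#' Write phase-stability metrics as CSV
#'
#' Emits per-pixel temporal statistics (`pixel`, `sigma_t_nm`, optionally
#' `snr_limit_nm`) or a per-frame spatial-accuracy table (`frame`,
#' `sigma_s_nm`).
#'
#' @param x A numeric vector of per-pixel `sigma_t` (nm) named by pixel
#'   index, or a `presir_sweep` object for the per-frame table.
#' @param path CSV file path.
#' @param snr_limit_nm Optional matching vector of SNR-limited
#'   sensitivities.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path, snr_limit_nm = NULL) {
  if (inherits(x, "presir_sweep")) {
    df <- data.frame(frame = seq_along(x$sigma_s_nm) - 1L,
                     displacement_um = x$displacement_um,
                     sigma_s_nm = x$sigma_s_nm)
  } else {
    df <- data.frame(pixel = if (is.null(names(x))) seq_along(x) else names(x),
                     sigma_t_nm = as.numeric(x))
    if (!is.null(snr_limit_nm)) df$snr_limit_nm <- snr_limit_nm
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
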