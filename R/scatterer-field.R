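#' Point-scatterer field
#'
#' A discrete scene of point scatterers, each with a lateral position
#' `x_um`, an axial OPL position `z_um`, and a real non-negative electric
#' field reflectivity `r`. The field carries the rectangular extent it was
#' generated on and (when generated against a system) the guarded axial span
#' translations must respect.
#'
#' @param x_um,z_um,r Equal-length numeric vectors of positions (um) and
#'   reflectivities.
#' @param x_range_um,z_range_um Length-2 extent bounds; default to the data
#'   range.
#' @param z_limits_um Optional guarded axial span `c(lo, hi)` the field (and
#'   any translated version of it) must stay inside.
#' @return A `scatterer_field`: a data frame with columns `x_um`, `z_um`,
#'   `r`, plus extent attributes.
#' @export
scatterer_field <- function(x_um, z_um, r = rep(1, length(x_um)),
                            x_range_um = if (length(x_um)) range(x_um) else c(0, 0),
                            z_range_um = if (length(z_um)) range(z_um) else c(0, 0),
                            z_limits_um = NULL) {
  stopifnot(length(x_um) == length(z_um), length(r) == length(x_um))
  if (length(r) && any(r < 0)) stop("reflectivities must be >= 0")
  if (length(x_um)) {
    if (any(x_um < x_range_um[1] | x_um > x_range_um[2]) ||
        any(z_um < z_range_um[1] | z_um > z_range_um[2])) {
      stop("scatterers must lie inside the stated extent")
    }
  }
  if (!is.null(z_limits_um) &&
      (z_range_um[1] < z_limits_um[1] || z_range_um[2] > z_limits_um[2])) {
    stop("axial extent outside the guarded span")
  }
  structure(
    data.frame(x_um = as.numeric(x_um), z_um = as.numeric(z_um),
               r = as.numeric(r)),
    x_range_um = as.numeric(x_range_um),
    z_range_um = as.numeric(z_range_um),
    z_limits_um = if (is.null(z_limits_um)) NULL else as.numeric(z_limits_um),
    class = c("scatterer_field", "data.frame")
  )
}

#' Generate a random fully-developed-speckle scatterer field
#'
#' Draws point scatterers with equal reflectivity at uniform i.i.d. positions
#' inside a rectangular extent. The scatterer count is
#' `round(density * area / L_c^2)` where `L_c` is the coherence length used
#' for density bookkeeping (the axial intensity FWHM), so the default density
#' of 5 per coherence length produces fully developed speckle.
#'
#' @param system An [oct_system]; supplies the coherence length, the image
#'   width (default lateral extent) and the guarded axial span (default and
#'   bound for the axial extent).
#' @param x_range_um Lateral extent `c(lo, hi)`; defaults to the full image
#'   width `c(0, n_x * dx_um)`.
#' @param z_range_um Axial extent `c(lo, hi)` in OPL um; defaults to the
#'   guarded span, and must lie inside it.
#' @param density_per_coherence_length Mean scatterer count per coherence
#'   length squared of extent area; must be positive.
#' @param reflectivity Common electric-field reflectivity; must be positive.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return A [scatterer_field].
#' @examples
#' sys <- oct_system(n_k = 256, n_x = 48)
#' f <- generate_scatterer_field(sys, seed = 1)
#' nrow(f)   # round(5 * area / axial_fwhm^2)
#' @export
generate_scatterer_field <- function(system,
                                     x_range_um = NULL,
                                     z_range_um = NULL,
                                     density_per_coherence_length = 5,
                                     reflectivity = 1,
                                     seed = 1L) {
  stopifnot(inherits(system, "oct_system"))
  if (density_per_coherence_length <= 0) stop("density must be positive")
  if (reflectivity <= 0) stop("reflectivity must be positive")
  span <- guarded_axial_span(system)
  if (is.null(x_range_um)) x_range_um <- c(0, system$n_x * system$dx_um)
  if (is.null(z_range_um)) z_range_um <- span
  if (diff(x_range_um) <= 0 || diff(z_range_um) <= 0) {
    stop("extent must be positive in both axes")
  }
  if (z_range_um[1] < span[1] || z_range_um[2] > span[2]) {
    stop("axial extent outside the guarded span")
  }
  lc <- system$coherence_length_um
  area <- diff(x_range_um) * diff(z_range_um)
  n <- as.integer(round(density_per_coherence_length * area / lc^2))
  if (n < 1L) stop("extent too small: zero scatterers at this density")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  x <- stats::runif(n, x_range_um[1], x_range_um[2])
  z <- stats::runif(n, z_range_um[1], z_range_um[2])
  scatterer_field(x, z, rep(reflectivity, n),
                  x_range_um = x_range_um, z_range_um = z_range_um,
                  z_limits_um = span)
}

#' Translate a scatterer field
#'
#' Shifts every scatterer by `(dx_um, dz_um)`; reflectivities are unchanged.
#' This is the forward model's notion of bulk sample motion: the coordinates
#' of all scatterers change while their relative arrangement is preserved.
#'
#' @param field A [scatterer_field].
#' @param dx_um,dz_um Lateral and axial (OPL) translation in um.
#' @return The translated [scatterer_field].
#' @export
translate_field <- function(field, dx_um = 0, dz_um = 0) {
  stopifnot(inherits(field, "scatterer_field"))
  zr <- attr(field, "z_range_um") + dz_um
  zl <- attr(field, "z_limits_um")
  if (!is.null(zl) && (zr[1] < zl[1] || zr[2] > zl[2])) {
    stop("translation pushes the field outside the guarded axial span")
  }
  scatterer_field(field$x_um + dx_um, field$z_um + dz_um, field$r,
                  x_range_um = attr(field, "x_range_um") + dx_um,
                  z_range_um = zr, z_limits_um = zl)
}

#' @export
print.scatterer_field <- function(x, ...) {
  xr <- attr(x, "x_range_um"); zr <- attr(x, "z_range_um")
  cat(sprintf("<scatterer_field> %d scatterers, x in [%.3g, %.3g] um, z in [%.3g, %.3g] um\n",
              nrow(x), xr[1], xr[2], zr[1], zr[2]))
  invisible(x)
}

# save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
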