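#' Wavelength grid for far-UV CD spectra
#'
#' A uniformly spaced, strictly descending wavelength axis. Far-UV CD data
#' are conventionally tabulated from long to short wavelength, so grids are
#' stored descending (the default 240 -> 190 nm in 1 nm steps gives 51
#' points); all arithmetic elsewhere in the package is order-agnostic.
#'
#' @param start_nm first (longest) wavelength in nm.
#' @param end_nm last (shortest) wavelength in nm; must be below `start_nm`.
#' @param step_nm positive spacing in nm; `(start_nm - end_nm)` must be an
#'   integer multiple of it.
#' @return An object of class `wavelength_grid` with elements `start_nm`,
#'   `end_nm`, `step_nm` and the enumerated `wavelengths`.
#' @examples
#' g <- wavelength_grid()
#' length(g)  # 51
#' @export
wavelength_grid <- function(start_nm = 240, end_nm = 190, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm),
            length(start_nm) == 1, length(end_nm) == 1, length(step_nm) == 1)
  if (step_nm <= 0) stop("step_nm must be positive")
  if (start_nm <= end_nm)
    stop("grids are stored descending: start_nm must exceed end_nm")
  npts <- (start_nm - end_nm) / step_nm + 1
  if (abs(npts - round(npts)) > 1e-8)
    stop(sprintf(
      "(start_nm - end_nm) must be an integer multiple of step_nm; %g - %g at step %g gives %.6g points",
      start_nm, end_nm, step_nm, npts))
  structure(
    list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm,
         wavelengths = seq(start_nm, end_nm, by = -step_nm)),
    class = "wavelength_grid")
}

#' @export
length.wavelength_grid <- function(x) length(x$wavelengths)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g -> %g nm, step %g nm (%d points)\n",
              x$start_nm, x$end_nm, x$step_nm, length(x)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelengths) == length(b$wavelengths) &&
    max(abs(a$wavelengths - b$wavelengths)) <= tol
}

#' A circular dichroism spectrum
#'
#' Holds delta-epsilon per molar residue (mol^-1 dm^3 cm^-1 per residue)
#' sampled on a [wavelength_grid()]. Per-residue normalisation makes
#' proteins of different lengths directly comparable and is assumed
#' throughout the package; conversion from instrument units is upstream.
#'
#' @param values numeric vector of delta-epsilon values, one per grid point,
#'   all finite.
#' @param grid a [wavelength_grid()].
#' @param label free-text label (e.g. protein name).
#' @param temperature_C optional temperature in degrees Celsius.
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(values, grid = wavelength_grid(), label = "",
                        temperature_C = NULL) {
  stopifnot(inherits(grid, "wavelength_grid"))
  values <- as.numeric(values)
  if (length(values) != length(grid))
    stop(sprintf("spectrum has %d values but the grid has %d points",
                 length(values), length(grid)))
  if (!all(is.finite(values)))
    stop("spectrum values must all be finite")
  if (!is.null(temperature_C)) stopifnot(is.numeric(temperature_C))
  structure(
    list(values = values, grid = grid, label = as.character(label),
         temperature_C = temperature_C),
    class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  tc <- if (is.null(x$temperature_C)) "" else sprintf(" @ %g C", x$temperature_C)
  cat(sprintf("<cd_spectrum> '%s'%s on %g-%g nm (%d points), range [%.3g, %.3g]\n",
              x$label, tc, x$grid$start_nm, x$grid$end_nm,
              length(x$grid), min(x$values), max(x$values)))
  invisible(x)
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation onto `grid`. Extrapolation is refused: the source
#' spectrum must span every target wavelength. No smoothing is applied.
#'
#' @param spectrum a [cd_spectrum()].
#' @param grid the target [wavelength_grid()].
#' @return A [cd_spectrum()] on `grid` with the same label and temperature.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "cd_spectrum"), inherits(grid, "wavelength_grid"))
  src <- spectrum$grid$wavelengths
  tgt <- grid$wavelengths
  if (same_grid(spectrum$grid, grid))
    return(cd_spectrum(spectrum$values, grid, spectrum$label,
                       spectrum$temperature_C))
  eps <- 1e-9
  missing <- tgt[tgt > max(src) + eps | tgt < min(src) - eps]
  if (length(missing))
    stop(sprintf(
      "cannot resample without extrapolating: spectrum spans %g-%g nm but the target grid needs %s nm",
      max(src), min(src), paste(missing, collapse = ", ")))
  vals <- stats::approx(src, spectrum$values, xout = tgt)$y
  cd_spectrum(vals, grid, spectrum$label, spectrum$temperature_C)
}

#' Normalised root-mean-square deviation between two spectra
#'
#' The goodness-of-fit statistic used throughout:
#' `sqrt(sum((obs - fit)^2) / sum(obs^2))` over the shared wavelength grid.
#' It is 0 iff the spectra are identical and is invariant under common
#' rescaling of both spectra. Note that other normalisations of the RMSD
#' (e.g. by the observed range) exist in the literature; this package uses
#' the sum-of-squares form above, under which fits below about 0.03 are
#' typically regarded as good for far-UV CD.
#'
#' @param observed,fitted [cd_spectrum()] objects on identical grids, or
#'   bare numeric vectors of equal length.
#' @return A non-negative scalar.
#' @export
nrmsd <- function(observed, fitted) {
  if (inherits(observed, "cd_spectrum") && inherits(fitted, "cd_spectrum")) {
    if (!same_grid(observed$grid, fitted$grid))
      stop("wavelength grids differ between observed and fitted spectra")
    o <- observed$values
    f <- fitted$values
  } else {
    o <- as.numeric(if (inherits(observed, "cd_spectrum")) observed$values else observed)
    f <- as.numeric(if (inherits(fitted, "cd_spectrum")) fitted$values else fitted)
    if (length(o) != length(f)) stop("observed and fitted lengths differ")
  }
  denom <- sum(o^2)
  if (denom == 0) stop("observed spectrum is identically zero")
  sqrt(sum((o - f)^2) / denom)
}
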