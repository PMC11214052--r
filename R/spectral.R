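#' Wavelength grid for spectral sampling
#'
#' Creates a strictly increasing wavelength grid (nm).  Band shapes in this
#' package are defined on the energy (wavenumber) scale, the natural scale
#' for retinal-protein absorption bands, and sampled onto this grid.
#'
#' @param from,to grid limits in nm (default 350--700 nm, the detection
#'   window of the flash-photolysis experiments this package targets).
#' @param n number of points (default 176, i.e. 2 nm spacing).
#' @return object of class `"wavelength_grid"`: a list with `wavelength`
#'   (nm) and `wavenumber` (cm^-1, decreasing).
#' @export
wavelength_grid <- function(from = 350, to = 700, n = 176) {
  stopifnot(is.numeric(from), is.numeric(to), from < to, n >= 30)
  wl <- seq(from, to, length.out = n)
  structure(
    list(wavelength = wl, wavenumber = nm_to_wavenumber(wl)),
    class = "wavelength_grid"
  )
}

#' Convert wavelength (nm) to wavenumber (cm^-1) and back
#'
#' The conversion is `nu = 1e7 / lambda`; it is an involution, so the same
#' formula converts in either direction.
#'
#' @param x wavelengths in nm (or wavenumbers in cm^-1).
#' @return wavenumbers in cm^-1 (or wavelengths in nm).
#' @export
nm_to_wavenumber <- function(x) {
  stopifnot(all(x > 0))
  1e7 / x
}

#' @rdname nm_to_wavenumber
#' @export
wavenumber_to_nm <- nm_to_wavenumber

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d points, %.0f-%.0f nm (%.0f-%.0f cm^-1)\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$wavelength) == length(b$wavelength) &&
    all(abs(a$wavelength - b$wavelength) < 1e-9)
}

#' Skewed-Gaussian spectral form on the wavenumber scale
#'
#' Builds one spectral form (an intermediate-state absorption band) as a
#' Fraser-Suzuki skewed Gaussian in wavenumber, sampled on a wavelength
#' grid.  At `skew = 0` the band is an exact Gaussian with FWHM `width`;
#' nonzero `skew` puts a heavier tail on one side while keeping the maximum
#' at `peak_wavenumber`.
#'
#' @param name form label, conventionally one of `"K-like"`, `"L-like"`,
#'   `"M"`, `"R"` (extensible, e.g. `"L'"` for blue-shifted early forms).
#' @param peak_wavenumber band maximum position, cm^-1; must lie inside the
#'   grid's wavenumber range.
#' @param width full width at half maximum, cm^-1 (> 0).
#' @param skew dimensionless asymmetry (0 = symmetric).
#' @param amplitude peak absorbance, arbitrary units (> 0).
#' @param grid a [wavelength_grid()].
#' @return object of class `"spectral_form"` with fields `name`,
#'   `absorbance` (nonnegative, one value per grid point), `peak_wavenumber`,
#'   `width`, `skew`, `amplitude`, `grid`.
#' @export
make_spectral_form <- function(name, peak_wavenumber, width, skew = 0,
                               amplitude = 1, grid = wavelength_grid()) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (!is.finite(width) || width <= 0) stop("`width` must be positive")
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("`amplitude` must be positive")
  }
  nu <- grid$wavenumber
  if (peak_wavenumber < min(nu) || peak_wavenumber > max(nu)) {
    stop(sprintf(
      "peak_wavenumber %.0f cm^-1 outside grid range [%.0f, %.0f]: basis unusable",
      peak_wavenumber, min(nu), max(nu)))
  }
  absorbance <- fraser_suzuki(nu, peak_wavenumber, width, skew) * amplitude
  structure(
    list(name = name, absorbance = absorbance,
         peak_wavenumber = peak_wavenumber, width = width, skew = skew,
         amplitude = amplitude, grid = grid),
    class = "spectral_form"
  )
}

# Fraser-Suzuki profile, unit height at nu0; reduces to a Gaussian at b = 0.
fraser_suzuki <- function(nu, nu0, fwhm, b) {
  z <- 2 * (nu - nu0) / fwhm
  if (abs(b) < 1e-12) {
    return(exp(-log(2) * z^2))
  }
  arg <- 1 + b * z
  out <- numeric(length(nu))
  ok <- arg > 0
  out[ok] <- exp(-log(2) * (log(arg[ok]) / b)^2)
  out
}

#' @export
print.spectral_form <- function(x, ...) {
  cat(sprintf(
    "<spectral_form> %s: peak %.0f cm^-1 (%.1f nm), FWHM %.0f cm^-1, skew %.2f\n",
    x$name, x$peak_wavenumber, wavenumber_to_nm(x$peak_wavenumber),
    x$width, x$skew))
  invisible(x)
}

#' Assemble a spectral basis matrix
#'
#' Stacks spectral forms into the basis matrix `E` (wavelengths x forms)
#' whose product with concentration profiles reconstructs the data, and
#' whose product with eigenvector weights gives the amplitude b-spectra.
#'
#' @param forms list of [make_spectral_form()] objects on identical grids.
#' @return object of class `"spectral_basis"`: list with `E` (matrix, columns
#'   named by form), `forms`, `grid`, `condition` (2-norm condition number of
#'   `E`).  Rank-deficient bases trigger a warning.
#' @export
build_basis <- function(forms) {
  if (inherits(forms, "spectral_form")) forms <- list(forms)
  stopifnot(length(forms) >= 1, all(vapply(forms, inherits, TRUE,
                                           "spectral_form")))
  grid <- forms[[1]]$grid
  for (f in forms[-1]) {
    if (!same_grid(grid, f$grid)) stop("all forms must share one grid")
  }
  E <- vapply(forms, function(f) f$absorbance, numeric(length(grid$wavelength)))
  E <- matrix(E, ncol = length(forms),
              dimnames = list(NULL, vapply(forms, `[[`, "", "name")))
  sv <- svd(E, nu = 0, nv = 0)$d
  cond <- if (min(sv) < .Machine$double.eps * max(sv) * nrow(E)) Inf
          else max(sv) / min(sv)
  if (!is.finite(cond) || cond > 1e12) {
    warning(sprintf("rank-deficient spectral basis (condition number %.3g)",
                    cond))
  }
  structure(list(E = E, forms = forms, grid = grid, condition = cond),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> %d forms x %d wavelengths, condition %.3g\n",
              ncol(x$E), nrow(x$E), x$condition))
  cat("  forms:", paste(colnames(x$E), collapse = ", "), "\n")
  invisible(x)
}

#' Default spectral-form parameters
#'
#' Qualitative stand-ins for the four deconvolved forms of the GtACR1
#' photoreaction: a red-absorbing K-like band, a blue-shifted L-like band,
#' a strongly blue-shifted deprotonated M band, and the recovered R band
#' near the dark-state maximum.  Peak positions/widths are configuration,
#' not measured values.
#'
#' @return named list of parameter lists (`peak_nm`, `width`, `skew`,
#'   `amplitude`).
#' @export
default_form_params <- function() {
  list(
    "K-like" = list(peak_nm = 540, width = 3600, skew = 0.25, amplitude = 1.0),
    "L-like" = list(peak_nm = 480, width = 3800, skew = 0.25, amplitude = 0.95),
    "M"      = list(peak_nm = 400, width = 4200, skew = 0.20, amplitude = 0.85),
    "R"      = list(peak_nm = 515, width = 3600, skew = 0.25, amplitude = 1.0)
  )
}

#' Default four-form basis (K-like, L-like, M, R)
#'
#' @param grid a [wavelength_grid()].
#' @param params parameter list in the shape of [default_form_params()].
#' @return a [build_basis()] object.
#' @export
default_basis <- function(grid = wavelength_grid(),
                          params = default_form_params()) {
  forms <- lapply(names(params), function(nm) {
    p <- params[[nm]]
    make_spectral_form(nm, nm_to_wavenumber(p$peak_nm), p$width, p$skew,
                       p$amplitude, grid)
  })
  build_basis(forms)
}

#' Write a spectral basis as CSV with a JSON parameter sidecar
#'
#' @param basis a [build_basis()] object.
#' @param path CSV file path; a `.json` sidecar with the form parameters is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_basis_csv <- function(basis, path) {
  df <- data.frame(wavelength_nm = basis$grid$wavelength, basis$E,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- lapply(basis$forms, function(f) {
    list(name = f$name, peak_wavenumber = f$peak_wavenumber,
         width = f$width, skew = f$skew, amplitude = f$amplitude)
  })
  jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
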