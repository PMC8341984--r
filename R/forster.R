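#' Fluorescence or extinction spectrum
#'
#' A two-column spectrum: wavelengths (nm, strictly increasing) and
#' non-negative values — emission intensity in arbitrary units for a donor,
#' or molar extinction (M^-1 cm^-1) for an acceptor.
#'
#' @param wavelength wavelengths in nm, strictly increasing, length >= 2.
#' @param value non-negative intensities or extinction coefficients.
#' @return A data frame of class `fluor_spectrum`.
#' @export
fluor_spectrum <- function(wavelength, value) {
  if (length(wavelength) != length(value))
    stop("'wavelength' and 'value' must have equal length")
  if (length(wavelength) < 2L) stop("a spectrum needs at least 2 points")
  if (any(!is.finite(wavelength)) || is.unsorted(wavelength, strictly = TRUE))
    stop("'wavelength' must be finite and strictly increasing")
  if (any(!is.finite(value)) || any(value < 0))
    stop("'value' must be finite and non-negative")
  out <- data.frame(wavelength = wavelength, value = value)
  class(out) <- c("fluor_spectrum", "data.frame")
  out
}

#' Spectral overlap integral
#'
#' The donor-normalized Forster overlap
#' `J = integral F_D(l) eps_A(l) l^4 dl / integral F_D(l) dl`
#' with wavelengths in nm, so `J` carries units M^-1 cm^-1 nm^4. Both
#' spectra are linearly interpolated onto the union grid of their common
#' wavelength range and integrated by the trapezoidal rule. Normalization
#' by the donor area makes `J` invariant to rescaling the donor emission.
#'
#' @param donor_emission donor emission [fluor_spectrum()].
#' @param acceptor_extinction acceptor molar-extinction [fluor_spectrum()]
#'   (M^-1 cm^-1).
#' @return Overlap integral J in M^-1 cm^-1 nm^4.
#' @export
overlap_integral <- function(donor_emission, acceptor_extinction) {
  stopifnot(inherits(donor_emission, "fluor_spectrum"),
            inherits(acceptor_extinction, "fluor_spectrum"))
  lo <- max(min(donor_emission$wavelength), min(acceptor_extinction$wavelength))
  hi <- min(max(donor_emission$wavelength), max(acceptor_extinction$wavelength))
  if (lo >= hi)
    stop("donor and acceptor spectra have disjoint wavelength ranges")
  grid <- sort(unique(c(donor_emission$wavelength, acceptor_extinction$wavelength)))
  grid <- grid[grid >= lo & grid <= hi]
  fd <- stats::approx(donor_emission$wavelength, donor_emission$value,
                      xout = grid)$y
  ea <- stats::approx(acceptor_extinction$wavelength, acceptor_extinction$value,
                      xout = grid)$y
  denom <- pracma::trapz(donor_emission$wavelength, donor_emission$value)
  if (denom == 0) stop("donor emission spectrum integrates to zero")
  pracma::trapz(grid, fd * ea * grid^4) / denom
}

#' Photophysical parameters for the Forster radius
#'
#' @param kappa2 orientation factor, in `[0, 4]`; 2/3 is the dynamic
#'   isotropic average.
#' @param quantum_yield donor quantum yield in `(0, 1]`.
#' @param refractive_index medium refractive index; 1.4 is the usual
#'   cytoplasmic value.
#' @return List of class `forster_params`.
#' @export
forster_params <- function(kappa2 = 2 / 3, quantum_yield = 0.93,
                           refractive_index = 1.4) {
  if (kappa2 < 0 || kappa2 > 4) stop("'kappa2' must be in [0, 4]")
  if (quantum_yield <= 0 || quantum_yield > 1)
    stop("'quantum_yield' must be in (0, 1]")
  if (refractive_index <= 0) stop("'refractive_index' must be positive")
  structure(list(kappa2 = kappa2, quantum_yield = quantum_yield,
                 refractive_index = refractive_index),
            class = "forster_params")
}

#' Forster radius from the overlap integral
#'
#' `R0^6 = 8.79e-5 * kappa2 * n^-4 * QY * J` with `J` in M^-1 cm^-1 nm^4
#' gives `R0` in Angstrom. Doubling `J` scales `R0` by `2^(1/6)`.
#'
#' @param j overlap integral (M^-1 cm^-1 nm^4), `>= 0`.
#' @param params a [forster_params()].
#' @return Forster radius in Angstrom.
#' @export
forster_radius <- function(j, params = forster_params()) {
  stopifnot(inherits(params, "forster_params"))
  if (!is.numeric(j) || any(!is.finite(j)) || any(j < 0))
    stop("'j' must be finite and non-negative")
  (8.79e-5 * params$kappa2 * params$refractive_index^-4 *
     params$quantum_yield * j)^(1 / 6)
}

#' Molar extinction coefficient from a dilution series
#'
#' Beer-Lambert slope fit: absorbance against concentration with a fitted
#' intercept (guarding against baseline offset), slope divided by the path
#' length.
#'
#' @param concentration molar concentrations (>= 2 distinct values).
#' @param absorbance matching absorbance readings.
#' @param pathlength cuvette path length in cm.
#' @return List with `epsilon` (M^-1 cm^-1), its standard error `se`,
#'   the fitted `intercept`, and the underlying `lm` fit.
#' @examples
#' conc <- seq(2e-6, 16e-6, by = 2e-6)
#' extinction_from_dilutions(conc, 26500 * conc)$epsilon
#' @export
extinction_from_dilutions <- function(concentration, absorbance, pathlength = 1) {
  if (length(concentration) != length(absorbance))
    stop("'concentration' and 'absorbance' must have equal length")
  if (length(unique(concentration)) < 2L)
    stop("degenerate design: need at least 2 distinct concentrations")
  if (pathlength <= 0) stop("'pathlength' must be positive")
  fit <- stats::lm(absorbance ~ concentration)
  # summary.lm warns on exact (zero-residual) fits; the slope SE is still 0
  co <- suppressWarnings(summary(fit)$coefficients)
  slope_se <- if (nrow(co) >= 2L && ncol(co) >= 2L) co["concentration", 2L] else NA_real_
  list(epsilon = unname(stats::coef(fit)["concentration"]) / pathlength,
       se = unname(slope_se) / pathlength,
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       fit = fit)
}
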