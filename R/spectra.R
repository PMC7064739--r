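# Formulation metrics from absorbance spectra: the J-aggregate-to-
# monomer absorbance ratio (A892/A792 for indocyanine green) and the
# two encapsulation-efficiency formulas used for dye- and drug-loaded
# liposomes.

#' Absorbance spectrum table
#'
#' @param wavelengths wavelengths in nm, strictly increasing.
#' @param absorbance absorbance values (dimensionless), same length,
#'   finite.
#' @return object of class `"spectrum_table"`.
#' @export
spectrum_table <- function(wavelengths, absorbance) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.numeric(absorbance)
  if (length(wavelengths) != length(absorbance))
    stop("wavelengths and absorbance must have the same length")
  if (length(wavelengths) < 2) stop("need at least two points")
  if (any(!is.finite(wavelengths)) || any(!is.finite(absorbance)))
    stop("non-finite values in spectrum")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(wavelengths = wavelengths, absorbance = absorbance),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("spectrum: %d points, %g-%g nm\n", length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Read a two-column absorbance spectrum CSV
#'
#' Expects columns `wavelength_nm` and `absorbance` (or any two columns
#' in that order).
#'
#' @param path CSV file path.
#' @return a [spectrum_table()].
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  if (all(c("wavelength_nm", "absorbance") %in% names(d)))
    spectrum_table(d$wavelength_nm, d$absorbance)
  else
    spectrum_table(d[[1]], d[[2]])
}

#' Absorbance at a wavelength
#'
#' Nearest grid point when one lies within 0.5 nm (so 1 nm plate-reader
#' grids hit 892/792 nm exactly), else linear interpolation between the
#' neighboring points.
#'
#' @param spec a [spectrum_table()].
#' @param wavelength target wavelength, nm; must be inside the grid.
#' @return absorbance value.
#' @export
absorbance_at <- function(spec, wavelength) {
  stopifnot(inherits(spec, "spectrum_table"))
  w <- spec$wavelengths
  if (wavelength < min(w) || wavelength > max(w))
    stop("wavelength ", wavelength, " nm outside the measured range ",
         min(w), "-", max(w), " nm")
  i <- which.min(abs(w - wavelength))
  if (abs(w[i] - wavelength) <= 0.5) return(spec$absorbance[i])
  stats::approx(w, spec$absorbance, xout = wavelength)$y
}

#' J-aggregate to monomer absorbance ratio (A892/A792)
#'
#' The standard J-aggregate content metric for indocyanine green: the
#' ratio of absorbance at the J-aggregate band (892 nm) to the monomer
#' band (792 nm).  Raw absorbances are used; no baseline correction.
#'
#' @param spec a [spectrum_table()] covering both wavelengths.
#' @param j_band,monomer_band band positions in nm (defaults 892, 792).
#' @return dimensionless ratio.
#' @examples
#' s <- spectrum_table(700:950, dnorm(700:950, 892, 15) +
#'                               0.3 * dnorm(700:950, 792, 20))
#' ija_icg_ratio(s)
#' @export
ija_icg_ratio <- function(spec, j_band = 892, monomer_band = 792) {
  a_mon <- absorbance_at(spec, monomer_band)
  if (a_mon <= 0)
    stop("monomer-band absorbance at ", monomer_band,
         " nm is not positive (", a_mon, "); ratio undefined")
  absorbance_at(spec, j_band) / a_mon
}

#' Dye encapsulation efficiency from concentrations
#'
#' Percent of dye retained in the purified formulation relative to the
#' input: `100 * encapsulated / initial`.
#'
#' @param encapsulated_conc concentration of encapsulated dye, uM (>= 0).
#' @param initial_conc initial dye concentration, uM (> 0).
#' @return percent.
#' @export
icg_ee <- function(encapsulated_conc, initial_conc) {
  if (initial_conc <= 0) stop("initial concentration must be positive")
  if (encapsulated_conc < 0) stop("encapsulated concentration must be >= 0")
  100 * encapsulated_conc / initial_conc
}

#' Drug encapsulation efficiency from fluorescence intensities
#'
#' Percent efficiency of remote loading measured as
#' `100 * I_after / I_before`, where both intensities come from
#' detergent-solubilized, lipid-matched samples before and after
#' purification (matching the samples is the caller's responsibility).
#' Values above 100 percent are physically implausible and produce a
#' warning.
#'
#' @param fluor_after_purification,fluor_before_purification
#'   fluorescence intensities, arbitrary units; `before` must be
#'   positive.
#' @return percent.
#' @export
dox_ee <- function(fluor_after_purification, fluor_before_purification) {
  if (fluor_before_purification <= 0)
    stop("pre-purification fluorescence must be positive")
  if (fluor_after_purification < 0)
    stop("post-purification fluorescence must be >= 0")
  ee <- 100 * fluor_after_purification / fluor_before_purification
  if (ee > 100)
    warning("encapsulation efficiency above 100% is physically ",
            "implausible (", signif(ee, 4), "%); check sample matching")
  ee
}

#' Peak absorbance in a wavelength window
#'
#' Argmax and maximum of the absorbance over grid points inside the
#' window; ties resolved to the lowest wavelength.
#'
#' @param spec a [spectrum_table()].
#' @param window length-2 numeric, nm range (inclusive), inside the grid.
#' @return list with `wavelength` (nm) and `absorbance`.
#' @export
peak_absorbance <- function(spec, window) {
  stopifnot(inherits(spec, "spectrum_table"), length(window) == 2)
  window <- sort(as.numeric(window))
  inside <- spec$wavelengths >= window[1] & spec$wavelengths <= window[2]
  if (!any(inside))
    stop("window ", window[1], "-", window[2],
         " nm contains no grid points")
  w <- spec$wavelengths[inside]; a <- spec$absorbance[inside]
  i <- which.max(a)  # which.max takes the first (lowest wavelength) tie
  list(wavelength = w[i], absorbance = a[i])
}
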