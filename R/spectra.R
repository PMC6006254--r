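#' Chromophore species known to the simulator
#'
#' @return Character vector of species names.
#' @export
chromophore_species <- function() {
  c("MBNP_ground", "MBNP_triplet", "Hb", "HbO2", "blue_ink", "GNP", "water")
}

# Parametric specific-absorption models. Units: cm^-1 per mg/mL for
# MBNP_ground/MBNP_triplet and blue_ink (ink per % volume); cm^-1 per unit
# volume fraction of whole blood for Hb/HbO2 and of suspension for GNP/water.
#
# Hb/HbO2 values approximate tabulated whole-blood absorption (150 g Hb/L)
# from standard molar extinction compilations; 570 nm sits near the
# Hb/HbO2 isosbestic region so the two are comparable there. Peaks: dye
# ground state 660 nm, triplet state 840 nm, gold nanoparticles 532 nm.
# The blue ink is deliberately near-proportional to the dye ground-state
# spectrum over 570-660 nm (similar absorption profile at the unmixing
# wavelengths).
.gauss_peak <- function(wl, center, width, peak) {
  peak * exp(-(wl - center)^2 / (2 * width^2))
}

.blood_table <- list(
  wavelengths = c(570, 606, 660, 840),
  Hb = c(238, 67, 17.3, 3.7),
  HbO2 = c(230, 9.2, 1.7, 5.6),
  water = c(6e-4, 1.5e-3, 3.6e-3, 4.0e-2)
)

.table_absorption <- function(values, wavelength_nm, species) {
  tb <- .blood_table
  vapply(wavelength_nm, function(w)
    interp_coef(tb$wavelengths, values, w, species), numeric(1))
}

#' Specific absorption of a chromophore at given wavelengths
#'
#' Evaluates the built-in parametric spectra. Dye ground state peaks at
#' 660 nm, dye triplet state at 840 nm, gold nanoparticles at 532 nm;
#' hemoglobin and water values come from a small built-in table spanning
#' 570-840 nm (log-interpolated; no extrapolation).
#'
#' @param species One of [chromophore_species()].
#' @param wavelength_nm Wavelengths, nm. Vectorised.
#' @return Specific absorption, cm^-1 per unit concentration.
#' @export
specific_absorption <- function(species, wavelength_nm) {
  species <- match.arg(species, chromophore_species())
  switch(species,
    MBNP_ground = .gauss_peak(wavelength_nm, 660, 45, 10),
    MBNP_triplet = .gauss_peak(wavelength_nm, 840, 50, 8),
    blue_ink = .gauss_peak(wavelength_nm, 655, 50, 250),
    GNP = .gauss_peak(wavelength_nm, 532, 40, 80),
    Hb = .table_absorption(.blood_table$Hb, wavelength_nm, "Hb"),
    HbO2 = .table_absorption(.blood_table$HbO2, wavelength_nm, "HbO2"),
    water = .table_absorption(.blood_table$water, wavelength_nm, "water"))
}

#' Tabulated spectrum of one chromophore
#'
#' @param species One of [chromophore_species()].
#' @param wavelengths Wavelengths at which to tabulate, nm.
#' @return An object of class `chromophore_spectrum` with fields `species`,
#'   `wavelengths`, `specific_absorption`.
#' @export
chromophore_spectrum <- function(species, wavelengths = c(570, 606, 660, 840)) {
  species <- match.arg(species, chromophore_species())
  structure(list(species = species,
                 wavelengths = as.numeric(wavelengths),
                 specific_absorption = specific_absorption(species, wavelengths)),
            class = "chromophore_spectrum")
}

#' Absorption matrix for a set of species at a set of wavelengths
#'
#' Rows are wavelengths, columns are species; entry (i, j) is the specific
#' absorption of species j at wavelength i. This is the system matrix of the
#' spectral-unmixing linear model.
#'
#' @param wavelengths Wavelengths, nm.
#' @param species Species names; default the three unmixing chromophores.
#' @return Numeric matrix with dimnames.
#' @export
absorption_matrix <- function(wavelengths = c(570, 606, 660),
                              species = c("Hb", "HbO2", "MBNP_ground")) {
  A <- vapply(species, function(s) specific_absorption(s, wavelengths),
              numeric(length(wavelengths)))
  A <- matrix(A, nrow = length(wavelengths),
              dimnames = list(paste0(wavelengths, "nm"), species))
  A
}
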