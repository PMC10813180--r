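# Reference band tables for low-molecular-weight blood-fraction SERS:
# vibrational-mode assignments for the major fingerprint bands and for the
# bands that dominate the FM / non-FM discriminant regression vector.

#' Band assignments for blood-fraction SERS spectra
#'
#' Two reference tables are pooled: the major bands seen in mean spectra
#' (`source = "major"`) and the bands dominating the class-discriminant
#' regression vector (`source = "regression"`). Assignments are dominated by
#' plasma amino acids (Phe, Tyr, Trp, Ser, Lys), lipids and amide backbone
#' modes.
#'
#' @return A data.frame with columns `position` (cm^-1), `mode`, `assignment`,
#'   `source`.
#' @export
band_assignments <- function() {
  major <- data.frame(
    position = c(911, 967, 1014, 1129, 1189, 1222, 1305, 1354, 1453, 1586, 1633),
    mode = c("C-C stretching", "C-C stretching", "Benzene ring breathing",
             "C-H bending", "C-H bending", "C-H stretching", "Amide III",
             "C-H bending", "CH2, CH3 bending", "C=C", "Beta sheet"),
    assignment = c("Lys", "Phe", "Trp", "Trp and Phe", "Tyr and Phe",
                   "Phe, Tyr, and Amide III", "Amide III", "Trp",
                   "Phospholipids and lipids", "Phe and Tyr", "Amide I"),
    source = "major", stringsAsFactors = FALSE)
  regr <- data.frame(
    position = c(918, 978, 991, 1013, 1202, 1222, 1326, 1348, 1370, 1448,
                 1474, 1566, 1582),
    mode = c("C-C backbone", "OCH3 stretching", "C-H bending", "C-H bending",
             "Amide III", "C-H stretching", "CH2 twisting", "C-H bending",
             "C-C stretch", "CH2, CH3 bending", "C-N stretching",
             "C=C bending", "C=C bending"),
    assignment = c("Ser", "Polysaccharides", "Phe", "Trp",
                   "Phe, Trp, and Amide III", "Phe and Tyr", "D-Ser", "Trp",
                   "Trp", "Phospholipids and lipids", "Aromatic ring", "Phe",
                   "Phe and Tyr"),
    source = "regression", stringsAsFactors = FALSE)
  rbind(major, regr)
}

#' Discriminant band positions
#'
#' The eight wavenumbers that dominate the FM vs non-FM regression vector,
#' all linked to plasma amino acids (Phe, Tyr, Trp, Ser).
#'
#' @return Numeric vector of positions in cm^-1.
#' @export
discriminant_bands <- function() {
  c(991, 1013, 1202, 1222, 1348, 1370, 1566, 1582)
}

#' Band specification for the synthetic generator
#'
#' @param position centre in cm^-1.
#' @param width half-width at half-maximum in cm^-1 (> 0).
#' @param amplitude peak amplitude in arbitrary units (>= 0).
#' @param class_effect fractional FM-minus-non-FM amplitude difference in
#'   [-1, 1] (applied as +/- half the effect to the two classes).
#' @param shape `"lorentzian"` (default, the natural Raman lineshape) or
#'   `"gaussian"`.
#' @return A one-row data.frame (class `"band_spec"` rows are plain rows of
#'   the band table).
#' @export
band_spec <- function(position, width = 10, amplitude = 1, class_effect = 0,
                      shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (width <= 0) stop("band width must be > 0")
  if (amplitude < 0) stop("band amplitude must be >= 0")
  if (abs(class_effect) > 1) stop("|class_effect| must be <= 1")
  data.frame(position = position, width = width, amplitude = amplitude,
             class_effect = class_effect, shape = shape,
             stringsAsFactors = FALSE)
}

#' Default band table for synthetic cohorts
#'
#' The union of the major-band and regression-vector band positions, with
#' Lorentzian shape, 10 cm^-1 half-width, and a two-level amplitude hierarchy
#' (strong bands 1014, 1222, 1354, 1448, 1586 at amplitude 1; the rest at
#' 0.5). The per-band amplitudes are free parameters of the generator, not
#' measured values. A unit `class_effect` is planted at the eight
#' discriminant bands only; the generator's `effect_scale` multiplies it.
#'
#' @return A data.frame of band specifications (one row per band).
#' @export
default_band_table <- function() {
  pos <- sort(unique(band_assignments()$position))
  strong <- c(1014, 1222, 1354, 1448, 1586)
  amp <- ifelse(pos %in% strong, 1, 0.5)
  eff <- ifelse(pos %in% discriminant_bands(), 1, 0)
  do.call(rbind, lapply(seq_along(pos), function(i)
    band_spec(pos[i], width = 10, amplitude = amp[i], class_effect = eff[i])))
}
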