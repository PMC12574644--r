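# Capsid-protein mass prediction and the ssDNA-length -> filament-length
# calibration for filamentous M13 phage.

# Standard IUPAC/Expasy residue masses (Da). Residue = amino acid minus
# water; a peptide's mass is the residue sum plus one water.
AA_AVERAGE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

WATER_AVERAGE <- 18.01528
WATER_MONO <- 18.0105646863
PROTON_MASS <- 1.00728

#' Canonical mature wild-type M13 pVIII major coat protein
#'
#' The 50-residue mature chain (signal peptide removed) of the M13 major
#' coat protein, present at ~2700 copies per wild-type virion. Its
#' predicted linear positive-mode MALDI peak \code{[M+H]+} rounds to
#' 5239 Da.
#'
#' @return the one-letter sequence as a character scalar.
#' @examples
#' round(proteinMass(wtPVIII())@maldiMz)
#' @export
wtPVIII <- function() {
  "AEGDDPAKAAFNSLQASATEYIGYAWAMVVVIVGATIGIKLFKKFTSKAS"
}

#' Predict protein masses and the MALDI [M+H]+ peak
#'
#' Computes the average (chemical) and monoisotopic mass of a protein
#' from standard residue mass tables plus one water, and the predicted
#' linear positive-mode MALDI-TOF peak as the singly protonated ion
#' \code{[M+H]+} = average mass + 1.00728 Da. No rounding is applied;
#' round at presentation.
#'
#' @param seq one-letter amino-acid string (20 standard residues).
#' @return a \code{\linkS4class{MassResult}}.
#' @examples
#' proteinMass("G")                    # glycine: 75.07 Da average
#' proteinMass(wtPVIII())              # [M+H]+ ~ 5239 Da
#' @export
proteinMass <- function(seq) {
  if (is(seq, "XString") || is(seq, "XStringSet"))
    seq <- as.character(seq)
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    stopIO("expected a single protein sequence")
  s <- toupper(seq)
  if (nchar(s) == 0L) stopIO("empty protein sequence")
  res <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(res), names(AA_AVERAGE))
  if (length(bad))
    stopIO(sprintf("invalid amino-acid letter(s): %s",
                   paste(bad, collapse = ", ")))
  avg <- sum(AA_AVERAGE[res]) + WATER_AVERAGE
  mono <- sum(AA_MONO[res]) + WATER_MONO
  new("MassResult", averageMass = avg, monoisotopicMass = mono,
      maldiMz = avg + PROTON_MASS)
}

#' Calibrate the ssDNA-length to phage-length model
#'
#' Filament length is proportional to the packaged ssDNA size, so the
#' model is a least-squares line through the origin,
#' slope = sum(nt * nm) / sum(nt^2). The default calibration pairs are
#' the four length-series designs (721, 1447, 3241, 6261 nt) and their
#' measured filament lengths (~100, 200, 400, 800 nm), giving a slope of
#' ~0.127 nm/nt. Calibration residuals are retained; empirical scatter
#' of the pairs corresponds to a ~20% accuracy band.
#'
#' @param nt nucleotide lengths of the calibration designs.
#' @param nm measured filament lengths in nm.
#' @return a \code{\linkS4class{LengthModel}}.
#' @examples
#' calibrateLengthModel()
#' @export
calibrateLengthModel <- function(nt = c(721, 1447, 3241, 6261),
                                 nm = c(100, 200, 400, 800)) {
  if (length(nt) != length(nm) || length(nt) < 1L)
    stopIO("nt and nm must be non-empty vectors of equal length")
  if (any(nt <= 0) || any(nm <= 0))
    stopIO("calibration pairs must be positive")
  slope <- sum(nt * nm) / sum(nt^2)
  new("LengthModel", slopeNmPerNt = slope,
      calibration = data.frame(nt = nt, nm = nm),
      residuals = nm - slope * nt)
}

#' Predict phage filament length from ssDNA size
#'
#' @param nNt ssDNA length in nucleotides (> 0).
#' @param model a \code{\linkS4class{LengthModel}}; default is the
#'   standard four-point calibration.
#' @return predicted filament length in nm.
#' @examples
#' phageLengthFromSsdna(1447)   # ~200 nm class
#' phageLengthFromSsdna(1719)   # hexamer-converted design, ~220 nm
#' @export
phageLengthFromSsdna <- function(nNt, model = calibrateLengthModel()) {
  if (!is(model, "LengthModel")) stopIO("model must be a LengthModel")
  if (any(!is.finite(nNt)) || any(nNt <= 0))
    stopIO("ssDNA length must be a positive number of nucleotides")
  model@slopeNmPerNt * nNt
}
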