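#' @import methods
#' @importFrom stats median sd setNames
#' @importFrom utils head tail read.csv write.csv packageVersion
NULL

#' Design specification for a reprogrammed ssDNA
#'
#' A \code{DesignSpec} is the complete recipe for one programmable
#' single-stranded DNA insert: the target length, the fraction of
#' nucleotides that belong to placed CG dimers (the TLR9-stimulatory
#' motif), the fraction of those dimers to embed in canonical CpG
#' hexamers, the constraint thresholds for the repair passes, and the
#' seed that makes the whole design reproducible.
#'
#' The CG fraction is dimer-based: a spec with \code{cgFraction = f} and
#' length \eqn{L} places \eqn{N = \mathrm{round}(fL/2)} CG dimers, so the
#' realized fraction is \eqn{2N/L}. A 1415-nt design at 27\% carries 191
#' dimers.
#'
#' @slot lengthNt target sequence length in nucleotides (before any
#'   hexamer insertion).
#' @slot cgFraction target fraction of nucleotides inside placed CG
#'   dimers, in \code{[0, 1]}.
#' @slot hexamerFraction fraction of CG dimers to convert into canonical
#'   CpG hexamers, in \code{[0, 1]}.
#' @slot hexamerSet candidate hexamers; each must contain exactly one CG
#'   dimer. Defaults to the canonical murine motifs AACGTT and GACGTT.
#' @slot minRepeatLen direct repeats of this length or longer are
#'   eliminated (default 9).
#' @slot minStemLen inverted repeats (hairpin stems) of this length or
#'   longer are eliminated (default 13, i.e. "longer than 12 bases").
#' @slot seed integer seed controlling scaffold placement, flank
#'   sampling and hexamer site choice.
#' @export
setClass("DesignSpec",
  representation(
    lengthNt = "integer",
    cgFraction = "numeric",
    hexamerFraction = "numeric",
    hexamerSet = "character",
    minRepeatLen = "integer",
    minStemLen = "integer",
    seed = "integer"
  )
)

setValidity("DesignSpec", function(object) {
  msg <- character()
  if (length(object@lengthNt) != 1L || is.na(object@lengthNt) ||
      object@lengthNt < 1L)
    msg <- c(msg, "lengthNt must be a single positive integer")
  if (object@cgFraction < 0 || object@cgFraction > 1)
    msg <- c(msg, "cgFraction must lie in [0, 1]")
  if (object@hexamerFraction < 0 || object@hexamerFraction > 1)
    msg <- c(msg, "hexamerFraction must lie in [0, 1]")
  if (length(msg) == 0L) {
    nCG <- round(object@cgFraction * object@lengthNt / 2)
    if (object@lengthNt < 2L * nCG)
      msg <- c(msg, sprintf(
        "lengthNt (%d) cannot hold %d CG dimers (needs >= %d nt)",
        object@lengthNt, nCG, 2L * nCG))
  }
  bad <- vapply(object@hexamerSet, function(h) {
    m <- gregexpr("CG", h, fixed = TRUE)[[1]]
    nchar(h) != 6L || sum(m > 0) != 1L
  }, logical(1))
  if (any(bad))
    msg <- c(msg, paste0("hexamerSet members must be 6-mers containing ",
                         "exactly one CG dimer: ",
                         paste(object@hexamerSet[bad], collapse = ", ")))
  if (object@minRepeatLen < 2L) msg <- c(msg, "minRepeatLen must be >= 2")
  if (object@minStemLen < 2L) msg <- c(msg, "minStemLen must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct a DesignSpec
#'
#' @param lengthNt target length in nucleotides.
#' @param cgFraction target dimer-based CG fraction in \code{[0, 1]}.
#' @param hexamerFraction fraction of CG dimers to convert to canonical
#'   hexamers (default 0: no conversion stage).
#' @param hexamerSet candidate CpG hexamers.
#' @param minRepeatLen minimum direct-repeat length to eliminate.
#' @param minStemLen minimum hairpin stem length to eliminate.
#' @param seed integer seed.
#' @return a validated \code{\linkS4class{DesignSpec}} object.
#' @examples
#' DesignSpec(1415, 0.27, seed = 1)
#' @export
DesignSpec <- function(lengthNt, cgFraction, hexamerFraction = 0,
                       hexamerSet = c("AACGTT", "GACGTT"),
                       minRepeatLen = 9L, minStemLen = 13L, seed = 1L) {
  new("DesignSpec",
      lengthNt = as.integer(lengthNt),
      cgFraction = as.numeric(cgFraction),
      hexamerFraction = as.numeric(hexamerFraction),
      hexamerSet = toupper(as.character(hexamerSet)),
      minRepeatLen = as.integer(minRepeatLen),
      minStemLen = as.integer(minStemLen),
      seed = as.integer(seed))
}

setMethod("show", "DesignSpec", function(object) {
  nCG <- round(object@cgFraction * object@lengthNt / 2)
  cat("DesignSpec:", object@lengthNt, "nt,",
      sprintf("CG fraction %.1f%% (%d dimers),", 100 * object@cgFraction, nCG),
      sprintf("hexamer fraction %.0f%%,", 100 * object@hexamerFraction),
      "seed", object@seed, "\n")
  cat("  hexamers:", paste(object@hexamerSet, collapse = "/"),
      " repeat >=", object@minRepeatLen,
      " stem >=", object@minStemLen, "\n")
})

#' Constraint audit of a designed sequence
#'
#' Machine-readable report produced by \code{\link{validateDesign}}:
#' CG-dimer census, hexamer embedding, remaining direct repeats and
#' hairpin stems, and flank boundary-rule violations. \code{clean} is
#' \code{TRUE} iff repeats, hairpins and boundary violations are all
#' absent.
#'
#' @slot lengthNt sequence length.
#' @slot nCgDimers number of CG dimers found by scanning.
#' @slot cgFractionRealized \code{2 * nCgDimers / lengthNt}.
#' @slot cgPercentRounded realized fraction as nearest integer percent.
#' @slot nHexamerEmbedded CG dimers embedded in a hexamer-set motif.
#' @slot hexamerPctOfCg percent of CG dimers hexamer-embedded.
#' @slot repeats data.frame of direct-repeat families (kmer, length,
#'   positions as a list column of 0-based offsets). When the spec
#'   installs hexamer cassettes, families induced entirely by those
#'   multi-copy motifs are excluded here and reported in
#'   \code{motifRepeats} instead: they are an inherent consequence of
#'   deliberately installing the same hexamer many times, not a design
#'   defect.
#' @slot motifRepeats data.frame of motif-induced repeat families (same
#'   columns as \code{repeats}).
#' @slot hairpins data.frame of inverted-repeat pairs (stemLen,
#'   arm1Start, arm2Start; 0-based). Never motif-exempted.
#' @slot boundaryViolations 0-based offsets of flank bases violating the
#'   no-C-after / no-G-before dimer rule.
#' @slot clean overall pass flag.
#' @export
setClass("ConstraintReport",
  representation(
    lengthNt = "integer",
    nCgDimers = "integer",
    cgFractionRealized = "numeric",
    cgPercentRounded = "integer",
    nHexamerEmbedded = "integer",
    hexamerPctOfCg = "numeric",
    repeats = "data.frame",
    motifRepeats = "data.frame",
    hairpins = "data.frame",
    boundaryViolations = "integer",
    clean = "logical"
  )
)

setMethod("show", "ConstraintReport", function(object) {
  cat("ConstraintReport:", object@lengthNt, "nt,",
      object@nCgDimers, "CG dimers",
      sprintf("(%.2f%%, ~%d%%),", 100 * object@cgFractionRealized,
              object@cgPercentRounded),
      object@nHexamerEmbedded, "hexamer-embedded",
      sprintf("(%.1f%% of dimers)\n", object@hexamerPctOfCg))
  cat("  repeat families:", nrow(object@repeats),
      " motif-induced:", nrow(object@motifRepeats),
      " hairpin pairs:", nrow(object@hairpins),
      " boundary violations:", length(object@boundaryViolations), "\n")
  cat(if (object@clean) "  CLEAN\n" else "  NOT clean\n")
})

#' Is a design report clean?
#' @param x a \code{\linkS4class{ConstraintReport}}.
#' @return logical.
#' @export
isClean <- function(x) {
  stopifnot(is(x, "ConstraintReport"))
  x@clean
}

#' A chromatogram trace
#'
#' Two aligned vectors: retention time in minutes (strictly increasing)
#' and detector response in arbitrary absorbance units.
#'
#' @slot time minutes, strictly increasing.
#' @slot signal detector response, same length as \code{time}.
#' @export
setClass("Chromatogram",
  representation(time = "numeric", signal = "numeric"))

setValidity("Chromatogram", function(object) {
  msg <- character()
  if (length(object@time) != length(object@signal))
    msg <- c(msg, "time and signal must have the same length")
  if (anyNA(object@time) || anyNA(object@signal))
    msg <- c(msg, "time/signal must not contain missing values")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a Chromatogram
#' @param time retention times in minutes, strictly increasing.
#' @param signal detector response, same length.
#' @return a \code{\linkS4class{Chromatogram}}.
#' @export
Chromatogram <- function(time, signal) {
  new("Chromatogram", time = as.numeric(time), signal = as.numeric(signal))
}

setMethod("show", "Chromatogram", function(object) {
  cat("Chromatogram:", length(object@time), "samples,",
      sprintf("%.2f-%.2f min, max signal %.4g\n",
              min(object@time), max(object@time), max(object@signal)))
})

#' One chromatographic peak as a sum of two Gaussians
#'
#' An asymmetric (e.g. tailing) peak is modeled as
#' \eqn{a_1 e^{-(t-\mu_1)^2/2\sigma_1^2} + a_2 e^{-(t-\mu_2)^2/2\sigma_2^2}}.
#' Its area has the closed form \eqn{\sqrt{2\pi}(a_1\sigma_1 + a_2\sigma_2)}.
#'
#' @slot a1,a2 component amplitudes (>= 0).
#' @slot mu1,mu2 component centers (minutes).
#' @slot sigma1,sigma2 component widths (minutes, > 0).
#' @export
setClass("DoubleGaussianPeak",
  representation(a1 = "numeric", a2 = "numeric",
                 mu1 = "numeric", mu2 = "numeric",
                 sigma1 = "numeric", sigma2 = "numeric"))

setValidity("DoubleGaussianPeak", function(object) {
  msg <- character()
  if (object@a1 < 0 || object@a2 < 0)
    msg <- c(msg, "amplitudes must be >= 0")
  if (object@sigma1 <= 0 || object@sigma2 <= 0)
    msg <- c(msg, "widths must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DoubleGaussianPeak
#' @param a1,a2 amplitudes.
#' @param mu1,mu2 centers (min).
#' @param sigma1,sigma2 widths (min).
#' @return a \code{\linkS4class{DoubleGaussianPeak}}.
#' @export
DoubleGaussianPeak <- function(a1, a2, mu1, mu2, sigma1, sigma2) {
  new("DoubleGaussianPeak", a1 = a1, a2 = a2, mu1 = mu1, mu2 = mu2,
      sigma1 = sigma1, sigma2 = sigma2)
}

#' Closed-form area of a peak
#' @param x a \code{\linkS4class{DoubleGaussianPeak}}.
#' @return the analytic area \eqn{\sqrt{2\pi}(a_1\sigma_1 + a_2\sigma_2)}.
#' @export
setGeneric("peakArea", function(x) standardGeneric("peakArea"))

#' @rdname peakArea
#' @export
setMethod("peakArea", "DoubleGaussianPeak", function(x) {
  sqrt(2 * pi) * (x@a1 * x@sigma1 + x@a2 * x@sigma2)
})

#' Area-weighted effective center of a peak
#' @param x a \code{\linkS4class{DoubleGaussianPeak}}.
#' @return minutes.
#' @export
setGeneric("effectiveCenter", function(x) standardGeneric("effectiveCenter"))

#' @rdname effectiveCenter
#' @export
setMethod("effectiveCenter", "DoubleGaussianPeak", function(x) {
  w1 <- x@a1 * x@sigma1
  w2 <- x@a2 * x@sigma2
  if (w1 + w2 <= 0) return((x@mu1 + x@mu2) / 2)
  (w1 * x@mu1 + w2 * x@mu2) / (w1 + w2)
})

#' Fitted two-peak double-Gaussian model of a chromatogram window
#'
#' The wild-type (main) and antigen (shoulder) peaks, the linear
#' baseline, the resulting antigen pVIII display ratio, the root mean
#' squared residual, and the optimizer's convergence flag.
#'
#' @slot wtPeak,antigenPeak \code{\linkS4class{DoubleGaussianPeak}}s;
#'   the antigen effective center is at or after the wild-type one.
#' @slot baseline numeric length 2: intercept and slope (response units,
#'   response units per minute; slope applied to time centered on the
#'   window midpoint).
#' @slot displayRatio antigen area / total area, in \code{[0, 1]}.
#' @slot rmse root mean squared residual of the fit.
#' @slot converged optimizer status.
#' @export
setClass("HplcFit",
  representation(wtPeak = "DoubleGaussianPeak",
                 antigenPeak = "DoubleGaussianPeak",
                 baseline = "numeric",
                 displayRatio = "numeric",
                 rmse = "numeric",
                 converged = "logical"))

setMethod("show", "HplcFit", function(object) {
  cat(sprintf(
    "HplcFit: display ratio %.1f%% (wt area %.4g @ %.2f min, antigen area %.4g @ %.2f min)\n",
    100 * object@displayRatio, peakArea(object@wtPeak),
    effectiveCenter(object@wtPeak), peakArea(object@antigenPeak),
    effectiveCenter(object@antigenPeak)))
  cat(sprintf("  rmse %.4g, converged: %s\n", object@rmse, object@converged))
})

#' Antigen pVIII display ratio of a fit
#'
#' The proportion of antigen pVIII among all pVIII copies, estimated as
#' area(antigen peak) / (area(antigen) + area(wild type)) using the
#' closed-form double-Gaussian areas.
#'
#' @param x an \code{\linkS4class{HplcFit}}.
#' @return a value in \code{[0, 1]}.
#' @export
setGeneric("displayRatio", function(x) standardGeneric("displayRatio"))

#' @rdname displayRatio
#' @export
setMethod("displayRatio", "HplcFit", function(x) {
  aW <- peakArea(x@wtPeak)
  aA <- peakArea(x@antigenPeak)
  if (aW + aA <= 0)
    stop(phageError("zero total peak area: display ratio undefined",
                    "phageDesign_zeroArea"))
  aA / (aW + aA)
})

#' Simulation recipe for a synthetic two-peak chromatogram
#'
#' Describes a wild-type pVIII main peak (default apex 51.3 min) with a
#' trailing antigen pVIII shoulder, each an asymmetric sum of two
#' Gaussians, plus optional linear baseline drift and Gaussian noise.
#' The generative antigen area fraction is exact by construction (areas
#' are closed-form).
#'
#' @slot wtCenter main-peak leading-component center, minutes.
#' @slot shoulderOffset antigen minus wild-type center, minutes.
#' @slot antigenAreaFraction generative antigen share of total peak
#'   area, in \code{[0, 1]}.
#' @slot totalArea total peak area in response units x minutes.
#' @slot sigma1,sigma2 per-peak component widths (shared shape for both
#'   peaks), minutes.
#' @slot tailOffset center shift of the trailing (second) component,
#'   minutes.
#' @slot tailAreaFraction share of each peak's area in its trailing
#'   component.
#' @slot noiseSd standard deviation of additive Gaussian noise,
#'   response units.
#' @slot baseline intercept and slope of the linear drift.
#' @slot dt sampling interval, minutes.
#' @slot window fit window, minutes (length 2).
#' @slot seed seed for the noise generator.
#' @export
setClass("SimSpec",
  representation(wtCenter = "numeric", shoulderOffset = "numeric",
                 antigenAreaFraction = "numeric", totalArea = "numeric",
                 sigma1 = "numeric", sigma2 = "numeric",
                 tailOffset = "numeric", tailAreaFraction = "numeric",
                 noiseSd = "numeric", baseline = "numeric",
                 dt = "numeric", window = "numeric", seed = "integer"))

setValidity("SimSpec", function(object) {
  msg <- character()
  if (object@antigenAreaFraction < 0 || object@antigenAreaFraction > 1)
    msg <- c(msg, "antigenAreaFraction must lie in [0, 1]")
  if (object@sigma1 <= 0 || object@sigma2 <= 0)
    msg <- c(msg, "component widths must be > 0")
  if (object@tailAreaFraction < 0 || object@tailAreaFraction >= 1)
    msg <- c(msg, "tailAreaFraction must lie in [0, 1)")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "window must be increasing length-2")
  if (length(msg)) msg else TRUE
})

#' Construct a SimSpec
#'
#' @param antigenAreaFraction generative antigen area fraction.
#' @param wtCenter wild-type peak center (min); default 51.3.
#' @param shoulderOffset antigen shoulder offset (min); default 0.6.
#' @param totalArea total peak area; default 100.
#' @param sigma1,sigma2 leading/trailing component widths (min).
#' @param tailOffset trailing-component center shift (min).
#' @param tailAreaFraction area share of the trailing component.
#' @param noiseSd Gaussian noise SD (response units); default 0.
#' @param baseline length-2 intercept/slope of linear drift; default 0.
#' @param dt sampling interval (min).
#' @param window fit window (min); default \code{wtCenter + c(-3, 4)}.
#' @param seed noise seed.
#' @return a validated \code{\linkS4class{SimSpec}}.
#' @export
SimSpec <- function(antigenAreaFraction, wtCenter = 51.3,
                    shoulderOffset = 0.6, totalArea = 100,
                    sigma1 = 0.18, sigma2 = 0.45,
                    tailOffset = 0.25, tailAreaFraction = 0.35,
                    noiseSd = 0, baseline = c(0, 0), dt = 0.01,
                    window = wtCenter + c(-3, 4), seed = 1L) {
  new("SimSpec", wtCenter = wtCenter, shoulderOffset = shoulderOffset,
      antigenAreaFraction = antigenAreaFraction, totalArea = totalArea,
      sigma1 = sigma1, sigma2 = sigma2, tailOffset = tailOffset,
      tailAreaFraction = tailAreaFraction, noiseSd = noiseSd,
      baseline = as.numeric(baseline), dt = dt,
      window = as.numeric(window), seed = as.integer(seed))
}

#' Predicted masses of a capsid protein
#'
#' @slot averageMass average (chemical) mass in Da.
#' @slot monoisotopicMass monoisotopic mass in Da.
#' @slot maldiMz predicted linear positive-mode MALDI peak, the singly
#'   protonated ion \code{[M+H]+} = average mass + 1.00728 Da.
#' @export
setClass("MassResult",
  representation(averageMass = "numeric", monoisotopicMass = "numeric",
                 maldiMz = "numeric"))

setMethod("show", "MassResult", function(object) {
  cat(sprintf("MassResult: average %.2f Da, monoisotopic %.2f Da, MALDI [M+H]+ %.2f Da (~%d Da)\n",
              object@averageMass, object@monoisotopicMass,
              object@maldiMz, round(object@maldiMz)))
})

#' Linear ssDNA-length to phage-length calibration
#'
#' Filamentous M13 phage length is proportional to the packaged ssDNA
#' size; the model is a least-squares line through the origin.
#'
#' @slot slopeNmPerNt calibrated slope, nm per nucleotide.
#' @slot calibration data.frame of (nt, nm) calibration pairs.
#' @slot residuals fit residuals in nm.
#' @export
setClass("LengthModel",
  representation(slopeNmPerNt = "numeric", calibration = "data.frame",
                 residuals = "numeric"))

setValidity("LengthModel", function(object) {
  if (object@slopeNmPerNt <= 0) "slope must be > 0" else TRUE
})

setMethod("show", "LengthModel", function(object) {
  cat(sprintf("LengthModel: %.4f nm/nt (origin-anchored least squares on %d pairs, max |resid| %.1f nm)\n",
              object@slopeNmPerNt, nrow(object@calibration),
              max(abs(object@residuals))))
})
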