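# Format plumbing: FASTA with design metadata, chromatogram CSV, JSON
# reports. All coordinates written to reports are 0-based half-open.

#' Write a designed sequence to FASTA
#'
#' Sequences are wrapped at 70 columns. Design metadata are carried in
#' the description line as space-separated \code{key=value} pairs after
#' the record name.
#'
#' @param seq nucleotide sequence (character or \code{DNAString}).
#' @param file output path.
#' @param name record name (no whitespace).
#' @param metadata named list/vector of scalar metadata values.
#' @return the file path, invisibly.
#' @export
writeDesignFasta <- function(seq, file, name = "design",
                             metadata = list()) {
  s <- asBases(seq)
  desc <- name
  if (length(metadata)) {
    kv <- paste0(names(metadata), "=",
                 vapply(metadata, function(v) as.character(v)[1],
                        character(1)))
    desc <- paste(c(name, kv), collapse = " ")
  }
  set <- Biostrings::DNAStringSet(s)
  names(set) <- desc
  Biostrings::writeXStringSet(set, filepath = file, width = 70L)
  invisible(file)
}

#' Read a design FASTA
#'
#' @param file FASTA path.
#' @return a list of records, each a list with \code{name},
#'   \code{sequence}, and \code{metadata} (named character vector parsed
#'   from \code{key=value} pairs in the description). An empty file
#'   yields an empty list.
#' @export
readDesignFasta <- function(file) {
  if (!file.exists(file)) stopIO(sprintf("file not found: %s", file))
  if (file.size(file) == 0L) return(list())
  set <- tryCatch(Biostrings::readDNAStringSet(file),
                  error = function(e) stopIO(sprintf(
                    "malformed FASTA '%s': %s", file, conditionMessage(e))))
  lapply(seq_along(set), function(i) {
    desc <- names(set)[i]
    toks <- strsplit(desc, "\\s+")[[1]]
    kv <- grep("=", toks, fixed = TRUE, value = TRUE)
    meta <- character()
    if (length(kv)) {
      parts <- strsplit(kv, "=", fixed = TRUE)
      meta <- setNames(vapply(parts, `[`, character(1), 2L),
                       vapply(parts, `[`, character(1), 1L))
    }
    list(name = toks[1], sequence = as.character(set[[i]]),
         metadata = meta)
  })
}

#' Read a chromatogram from CSV
#'
#' Accepts the canonical header form (\code{time_min,signal}) or a
#' headerless two-column whitespace table. Time must be strictly
#' increasing; a violation is reported with its row number.
#'
#' @param file input path.
#' @return a \code{\linkS4class{Chromatogram}}.
#' @export
readChromatogramCsv <- function(file) {
  if (!file.exists(file)) stopIO(sprintf("file not found: %s", file))
  first <- readLines(file, n = 1L)
  if (grepl("time_min", first, fixed = TRUE)) {
    df <- tryCatch(read.csv(file), error = function(e)
      stopIO(sprintf("malformed CSV '%s': %s", file, conditionMessage(e))))
    if (!all(c("time_min", "signal") %in% names(df)))
      stopIO("CSV must have columns time_min,signal")
    tm <- df$time_min; sg <- df$signal
  } else {
    df <- tryCatch(utils::read.table(file), error = function(e)
      stopIO(sprintf("malformed table '%s': %s", file, conditionMessage(e))))
    if (ncol(df) < 2L) stopIO("table must have two columns: time, signal")
    tm <- df[[1]]; sg <- df[[2]]
  }
  hdr <- as.integer(grepl("time_min", first, fixed = TRUE))
  if (anyNA(tm) || anyNA(sg))
    stopIO(sprintf("missing values at row %d",
                   which(is.na(tm) | is.na(sg))[1] + hdr))
  bad <- which(diff(tm) <= 0)
  if (length(bad))
    stopIO(sprintf("time not strictly increasing at row %d",
                   bad[1] + 1L + hdr))
  Chromatogram(tm, sg)
}

#' Write a chromatogram to CSV
#'
#' Uses the canonical \code{time_min,signal} header.
#'
#' @param chrom a \code{\linkS4class{Chromatogram}}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeChromatogramCsv <- function(chrom, file) {
  validObject(chrom)
  write.csv(data.frame(time_min = chrom@time, signal = chrom@signal),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Plain-list views of report objects for JSON serialization.
reportAsList <- function(x) {
  if (is(x, "ConstraintReport")) {
    list(length_nt = x@lengthNt,
         n_cg_dimers = x@nCgDimers,
         cg_fraction_realized = x@cgFractionRealized,
         cg_percent_rounded = x@cgPercentRounded,
         n_hexamer_embedded = x@nHexamerEmbedded,
         hexamer_pct_of_cg = x@hexamerPctOfCg,
         repeats = lapply(seq_len(nrow(x@repeats)), function(i)
           list(kmer = x@repeats$kmer[i], length = x@repeats$length[i],
                positions = x@repeats$positions[[i]])),
         motif_repeats = lapply(seq_len(nrow(x@motifRepeats)), function(i)
           list(kmer = x@motifRepeats$kmer[i],
                length = x@motifRepeats$length[i],
                positions = x@motifRepeats$positions[[i]])),
         hairpins = lapply(seq_len(nrow(x@hairpins)), function(i)
           list(stem_len = x@hairpins$stemLen[i],
                arm1_start = x@hairpins$arm1Start[i],
                arm2_start = x@hairpins$arm2Start[i])),
         boundary_violations = x@boundaryViolations,
         clean = x@clean)
  } else if (is(x, "HplcFit")) {
    pk <- function(p) list(a1 = p@a1, a2 = p@a2, mu1 = p@mu1, mu2 = p@mu2,
                           sigma1 = p@sigma1, sigma2 = p@sigma2,
                           area = peakArea(p),
                           effective_center = effectiveCenter(p))
    list(wt_peak = pk(x@wtPeak), antigen_peak = pk(x@antigenPeak),
         baseline = list(intercept = x@baseline[1], slope = x@baseline[2]),
         display_ratio = x@displayRatio, rmse = x@rmse,
         converged = x@converged)
  } else if (is(x, "MassResult")) {
    list(average_mass = x@averageMass,
         monoisotopic_mass = x@monoisotopicMass,
         maldi_mz = x@maldiMz, maldi_mz_rounded = round(x@maldiMz))
  } else if (is.data.frame(x) || is.list(x)) {
    x
  } else {
    stopIO(sprintf("cannot serialize object of class %s", class(x)[1]))
  }
}

#' Write a report object as JSON
#'
#' Serializes \code{\linkS4class{ConstraintReport}},
#' \code{\linkS4class{HplcFit}}, \code{\linkS4class{MassResult}},
#' mutation-log data frames, or plain lists. All coordinates are 0-based
#' half-open.
#'
#' @param x the object to serialize.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeJsonReport <- function(x, file) {
  jsonlite::write_json(reportAsList(x), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(file)
}
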