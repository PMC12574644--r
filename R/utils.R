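# Internal helpers: condition constructors, seeded evaluation, base ops.

phageError <- function(msg, class, ...) {
  structure(class = c(class, "phageDesign_error", "error", "condition"),
            list(message = msg, call = sys.call(-1), ...))
}

stopInfeasible <- function(msg, ...) {
  stop(phageError(msg, "phageDesign_infeasible", ...))
}

stopUnresolvable <- function(msg, ...) {
  stop(phageError(msg, "phageDesign_unresolvable", ...))
}

stopIO <- function(msg, ...) {
  stop(phageError(msg, "phageDesign_io", ...))
}

# Evaluate expr with the RNG seeded, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (lets design() drive every
# stage from a single seeded generator).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# Coerce character / DNAString / DNAStringSet (first element) to a plain
# upper-case character scalar and check the alphabet.
asBases <- function(seq) {
  if (is(seq, "XString") || is(seq, "XStringSet"))
    seq <- as.character(seq)
  if (length(seq) != 1L || !is.character(seq))
    stopIO("expected a single nucleotide sequence")
  s <- toupper(seq)
  if (nchar(s) == 0L) stopIO("empty nucleotide sequence")
  bad <- gsub("[ACGT]", "", s)
  if (nchar(bad) > 0L)
    stopIO(sprintf("sequence contains non-ACGT characters: '%s'",
                   substr(bad, 1L, 10L)))
  s
}

# Reverse complement of a plain character sequence (delegates to
# Biostrings, the canonical implementation).
revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# 1-based start positions of all (non-overlapping-impossible) CG dimers.
cgDimerStarts <- function(s) {
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

# 1-based [start, end] intervals of hexamer-set motif occurrences.
# protectedOnly additionally requires every position to be mask-protected
# (true only for deliberately installed cassettes).
motifRanges <- function(s, hexamerSet, mask = NULL, protectedOnly = FALSE) {
  out <- matrix(integer(), ncol = 2L)
  for (h in hexamerSet) {
    m <- gregexpr(h, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    st <- as.integer(m)
    if (protectedOnly && !is.null(mask))
      st <- st[vapply(st, function(p) all(mask[p:(p + 5L)]), logical(1))]
    if (length(st)) out <- rbind(out, cbind(st, st + 5L))
  }
  out
}

# Does the 1-based window [w, w+width-1] overlap any interval?
overlapsRanges <- function(w, width, ranges) {
  if (is.null(ranges) || nrow(ranges) == 0L) return(FALSE)
  any(ranges[, 1L] <= w + width - 1L & ranges[, 2L] >= w)
}

# TRUE per repeat family iff every instance overlaps a motif interval
# (such families are induced by the installed cassettes themselves).
motifInducedRepeats <- function(reps, ranges) {
  if (nrow(reps) == 0L) return(logical(0))
  vapply(seq_len(nrow(reps)), function(i) {
    all(vapply(reps$positions[[i]] + 1L, overlapsRanges, logical(1),
               width = reps$length[i], ranges = ranges))
  }, logical(1))
}

emptyRepeatFrame <- function() {
  data.frame(kmer = character(), length = integer(),
             positions = I(list()), stringsAsFactors = FALSE)
}

emptyHairpinFrame <- function() {
  data.frame(stemLen = integer(), arm1Start = integer(),
             arm2Start = integer())
}

emptyMutationLog <- function() {
  data.frame(position = integer(), from = character(), to = character(),
             reason = character(), stringsAsFactors = FALSE)
}
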