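#' Generate a CG-placed scaffold sequence
#'
#' Emits a sequence of exactly \code{spec@lengthNt} nucleotides carrying
#' exactly \code{round(cgFraction * lengthNt / 2)} CG dimers. Dimers are
#' spread evenly along the sequence with seeded jitter (gap lengths drawn
#' within +/- 25\% of the mean gap and then rescaled to the exact total),
#' which hits the dimer count exactly while avoiding the periodicity that
#' uniform spacing would imprint. The flanking stretches between dimers
#' are sampled from \{A,C,G,T\} under three rules: they contain no
#' internal CG dimer (so the CG census is exactly the placed count), a
#' flank that follows a dimer does not start with C, and a flank that
#' precedes a dimer does not end with G.
#'
#' @param spec a \code{\linkS4class{DesignSpec}}.
#' @param seed seed for placement and flank sampling; defaults to
#'   \code{spec@seed}. Pass \code{NULL} to draw from the current RNG
#'   stream (used internally by \code{\link{designSsDNA}}).
#' To keep the downstream repeat-repair load small even when dimers are
#' dense (a 6261-nt design carries 814 dimers about 5.7 nt apart, so
#' thousands of 9-windows span two dimers and share the rigid CG
#' anchors), each flank is accepted by rejection sampling: a candidate
#' that would duplicate any 9-mer already present in the growing
#' scaffold is redrawn (up to a bounded number of tries), so repeats are
#' avoided at construction rather than mutated away afterwards.
#'
#' @return a list with \code{sequence} (character scalar) and
#'   \code{mask} (logical vector; \code{TRUE} at every placed dimer
#'   position, meaning repair passes must not touch it).
#' @examples
#' sc <- scaffoldSequence(DesignSpec(1415, 0.27, seed = 1))
#' nchar(sc$sequence)
#' @export
scaffoldSequence <- function(spec, seed = spec@seed) {
  validObject(spec)
  L <- spec@lengthNt
  k <- spec@minRepeatLen
  nCG <- as.integer(round(spec@cgFraction * L / 2))
  if (2L * nCG > L)
    stopInfeasible(sprintf(
      "cannot place %d CG dimers in %d nt (needs %d nt)", nCG, L, 2L * nCG))
  withSeed(seed, {
    flankTotal <- L - 2L * nCG
    nGaps <- nCG + 1L
    gaps <- if (nCG == 0L) L else jitteredGapSizes(flankTotal, nGaps)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    built <- ""
    appendAccepted <- function(cand) {
      for (w in newWindows(built, cand, k))
        assign(w, TRUE, envir = seen)
      built <<- paste0(built, cand)
    }
    for (i in seq_len(nGaps)) {
      remaining <- gaps[i]
      first <- TRUE
      repeat {
        csize <- min(24L, remaining)       # rejection granularity
        last <- csize == remaining
        withCG <- last && i <= nCG
        piece <- NULL
        for (try in seq_len(40L)) {
          fl <- sampleFlank(csize,
                            noStartC = first && i > 1L, # follows a dimer
                            noEndG   = last && i < nGaps, # precedes one
                            noStartG = endsWith(built, "C"))
          cand <- if (withCG) paste0(fl, "CG") else fl
          wins <- newWindows(built, cand, k)
          piece <- cand   # keep the last draw if every try collides
          if (!anyDuplicated(wins) &&
              !any(vapply(wins, exists, logical(1), envir = seen,
                          inherits = FALSE)))
            break
        }
        appendAccepted(piece)
        remaining <- remaining - csize
        first <- FALSE
        if (last) break
      }
    }
    mask <- rep(FALSE, L)
    if (nCG > 0L) {
      # dimer i starts right after gaps 1..i and dimers 1..(i-1)
      dimerStarts <- cumsum(gaps[seq_len(nCG)] +
                              c(0L, rep(2L, nCG - 1L))) + 1L
      mask[c(dimerStarts, dimerStarts + 1L)] <- TRUE
    }
    list(sequence = built, mask = mask)
  })
}

# The k-mers completed by appending `piece` to `prefix` (i.e. every
# k-window that ends inside the appended region).
newWindows <- function(prefix, piece, k) {
  np <- nchar(prefix)
  ctx <- paste0(substr(prefix, max(1L, np - k + 2L), np), piece)
  nc <- nchar(ctx)
  if (nc < k) return(character(0))
  starts <- seq_len(nc - k + 1L)
  substring(ctx, starts, starts + k - 1L)
}

# Split flankTotal into nGaps non-negative integers, each near the mean
# with +/-25% jitter, summing exactly (largest-remainder apportionment).
jitteredGapSizes <- function(flankTotal, nGaps) {
  if (flankTotal == 0L) return(rep(0L, nGaps))
  w <- stats::runif(nGaps, 0.75, 1.25)
  raw <- w / sum(w) * flankTotal
  sizes <- floor(raw)
  short <- flankTotal - sum(sizes)
  if (short > 0L) {
    bump <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[bump] <- sizes[bump] + 1L
  }
  as.integer(sizes)
}

# Sample a flank of given length containing no internal CG, optionally
# barred from starting with C / ending with G. A and T are always legal,
# so the constraints are always satisfiable.
sampleFlank <- function(len, noStartC, noEndG, noStartG = FALSE) {
  if (len == 0L) return("")
  out <- character(len)
  prev <- ""
  for (i in seq_len(len)) {
    allowed <- DNA_BASES
    if (i == 1L && noStartC) allowed <- setdiff(allowed, "C")
    if (i == 1L && noStartG) allowed <- setdiff(allowed, "G")
    if (prev == "C") allowed <- setdiff(allowed, "G")
    if (i == len && noEndG) allowed <- setdiff(allowed, "G")
    prev <- allowed[sample.int(length(allowed), 1L)]
    out[i] <- prev
  }
  paste(out, collapse = "")
}

#' Find direct repeats
#'
#' Reports every k-mer (k = \code{minLen}) occurring at two or more
#' distinct offsets. Any repeated stretch of length >= \code{minLen}
#' necessarily contains a repeated \code{minLen}-mer, so scanning at
#' exactly k covers "\code{minLen} bases or longer" completely.
#'
#' @param seq character, \code{DNAString}, or anything coercible.
#' @param minLen repeat seed length (default 9).
#' @return a data.frame with columns \code{kmer}, \code{length}, and a
#'   list column \code{positions} of sorted 0-based start offsets
#'   (>= 2 per family), ordered by first occurrence. Zero rows means
#'   repeat-free; a sequence shorter than \code{minLen} yields zero rows.
#' @examples
#' findDirectRepeats(strrep("A", 20), 9)
#' @export
findDirectRepeats <- function(seq, minLen = 9L) {
  s <- asBases(seq)
  n <- nchar(s)
  k <- as.integer(minLen)
  if (n < k) return(emptyRepeatFrame())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  fams <- split(starts - 1L, kmers)
  fams <- fams[lengths(fams) >= 2L]
  if (length(fams) == 0L) return(emptyRepeatFrame())
  fams <- lapply(fams, sort)
  ord <- order(vapply(fams, `[`, integer(1), 1L))
  fams <- fams[ord]
  data.frame(kmer = names(fams), length = k,
             positions = I(unname(fams)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find inverted repeats (hairpin stems)
#'
#' Reports every pair of length-\code{minStem} windows where one window
#' equals the reverse complement of the other — the exact-complementarity
#' definition of a hairpin stem, with no minimum loop separation (a
#' conservative superset of foldable hairpins). A window is never paired
#' with itself at identical coordinates.
#'
#' @param seq character, \code{DNAString}, or anything coercible.
#' @param minStem stem window length (default 13, i.e. stems longer than
#'   12 bases).
#' @return a data.frame with columns \code{stemLen}, \code{arm1Start},
#'   \code{arm2Start} (0-based, \code{arm1Start < arm2Start}), sorted by
#'   arm1 then arm2. Zero rows means hairpin-free.
#' @examples
#' s <- "ATCGGATTACCAG"
#' findInvertedRepeats(paste0(s, revCompSequence(s)), 13)
#' @export
findInvertedRepeats <- function(seq, minStem = 13L) {
  s <- asBases(seq)
  n <- nchar(s)
  k <- as.integer(minStem)
  if (n < k) return(emptyHairpinFrame())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  rcs <- revComp(s)
  # revcomp of window [i, i+k-1] is the window [n-i-k+2, n-i+1] of rcs
  rcKmers <- substring(rcs, n - starts - k + 2L, n - starts + 1L)
  uk <- unique(kmers)
  gid <- match(kmers, uk)
  gidRC <- match(rcKmers, uk)
  members <- split(starts, gid)
  hits <- vector("list", length(starts))
  for (i in starts) {
    g <- gidRC[i]
    if (is.na(g)) next
    js <- members[[as.character(g)]]
    js <- js[js > i]
    if (length(js))
      hits[[i]] <- data.frame(stemLen = k, arm1Start = i - 1L,
                              arm2Start = js - 1L)
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L) return(emptyHairpinFrame())
  out <- do.call(rbind, hits)
  out <- out[order(out$arm1Start, out$arm2Start), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Reverse complement of a nucleotide sequence
#' @param seq character or \code{DNAString}.
#' @return character scalar.
#' @export
revCompSequence <- function(seq) revComp(asBases(seq))

# Pick the mutation position for one flagged window set: a random
# unprotected A/T in the first window, falling back to later windows.
# A deterministic (leftmost) choice can cycle — flipping a base may spawn
# a new repeat family whose deterministic fix flips the same base back —
# so the pick is randomized (seeded by the caller's RNG stream).
# Returns the 1-based position or NA.
pickMutablePosition <- function(chars, mask, windowStarts, width) {
  for (w in windowStarts) {
    idx <- w:(w + width - 1L)
    cand <- idx[chars[idx] %in% c("A", "T") & !mask[idx]]
    if (length(cand) == 1L) return(cand)
    if (length(cand)) return(cand[sample.int(length(cand), 1L)])
  }
  NA_integer_
}

# Core repair loop. Each sweep rescans the sequence, then fixes every
# open family once: a seeded-random unprotected A/T in the family's
# first instance (falling back to later instances) is flipped. One
# mutation per family per sweep keeps progress spread across the
# sequence (attacking only the lowest-offset family can hammer a
# near-frozen window forever while the rest wait) and keeps the number
# of full rescans proportional to the sweep count rather than the
# mutation count. A family with no unprotected A/T in any instance is
# permanently unfixable (no legal mutation can ever touch its windows)
# and raises immediately.
repairPass <- function(seq, mask, minLen, kind = c("repeat", "hairpin"),
                       maxIter = NULL, exemptRanges = NULL) {
  kind <- match.arg(kind)
  s <- asBases(seq)
  n <- nchar(s)
  if (length(mask) != n)
    stopIO("mask length does not match sequence length")
  if (is.null(maxIter)) maxIter <- 10L * n
  chars <- strsplit(s, "")[[1]]
  log <- vector("list", 0L)
  muts <- 0L
  bestLoad <- Inf        # stall detection: running minimum of open hits
  staleSweeps <- 0L
  repeat {
    s <- paste(chars, collapse = "")
    if (kind == "repeat") {
      hits <- findDirectRepeats(s, minLen)
      if (nrow(hits) > 0L && !is.null(exemptRanges))
        hits <- hits[!motifInducedRepeats(hits, exemptRanges), ,
                     drop = FALSE]
      if (nrow(hits) == 0L) break
      load <- sum(lengths(hits$positions))
      famWindows <- lapply(hits$positions, function(p) p + 1L)
      width <- hits$length
      what <- sprintf("repeat '%s' at offsets %s", hits$kmer,
                      vapply(hits$positions, function(p)
                        paste(p, collapse = ","), character(1)))
    } else {
      hits <- findInvertedRepeats(s, minLen)
      if (nrow(hits) == 0L) break
      load <- nrow(hits)
      famWindows <- lapply(seq_len(nrow(hits)), function(i)
        c(hits$arm1Start[i], hits$arm2Start[i]) + 1L)
      width <- hits$stemLen
      what <- sprintf("hairpin arms at offsets %d/%d (stem %d)",
                      hits$arm1Start, hits$arm2Start, hits$stemLen)
    }
    if (load < bestLoad) {
      bestLoad <- load
      staleSweeps <- 0L
    } else staleSweeps <- staleSweeps + 1L
    if (staleSweeps > 30L)
      stopUnresolvable(sprintf(
        "%s repair stalled (%d open hits after %d mutations)",
        kind, load, muts))
    touched <- logical(n)
    for (i in seq_along(famWindows)) {
      p <- pickMutablePosition(chars, mask | touched, famWindows[[i]],
                               width[i])
      if (is.na(p)) {
        # retry without the same-sweep exclusion before declaring dead
        p <- pickMutablePosition(chars, mask, famWindows[[i]], width[i])
        if (is.na(p))
          stopUnresolvable(sprintf(
            "unresolvable %s: no unprotected A/T in %s", kind, what[i]))
        next   # window already touched this sweep; rescan first
      }
      muts <- muts + 1L
      if (muts > maxIter)
        stopUnresolvable(sprintf(
          "%s repair exceeded the mutation cap (%d)", kind, maxIter))
      touched[p] <- TRUE
      from <- chars[p]
      to <- if (from == "A") "T" else "A"
      chars[p] <- to
      log[[length(log) + 1L]] <- data.frame(
        position = p - 1L, from = from, to = to, reason = kind,
        stringsAsFactors = FALSE)
    }
  }
  log <- if (length(log)) do.call(rbind, log) else emptyMutationLog()
  list(sequence = paste(chars, collapse = ""), log = log)
}

#' Eliminate direct repeats by A/T transversion
#'
#' Repeated stretches are removed by mutating the leftmost unprotected A
#' or T within the first instance of the offending repeat to T or A
#' (falling back to later instances when the first is fully protected),
#' rescanning after every mutation until the sequence is repeat-free.
#' A<->T substitutions cannot create or destroy C or G, so the C count,
#' G count and CG-dimer census are invariant under this pass.
#'
#' @param seq sequence to repair.
#' @param mask logical protected-position mask (placed dimers, inserted
#'   hexamers); \code{NULL} means nothing is protected.
#' @param minLen minimum repeat length (default 9).
#' @param maxIter mutation cap; default 10x sequence length.
#' @param seed optional seed for the randomized within-window mutation
#'   pick; \code{NULL} uses the current RNG stream (as
#'   \code{\link{designSsDNA}} does).
#' @param exemptRanges optional 2-column matrix of 1-based motif-cassette
#'   intervals; repeat families whose every instance overlaps one are
#'   motif-induced and skipped (see \code{\link{insertCpgHexamers}}).
#' @return list with \code{sequence} and \code{log} (a mutation
#'   data.frame: 0-based \code{position}, \code{from}, \code{to},
#'   \code{reason}).
#' @export
eliminateRepeats <- function(seq, mask = NULL, minLen = 9L, maxIter = NULL,
                             seed = NULL, exemptRanges = NULL) {
  s <- asBases(seq)
  if (is.null(mask)) mask <- rep(FALSE, nchar(s))
  withSeed(seed,
           repairPass(s, mask, minLen, "repeat", maxIter, exemptRanges))
}

#' Eliminate hairpin stems by A/T transversion
#'
#' As \code{\link{eliminateRepeats}}, applied to inverted-repeat windows:
#' the mutation targets the leftmost unprotected A/T in the first
#' (leftmost) arm, falling back to the second arm. Any single base change
#' in an arm breaks that window pair's exact complementarity.
#'
#' @inheritParams eliminateRepeats
#' @param minStem minimum stem length (default 13).
#' @return list with \code{sequence} and \code{log}.
#' @export
eliminateHairpins <- function(seq, mask = NULL, minStem = 13L,
                              maxIter = NULL, seed = NULL) {
  s <- asBases(seq)
  if (is.null(mask)) mask <- rep(FALSE, nchar(s))
  withSeed(seed, repairPass(s, mask, minStem, "hairpin", maxIter))
}

#' Convert CG dimers into canonical CpG hexamers
#'
#' Upgrades \code{round(fraction * nCG)} CG dimers, chosen uniformly at
#' random (seeded), into canonical CpG hexamer contexts. In the default
#' \code{"insert"} mode each chosen 2-nt CG is replaced by a 6-nt
#' hexamer, growing the sequence by 4 nt per site — consistent with the
#' converted phage being longer than its parent. Hexamers alternate
#' through \code{hexamerSet} starting at a seed-determined member, which
#' limits repeat creation. Each hexamer carries exactly one CG and
#' starts with A/G and ends with T, so junctions cannot create a CG and
#' the total CG-dimer count is unchanged. All six positions of every
#' inserted hexamer are protected in the returned mask. In
#' \code{"in_place"} mode the 6-nt window centered on the dimer is
#' rewritten instead (length preserved); only dimers with 2 nt of
#' unprotected, dimer-free context on each side are eligible.
#'
#' Installing the same 6-mer at many sites necessarily repeats it;
#' repeat families induced entirely by the cassettes are therefore
#' classified motif-induced and tolerated (see
#' \code{\link{validateDesign}}). What must not happen is a repeat that
#' pairs a cassette window with cassette-free sequence while carrying no
#' unprotected A/T anywhere — no legal mutation could break it. The
#' insertion stage therefore audits its own output: it scans for such
#' unrepairable repeat or hairpin windows and re-draws the offending
#' site from the unconverted pool until none remains (the converted-site
#' count stays exact throughout). Repairable repeats and hairpins are
#' left for the caller's re-elimination passes
#' (\code{\link{designSsDNA}} runs them with the returned mask).
#'
#' @param seq sequence containing at least one CG dimer (when
#'   \code{fraction > 0}).
#' @param mask logical protected mask; \code{NULL} = none.
#' @param fraction fraction of CG dimers to convert, in \code{[0, 1]}.
#' @param hexamerSet candidate hexamers (default AACGTT/GACGTT).
#' @param seed seed for site choice; \code{NULL} = current RNG stream.
#' @param mode \code{"insert"} (default, +4 nt per site) or
#'   \code{"in_place"} (length-preserving context rewrite; only dimers
#'   with 2 nt of unprotected, dimer-free context on each side are
#'   eligible, and no site audit is performed).
#' @param minRepeatLen,minStemLen thresholds used by the site audit.
#' @return list with \code{sequence}, \code{mask}, and \code{log} (one
#'   row per converted site: 0-based dimer offset in the input, the
#'   hexamer written, reason \code{"hexamer"}).
#' @export
insertCpgHexamers <- function(seq, mask = NULL, fraction,
                              hexamerSet = c("AACGTT", "GACGTT"),
                              seed = NULL, mode = c("insert", "in_place"),
                              minRepeatLen = 9L, minStemLen = 13L) {
  mode <- match.arg(mode)
  s <- asBases(seq)
  n <- nchar(s)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (fraction < 0 || fraction > 1) stopIO("fraction must lie in [0, 1]")
  dimers <- cgDimerStarts(s)
  nCG <- length(dimers)
  if (fraction > 0 && nCG == 0L)
    stopInfeasible("hexamer conversion requested but the sequence has no CG dimer")
  nHex <- as.integer(round(fraction * nCG))
  if (nHex == 0L)
    return(list(sequence = s, mask = mask,
                log = data.frame(position = integer(), hexamer = character(),
                                 reason = character(),
                                 stringsAsFactors = FALSE)))
  withSeed(seed, {
    if (mode == "in_place") {
      # rewriting [p-2, p+3] must not form a CG across either junction
      safeMotifs <- function(p) {
        before <- if (p > 3L) substr(s, p - 3L, p - 3L) else ""
        after <- if (p + 4L <= n) substr(s, p + 4L, p + 4L) else ""
        hexamerSet[!(before == "C" & startsWith(hexamerSet, "G")) &
                     !(endsWith(hexamerSet, "C") & after == "G")]
      }
      ok <- vapply(dimers, function(p) {
        if (p < 3L || p + 3L > n) return(FALSE)
        ctx <- c(p - 2L, p - 1L, p + 2L, p + 3L)
        !any(mask[ctx]) && !any(ctx %in% c(dimers, dimers + 1L)) &&
          length(safeMotifs(p)) > 0L
      }, logical(1))
      eligible <- dimers[ok]
      if (length(eligible) < nHex)
        stopInfeasible(sprintf(
          "in_place conversion needs %d eligible dimers but only %d have free context",
          nHex, length(eligible)))
      sites <- sort(eligible[sample.int(length(eligible), nHex)])
      first <- sample.int(length(hexamerSet), 1L)
      hex <- hexamerSet[((first - 1L + seq_len(nHex) - 1L) %%
                           length(hexamerSet)) + 1L]
      for (j in seq_len(nHex)) {
        safe <- safeMotifs(sites[j])
        if (!hex[j] %in% safe) hex[j] <- safe[1L]
      }
      chars <- strsplit(s, "")[[1]]
      newMask <- mask
      for (j in seq_len(nHex)) {
        w <- (sites[j] - 2L):(sites[j] + 3L)
        chars[w] <- strsplit(hex[j], "")[[1]]
        newMask[w] <- TRUE
      }
      return(list(sequence = paste(chars, collapse = ""), mask = newMask,
                  log = data.frame(position = sites - 1L, hexamer = hex,
                                   reason = "hexamer",
                                   stringsAsFactors = FALSE)))
    }
    chosen <- dimers[sample.int(nCG, nHex)]
    first <- sample.int(length(hexamerSet), 1L)
    for (round in seq_len(200L)) {
      sites <- sort(chosen)
      hex <- hexamerSet[((first - 1L + seq_len(nHex) - 1L) %%
                           length(hexamerSet)) + 1L]
      # a motif may not form a new CG across either junction (e.g. a
      # C-ending flank followed by the G-initial motif); reassign such
      # sites to a junction-safe motif or swap them out
      swapOut <- NA_integer_
      for (j in seq_len(nHex)) {
        ok <- junctionSafe(s, sites[j], hex[j])
        if (!ok) {
          alt <- hexamerSet[vapply(hexamerSet, junctionSafe,
                                   logical(1), s = s, site = sites[j])]
          if (length(alt)) hex[j] <- alt[1L] else swapOut <- sites[j]
        }
        if (!is.na(swapOut)) break
      }
      if (!is.na(swapOut)) {
        pool <- setdiff(dimers, chosen)
        if (length(pool) == 0L)
          stopUnresolvable(
            "hexamer conversion: no unconverted dimer left to swap in")
        chosen <- c(setdiff(chosen, swapOut),
                    pool[sample.int(length(pool), 1L)])
        next
      }
      built <- buildWithHexamers(s, mask, sites, hex)
      badSite <- findUnrepairableSite(built, minRepeatLen, minStemLen)
      if (is.na(badSite))
        return(list(sequence = built$sequence, mask = built$mask,
                    log = data.frame(position = sites - 1L, hexamer = hex,
                                     reason = "hexamer",
                                     stringsAsFactors = FALSE)))
      pool <- setdiff(dimers, chosen)
      if (length(pool) == 0L)
        stopUnresolvable(
          "hexamer conversion: no unconverted dimer left to swap in")
      chosen <- c(setdiff(chosen, badSite),
                  pool[sample.int(length(pool), 1L)])
    }
    stopUnresolvable(
      "hexamer conversion could not find a repairable site placement")
  })
}

# Would writing motif m in place of the CG at `site` leave the junctions
# CG-free? (The motif body itself carries exactly one CG by validity.)
junctionSafe <- function(s, site, m) {
  n <- nchar(s)
  before <- if (site > 1L) substr(s, site - 1L, site - 1L) else ""
  after <- if (site + 2L <= n) substr(s, site + 2L, site + 2L) else ""
  !(before == "C" && startsWith(m, "G")) &&
    !(endsWith(m, "C") && after == "G")
}

# Assemble the sequence with hexamers replacing the CG at each (sorted,
# 1-based) site; returns the new sequence, mask, and the 1-based start
# of each inserted hexamer in the new coordinates plus its origin site.
buildWithHexamers <- function(s, mask, sites, hex) {
  n <- nchar(s)
  pieces <- character(0)
  maskPieces <- list()
  prev <- 1L
  for (j in seq_along(sites)) {
    p <- sites[j]
    if (p > prev) {
      pieces <- c(pieces, substr(s, prev, p - 1L))
      maskPieces <- c(maskPieces, list(mask[prev:(p - 1L)]))
    }
    pieces <- c(pieces, hex[j])
    maskPieces <- c(maskPieces, list(rep(TRUE, 6L)))
    prev <- p + 2L
  }
  if (prev <= n) {
    pieces <- c(pieces, substr(s, prev, n))
    maskPieces <- c(maskPieces, list(mask[prev:n]))
  }
  list(sequence = paste(pieces, collapse = ""),
       mask = unlist(maskPieces),
       hexStarts = sites + 4L * (seq_along(sites) - 1L),
       origSites = sites)
}

# Scan a freshly built hexamer-converted sequence for repeat or hairpin
# windows that A/T repair cannot break (no instance holds an unprotected
# A/T). Returns the 1-based origin site of an overlapping hexamer to
# swap out, or NA if everything is repairable.
findUnrepairableSite <- function(built, minRepeatLen, minStemLen) {
  chars <- strsplit(built$sequence, "")[[1]]
  mask <- built$mask
  mutable <- function(w, width) {
    idx <- w:(w + width - 1L)
    any(chars[idx] %in% c("A", "T") & !mask[idx])
  }
  siteFor <- function(w, width) {
    ov <- which(built$hexStarts <= w + width - 1L &
                  built$hexStarts + 5L >= w)
    if (length(ov)) built$origSites[ov[1L]] else NA_integer_
  }
  ranges <- cbind(built$hexStarts, built$hexStarts + 5L)
  reps <- findDirectRepeats(built$sequence, minRepeatLen)
  if (nrow(reps) > 0L)
    reps <- reps[!motifInducedRepeats(reps, ranges), , drop = FALSE]
  for (i in seq_len(nrow(reps))) {
    wins <- reps$positions[[i]] + 1L
    if (!any(vapply(wins, mutable, logical(1), width = reps$length[i]))) {
      for (w in wins) {
        site <- siteFor(w, reps$length[i])
        if (!is.na(site)) return(site)
      }
    }
  }
  hps <- findInvertedRepeats(built$sequence, minStemLen)
  for (i in seq_len(nrow(hps))) {
    wins <- c(hps$arm1Start[i], hps$arm2Start[i]) + 1L
    if (!any(vapply(wins, mutable, logical(1), width = hps$stemLen[i]))) {
      for (w in wins) {
        site <- siteFor(w, hps$stemLen[i])
        if (!is.na(site)) return(site)
      }
    }
  }
  NA_integer_
}

#' Audit a sequence against the design constraints
#'
#' Computes the full constraint report by scanning: CG-dimer count and
#' realized fraction (raw and rounded to the nearest integer percent),
#' the number and percentage of dimers embedded in hexamer-set motifs,
#' all remaining direct repeats and hairpin stems, and flank boundary
#' violations (a flank base C immediately after a dimer, or G immediately
#' before one). \code{clean} is \code{TRUE} iff repeats, hairpins and
#' boundary violations are all empty.
#'
#' For a spec with \code{hexamerFraction > 0}, repeat families whose
#' every instance overlaps a hexamer-set motif occurrence are classified
#' motif-induced and moved to the \code{motifRepeats} slot: installing
#' the same 6-mer cassette at dozens of sites necessarily repeats it,
#' and the A/T-only repair rule (which preserves the CG census) cannot
#' — and should not — remove the cassettes themselves. Such families do
#' not affect \code{clean}. Hairpins are never exempted.
#'
#' @param seq sequence to audit.
#' @param spec the \code{\linkS4class{DesignSpec}} providing thresholds
#'   and the hexamer set.
#' @return a \code{\linkS4class{ConstraintReport}}.
#' @examples
#' validateDesign("CGCG", DesignSpec(4, 1.0, seed = 1))
#' @export
validateDesign <- function(seq, spec) {
  s <- asBases(seq)
  n <- nchar(s)
  dimers <- cgDimerStarts(s)
  nCg <- length(dimers)
  frac <- if (n > 0) 2 * nCg / n else 0
  dimerPos <- c(dimers, dimers + 1L)
  chars <- strsplit(s, "")[[1]]

  # hexamer-embedded dimers: CG occurrences covered by a motif occurrence
  embedded <- integer()
  for (h in spec@hexamerSet) {
    cgOff <- cgDimerStarts(h)[1L]           # offset of CG inside motif
    m <- gregexpr(h, s, fixed = TRUE)[[1]]
    if (m[1] != -1L) embedded <- c(embedded, as.integer(m) + cgOff - 1L)
  }
  embedded <- intersect(unique(embedded), dimers)
  nEmb <- length(embedded)

  viol <- integer()
  for (p in dimers) {
    after <- p + 2L
    if (after <= n && !(after %in% dimerPos) && chars[after] == "C")
      viol <- c(viol, after - 1L)
    before <- p - 1L
    if (before >= 1L && !(before %in% dimerPos) && chars[before] == "G")
      viol <- c(viol, before - 1L)
  }
  reps <- findDirectRepeats(s, spec@minRepeatLen)
  motifReps <- emptyRepeatFrame()
  if (spec@hexamerFraction > 0 && nrow(reps) > 0L) {
    ranges <- motifRanges(s, spec@hexamerSet)
    induced <- motifInducedRepeats(reps, ranges)
    motifReps <- reps[induced, , drop = FALSE]
    reps <- reps[!induced, , drop = FALSE]
    row.names(reps) <- row.names(motifReps) <- NULL
  }
  hps <- findInvertedRepeats(s, spec@minStemLen)
  new("ConstraintReport",
      lengthNt = n,
      nCgDimers = nCg,
      cgFractionRealized = frac,
      cgPercentRounded = as.integer(round(100 * frac)),
      nHexamerEmbedded = nEmb,
      hexamerPctOfCg = if (nCg > 0) 100 * nEmb / nCg else 0,
      repeats = reps,
      motifRepeats = motifReps,
      hairpins = hps,
      boundaryViolations = sort(unique(viol)),
      clean = nrow(reps) == 0L && nrow(hps) == 0L && length(viol) == 0L)
}

#' Design a reprogrammed ssDNA end to end
#'
#' Runs the full programming pipeline: scaffold with exact CG placement,
#' iterative elimination of direct repeats and hairpin stems by A/T
#' transversion, optional conversion of a fraction of CG dimers into
#' canonical CpG hexamers, re-elimination with the hexamer motifs
#' protected, and a final constraint audit. Because the hexamer census
#' is a controlled variable, chance canonical contexts (a dimer whose
#' flanks happen to spell a hexamer-set motif) are scrubbed by the same
#' CG-conserving A/T flips, so the validator's motif census equals
#' exactly the number of installed cassettes at every stage. The result is deterministic
#' given \code{spec@seed}; on an unresolvable repair the pipeline retries
#' with a fresh scaffold (seed advanced by one) up to \code{restarts}
#' times before surfacing the error.
#'
#' The final length is \code{lengthNt + 4 * round(hexamerFraction * nCG)}
#' in the default insertion mode.
#'
#' @param spec a \code{\linkS4class{DesignSpec}}.
#' @param restarts maximum fresh-scaffold retries (default 5).
#' @param hexamerMode \code{"insert"} or \code{"in_place"}; see
#'   \code{\link{insertCpgHexamers}}.
#' @return a list with \code{sequence}, \code{report} (a clean
#'   \code{\linkS4class{ConstraintReport}}), \code{log} (all repair
#'   mutations), \code{hexamerLog}, and \code{mask}.
#' @examples
#' d <- designSsDNA(DesignSpec(300, 0.27, seed = 1))
#' isClean(d$report)
#' @export
designSsDNA <- function(spec, restarts = 5L, hexamerMode = "insert") {
  validObject(spec)
  lastErr <- NULL
  for (attempt in 0:restarts) {
    res <- tryCatch(
      designOnce(spec, spec@seed + attempt, hexamerMode),
      phageDesign_unresolvable = function(e) e)
    if (!inherits(res, "condition")) return(res)
    lastErr <- res
  }
  stop(lastErr)
}

designOnce <- function(spec, seed, hexamerMode) {
  withSeed(seed, {
    sc <- scaffoldSequence(spec, seed = NULL)
    s <- sc$sequence
    mask <- sc$mask
    log <- emptyMutationLog()
    hexLog <- data.frame(position = integer(), hexamer = character(),
                         reason = character(), stringsAsFactors = FALSE)
    res <- repairAndScrub(s, mask, spec, exemptRanges = NULL)
    s <- res$sequence
    log <- rbind(log, res$log)
    nHexExpected <- 0L
    if (spec@hexamerFraction > 0) {
      ins <- insertCpgHexamers(s, mask, spec@hexamerFraction,
                               spec@hexamerSet, seed = NULL,
                               mode = hexamerMode,
                               minRepeatLen = spec@minRepeatLen,
                               minStemLen = spec@minStemLen)
      s <- ins$sequence
      mask <- ins$mask
      hexLog <- ins$log
      nHexExpected <- nrow(hexLog)
      cassettes <- motifRanges(s, spec@hexamerSet, mask,
                               protectedOnly = TRUE)
      res <- repairAndScrub(s, mask, spec, exemptRanges = cassettes)
      s <- res$sequence
      log <- rbind(log, res$log)
    }
    report <- validateDesign(s, spec)
    if (!report@clean)
      stopUnresolvable("design pipeline ended with a non-clean report")
    if (report@nHexamerEmbedded != nHexExpected)
      stopUnresolvable(sprintf(
        "hexamer census %d does not match the %d installed cassettes",
        report@nHexamerEmbedded, nHexExpected))
    list(sequence = s, report = report, log = log, hexamerLog = hexLog,
         mask = mask)
  })
}

# Alternate constraint repair with chance-motif scrubbing until both are
# quiescent. The hexamer census is a controlled variable of the design:
# a dimer whose flanks happen to spell a canonical hexamer context would
# shift the measured motif content, so every hexamer-set occurrence that
# is not an installed (protected) cassette is destroyed by flipping one
# of its unprotected A/T bases — the same CG-conserving move the repair
# passes use. Repair can recreate chance motifs and scrubbing can create
# repeats, hence the fixpoint loop.
repairAndScrub <- function(s, mask, spec, exemptRanges = NULL,
                           maxRounds = 10L) {
  log <- emptyMutationLog()
  for (i in seq_len(maxRounds)) {
    r <- repairUntilClean(s, mask, spec, exemptRanges = exemptRanges)
    s <- r$sequence
    log <- rbind(log, r$log)
    sc <- scrubChanceMotifs(s, mask, spec@hexamerSet)
    s <- sc$sequence
    log <- rbind(log, sc$log)
    if (nrow(sc$log) == 0L) return(list(sequence = s, log = log))
  }
  stopUnresolvable("chance-motif scrubbing did not stabilize")
}

scrubChanceMotifs <- function(s, mask, hexamerSet, maxRounds = 200L) {
  log <- vector("list", 0L)
  chars <- strsplit(s, "")[[1]]
  for (i in seq_len(maxRounds)) {
    cur <- paste(chars, collapse = "")
    ranges <- motifRanges(cur, hexamerSet)
    if (nrow(ranges) > 0L) {
      chance <- ranges[!vapply(ranges[, 1L], function(p)
        all(mask[p:(p + 5L)]), logical(1)), , drop = FALSE]
    } else chance <- ranges
    if (nrow(chance) == 0L)
      return(list(sequence = cur,
                  log = if (length(log)) do.call(rbind, log)
                        else emptyMutationLog()))
    p <- pickMutablePosition(chars, mask, chance[1L, 1L], 6L)
    if (is.na(p))
      stopUnresolvable(sprintf(
        "chance hexamer context at offset %d has no unprotected A/T",
        chance[1L, 1L] - 1L))
    from <- chars[p]
    to <- if (from == "A") "T" else "A"
    chars[p] <- to
    log[[length(log) + 1L]] <- data.frame(
      position = p - 1L, from = from, to = to, reason = "motif",
      stringsAsFactors = FALSE)
  }
  stopUnresolvable("chance-motif scrub exceeded its round cap")
}

# Alternate repeat/hairpin passes until neither finds anything (a hairpin
# fix can create a repeat and vice versa).
repairUntilClean <- function(s, mask, spec, maxRounds = 25L,
                             exemptRanges = NULL) {
  log <- emptyMutationLog()
  for (i in seq_len(maxRounds)) {
    r <- eliminateRepeats(s, mask, spec@minRepeatLen,
                          exemptRanges = exemptRanges)
    h <- eliminateHairpins(r$sequence, mask, spec@minStemLen)
    s <- h$sequence
    log <- rbind(log, r$log, h$log)
    if (nrow(h$log) == 0L) return(list(sequence = s, log = log))
  }
  stopUnresolvable("repeat/hairpin repair did not stabilize")
}
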