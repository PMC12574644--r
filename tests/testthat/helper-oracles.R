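# Independent brute-force oracles and fixture generators. These stay
# deliberately naive (O(n^2) pairwise window comparison, hand-rolled
# complementation) so they share no code path with the scanners they
# check.

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

naiveRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# every k-mer value occurring at >= 2 offsets, as a named list of sorted
# 0-based offset vectors, built by pairwise comparison
oracleRepeatFamilies <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  wins <- substring(s, starts, starts + k - 1L)
  eq <- outer(wins, wins, "==")
  hit <- which(colSums(eq) >= 2L)
  if (!length(hit)) return(list())
  fams <- list()
  for (i in hit) {
    if (!wins[i] %in% names(fams))
      fams[[wins[i]]] <- sort(starts[eq[, i]] - 1L)
  }
  fams[order(vapply(fams, `[`, integer(1), 1L))]
}

# every (i < j) window pair with window_j == revcomp(window_i), as a
# two-column matrix of 0-based starts
oracleHairpinPairs <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(matrix(integer(), ncol = 2))
  starts <- seq_len(n - k + 1L)
  wins <- substring(s, starts, starts + k - 1L)
  rcs <- vapply(wins, naiveRevComp, character(1), USE.NAMES = FALSE)
  out <- matrix(integer(), ncol = 2)
  for (i in seq_along(wins)) {
    js <- which(wins == rcs[i])
    js <- js[js > i]
    if (length(js)) out <- rbind(out, cbind(i - 1L, js - 1L))
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

countCGdimers <- function(s) {
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

baseCounts <- function(s) {
  table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

dgCurve <- function(t, p) {
  p@a1 * exp(-((t - p@mu1)^2) / (2 * p@sigma1^2)) +
    p@a2 * exp(-((t - p@mu2)^2) / (2 * p@sigma2^2))
}
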