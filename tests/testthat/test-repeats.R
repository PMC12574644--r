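test_that("homopolymer and duplication repeats are found", {
  hits <- findDirectRepeats(strrep("A", 20), 9)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$kmer, strrep("A", 9))
  expect_equal(hits$positions[[1]], 0:11)

  dup <- paste0("ACGTTGCAA", "ACGTTGCAA")
  hits2 <- findDirectRepeats(dup, 9)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$positions[[1]], c(0L, 9L))

  expect_equal(nrow(findDirectRepeats("ACGT", 9)), 0L)
})

test_that("repeat scanner agrees with the brute-force oracle", {
  set.seed(101)
  for (k in c(4L, 9L, 13L)) {
    for (i in 1:12) {
      s <- randomDNA(sample(60:300, 1))
      got <- findDirectRepeats(s, k)
      want <- oracleRepeatFamilies(s, k)
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        expect_setequal(got$kmer, names(want))
        for (j in seq_len(nrow(got)))
          expect_equal(got$positions[[j]], want[[got$kmer[j]]])
      }
    }
  }
})

test_that("repeat elimination reaches a repeat-free sequence with A/T flips only", {
  set.seed(7)
  res <- eliminateRepeats(strrep("A", 20), minLen = 9)
  expect_equal(nrow(findDirectRepeats(res$sequence, 9)), 0L)
  expect_true(all(res$log$from %in% c("A", "T")))
  expect_true(all(res$log$to %in% c("A", "T")))
  expect_true(all(res$log$from != res$log$to))
  expect_true(all(res$log$reason == "repeat"))
})

test_that("repeat-free input is a fixpoint", {
  s <- "ACGTTGCATTGCACATG"
  res <- eliminateRepeats(s, minLen = 9)
  expect_identical(res$sequence, s)
  expect_equal(nrow(res$log), 0L)
})

test_that("repair conserves C/G counts, the dimer census and the mask", {
  sc <- scaffoldSequence(DesignSpec(500, 0.27, seed = 5))
  dup <- paste0(sc$sequence, substr(sc$sequence, 1, 40))
  mask <- c(sc$mask, rep(FALSE, 40))
  before <- baseCounts(dup)
  res <- eliminateRepeats(dup, mask, 9, seed = 2)
  after <- baseCounts(res$sequence)
  expect_equal(after[["C"]], before[["C"]])
  expect_equal(after[["G"]], before[["G"]])
  expect_equal(countCGdimers(res$sequence), countCGdimers(dup))
  expect_false(any(res$log$position %in% (which(mask) - 1L)))
  expect_equal(nrow(findDirectRepeats(res$sequence, 9)), 0L)
})
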