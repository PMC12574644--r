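test_that("a constructed inverted repeat is detected at its arms", {
  s <- "ATCGGATTACCAG"          # 13-mer
  seq <- paste0(s, naiveRevComp(s))
  hits <- findInvertedRepeats(seq, 13)
  expect_true(nrow(hits) >= 1L)
  expect_true(any(hits$arm1Start == 0L & hits$arm2Start == 13L))

  expect_equal(nrow(findInvertedRepeats(strrep("A", 40), 13)), 0L)
})

test_that("inverted-repeat scanner agrees with the brute-force oracle", {
  set.seed(202)
  for (k in c(4L, 9L, 13L)) {
    for (i in 1:10) {
      s <- randomDNA(sample(60:300, 1))
      # splice in a stem pair occasionally so k=13 cases are non-trivial
      if (i %% 3 == 0) {
        arm <- randomDNA(k)
        s <- paste0(s, arm, randomDNA(8), naiveRevComp(arm))
      }
      got <- findInvertedRepeats(s, k)
      want <- oracleHairpinPairs(s, k)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$arm1Start, unname(want[, 1]))
        expect_equal(got$arm2Start, unname(want[, 2]))
      }
    }
  }
})

test_that("hairpin elimination removes stems and leaves clean input alone", {
  set.seed(9)
  arm <- "ATCGGATTACCAG"
  seq <- paste0(arm, naiveRevComp(arm))
  res <- eliminateHairpins(seq, minStem = 13)
  expect_equal(nrow(findInvertedRepeats(res$sequence, 13)), 0L)
  expect_true(all(res$log$reason == "hairpin"))
  expect_true(all(res$log$from %in% c("A", "T")))

  clean <- "ACGTTGCATTGCACATG"
  res2 <- eliminateHairpins(clean, minStem = 13)
  expect_identical(res2$sequence, clean)
  expect_equal(nrow(res2$log), 0L)
})

test_that("arms with no mutable A/T raise an unresolvable-repair error", {
  seq <- paste0(strrep("C", 13), strrep("G", 13))
  expect_error(eliminateHairpins(seq, minStem = 13),
               class = "phageDesign_unresolvable")
})
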