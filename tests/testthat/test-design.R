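test_that("the CG-series pipeline emits clean designs at exact census", {
  d <- designSsDNA(DesignSpec(1415, 0.27, seed = 1))
  expect_true(isClean(d$report))
  expect_equal(d$report@lengthNt, 1415L)
  expect_equal(d$report@nCgDimers, 191L)
  expect_equal(d$report@cgPercentRounded, 27L)
  expect_equal(countCGdimers(d$sequence), 191L)

  d0 <- designSsDNA(DesignSpec(1415, 0, seed = 1))
  expect_true(isClean(d0$report))
  expect_equal(d0$report@nCgDimers, 0L)
})

test_that("the hexamer-conversion pipeline embeds the exact dimer share", {
  d <- designSsDNA(DesignSpec(1415, 0.27, hexamerFraction = 0.4, seed = 1))
  expect_true(isClean(d$report))
  expect_equal(d$report@lengthNt, 1719L)
  expect_equal(d$report@nCgDimers, 191L)
  expect_equal(d$report@nHexamerEmbedded, 76L)
  expect_equal(d$report@hexamerPctOfCg, 100 * 76 / 191)
})

test_that("designs are deterministic per seed and vary across seeds", {
  a <- designSsDNA(DesignSpec(900, 0.26, seed = 4))
  b <- designSsDNA(DesignSpec(900, 0.26, seed = 4))
  c <- designSsDNA(DesignSpec(900, 0.26, seed = 5))
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, c$sequence))
  expect_equal(a$report@nCgDimers, c$report@nCgDimers)
  expect_equal(a$report@lengthNt, c$report@lengthNt)
  expect_true(isClean(c$report))
})

test_that("design output is a fixpoint of both repair passes", {
  d <- designSsDNA(DesignSpec(1000, 0.27, seed = 2))
  r <- eliminateRepeats(d$sequence, d$mask, 9, seed = 1)
  h <- eliminateHairpins(d$sequence, d$mask, 13, seed = 1)
  expect_equal(nrow(r$log), 0L)
  expect_equal(nrow(h$log), 0L)

  dh <- designSsDNA(DesignSpec(1000, 0.27, hexamerFraction = 0.4, seed = 2))
  cassettes <- phageDesign:::motifRanges(dh$sequence,
                                         c("AACGTT", "GACGTT"),
                                         dh$mask, protectedOnly = TRUE)
  rh <- eliminateRepeats(dh$sequence, dh$mask, 9, seed = 1,
                         exemptRanges = cassettes)
  hh <- eliminateHairpins(dh$sequence, dh$mask, 13, seed = 1)
  expect_equal(nrow(rh$log), 0L)
  expect_equal(nrow(hh$log), 0L)
})

test_that("validator census matches hand-checkable cases", {
  rep1 <- validateDesign("CGCG", DesignSpec(4, 1.0, seed = 1))
  expect_equal(rep1@nCgDimers, 2L)
  expect_equal(rep1@cgFractionRealized, 1.0)
  expect_equal(rep1@cgPercentRounded, 100L)

  rep2 <- validateDesign(strrep("A", 20), DesignSpec(20, 0, seed = 1))
  expect_false(rep2@clean)
  expect_equal(nrow(rep2@repeats), 1L)
})
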