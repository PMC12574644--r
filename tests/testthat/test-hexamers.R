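cg27design <- local({
  d <- designSsDNA(DesignSpec(1415, 0.27, seed = 1))
  d
})

test_that("hexamer conversion hits the exact site count and length arithmetic", {
  ins <- insertCpgHexamers(cg27design$sequence, cg27design$mask,
                           fraction = 0.4, seed = 1)
  expect_equal(nrow(ins$log), 76L)             # round(0.4 * 191)
  expect_equal(nchar(ins$sequence), 1415L + 4L * 76L)
  expect_equal(countCGdimers(ins$sequence), 191L)

  full <- insertCpgHexamers(cg27design$sequence, cg27design$mask,
                            fraction = 1, seed = 1)
  expect_equal(nrow(full$log), 191L)
  expect_equal(nchar(full$sequence), 1415L + 4L * 191L)
  expect_equal(countCGdimers(full$sequence), 191L)
})

test_that("fraction zero is the identity and zero dimers is an error", {
  ins <- insertCpgHexamers(cg27design$sequence, cg27design$mask,
                           fraction = 0, seed = 1)
  expect_identical(ins$sequence, cg27design$sequence)
  expect_equal(nrow(ins$log), 0L)

  expect_error(insertCpgHexamers(strrep("AT", 20), fraction = 0.5, seed = 1),
               class = "phageDesign_infeasible")
})

test_that("inserted hexamers are protected and survive repair passes", {
  ins <- insertCpgHexamers(cg27design$sequence, cg27design$mask,
                           fraction = 0.4, seed = 1)
  occ <- phageDesign:::motifRanges(ins$sequence, c("AACGTT", "GACGTT"),
                                   ins$mask, protectedOnly = TRUE)
  expect_equal(nrow(occ), 76L)
  for (i in seq_len(nrow(occ)))
    expect_true(all(ins$mask[occ[i, 1]:occ[i, 2]]))

  spec <- DesignSpec(1415, 0.27, hexamerFraction = 0.4, seed = 1)
  r <- eliminateRepeats(ins$sequence, ins$mask, 9, seed = 4,
                        exemptRanges = occ)
  h <- eliminateHairpins(r$sequence, ins$mask, 13, seed = 4)
  after <- phageDesign:::motifRanges(h$sequence, c("AACGTT", "GACGTT"),
                                     ins$mask, protectedOnly = TRUE)
  expect_equal(nrow(after), 76L)
  expect_equal(countCGdimers(h$sequence), 191L)
})

test_that("in-place conversion preserves length and the dimer census", {
  ins <- insertCpgHexamers(cg27design$sequence, cg27design$mask,
                           fraction = 0.2, seed = 2, mode = "in_place")
  expect_equal(nchar(ins$sequence), 1415L)
  expect_equal(nrow(ins$log), round(0.2 * 191))
  expect_equal(countCGdimers(ins$sequence), 191L)
})
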