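test_that("DesignSpec validates its invariants", {
  expect_error(DesignSpec(1415, 1.2), "cgFraction")
  expect_error(DesignSpec(0, 0.27), "positive")
  expect_error(DesignSpec(3, 1.0), "cannot hold")
  expect_error(DesignSpec(100, 0.2, hexamerSet = c("AAATTT")), "hexamerSet")
  expect_error(DesignSpec(100, 0.2, hexamerSet = c("ACGCGT")), "hexamerSet")
  expect_s4_class(DesignSpec(1415, 0.27, seed = 1), "DesignSpec")
})

test_that("scaffold places the exact CG dimer count at the exact length", {
  sc <- scaffoldSequence(DesignSpec(1415, 0.27, seed = 1))
  expect_equal(nchar(sc$sequence), 1415L)
  expect_equal(countCGdimers(sc$sequence), 191L)

  sc0 <- scaffoldSequence(DesignSpec(1415, 0, seed = 1))
  expect_equal(nchar(sc0$sequence), 1415L)
  expect_equal(countCGdimers(sc0$sequence), 0L)

  tiny <- scaffoldSequence(DesignSpec(10, 0, seed = 7))
  expect_equal(nchar(tiny$sequence), 10L)
  expect_false(grepl("CG", tiny$sequence, fixed = TRUE))
})

test_that("scaffold mask protects exactly the placed dimer positions", {
  sc <- scaffoldSequence(DesignSpec(600, 0.27, seed = 3))
  d <- gregexpr("CG", sc$sequence, fixed = TRUE)[[1]]
  expect_equal(sort(which(sc$mask)), sort(c(d, d + 1L)))
})

test_that("scaffold flanks respect the boundary rules", {
  for (seed in 1:4) {
    sc <- scaffoldSequence(DesignSpec(800, 0.25, seed = seed))
    rep <- validateDesign(sc$sequence, DesignSpec(800, 0.25, seed = seed))
    expect_length(rep@boundaryViolations, 0L)
  }
})

test_that("scaffold is deterministic in the seed and varies across seeds", {
  a <- scaffoldSequence(DesignSpec(700, 0.2, seed = 11))
  b <- scaffoldSequence(DesignSpec(700, 0.2, seed = 11))
  c <- scaffoldSequence(DesignSpec(700, 0.2, seed = 12))
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, c$sequence))
  expect_equal(countCGdimers(a$sequence), countCGdimers(c$sequence))
})
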