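test_that("single residues and condensation arithmetic are right", {
  g <- proteinMass("G")
  expect_equal(g@averageMass, 75.07, tolerance = 0.01)
  gg <- proteinMass("GG")
  expect_equal(gg@averageMass, 2 * 57.0519 + 18.01528, tolerance = 1e-6)
  expect_equal(gg@averageMass, 2 * g@averageMass - 18.01528,
               tolerance = 1e-6)
})

test_that("mass additivity holds across concatenation", {
  set.seed(33)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    a <- paste(sample(aas, sample(3:20, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:20, 1), replace = TRUE), collapse = "")
    ab <- proteinMass(paste0(a, b))
    expect_equal(ab@averageMass,
                 proteinMass(a)@averageMass + proteinMass(b)@averageMass -
                   18.01528, tolerance = 1e-9)
    expect_lt(ab@monoisotopicMass, ab@averageMass)
    expect_gt(ab@maldiMz, ab@averageMass)
  }
})

test_that("the canonical mature pVIII predicts the expected MALDI peak", {
  m <- proteinMass(wtPVIII())
  expect_equal(nchar(wtPVIII()), 50L)
  # frozen oracle values (independent residue-table summation)
  expect_equal(m@averageMass, 5237.985, tolerance = 0.05)
  expect_equal(m@monoisotopicMass, 5234.737, tolerance = 0.05)
  expect_equal(round(m@maldiMz), 5239)
})

test_that("invalid protein input is rejected by name", {
  expect_error(proteinMass("GAVX"), "X")
  expect_error(proteinMass(""), class = "phageDesign_io")
})

test_that("length calibration matches an independent regression oracle", {
  model <- calibrateLengthModel()
  ref <- unname(coef(lm(nm ~ 0 + nt,
                        data = data.frame(nt = c(721, 1447, 3241, 6261),
                                          nm = c(100, 200, 400, 800)))))
  expect_equal(model@slopeNmPerNt, ref, tolerance = 1e-12)
  expect_equal(model@residuals,
               c(100, 200, 400, 800) - ref * c(721, 1447, 3241, 6261),
               tolerance = 1e-9)
})

test_that("length predictions are proportional and in the accuracy band", {
  model <- calibrateLengthModel()
  expect_lt(abs(phageLengthFromSsdna(1447, model) - 200), 0.2 * 200)
  p <- phageLengthFromSsdna(1719, model)
  expect_lt(abs(p - 219), 5)          # hexamer-converted design, ~220 nm class
  expect_equal(phageLengthFromSsdna(2000, model),
               2 * phageLengthFromSsdna(1000, model))
  expect_error(phageLengthFromSsdna(0), class = "phageDesign_io")
  expect_error(phageLengthFromSsdna(-5), class = "phageDesign_io")
})
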