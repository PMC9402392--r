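test_that("PDB text is parsed with Angstrom-to-nm conversion", {
  s <- readStructure(miniPdbText())
  expect_s3_class(s, "Structure")
  expect_equal(residueNumbers(s), 1:3)
  ca <- caCoords(s)
  expect_equal(unname(ca[1, ]), c(0.15, 0, 0))       # 1.5 A -> 0.15 nm
  expect_equal(unname(ca[2, ]), c(0.33, 0.32, 0))
  expect_equal(nrow(s$atoms), 9)
})

test_that("only the first altloc is retained", {
  txt <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       2.000   0.000   0.000  1.00  0.00           C",
    "END"
  )
  s <- readStructure(txt)
  ca <- caCoords(s)
  expect_equal(nrow(ca), 2)
  expect_equal(unname(ca[1, 1]), 0.1)  # altloc A kept, B dropped
})

test_that("structure write/read round-trips coordinates to PDB precision", {
  toy <- toyFixture()
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(toy$open, path)
  back <- readStructure(path)
  expect_lt(max(abs(caCoords(back) - caCoords(toy$open))), 1e-4)
})

test_that("superposition recovers a planted rigid transform", {
  s <- beadChain(30)
  expect_equal(superpose(s, s)$rmsd, 0, tolerance = 1e-10)
  expect_equal(superpose(s, s)$rotation, diag(3), tolerance = 1e-8)

  R <- rotationMatrix(c(1, 2, 3), 0.8)
  tr <- c(1.2, -0.5, 2.0)
  moved <- transformStructure(s, R, tr)
  fit <- superpose(s, moved)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(fit$translation, tr, tolerance = 1e-8)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)

  # rmsd is symmetric and refitting the fitted structure gives identity
  set.seed(5)
  noisy <- moved
  noisy$atoms$x <- noisy$atoms$x + rnorm(nrow(noisy$atoms), 0, 0.05)
  f_ab <- superpose(s, noisy)
  f_ba <- superpose(noisy, s)
  expect_equal(f_ab$rmsd, f_ba$rmsd, tolerance = 1e-10)
  refit <- superpose(applyTransform(s, f_ab), noisy)
  expect_equal(refit$rotation, diag(3), tolerance = 1e-6)

  expect_error(superpose(beadChain(3), beadChain(3, resno_start = 10L)),
               "at least 3 shared")
})

test_that("superposition agrees with an independent reference implementation", {
  s <- beadChain(25)
  R <- rotationMatrix(c(0, 1, 1), 1.1)
  moved <- transformStructure(s, R, c(0.3, 0.1, -0.7))
  set.seed(11)
  moved$atoms$x <- moved$atoms$x + rnorm(25, 0, 0.08)
  fit <- superpose(s, moved)
  ref <- suppressWarnings(bio3d::fit.xyz(
    fixed = as.vector(t(caCoords(moved))),
    mobile = as.vector(t(caCoords(s)))
  ))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) -
                                   caCoords(moved))^2)))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rmsdNoFit matches direct summation", {
  a <- matrix(0, 2, 3)
  b <- cbind(c(0.3, 0.3), 0, 0)
  expect_equal(rmsdNoFit(a, a), 0)
  expect_equal(rmsdNoFit(a, b), 0.3)
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3); y <- matrix(rnorm(60), 20, 3)
  expect_equal(rmsdNoFit(x, y), sqrt(sum((x - y)^2) / 20), tolerance = 1e-12)
  expect_error(rmsdNoFit(x, y[1:10, ]), "differ in size")
})

test_that("CA distances behave", {
  toy <- toyFixture()
  expect_equal(caDistance(toy$open, 1, 1), 0)
  d <- caDistance(toy$open, toy$rc_pair[1], toy$rc_pair[2])
  ca <- caCoords(toy$open, toy$rc_pair)
  expect_equal(d, sqrt(sum((ca[1, ] - ca[2, ])^2)))
  expect_error(caDistance(toy$open, 1, 999), "999")
})

test_that("grafting a swapped tail yields one chain with every CA exactly once", {
  body <- beadChain(60)
  R <- rotationMatrix(c(0, 0, 1), 0.6)
  tr <- c(2, 1, 0)
  chainA <- transformStructure(body, R, tr)
  # donor tail 61-70 placed just beyond chain A's last residue
  tail <- beadChain(10, resno_start = 61L, seed = 7L)
  tail$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(tail$atoms[, c("x", "y", "z")]), 2,
          unname(caCoords(chainA, 60)[1, ] - caCoords(tail, 61)[1, ] +
                   c(0.38, 0, 0)), "+")
  mono <- buildMonomerOsCth(body, chainA, tail, graft_range = c(61L, 70L))
  expect_equal(residueNumbers(mono), 1:70)
  expect_equal(max(residueNumbers(mono)), 70)
  # grafted tail is expressed in the body frame: continuous at the junction
  expect_lt(caDistance(mono, 60, 61), 0.6)
  # every input CA appears exactly once
  expect_equal(sum(mono$atoms$elety == "CA"), 70)

  # empty graft range returns the input untouched
  same <- buildMonomerOsCth(body, chainA, tail, graft_range = c(61L, 60L))
  expect_identical(same, body)

  expect_error(buildMonomerOsCth(body, chainA, tail,
                                 graft_range = c(61L, 99L)), "missing")
})

test_that("residue numbering maps across an insertion via sequence alignment", {
  s <- readStructure(miniPdbText())   # ALA GLY SER, resno 1..3
  # same chain with an extra residue inserted before SER and shifted numbering
  txt <- c(
    "ATOM      1  CA  ALA A   5       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   6       3.300   3.200   0.000  1.00  0.00           C",
    "ATOM      3  CA  TRP A   7       5.000   3.000   0.500  1.00  0.00           C",
    "ATOM      4  CA  SER A   8       6.900   2.800   1.100  1.00  0.00           C",
    "END"
  )
  other <- readStructure(txt)
  map <- mapResidueNumbering(other, s)
  expect_equal(map$ref_resno[map$resno == 5], 1)
  expect_equal(map$ref_resno[map$resno == 8], 3)
  expect_false(7 %in% map$resno)  # the insertion has no counterpart
})
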