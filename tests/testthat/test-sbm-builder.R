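test_that("pair potentials take their closed-form values at the minima", {
  # dual-Gaussian: depth exactly -eps_dg at both native distances
  expect_equal(dualGaussianEnergy(0.8, r1 = 0.8, r2 = 1.4), -1)
  expect_equal(dualGaussianEnergy(1.4, r1 = 0.8, r2 = 1.4), -1)
  expect_equal(dualGaussianEnergy(0.9, 0.9, 1.2, eps_dg = 2.5), -2.5)
  # swap symmetry in the two native distances
  r <- seq(0.3, 3, by = 0.01)
  expect_equal(dualGaussianEnergy(r, 0.7, 1.3), dualGaussianEnergy(r, 1.3, 0.7))
  # vanishes far away, repulsive at the core
  expect_lt(abs(dualGaussianEnergy(10 * 1.4, 0.8, 1.4)), 1e-6)
  expect_gt(dualGaussianEnergy(0.1, 0.8, 1.4), 1e4)

  # 10-12: minimum exactly -strength at sigma, zero slope there
  expect_equal(lj1012Energy(0.6, sigma = 0.6, strength = 1), -1)
  expect_equal(lj1012Energy(0.6, sigma = 0.6, strength = 0.79), -0.79)
  h <- 1e-7
  slope <- (lj1012Energy(0.6 + h, 0.6) - lj1012Energy(0.6 - h, 0.6)) / (2 * h)
  expect_lt(abs(slope), 1e-4)
  # hand-evaluated point off the minimum
  sig <- 0.5; rr <- sig / 1.2
  expect_equal(lj1012Energy(rr, sig, 2),
               2 * (5 * 1.2^12 - 6 * 1.2^10), tolerance = 1e-12)

  # excluded volume
  expect_equal(excludedVolumeEnergy(0.4), 1)
  expect_equal(excludedVolumeEnergy(0.8), 1 / 4096)
  expect_error(lj1012Energy(-1, 0.5), "positive")
  expect_error(dualGaussianEnergy(0, 0.8, 1.4), "positive")
})

test_that("topology assembly counts terms correctly", {
  toy <- toyFixture()
  top <- toy$topology
  n <- top$n_beads
  cc <- classCounts(toy$contacts)
  expect_equal(nrow(top$bonds), n - 1)
  expect_equal(nrow(top$angles), n - 2)
  expect_equal(nrow(top$dihedrals), n - 3)
  expect_equal(nrow(top$dg), cc[["common"]])
  expect_equal(nrow(top$spec_open), cc[["open_specific"]])
  expect_equal(nrow(top$spec_closed), cc[["closed_specific"]])
  # no pair in more than one non-bonded category; exclusions complete
  keys <- c(paste(top$dg[, 1], top$dg[, 2]),
            paste(top$spec_open[, 1], top$spec_open[, 2]),
            paste(top$spec_closed[, 1], top$spec_closed[, 2]),
            paste(top$ev_pairs[, 1], top$ev_pairs[, 2]))
  expect_equal(anyDuplicated(keys), 0)
  # every pair at least 4 apart is either a contact term or excluded volume
  # (discarded detections fall back to plain repulsion)
  n_far <- choose(n, 2) - ((n - 1) + (n - 2) + (n - 3))
  expect_equal(length(keys), n_far)
})

test_that("tail scaling multiplies only tail-involving open-specific strengths", {
  toy <- toyFixture()
  p2 <- toy$params
  p2$cth_scale <- 2.0
  top1 <- toy$topology
  top2 <- buildTopology(toy$open, toy$contacts, p2)
  cth <- toy$contacts$involves_cth[toy$contacts$class == "open_specific"]
  expect_equal(top2$spec_open[cth, 4], 2 * top1$spec_open[cth, 4])
  if (any(!cth)) {
    expect_equal(top2$spec_open[!cth, 4], top1$spec_open[!cth, 4])
  }
  expect_equal(top2$spec_closed, top1$spec_closed)
})

test_that("native open-state energy matches the analytic ledger and a brute-force oracle", {
  toy <- toyFixture()
  top <- toy$topology
  coords <- caCoords(toy$open)
  e <- totalEnergy(top, coords)
  cc <- classCounts(toy$contacts)
  # bonded natives vanish at the reference geometry
  expect_equal(e[["bond"]], 0, tolerance = 1e-10)
  expect_equal(e[["angle"]], 0, tolerance = 1e-10)
  expect_equal(e[["dihedral"]], 0, tolerance = 1e-10)
  # each dual-Gaussian well is exactly -eps_dg at its open-state minimum
  expect_equal(e[["dual_gaussian"]], -cc[["common"]], tolerance = 1e-9)
  # each open-specific 10-12 well is exactly -eps_os at sigma
  expect_equal(e[["specific_open"]], -cc[["open_specific"]],
               tolerance = 1e-9)
  expect_equal(e[["total"]], sum(e[1:7]), tolerance = 1e-10)
  # independent plain-R evaluation of every term agrees
  brute <- bruteForceEnergy(top, coords)
  expect_equal(e[1:7], brute, tolerance = 1e-10, ignore_attr = TRUE)
  # off-minimum configuration: oracle still agrees
  set.seed(31)
  pert <- coords + matrix(rnorm(length(coords), 0, 0.05), ncol = 3)
  expect_equal(totalEnergy(top, pert)[1:7], bruteForceEnergy(top, pert),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("analytic forces match central finite differences", {
  toy <- toyFixture()
  # random 20-bead sub-chain model keeps the finite-difference loop fast
  sub <- toy$open
  sub$atoms <- sub$atoms[sub$atoms$resno <= 20, ]
  cm <- classifyContacts(sub, local({
    s <- toy$closed; s$atoms <- s$atoms[s$atoms$resno <= 20, ]; s
  }), "ca_cutoff", cutoff = 0.8, min_seq_sep = 4)
  top <- buildTopology(sub, cm, toy$params)
  set.seed(17)
  for (rep in 1:3) {
    x <- caCoords(sub) + matrix(rnorm(60, 0, 0.04), ncol = 3)
    f <- sbmForces(top, x)
    fd <- finiteDifferenceForces(top, x)
    expect_lt(max(abs(f - fd)), 1e-5)
    # translation invariance: forces sum to zero
    expect_lt(max(abs(colSums(f))), 1e-10)
  }
})

test_that("scaling eps_cs scales the closed-specific component exactly", {
  toy <- toyFixture()
  set.seed(4)
  x <- caCoords(toy$open) + matrix(rnorm(3 * toy$topology$n_beads, 0, 0.05),
                                   ncol = 3)
  lambda <- 3.7
  p2 <- toy$params
  p2$eps_cs <- toy$params$eps_cs * lambda
  top2 <- buildTopology(toy$open, toy$contacts, p2)
  e1 <- totalEnergy(toy$topology, x)
  e2 <- totalEnergy(top2, x)
  expect_equal(e2[["specific_closed"]], lambda * e1[["specific_closed"]],
               tolerance = 1e-12)
  expect_equal(e2[["dual_gaussian"]], e1[["dual_gaussian"]])
})

test_that("topology export round-trips and the GROMACS dialect is well-formed", {
  toy <- toyFixture()
  top <- toy$topology
  path <- withr::local_tempfile(fileext = ".json")
  exportTopology(top, path, "native_json")
  back <- readTopology(path)
  for (fld in c("n_beads", "resnos", "bonds", "angles", "dihedrals", "dg",
                "spec_open", "spec_closed")) {
    expect_equal(back[[fld]], top[[fld]], ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_equal(totalEnergy(back, caCoords(toy$open)),
               totalEnergy(top, caCoords(toy$open)), tolerance = 1e-12)

  base <- withr::local_tempfile()
  files <- exportTopology(top, base, "gromacs_dialect")
  gro <- readLines(paste0(base, ".gro"))
  expect_equal(as.integer(trimws(gro[2])), top$n_beads)
  expect_equal(length(gro), top$n_beads + 3)  # title, count, beads, box
  topf <- readLines(paste0(base, ".top"))
  bonds_at <- grep("\\[ bonds \\]", topf)
  angles_at <- grep("\\[ angles \\]", topf)
  expect_equal(angles_at - bonds_at - 2, top$n_beads - 1)  # one line per bond
  expect_equal(sum(grepl("^\\s*\\d", topf[seq(grep("pairs_dualgaussian", topf),
                                              grep("pairs_1012", topf))])),
               nrow(top$dg))
})
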