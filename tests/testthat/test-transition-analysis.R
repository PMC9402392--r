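test_that("reaction-coordinate series recover planted distances", {
  toy <- toyFixture()
  # static one-frame trajectory at the open structure
  ca <- caCoords(toy$open)
  traj <- structure(list(
    xyz = array(ca, dim = c(1, nrow(ca), 3)), steps = 0,
    resnos = toy$topology$resnos), class = "Trajectory")
  traj$xyz[1, , ] <- ca
  rc <- rcSeries(traj, toy$rc_pair[1], toy$rc_pair[2])
  expect_equal(rc$values,
               caDistance(toy$open, toy$rc_pair[1], toy$rc_pair[2]))
  expect_error(rcSeries(traj, 1, 999), "999")
})

test_that("free-energy profiles follow Boltzmann inversion of planted mixtures", {
  # uniform samples: flat profile within the binomial sampling band
  set.seed(1)
  u <- runif(2e4, 1, 2)
  prof <- pmf(u, temperature = 100, n_bins = 20)
  kT <- 0.008314 * 100
  p0 <- 1 / 20
  band <- 3 * sqrt((1 - p0) / (2e4 * p0))  # 3 sigma on ln P per bin
  expect_lt(max(prof$F), kT * 2 * band + kT * band)  # min-shift doubles range
  expect_equal(min(prof$F), 0)

  # two-Gaussian mixture with planted 0.7/0.3 weights: basin free-energy gap
  mix <- makeRCSeries(basin_means = c(2.2, 0.7), widths = c(0.1, 0.1),
                      switch_prob = 0.5, n = 1e5, seed = 3,
                      weights = c(0.7, 0.3))
  prof <- pmf(mix$series, temperature = 100, n_bins = 50)
  dF <- basinDeltaF(prof, divide = 1.45)
  expect_equal(dF, -kT * log(0.3 / 0.7), tolerance = 0.05)

  # basin gap is stable in the bin count
  for (nb in c(20, 50, 80)) {
    profb <- pmf(mix$series, temperature = 100, n_bins = nb)
    expect_lt(abs(basinDeltaF(profb, 1.45) - dF), 0.3)
  }

  # degenerate input warns
  expect_warning(pmf(rep(1, 100), 100, 10), "identical")
})

test_that("hysteretic state assignment matches a replayed automaton", {
  # alternating far/near series: a transition at every frame after the first
  v <- rep(c(2.3, 0.8), 5)
  lab <- assignStates(v, 1.8, 1.0)
  expect_equal(countTransitions(lab), 9)
  expect_equal(basinPopulations(lab), c(open = 0.5, closed = 0.5))

  # series entirely between the thresholds: never commits
  v2 <- runif(50, 1.05, 1.75)
  lab2 <- assignStates(v2, 1.8, 1.0)
  expect_true(all(lab2 == "intermediate"))
  expect_equal(countTransitions(lab2), 0)

  expect_error(assignStates(v, 1.0, 1.8), "exceed")

  # random walk against an independent replay of the hysteresis rule
  set.seed(12)
  w <- cumsum(rnorm(5000, 0, 0.05)) + 1.4
  got <- assignStates(w, 1.8, 1.0)
  state <- "intermediate"; exp_lab <- character(length(w))
  for (t in seq_along(w)) {
    if (w[t] > 1.8) state <- "open"
    if (w[t] < 1.0) state <- "closed"
    exp_lab[t] <- state
  }
  expect_identical(got, exp_lab)

  # transition count is invariant under series reversal
  expect_equal(countTransitions(assignStates(rev(w), 1.8, 1.0)),
               countTransitions(got))
})

test_that("transition counting uses committed states only", {
  expect_equal(countTransitions(c("open", "open", "closed", "open")), 2)
  expect_equal(countTransitions(c("intermediate", "open", "intermediate")), 0)
  expect_equal(basinPopulations(c("open", "open", "open")),
               c(open = 1, closed = 0))
  expect_equal(basinPopulations(rep("intermediate", 3)),
               c(open = 0, closed = 0))
})

test_that("salt-bridge distances are charged-centre minima over all-atom input", {
  fx <- makeSaltBridgeFixture(c(0.35, 0.7))
  d <- saltBridgeSeries(fx, 10, 30)
  expect_equal(d, c(0.35, 0.7), tolerance = 1e-3)
  # symmetric in residue order
  expect_equal(saltBridgeSeries(fx, 30, 10), d)
  expect_equal(fractionFormed(d, 0.5), 0.5)
  expect_equal(fractionFormed(saltBridgeSeries(
    makeSaltBridgeFixture(rep(0.4, 4)), 10, 30), 0.5), 1.0)
  # 0.6 nm pair is not formed at the 0.5 nm cutoff
  expect_equal(fractionFormed(saltBridgeSeries(
    makeSaltBridgeFixture(0.6), 10, 30), 0.5), 0)

  # brute-force all-pairs minimum agrees
  at <- fx$atoms
  o_idx <- which(at$resno == 10 & at$elety %in% c("OD1", "OD2"))
  n_idx <- which(at$resno == 30 & at$elety == "NZ")
  brute <- min(outer(o_idx, n_idx, Vectorize(function(i, j)
    sqrt(sum((fx$xyz[1, i, ] - fx$xyz[1, j, ])^2)))))
  expect_equal(d[1], brute, tolerance = 1e-12)

  # CA-only input is refused with an informative error
  toy <- toyFixture()
  expect_error(saltBridgeSeries(toy$open, 1, 2), "all-atom")
})

test_that("all-atom trajectories round-trip through multi-model PDB", {
  fx <- makeSaltBridgeFixture(c(0.3, 0.45, 0.8))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeAtomTrajectory(fx, path)
  back <- readAtomTrajectory(path)
  expect_equal(dim(back$xyz), dim(fx$xyz))
  expect_lt(max(abs(back$xyz - fx$xyz)), 1e-4 + 1e-12)
  expect_equal(back$atoms$elety, fx$atoms$elety)
  d <- saltBridgeSeries(back, 10, 30)
  expect_equal(d, c(0.3, 0.45, 0.8), tolerance = 2e-3)
})

test_that("degenerate scan criteria return the first grid point", {
  toy <- toyFixture()
  scan <- tuneEpsilonCS(
    toy$open, toy$contacts, toy$params,
    integrator = integratorParams(n_steps = 2e4, save_every = 2000, seed = 1),
    eps_grid = c(0.5, 0.8), rc_pair = toy$rc_pair,
    open_threshold = 2.6, closed_threshold = 1.6,
    min_transitions = 0L, balance = c(0, 1)
  )
  expect_equal(scan$chosen, 0.5)
  expect_equal(nrow(scan$report), 2)
  expect_error(tuneEpsilonCS(toy$open, toy$contacts, toy$params,
                             eps_grid = c(1, 0.5), rc_pair = toy$rc_pair,
                             open_threshold = 2.6, closed_threshold = 1.6),
               "ascending")
})

test_that("an unreachable closed basin yields a structured scan failure", {
  toy <- toyFixture()
  # eps_cs = 0 cannot stabilise the closed state at all
  scan <- tuneEpsilonCS(
    toy$open, toy$contacts, toy$params,
    integrator = integratorParams(n_steps = 1e5, save_every = 2000, seed = 2),
    eps_grid = c(0, 0.01), rc_pair = toy$rc_pair,
    open_threshold = 2.6, closed_threshold = 1.6,
    min_transitions = 2L, balance = c(0.3, 0.7)
  )
  expect_true(is.na(scan$chosen))
  expect_equal(nrow(scan$report), 2)
  expect_true(all(!scan$report$qualifies))
  expect_true(all(scan$report$pop_closed < 0.1))
})
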