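# shared fixtures, built in code

# three-residue PDB text (coordinates in Angstrom)
miniPdbText <- function() {
  c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.200   1.300   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       2.000   2.600   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       3.300   3.200   0.000  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       4.500   2.500   0.600  1.00  0.00           C",
    "ATOM      7  N   SER A   3       5.600   3.300   0.700  1.00  0.00           N",
    "ATOM      8  CA  SER A   3       6.900   2.800   1.100  1.00  0.00           C",
    "ATOM      9  OG  SER A   3       7.500   3.900   1.900  1.00  0.00           O",
    "END"
  )
}

# cache the default toy + topology across tests within one run
toyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- makeTwoStateToy(toySpec())
      params <- sbmParams(eps_os = 1, eps_cs = 1,
                          cth_range = attr(toy$contacts, "params")$cth_range)
      toy$params <- params
      toy$topology <- buildTopology(toy$open, toy$contacts, params)
      cache <<- toy
    }
    cache
  }
})

# straight-ish CA-only chain used for superposition / graft tests
beadChain <- function(n, resno_start = 1L, spread = 0.2, seed = 99L) {
  set.seed(seed)
  xyz <- cbind(0.38 * seq_len(n), 0, 0) +
    matrix(runif(3 * n, -spread, spread), n, 3)
  Structure(
    data.frame(chain = "A", resno = seq(resno_start, length.out = n),
               resid = "ALA", elety = "CA", elesym = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE),
    chain_id = "A", title = sprintf("bead chain n=%d", n)
  )
}

rotationMatrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

transformStructure <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# independent brute-force total energy: plain R loops over every term
bruteForceEnergy <- function(top, coords) {
  p <- top$params
  E <- c(bond = 0, angle = 0, dihedral = 0, dual_gaussian = 0,
         specific_open = 0, specific_closed = 0, excluded = 0)
  dist_ij <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  for (r in seq_len(nrow(top$bonds))) {
    d <- dist_ij(top$bonds[r, 1], top$bonds[r, 2])
    E["bond"] <- E["bond"] + p$k_r * (d - top$bonds[r, 3])^2
  }
  ang <- function(a, b, c) {
    u <- coords[a, ] - coords[b, ]; v <- coords[c, ] - coords[b, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  for (r in seq_len(nrow(top$angles))) {
    th <- ang(top$angles[r, 1], top$angles[r, 2], top$angles[r, 3])
    E["angle"] <- E["angle"] + p$k_theta * (th - top$angles[r, 4])^2
  }
  dih <- function(a, b, c, d) {
    b1 <- coords[b, ] - coords[a, ]; b2 <- coords[c, ] - coords[b, ]
    b3 <- coords[d, ] - coords[c, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
           n1[1] * n2[2] - n1[2] * n2[1])
    atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  }
  for (r in seq_len(nrow(top$dihedrals))) {
    phi <- dih(top$dihedrals[r, 1], top$dihedrals[r, 2],
               top$dihedrals[r, 3], top$dihedrals[r, 4])
    dp <- phi - top$dihedrals[r, 5]
    E["dihedral"] <- E["dihedral"] + p$k_phi1 * (1 - cos(dp)) +
      p$k_phi3 * (1 - cos(3 * dp))
  }
  for (r in seq_len(nrow(top$dg))) {
    d <- dist_ij(top$dg[r, 1], top$dg[r, 2])
    g1 <- -exp(-(d - top$dg[r, 3])^2 / (2 * p$gauss_width^2))
    g2 <- -exp(-(d - top$dg[r, 4])^2 / (2 * p$gauss_width^2))
    E["dual_gaussian"] <- E["dual_gaussian"] +
      p$eps_dg * ((1 + (p$sigma_nc / d)^12) * (1 + g1) * (1 + g2) - 1)
  }
  for (r in seq_len(nrow(top$spec_open))) {
    d <- dist_ij(top$spec_open[r, 1], top$spec_open[r, 2])
    sig <- top$spec_open[r, 3]
    E["specific_open"] <- E["specific_open"] +
      top$spec_open[r, 4] * (5 * (sig / d)^12 - 6 * (sig / d)^10)
  }
  for (r in seq_len(nrow(top$spec_closed))) {
    d <- dist_ij(top$spec_closed[r, 1], top$spec_closed[r, 2])
    sig <- top$spec_closed[r, 3]
    E["specific_closed"] <- E["specific_closed"] +
      top$spec_closed[r, 4] * (5 * (sig / d)^12 - 6 * (sig / d)^10)
  }
  for (r in seq_len(nrow(top$ev_pairs))) {
    d <- dist_ij(top$ev_pairs[r, 1], top$ev_pairs[r, 2])
    if (d <= p$ev_cutoff) {
      E["excluded"] <- E["excluded"] + p$eps_ev * (p$sigma_nc / d)^12
    }
  }
  E
}

# central finite-difference forces
finiteDifferenceForces <- function(top, coords, h = 1e-6) {
  fd <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) {
    for (d in 1:3) {
      xp <- coords; xm <- coords
      xp[i, d] <- xp[i, d] + h
      xm[i, d] <- xm[i, d] - h
      fd[i, d] <- -(totalEnergy(top, xp)[["total"]] -
                      totalEnergy(top, xm)[["total"]]) / (2 * h)
    }
  }
  fd
}
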