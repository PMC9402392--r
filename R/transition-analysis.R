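#' Reaction-coordinate series from a trajectory
#'
#' Per-frame CA-CA distance between two residues; for hinge-bending binding
#' proteins the canonical reporter is a cross-lobe pair (56-143 in TmArgBP
#' numbering, ~2.2 nm open / ~0.7 nm closed), with a second pair monitoring
#' tail docking (168-217).
#'
#' @param traj Trajectory (bead coordinates with `resnos`).
#' @param res_i,res_j author residue numbers.
#' @return list of class `"RCSeries"`: `values` (nm, one per frame), `steps`,
#'   `res_pair`.
#' @export
rcSeries <- function(traj, res_i, res_j) {
  ii <- match(res_i, traj$resnos)
  jj <- match(res_j, traj$resnos)
  if (is.na(ii) || is.na(jj)) {
    stop("residue ", paste(c(res_i, res_j)[is.na(c(ii, jj))], collapse = ", "),
         " not in trajectory topology")
  }
  d <- sqrt((traj$xyz[, ii, 1] - traj$xyz[, jj, 1])^2 +
            (traj$xyz[, ii, 2] - traj$xyz[, jj, 2])^2 +
            (traj$xyz[, ii, 3] - traj$xyz[, jj, 3])^2)
  structure(list(values = d, steps = traj$steps,
                 res_pair = c(res_i, res_j)),
            class = "RCSeries")
}

#' @export
print.RCSeries <- function(x, ...) {
  cat(sprintf("RCSeries %d-%d: %d frames, range %.3f-%.3f nm\n",
              x$res_pair[1], x$res_pair[2], length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Free-energy profile along a reaction coordinate
#'
#' Boltzmann inversion of the sampled distribution: histogram the series,
#' convert counts to probabilities, and take `F = -k_B T ln P`, shifted so
#' the global minimum sits at zero. Bins with zero counts are omitted rather
#' than smoothed.
#'
#' @param series RCSeries or numeric vector (nm).
#' @param temperature reduced temperature (k_B = 0.008314).
#' @param n_bins number of equal-width bins over the observed range.
#' @return data.frame of class `"FreeEnergyProfile"` with `bin_center` (nm),
#'   `F` (eps), `count`; attributes `temperature` and `bin_width`.
#' @export
pmf <- function(series, temperature = 100, n_bins = 50L) {
  v <- if (inherits(series, "RCSeries")) series$values else as.numeric(series)
  stopifnot(temperature > 0, n_bins >= 1)
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("all samples identical; single-point profile")
    out <- data.frame(bin_center = rng[1], F = 0, count = length(v))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    keep <- h$counts > 0
    if (sum(keep) == 1L) warning("all samples in one bin")
    p <- h$counts[keep] / length(v)
    F <- -KB_REDUCED * temperature * log(p)
    out <- data.frame(bin_center = h$mids[keep], F = F - min(F),
                      count = h$counts[keep])
  }
  attr(out, "temperature") <- temperature
  attr(out, "bin_width") <- if (diff(rng) == 0) 0 else diff(rng) / n_bins
  class(out) <- c("FreeEnergyProfile", "data.frame")
  out
}

#' Free-energy difference between two basins of a profile
#'
#' Integrates the sampled probability on each side of a dividing point and
#' returns the free energy of the basin below the divide relative to the one
#' above it: `F(below) - F(above) = -k_B T ln(P_below / P_above)`. For a
#' closed/open reaction coordinate divided at the midpoint this is the
#' closed-basin free energy relative to the open basin.
#'
#' @param profile FreeEnergyProfile.
#' @param divide dividing reaction-coordinate value (nm).
#' @return free-energy difference (eps).
#' @export
basinDeltaF <- function(profile, divide) {
  temperature <- attr(profile, "temperature")
  kT <- KB_REDUCED * temperature
  p_below <- sum(profile$count[profile$bin_center < divide])
  p_above <- sum(profile$count[profile$bin_center >= divide])
  if (p_below == 0 || p_above == 0) {
    stop("a basin has zero counts on one side of ", divide)
  }
  -kT * log(p_below / p_above)
}

#' Hysteretic two-state assignment along a reaction coordinate
#'
#' Commits to `open` when the coordinate exceeds `open_threshold`, to
#' `closed` when it drops below `closed_threshold`, and retains the previous
#' committed state in between (hysteresis suppresses spurious recrossings of
#' a single dividing surface). Frames before the first commitment are
#' `intermediate`.
#'
#' @param series RCSeries or numeric vector (nm).
#' @param open_threshold,closed_threshold thresholds (nm), open > closed.
#' @return character vector of labels.
#' @export
assignStates <- function(series, open_threshold, closed_threshold) {
  if (open_threshold <= closed_threshold) {
    stop("open_threshold must exceed closed_threshold")
  }
  v <- if (inherits(series, "RCSeries")) series$values else as.numeric(series)
  labels <- character(length(v))
  state <- "intermediate"
  for (t in seq_along(v)) {
    if (v[t] > open_threshold) state <- "open"
    else if (v[t] < closed_threshold) state <- "closed"
    labels[t] <- state
  }
  labels
}

#' Count committed-state transitions
#'
#' The number of alternations in the committed (`open`/`closed`) subsequence;
#' `intermediate` frames never count.
#'
#' @param labels output of [assignStates].
#' @return integer.
#' @export
countTransitions <- function(labels) {
  committed <- labels[labels != "intermediate"]
  if (length(committed) < 2L) return(0L)
  sum(committed[-1] != committed[-length(committed)])
}

#' Basin populations over committed frames
#'
#' @param labels output of [assignStates].
#' @return named numeric `c(open = ..., closed = ...)`, fractions of
#'   committed frames (both 0 when nothing committed).
#' @export
basinPopulations <- function(labels) {
  committed <- labels[labels != "intermediate"]
  if (length(committed) == 0L) return(c(open = 0, closed = 0))
  c(open = mean(committed == "open"), closed = mean(committed == "closed"))
}

ACIDIC_O_ATOMS <- c("OD1", "OD2", "OE1", "OE2")
BASIC_N_ATOMS <- c("NZ", "NH1", "NH2", "NE")

#' Salt-bridge distance series from an all-atom trajectory
#'
#' Per frame, the closest distance between any side-chain carboxylate oxygen
#' of the acidic residue (OD1/OD2/OE1/OE2) and any side-chain nitrogen of the
#' basic residue (NZ/NH1/NH2/NE). Requires all-atom input: a CA-only
#' trajectory is refused because the charged centres do not exist there. The
#' measure is symmetric in the order of the two residues.
#'
#' @param traj an all-atom trajectory as returned by [readAtomTrajectory], or
#'   a single [Structure] (one frame).
#' @param res_a,res_b author residue numbers of the acidic/basic pair (either
#'   order).
#' @param acidic_atoms,basic_atoms atom-name sets defining the charged
#'   centres (HIS can be included by adding its ring nitrogens).
#' @return numeric vector of per-frame minimum O-N distances (nm).
#' @export
saltBridgeSeries <- function(traj, res_a, res_b,
                             acidic_atoms = ACIDIC_O_ATOMS,
                             basic_atoms = BASIC_N_ATOMS) {
  if (inherits(traj, "Structure")) {
    m <- as.matrix(traj$atoms[, c("x", "y", "z")])
    xyz1 <- array(NA_real_, dim = c(1, nrow(m), 3))
    xyz1[1, , ] <- m
    traj <- list(atoms = traj$atoms, xyz = xyz1)
  }
  at <- traj$atoms
  pick <- function(resno, names) which(at$resno == resno & at$elety %in% names)
  o_idx <- pick(res_a, acidic_atoms); n_idx <- pick(res_a, basic_atoms)
  o2 <- pick(res_b, acidic_atoms); n2 <- pick(res_b, basic_atoms)
  # symmetric in argument order: find which residue carries the oxygens
  if (length(o_idx) > 0L && length(n2) > 0L) {
    ox <- o_idx; nx <- n2
  } else if (length(o2) > 0L && length(n_idx) > 0L) {
    ox <- o2; nx <- n_idx
  } else {
    stop("missing side-chain atoms: need ",
         paste(acidic_atoms, collapse = "/"), " on one residue and ",
         paste(basic_atoms, collapse = "/"), " on the other (residues ",
         res_a, ", ", res_b, "); is the input all-atom?")
  }
  nf <- dim(traj$xyz)[1]
  vapply(seq_len(nf), function(f) {
    oc <- traj$xyz[f, ox, , drop = FALSE]
    nc <- traj$xyz[f, nx, , drop = FALSE]
    dmin <- Inf
    for (a in seq_along(ox)) {
      d <- sqrt((oc[1, a, 1] - nc[1, , 1])^2 + (oc[1, a, 2] - nc[1, , 2])^2 +
                (oc[1, a, 3] - nc[1, , 3])^2)
      dmin <- min(dmin, d)
    }
    dmin
  }, numeric(1))
}

#' Fraction of frames with a formed salt bridge
#'
#' @param series per-frame distances (nm).
#' @param cutoff formation cutoff (nm); 0.5 nm is the conventional
#'   charged-centre criterion.
#' @return fraction in `[0, 1]`.
#' @export
fractionFormed <- function(series, cutoff = 0.5) {
  mean(series <= cutoff)
}

#' Read an all-atom multi-model PDB trajectory
#'
#' @param path multi-model PDB.
#' @return list with `atoms` (template atom table, nm) and `xyz`
#'   (frames x atoms x 3, nm).
#' @export
readAtomTrajectory <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          verbose = FALSE))
  at <- pdb$atom
  nf <- nrow(pdb$xyz)
  n <- nrow(at)
  xyz <- array(NA_real_, dim = c(nf, n, 3))
  for (f in seq_len(nf)) {
    m <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE) / 10
    xyz[f, , ] <- m
  }
  atoms <- data.frame(
    chain = at$chain, resno = as.integer(at$resno), resid = at$resid,
    elety = trimws(at$elety), elesym = trimws(at$elesy),
    x = xyz[1, , 1], y = xyz[1, , 2], z = xyz[1, , 3],
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, xyz = xyz)
}

#' Write an all-atom trajectory as a multi-model PDB
#'
#' @param traj list with `atoms` and `xyz` as from [readAtomTrajectory] or
#'   [makeSaltBridgeFixture].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAtomTrajectory <- function(traj, path) {
  at <- traj$atoms
  nf <- dim(traj$xyz)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyzA <- matrix(traj$xyz[f, , ], ncol = 3) * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), at$elety, at$resid, at$chain, at$resno,
      xyzA[, 1], xyzA[, 2], xyzA[, 3], at$elesym), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Tune the closed-state contact strength to balanced two-state sampling
#'
#' The dual-basin protocol fixes the open-specific strength and raises the
#' closed-specific strength `eps_cs` until the trajectory shows multiple
#' committed transitions with both basins populated. This runs one seeded
#' simulation per grid point (ascending), scores each by transition count and
#' basin balance, and returns the smallest qualifying `eps_cs` together with
#' the full per-point report. When no grid point qualifies the report is
#' still returned, with `chosen = NA`.
#'
#' @param open_ref open-state reference Structure.
#' @param cm classified ContactMap.
#' @param params [sbmParams()]; its `eps_cs` is overridden by the grid.
#' @param integrator [integratorParams()]; grid point k runs with seed
#'   `seed + k - 1` so points are independent but reproducible.
#' @param eps_grid ascending numeric grid of `eps_cs` values.
#' @param rc_pair `c(res_i, res_j)` reaction-coordinate residues.
#' @param open_threshold,closed_threshold hysteresis thresholds (nm).
#' @param min_transitions minimum committed transitions to qualify.
#' @param balance admissible `[low, high]` interval for the open-basin
#'   population (closed is its complement).
#' @return list of class `"EpsCSScan"`: `chosen` (numeric or NA), `report`
#'   (data.frame: eps_cs, seed, n_transitions, pop_open, pop_closed,
#'   qualifies), `criteria`.
#' @export
tuneEpsilonCS <- function(open_ref, cm, params = sbmParams(),
                          integrator = integratorParams(),
                          eps_grid = c(0.5, 0.8, 1.1),
                          rc_pair, open_threshold, closed_threshold,
                          min_transitions = 2L, balance = c(0.2, 0.8)) {
  if (is.unsorted(eps_grid)) stop("eps_grid must be ascending")
  rows <- vector("list", length(eps_grid))
  for (k in seq_along(eps_grid)) {
    p_k <- params
    p_k$eps_cs <- eps_grid[k]
    top <- buildTopology(open_ref, cm, p_k)
    integ <- integrator
    integ$seed <- integrator$seed + k - 1L
    traj <- runDynamics(top, params = integ)
    rc <- rcSeries(traj, rc_pair[1], rc_pair[2])
    labels <- assignStates(rc, open_threshold, closed_threshold)
    nt <- countTransitions(labels)
    pops <- basinPopulations(labels)
    rows[[k]] <- data.frame(
      eps_cs = eps_grid[k], seed = integ$seed, n_transitions = nt,
      pop_open = pops["open"], pop_closed = pops["closed"],
      qualifies = nt >= min_transitions &&
        pops["open"] >= balance[1] && pops["open"] <= balance[2]
    )
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  chosen <- if (any(report$qualifies)) {
    report$eps_cs[which(report$qualifies)[1L]]
  } else NA_real_
  structure(list(chosen = chosen, report = report,
                 criteria = list(min_transitions = min_transitions,
                                 balance = balance)),
            class = "EpsCSScan")
}

#' @export
print.EpsCSScan <- function(x, ...) {
  if (is.na(x$chosen)) {
    cat("eps_cs scan: NO grid point met the criteria\n")
  } else {
    cat(sprintf("eps_cs scan: chose eps_cs = %.3f\n", x$chosen))
  }
  print(x$report)
  invisible(x)
}
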