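KB_REDUCED <- 0.008314

#' Integrator parameters for reduced-unit Langevin dynamics
#'
#' Defaults are the standard coarse-grained SBM running conditions: time step
#' 0.0005 (reduced), NVT at a reduced temperature of 100 (with k_B = 0.008314
#' per reduced kelvin, i.e. k_B T = 0.8314 eps), frames and energies saved
#' every 2000 steps. Bead mass is 1 and the friction constant 1 (reduced
#' time^-1); neither affects equilibrium sampling, only the time scale.
#'
#' @param dt time step (reduced units).
#' @param temperature reduced temperature (entered like a Kelvin value;
#'   thermal energy is `0.008314 * temperature` eps).
#' @param friction Langevin friction gamma (reduced time^-1); 0 gives NVE
#'   (plain velocity-Verlet) propagation.
#' @param mass per-bead mass (reduced).
#' @param n_steps number of steps.
#' @param save_every save interval in steps.
#' @param seed RNG seed governing velocity initialisation and the thermostat
#'   noise stream.
#' @return list of class `"IntegratorParams"`.
#' @export
integratorParams <- function(dt = 5e-4, temperature = 100, friction = 1.0,
                             mass = 1.0, n_steps = 1e6, save_every = 2000L,
                             seed = 1L) {
  stopifnot(dt > 0, temperature >= 0, friction >= 0, mass > 0,
            save_every >= 1, n_steps >= 1)
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 mass = mass, n_steps = n_steps,
                 save_every = as.integer(save_every), seed = as.integer(seed)),
            class = "IntegratorParams")
}

#' Run Langevin (BAOAB leapfrog) dynamics over an SBM topology
#'
#' Propagates the beads in the NVT ensemble with a BAOAB-split stochastic
#' leapfrog. Velocities are initialised from the Maxwell-Boltzmann
#' distribution at the target temperature (centre-of-mass motion removed).
#' With `friction = 0` the thermostat is off and the scheme reduces exactly
#' to velocity Verlet, which conserves energy -- the standard integrator
#' sanity check. The same seed and inputs reproduce the trajectory
#' bit-identically.
#'
#' @param top SBMTopology.
#' @param coords0 starting coordinates (default: the topology's reference,
#'   i.e. the open state).
#' @param params [integratorParams()].
#' @return list of class `"Trajectory"`: `xyz` (frames x beads x 3 array,
#'   nm, including the initial frame), `steps`, `energy` (per-frame component
#'   table incl. kinetic energy and instantaneous temperature), `resnos`,
#'   `params`, `seed`.
#' @export
runDynamics <- function(top, coords0 = NULL, params = integratorParams()) {
  if (is.null(coords0)) coords0 <- top$ref_coords
  coords0 <- as.matrix(coords0)
  e0 <- totalEnergy(top, coords0)
  if (!is.finite(e0[["total"]])) stop("non-finite initial energy")
  set.seed(params$seed)
  res <- run_dynamics_cpp(coords0, topoToC(top), params$dt,
                          params$temperature, params$friction, params$mass,
                          params$n_steps, params$save_every)
  n_frames <- nrow(res$xyz)
  n <- top$n_beads
  xyz <- aperm(array(t(res$xyz), dim = c(3, n, n_frames)), c(3, 2, 1))
  traj <- list(
    xyz = xyz,
    steps = as.numeric(res$steps),
    energy = as.data.frame(res$energy),
    velocities = res$velocities,
    resnos = top$resnos,
    params = params,
    seed = params$seed
  )
  class(traj) <- "Trajectory"
  traj
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d frames x %d beads (steps %g..%g, save every %d)\n",
    dim(x$xyz)[1], dim(x$xyz)[2], min(x$steps), max(x$steps),
    x$params$save_every))
  cat(sprintf("  mean T = %.2f (target %.2f), seed %d\n",
              mean(x$energy$temperature), x$params$temperature, x$seed))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj Trajectory.
#' @return integer.
#' @export
nFrames <- function(traj) dim(traj$xyz)[1]

#' Instantaneous temperature from velocities
#'
#' `2 KE / (3 N k_B)` in reduced units, with `k_B = 0.008314` per reduced
#' kelvin.
#'
#' @param velocities n x 3 matrix.
#' @param mass per-bead mass.
#' @return reduced temperature.
#' @export
instantaneousTemperature <- function(velocities, mass = 1.0) {
  v <- as.matrix(velocities)
  ke <- 0.5 * mass * sum(v^2)
  2 * ke / (3 * nrow(v) * KB_REDUCED)
}

#' Write a trajectory to disk
#'
#' `multi_model_pdb` writes one MODEL per frame (CA-only bead records, author
#' numbering preserved, step indices stored on REMARK lines) -- a plain-text
#' container any structure viewer reads. `dcd` writes a CHARMM/NAMD-style DCD
#' binary readable by standard analysis tools (coordinates stored in
#' Angstrom, single precision).
#'
#' @param traj Trajectory.
#' @param path output file.
#' @param format `"multi_model_pdb"` or `"dcd"`.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, format = c("multi_model_pdb", "dcd")) {
  format <- match.arg(format)
  nf <- nFrames(traj)
  n <- dim(traj$xyz)[2]
  if (format == "multi_model_pdb") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("REMARK 250 STEPS %s",
                       paste(format(traj$steps, scientific = FALSE,
                                    trim = TRUE), collapse = " ")), con)
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      xyzA <- traj$xyz[f, , , drop = TRUE] * 10  # nm -> Angstrom
      if (is.null(dim(xyzA))) xyzA <- matrix(xyzA, ncol = 3)
      writeLines(sprintf(
        "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        seq_len(n), traj$resnos, xyzA[, 1], xyzA[, 2], xyzA[, 3]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  writeDcd(traj$xyz, path, traj$steps)
  invisible(path)
}

writeDcd <- function(xyz, path, steps) {
  nf <- dim(xyz)[1]; n <- dim(xyz)[2]
  first <- if (nf > 1) steps[2] else steps[1]
  interval <- if (nf > 1) steps[2] - steps[1] else 1
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L)
  # header block
  wInt(84L)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf
  icntrl[2] <- as.integer(first)
  icntrl[3] <- as.integer(interval)
  icntrl[4] <- as.integer(max(steps))
  wInt(icntrl)
  wInt(84L)
  # title block
  title <- sprintf("%-80s", "written by twostateSBM")
  wInt(4L + 80L)
  wInt(1L)
  writeChar(title, con, nchars = 80, eos = NULL)
  wInt(4L + 80L)
  # natoms block
  wInt(4L); wInt(n); wInt(4L)
  for (f in seq_len(nf)) {
    fr <- matrix(xyz[f, , ], ncol = 3) * 10  # nm -> Angstrom
    for (d in 1:3) {
      wInt(4L * n)
      writeBin(as.numeric(fr[, d]), con, size = 4L)
      wInt(4L * n)
    }
  }
}

#' Read a trajectory from disk
#'
#' @param path file written by [writeTrajectory] (or any multi-model PDB /
#'   CHARMM-style DCD).
#' @param format `"multi_model_pdb"` or `"dcd"`.
#' @return Trajectory (coordinate frames, steps when recorded; no energy
#'   log).
#' @export
readTrajectory <- function(path, format = c("multi_model_pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "multi_model_pdb") {
    lines <- readLines(path)
    atom <- grepl("^ATOM  |^HETATM", lines)
    models <- cumsum(grepl("^MODEL", lines))
    if (max(models) == 0L) models <- rep(1L, length(lines))
    al <- lines[atom]
    mf <- models[atom]
    nf <- length(unique(mf))
    n <- sum(mf == mf[1])
    if (length(al) != nf * n) stop("truncated or ragged multi-model PDB")
    x <- as.numeric(substr(al, 31, 38)) / 10
    y <- as.numeric(substr(al, 39, 46)) / 10
    z <- as.numeric(substr(al, 47, 54)) / 10
    resnos <- as.integer(substr(al[seq_len(n)], 23, 26))
    xyz <- array(NA_real_, dim = c(nf, n, 3))
    for (f in seq_len(nf)) {
      rows <- ((f - 1) * n + 1):(f * n)
      xyz[f, , 1] <- x[rows]; xyz[f, , 2] <- y[rows]; xyz[f, , 3] <- z[rows]
    }
    steps <- seq_len(nf) - 1
    rem <- grep("^REMARK 250 STEPS ", lines, value = TRUE)
    if (length(rem) == 1L) {
      st <- as.numeric(strsplit(sub("^REMARK 250 STEPS ", "", rem), " ")[[1]])
      if (length(st) == nf) steps <- st
    }
  } else {
    dcd <- readDcd(path)
    xyz <- dcd$xyz
    steps <- dcd$steps
    resnos <- seq_len(dim(xyz)[2])
  }
  traj <- list(xyz = xyz, steps = steps,
               energy = NULL, resnos = resnos,
               params = NULL, seed = NA_integer_)
  class(traj) <- "Trajectory"
  traj
}

readDcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rInt <- function(k = 1L) readBin(con, "integer", n = k, size = 4L)
  if (rInt() != 84L) stop("not a DCD file (bad header length)")
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("not a DCD file (magic '", magic, "')")
  icntrl <- rInt(20L)
  if (rInt() != 84L) stop("corrupt DCD header")
  tlen <- rInt()
  readBin(con, "raw", n = tlen)
  rInt()
  if (rInt() != 4L) stop("corrupt DCD natom block")
  n <- rInt()
  rInt()
  nf <- icntrl[1]
  xyz <- array(NA_real_, dim = c(nf, n, 3))
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      blen <- rInt()
      if (length(blen) == 0L || blen != 4L * n) {
        stop("truncated DCD at frame ", f)
      }
      vals <- readBin(con, "numeric", n = n, size = 4L)
      if (length(vals) != n) stop("truncated DCD at frame ", f)
      xyz[f, , d] <- vals / 10  # Angstrom -> nm
      rInt()
    }
  }
  first <- icntrl[2]; interval <- max(icntrl[3], 1L)
  steps <- first + interval * (seq_len(nf) - 1L)
  if (nf >= 1L && first > 0L) steps <- c(0L, steps[-nf] )
  list(xyz = xyz, first = first, interval = interval, steps = steps)
}
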