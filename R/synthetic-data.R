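#' Specification for the synthetic two-state toy protein
#'
#' The toy emulates the architecture of a hinge-bending, two-lobed binding
#' protein: two compact lobes (beta-hairpin-like bead arrangements) joined by
#' a curved hinge, plus an optional C-terminal tail that docks onto the
#' mobile lobe only in the open state (the analogue of a swapped C-terminal
#' helix). The closed state brings the lobe tips into contact across the
#' binding mouth; the open state rotates the mobile lobe away about the
#' hinge. All geometry is deterministic given the seed (the seed only sets a
#' small symmetry-breaking jitter).
#'
#' @param n_lobe1,n_lobe2 beads per lobe (>= 5).
#' @param n_tail tail beads (0 disables the tail).
#' @param n_hinge hinge beads.
#' @param hinge_angle opening rotation of lobe 2 between the states, degrees,
#'   in (20, 120).
#' @param bond_length virtual CA-CA bond (nm).
#' @param strand_sep cross-strand spacing inside a lobe (nm).
#' @param contact_cutoff CA-CA construction cutoff used for the planted
#'   contact labels (nm).
#' @param min_seq_sep minimum sequence separation for planted contacts.
#' @param ratio state-specificity distance ratio for planted labels.
#' @param seed integer seed.
#' @return list of class `"ToySpec"`.
#' @export
toySpec <- function(n_lobe1 = 15L, n_lobe2 = 15L, n_tail = 6L,
                    n_hinge = 8L, hinge_angle = 45, bond_length = 0.38,
                    strand_sep = 0.55, contact_cutoff = 0.8,
                    min_seq_sep = 4L, ratio = 1.5, seed = 1L) {
  stopifnot(n_lobe1 >= 5, n_lobe2 >= 5, n_tail >= 0, n_hinge >= 3,
            hinge_angle > 20, hinge_angle < 120, bond_length > 0)
  structure(list(n_lobe1 = as.integer(n_lobe1), n_lobe2 = as.integer(n_lobe2),
                 n_tail = as.integer(n_tail), n_hinge = as.integer(n_hinge),
                 hinge_angle = hinge_angle, bond_length = bond_length,
                 strand_sep = strand_sep, contact_cutoff = contact_cutoff,
                 min_seq_sep = as.integer(min_seq_sep), ratio = ratio,
                 seed = as.integer(seed)),
            class = "ToySpec")
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# beta-hairpin-like bead arrangement in a local frame: strand A out along
# +x, one turn bead, strand B back at y = strand_sep; small out-of-plane
# zig-zag keeps consecutive bonds away from collinearity
hairpinTemplate <- function(n, b, s, zig = 0.12) {
  a <- sqrt(b^2 - zig^2)
  mA <- ceiling((n - 1) / 2)
  mB <- n - 1L - mA
  xyz <- matrix(NA_real_, n, 3)
  for (k in seq_len(mA)) {
    xyz[k, ] <- c((k - 1) * a, 0, (k %% 2) * zig)
  }
  cturn <- sqrt(max(b^2 - (s / 2)^2, 0.02^2))
  xyz[mA + 1, ] <- c((mA - 1) * a + cturn, s / 2, 0)
  for (k in seq_len(mB)) {
    xyz[mA + 1 + k, ] <- c((mB - k) * a, s, (k %% 2) * zig)
  }
  xyz
}

placeSegment <- function(template, origin, axis_deg) {
  R2 <- rot2(axis_deg)
  xy <- template[, 1:2, drop = FALSE] %*% t(R2)
  cbind(xy[, 1] + origin[1], xy[, 2] + origin[2], template[, 3])
}

# hinge arc: step nh beads from a start point/heading, turning turn_total
# degrees distributed evenly over the bonds; returns bead positions plus the
# exit point and heading for the next segment
hingeArc <- function(start, heading_deg, turn_total, nh, b, zig = 0.1) {
  xyz <- matrix(NA_real_, nh, 3)
  per_bond <- turn_total / (nh + 1)
  dir <- heading_deg
  p <- start
  for (k in seq_len(nh)) {
    dir <- dir + per_bond
    p <- p + b * c(cos(dir * pi / 180), sin(dir * pi / 180))
    xyz[k, ] <- c(p[1], p[2], (k %% 2) * zig)
  }
  dir <- dir + per_bond
  exit <- p + b * c(cos(dir * pi / 180), sin(dir * pi / 180))
  list(xyz = xyz, exit = exit, exit_dir = dir)
}

buildToyState <- function(spec, state, jitter) {
  b <- spec$bond_length; s <- spec$strand_sep
  lobe1 <- hairpinTemplate(spec$n_lobe1, b, s) + jitter$lobe1
  lobe2 <- hairpinTemplate(spec$n_lobe2, b, s) + jitter$lobe2
  # lobe 1: axis slightly below +x; strand A (mouth side) faces lobe 2
  l1_axis <- -7
  l1 <- placeSegment(lobe1, origin = c(1.8, 0.6), axis_deg = l1_axis)
  exit1 <- l1[spec$n_lobe1, 1:2]
  heading <- 180 + l1_axis  # strand B runs back along -axis
  # closed: the hinge swings under lobe 1 and the lobes converge so that
  # lobe-2's mouth-facing strand (strand B) meets lobe-1's strand A near the
  # tips; open: the same arc turns hinge_angle less, splaying the mouth
  turn_closed <- 188
  turn <- if (state == "closed") turn_closed else turn_closed - spec$hinge_angle
  arc <- hingeArc(exit1, heading, turn, spec$n_hinge, b)
  arc$xyz <- arc$xyz + jitter[[paste0("hinge_", state)]]
  l2_axis <- arc$exit_dir
  l2 <- placeSegment(lobe2, origin = arc$exit, axis_deg = l2_axis)
  coords <- rbind(l1, arc$xyz, l2)
  if (spec$n_tail > 0) {
    a <- sqrt(b^2 - 0.12^2)
    exit2 <- lobe2[spec$n_lobe2, ]  # local frame of lobe 2
    # docked conformation: a third strand one layer beyond lobe-2's
    # mouth-facing strand, i.e. in the cleft that lobe 1 occupies when the
    # protein closes -- docking and closing are mutually exclusive, as for a
    # C-terminal helix parked at the back of the binding pocket
    cturn <- sqrt(max(b^2 - (s / 2)^2, 0.02^2))
    k <- seq_len(spec$n_tail)
    tail_local <- cbind(
      exit2[1] + cturn + (k - 1) * a,
      exit2[2] + s,
      (k %% 2) * 0.12
    )
    tail_local[1, 2] <- exit2[2] + s / 2  # connector bead sits between layers
    tail_local <- tail_local + jitter$tail
    if (state == "closed") {
      # undocked: the tail peels out of the cleft rigidly, the lift
      # distributed along its joints (starting at the attachment) so bonds
      # and internal pair distances are preserved
      per_joint <- 80 / spec$n_tail * pi / 180
      pivots <- rbind(exit2, tail_local[-spec$n_tail, , drop = FALSE])
      for (kk in seq_len(spec$n_tail)) {
        pivot <- pivots[kk, ]
        rows <- kk:spec$n_tail
        rel <- sweep(tail_local[rows, , drop = FALSE], 2, pivot)
        # rotate about the local y axis through the pivot (out of plane)
        xz <- rel[, c(1, 3), drop = FALSE] %*%
          t(matrix(c(cos(per_joint), sin(per_joint),
                     -sin(per_joint), cos(per_joint)), 2, 2))
        rel[, 1] <- xz[, 1]; rel[, 3] <- xz[, 2]
        tail_local[rows, ] <- sweep(rel, 2, pivot, "+")
      }
    }
    tail <- placeSegment(tail_local, origin = arc$exit, axis_deg = l2_axis)
    coords <- rbind(coords, tail)
  }
  coords
}

toyStructureFromCoords <- function(coords, title) {
  n <- nrow(coords)
  Structure(
    data.frame(chain = "A", resno = seq_len(n), resid = "GLY", elety = "CA",
               elesym = "C", x = coords[, 1], y = coords[, 2], z = coords[, 3],
               stringsAsFactors = FALSE),
    chain_id = "A", title = title
  )
}

# brute-force planted classification: plain double loop over all residue
# pairs, kept deliberately independent of detectContacts/classifyContacts
plantedContactMap <- function(open_xyz, closed_xyz, spec, segment) {
  n <- nrow(open_xyz)
  rec <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i < spec$min_seq_sep) next
      do <- sqrt(sum((open_xyz[i, ] - open_xyz[j, ])^2))
      dc <- sqrt(sum((closed_xyz[i, ] - closed_xyz[j, ])^2))
      po <- do <= spec$contact_cutoff
      pc <- dc <= spec$contact_cutoff
      if (!po && !pc) next
      klass <- if (po && pc) "common"
        else if (pc && do > spec$ratio * dc) "closed_specific"
        else if (po && dc > spec$ratio * do) "open_specific"
        else "discarded"
      rec[[length(rec) + 1]] <- data.frame(
        res_i = i, res_j = j, d_open = do, d_closed = dc,
        present_open = po, present_closed = pc, class = klass,
        involves_cth = segment[i] == "tail" | segment[j] == "tail",
        stringsAsFactors = FALSE
      )
    }
  }
  cm <- do.call(rbind, rec)
  attr(cm, "params") <- list(mode = "ca_cutoff", cutoff = spec$contact_cutoff,
                             min_seq_sep = spec$min_seq_sep,
                             ratio = spec$ratio,
                             cth_range = if (any(segment == "tail"))
                               range(which(segment == "tail")) else NULL)
  class(cm) <- c("ContactMap", "data.frame")
  cm
}

#' Generate the synthetic two-state toy protein
#'
#' Builds open- and closed-state CA-only structures of the same chain
#' differing by a hinge rotation of the mobile lobe, with the tail docked on
#' the mobile lobe only in the open state, and the ground-truth contact map
#' computed by a brute-force pair scan at the construction cutoff. The
#' generator checks its own output: no steric clash (non-bonded pairs below
#' 0.35 nm), all-bead open/closed RMSD of at least 0.3 nm, and at least one
#' planted contact in each of the common / open-specific / closed-specific
#' classes (a small jitter reseed is attempted before giving up).
#'
#' @param spec a [toySpec()].
#' @return list: `open`, `closed` ([Structure]s), `contacts` (planted
#'   [ContactMap][classifyContacts]), `segment` (per-bead segment labels),
#'   `rc_pair` (suggested reaction-coordinate residue pair: the two lobe
#'   tips), `spec`.
#' @export
makeTwoStateToy <- function(spec = toySpec()) {
  for (attempt in 0:4) {
    seed <- spec$seed + 1000L * attempt
    set.seed(seed)
    jit <- function(n) matrix(runif(3 * n, -0.005, 0.005), n, 3)
    jitter <- list(
      lobe1 = jit(spec$n_lobe1), lobe2 = jit(spec$n_lobe2),
      hinge_open = jit(spec$n_hinge), hinge_closed = jit(spec$n_hinge),
      tail = jit(spec$n_tail)
    )
    open_xyz <- buildToyState(spec, "open", jitter)
    closed_xyz <- buildToyState(spec, "closed", jitter)
    segment <- c(rep("lobe1", spec$n_lobe1), rep("hinge", spec$n_hinge),
                 rep("lobe2", spec$n_lobe2), rep("tail", spec$n_tail))
    # a clash is a non-bonded pair (where excluded volume acts, i.e. at least
    # min_seq_sep apart) closer than the 0.35 nm steric floor
    clash <- function(xyz) {
      dm <- as.matrix(stats::dist(xyz))
      sep <- abs(row(dm) - col(dm))
      any(dm[sep >= spec$min_seq_sep] < 0.35)
    }
    if (clash(open_xyz) || clash(closed_xyz)) next
    if (rmsdNoFit(open_xyz, closed_xyz) < 0.3) {
      stop("toy spec yields open/closed RMSD below 0.3 nm; increase ",
           "hinge_angle or lobe sizes")
    }
    cm <- plantedContactMap(open_xyz, closed_xyz, spec, segment)
    cc <- classCounts(cm)
    if (cc["common"] >= 1 && cc["open_specific"] >= 1 &&
        cc["closed_specific"] >= 1) {
      tip1 <- ceiling(spec$n_lobe1 / 2)  # turn bead = lobe-1 tip
      tip2 <- spec$n_lobe1 + spec$n_hinge + ceiling(spec$n_lobe2 / 2)
      return(list(
        open = toyStructureFromCoords(open_xyz, "toy two-state: open"),
        closed = toyStructureFromCoords(closed_xyz, "toy two-state: closed"),
        contacts = cm, segment = segment, rc_pair = c(tip1, tip2),
        spec = spec
      ))
    }
  }
  stop("could not generate a clash-free toy with all contact classes; ",
       "adjust the spec")
}

#' Synthetic two-state reaction-coordinate series
#'
#' Hidden two-state Markov path with Gaussian emissions, for exercising
#' free-energy and transition analysis against planted truth.
#'
#' @param basin_means length-2 means (nm), e.g. open and closed distances.
#' @param widths length-2 emission standard deviations (nm).
#' @param switch_prob per-frame switching scale in (0, 1).
#' @param n number of frames.
#' @param seed RNG seed.
#' @param weights stationary weights of the two states (sum to 1).
#' @return list: `series` (RCSeries), `path` (true state index per frame, 1
#'   or 2).
#' @export
makeRCSeries <- function(basin_means, widths = c(0.1, 0.1),
                         switch_prob = 0.05, n = 10000L, seed = 1L,
                         weights = c(0.5, 0.5)) {
  stopifnot(length(basin_means) == 2, basin_means[1] != basin_means[2],
            all(widths > 0), switch_prob >= 0, switch_prob < 1,
            abs(sum(weights) - 1) < 1e-9)
  set.seed(seed)
  # transition probs chosen so the stationary distribution equals `weights`
  p12 <- min(2 * switch_prob * weights[2], 1)
  p21 <- min(2 * switch_prob * weights[1], 1)
  path <- integer(n)
  path[1] <- sample(1:2, 1, prob = weights)
  if (n > 1) {
    u <- runif(n - 1)
    for (t in 2:n) {
      p <- if (path[t - 1] == 1) p12 else p21
      path[t] <- if (u[t - 1] < p) 3L - path[t - 1] else path[t - 1]
    }
  }
  values <- rnorm(n, mean = basin_means[path], sd = widths[path])
  series <- structure(list(values = values, steps = seq_len(n) - 1,
                           res_pair = c(NA_integer_, NA_integer_)),
                      class = "RCSeries")
  list(series = series, path = path)
}

#' All-atom salt-bridge fixture with a planted distance schedule
#'
#' Poses an aspartate and a lysine (full side chains) so that the closest
#' carboxylate-oxygen to amine-nitrogen distance in frame t equals
#' `distance_schedule[t]` to construction precision, giving
#' [saltBridgeSeries] a ground truth.
#'
#' @param distance_schedule per-frame OD1-NZ distances (nm, > 0.2).
#' @return all-atom trajectory: list with `atoms` (template table) and `xyz`
#'   (frames x atoms x 3, nm). ASP is residue 10, LYS residue 30.
#' @export
makeSaltBridgeFixture <- function(distance_schedule) {
  if (any(distance_schedule <= 0.2)) {
    stop("schedule distances must exceed 0.2 nm (steric floor)")
  }
  asp <- rbind(
    N   = c(-0.45,  0.11,  0.00),
    CA  = c(-0.38,  0.00,  0.00),
    C   = c(-0.45, -0.12,  0.00),
    O   = c(-0.55, -0.13,  0.05),
    CB  = c(-0.24,  0.02,  0.05),
    CG  = c(-0.12, -0.05,  0.00),
    OD1 = c( 0.00,  0.00,  0.00),
    OD2 = c(-0.12, -0.18, -0.05)
  )
  lys0 <- rbind(
    N   = c(0.70,  0.11,  0.10),
    CA  = c(0.64,  0.00,  0.05),
    C   = c(0.72, -0.10,  0.00),
    O   = c(0.80, -0.15,  0.06),
    CB  = c(0.52,  0.06,  0.00),
    CG  = c(0.40,  0.00,  0.05),
    CD  = c(0.28,  0.06,  0.00),
    CE  = c(0.15,  0.00,  0.05),
    NZ  = c(0.00,  0.00,  0.00)
  )
  atoms <- data.frame(
    chain = "A",
    resno = c(rep(10L, nrow(asp)), rep(30L, nrow(lys0))),
    resid = c(rep("ASP", nrow(asp)), rep("LYS", nrow(lys0))),
    elety = c(rownames(asp), rownames(lys0)),
    elesym = substr(c(rownames(asp), rownames(lys0)), 1, 1),
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE
  )
  nf <- length(distance_schedule)
  na <- nrow(asp) + nrow(lys0)
  xyz <- array(NA_real_, dim = c(nf, na, 3))
  for (f in seq_len(nf)) {
    d <- distance_schedule[f]
    lys <- lys0
    lys[, 1] <- lys[, 1] + d  # NZ lands at (d, 0, 0); OD1 at origin
    fr <- rbind(asp, lys)
    xyz[f, , ] <- fr
  }
  atoms$x <- xyz[1, , 1]; atoms$y <- xyz[1, , 2]; atoms$z <- xyz[1, , 3]
  list(atoms = atoms, xyz = xyz)
}
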