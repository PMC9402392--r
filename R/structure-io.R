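#' @useDynLib twostateSBM, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames rnorm runif sd var dist lm coef
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table head tail modifyList write.csv packageVersion
NULL

ANGSTROM_PER_NM <- 10

#' Construct a Structure object
#'
#' A `Structure` is the package's in-memory representation of one chain (or a
#' set of chains) of a protein model: an atom table in nanometres plus minimal
#' metadata. Author (crystallographic) residue numbering is preserved
#' end-to-end, because all residue references in two-state binding-protein
#' work (hinge residues, reporter pairs such as 56-143, C-terminal-helix
#' ranges) use it.
#'
#' @param atoms data.frame with columns `chain`, `resno` (author numbering,
#'   integer), `resid` (3-letter residue code), `elety` (atom name, e.g.
#'   `"CA"`), `elesym` (element symbol), `x`, `y`, `z` (nanometres).
#' @param chain_id chain identifier the structure represents.
#' @param title free-text description.
#' @return object of class `"Structure"`.
#' @export
Structure <- function(atoms, chain_id = "A", title = "") {
  required <- c("chain", "resno", "resid", "elety", "elesym", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in atom table")
  }
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  s <- structure(
    list(atoms = atoms, chain_id = chain_id, title = title),
    class = "Structure"
  )
  validateStructure(s)
  s
}

validateStructure <- function(s) {
  for (ch in unique(s$atoms$chain)) {
    rn <- unique(s$atoms$resno[s$atoms$chain == ch])
    if (is.unsorted(rn, strictly = TRUE)) {
      stop("residue numbering not strictly increasing in chain ", ch)
    }
  }
  invisible(s)
}

#' @export
print.Structure <- function(x, ...) {
  nres <- length(unique(paste(x$atoms$chain, x$atoms$resno)))
  cat(sprintf(
    "Structure: %d residues, %d atoms, chain(s) %s\n",
    nres, nrow(x$atoms), paste(unique(x$atoms$chain), collapse = ",")
  ))
  if (nzchar(x$title)) cat(" title:", x$title, "\n")
  rng <- range(x$atoms$resno)
  cat(sprintf(" residue range: %d-%d (author numbering)\n", rng[1], rng[2]))
  invisible(x)
}

#' Residue numbers present in a Structure
#' @param s Structure.
#' @return sorted integer vector of author residue numbers.
#' @export
residueNumbers <- function(s) sort(unique(s$atoms$resno))

#' C-alpha coordinates of selected residues
#'
#' @param s Structure.
#' @param resnos author residue numbers; default all residues that have a CA.
#' @return numeric matrix (n x 3, nm) with rownames set to residue numbers.
#' @export
caCoords <- function(s, resnos = NULL) {
  ca <- s$atoms[s$atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  if (!is.null(resnos)) {
    miss <- setdiff(resnos, ca$resno)
    if (length(miss) > 0L) {
      stop("residue(s) without CA atom: ", paste(miss, collapse = ", "))
    }
    ca <- ca[match(resnos, ca$resno), , drop = FALSE]
  }
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

#' Read a PDB file into a Structure
#'
#' Coordinates are converted from Angstrom to nanometres on the way in. Only
#' the first alternate location is kept; this is the usual choice for X-ray
#' inputs feeding a coarse-grained model. Residues lacking a C-alpha atom are
#' kept but flagged with a warning, since every coarse-grained operation
#' downstream needs CA positions.
#'
#' @param source path to a PDB file, or a character vector of PDB text lines.
#' @param model_index 1-based model number for multi-model files.
#' @param chain restrict to one chain id (default: keep all).
#' @param keep_hydrogens keep H atoms (default FALSE; they are never used for
#'   contacts).
#' @return a [Structure].
#' @export
readStructure <- function(source, model_index = 1L, chain = NULL,
                          keep_hydrogens = FALSE) {
  path <- source
  if (length(source) > 1L || !file.exists(source[1L])) {
    looks_like_pdb <- any(grepl("^(ATOM|HETATM|HEADER|MODEL|REMARK)", source))
    if (!looks_like_pdb) stop("file not found: ", source[1L])
    path <- tempfile(fileext = ".pdb")
    writeLines(source, path)
    on.exit(unlink(path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error for '", path[1L], "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in input")
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models) {
    stop("model_index ", model_index, " not present (file has ",
         n_models, " model(s))")
  }
  # bio3d keeps xyz in atom order; apply the same row filter used on $atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
  xyz <- xyz[pdb$atom$type == "ATOM", , drop = FALSE]
  # first altloc only
  keep <- at$alt %in% c(NA, "", "A")
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  elesym <- at$elesy
  if (is.null(elesym) || all(is.na(elesym)) || all(!nzchar(trimws(elesym)))) {
    elesym <- sub("^[0-9]*", "", trimws(at$elety))
    elesym <- substr(elesym, 1L, 1L)
  }
  elesym <- trimws(elesym)
  if (!keep_hydrogens) {
    hyd <- elesym == "H" | grepl("^[0-9]*H", trimws(at$elety))
    at <- at[!hyd, , drop = FALSE]
    xyz <- xyz[!hyd, , drop = FALSE]
    elesym <- elesym[!hyd]
  }
  if (!is.null(chain)) {
    keep <- at$chain %in% chain
    if (!any(keep)) stop("chain '", chain, "' not found")
    at <- at[keep, , drop = FALSE]
    xyz <- xyz[keep, , drop = FALSE]
    elesym <- elesym[keep]
  }
  atoms <- data.frame(
    chain = at$chain, resno = as.integer(at$resno), resid = at$resid,
    elety = trimws(at$elety), elesym = elesym,
    x = xyz[, 1] / ANGSTROM_PER_NM,
    y = xyz[, 2] / ANGSTROM_PER_NM,
    z = xyz[, 3] / ANGSTROM_PER_NM,
    stringsAsFactors = FALSE
  )
  # warn about residues without CA
  key <- paste(atoms$chain, atoms$resno)
  has_ca <- key %in% key[atoms$elety == "CA"]
  if (!all(has_ca)) {
    warning("residue(s) without CA atom flagged: ",
            paste(unique(key[!has_ca]), collapse = ", "))
  }
  Structure(atoms,
            chain_id = paste(unique(atoms$chain), collapse = ","),
            title = if (length(source) == 1L && file.exists(source[1L]))
              basename(source) else "from text")
}

#' Write a Structure to a PDB file
#'
#' Coordinates are converted back from nanometres to Angstrom.
#'
#' @param s Structure.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]) * ANGSTROM_PER_NM)),
    resno = a$resno, resid = a$resid, chain = a$chain,
    elety = a$elety, elesy = a$elesym
  )
  invisible(path)
}

#' Kabsch superposition of two structures
#'
#' Computes the least-squares optimal rigid transform (rotation plus
#' translation, no scaling) taking the mobile structure's C-alpha atoms onto
#' the target's, over a residue selection, via singular value decomposition
#' with the usual reflection correction so that `det(rotation) = +1`.
#'
#' @param mobile,target Structures sharing at least 3 selected residues.
#' @param selection author residue numbers to fit on; default, all residues
#'   shared by the two structures.
#' @return list of class `"SuperpositionResult"`: `rotation` (3x3, applied to
#'   mobile coordinates as `x %*% t(R)`), `translation` (nm), `rmsd` (post-fit
#'   CA RMSD over the selection, nm), `n_atoms_used`.
#' @export
superpose <- function(mobile, target, selection = NULL) {
  shared <- intersect(residueNumbers(mobile), residueNumbers(target))
  if (is.null(selection)) selection <- shared
  selection <- intersect(selection, shared)
  if (length(selection) < 3L) {
    stop("need at least 3 shared residues to superpose (have ",
         length(selection), ")")
  }
  X <- caCoords(mobile, selection)   # mobile
  Y <- caCoords(target, selection)   # target
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  H <- t(Xc) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- unname(sv$v %*% D %*% t(sv$u))
  translation <- unname(yc - as.vector(R %*% xc))
  fitted <- X %*% t(R)
  fitted <- sweep(fitted, 2, translation, "+")
  rmsd <- rmsdNoFit(fitted, Y)
  structure(
    list(rotation = R, translation = translation, rmsd = rmsd,
         n_atoms_used = length(selection)),
    class = "SuperpositionResult"
  )
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition over %d CA atoms: RMSD = %.4f nm\n",
              x$n_atoms_used, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to a Structure
#'
#' @param s Structure.
#' @param fit a [superpose] result.
#' @return transformed Structure (all atoms moved).
#' @export
applyTransform <- function(s, fit) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' RMSD between two matched coordinate sets, without fitting
#'
#' @param a,b n x 3 matrices (nm), rows matched.
#' @return RMSD in nm.
#' @export
rmsdNoFit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  if (nrow(a) < 1L) stop("empty coordinate sets")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' C-alpha distance between two residues
#'
#' The reporter distance for hinge-bending binding proteins (for TmArgBP, the
#' pair 56-143 separates the open state at ~2.2 nm from the closed state at
#' ~0.7 nm).
#'
#' @param s Structure.
#' @param res_i,res_j author residue numbers.
#' @return distance in nm.
#' @export
caDistance <- function(s, res_i, res_j) {
  xy <- caCoords(s, c(res_i, res_j))
  sqrt(sum((xy[1, ] - xy[2, ])^2))
}

#' Graft a swapped C-terminal segment onto a truncated open-state monomer
#'
#' Domain-swapped dimers dock the C-terminal helix (CTH) of one chain onto the
#' body of the other. To build a single-chain open-state model carrying its
#' own CTH: superpose the truncated open monomer onto chain A of the open
#' dimer, then append the CTH residues of chain B -- which dock on chain A --
#' expressed in the monomer's coordinate frame, keeping their author
#' numbering. The output is one chain running through the graft range.
#'
#' @param open_truncated Structure; open-state monomer lacking the tail.
#' @param dimer_chainA Structure; the dimer chain the monomer aligns to.
#' @param dimer_chainB Structure; the chain donating the grafted segment.
#' @param graft_range integer vector `c(first, last)` of author residue
#'   numbers to graft (default 212:225, loop + CTH).
#' @param max_gap chain-break tolerance (nm) between the last monomer CA and
#'   the first grafted CA; larger gaps only warn.
#' @return single-chain Structure ending at `max(graft_range)`.
#' @export
buildMonomerOsCth <- function(open_truncated, dimer_chainA, dimer_chainB,
                              graft_range = c(212L, 225L), max_gap = 0.6) {
  if (length(graft_range) != 2L) stop("graft_range must be c(first, last)")
  graft_ids <- seq(graft_range[1L], graft_range[2L])
  if (graft_range[2L] < graft_range[1L]) {
    return(open_truncated)  # empty graft: nothing to do
  }
  have <- residueNumbers(dimer_chainB)
  miss <- setdiff(graft_ids, have)
  if (length(miss) > 0L) {
    stop("graft residue(s) missing from donor chain: ",
         paste(miss, collapse = ", "))
  }
  shared <- intersect(residueNumbers(open_truncated),
                      residueNumbers(dimer_chainA))
  if (length(shared) < 50L) {
    stop("open monomer and dimer chain A share only ", length(shared),
         " residues; expected >= 50")
  }
  # transform taking dimer frame -> monomer frame (fit chain A onto monomer)
  fit <- superpose(dimer_chainA, open_truncated, shared)
  donor <- dimer_chainB
  donor$atoms <- donor$atoms[donor$atoms$resno %in% graft_ids, , drop = FALSE]
  donor <- applyTransform(donor, fit)
  last_res <- max(residueNumbers(open_truncated))
  if (min(graft_ids) <= last_res) {
    keep <- open_truncated$atoms$resno < min(graft_ids)
    open_truncated$atoms <- open_truncated$atoms[keep, , drop = FALSE]
    last_res <- max(open_truncated$atoms$resno)
  }
  out_chain <- open_truncated$atoms$chain[1L]
  donor$atoms$chain <- out_chain
  merged <- rbind(open_truncated$atoms, donor$atoms)
  out <- Structure(merged, chain_id = out_chain,
                   title = paste0(open_truncated$title, "+grafted ",
                                  graft_range[1L], "-", graft_range[2L]))
  gap <- caDistance(out, last_res, min(graft_ids))
  if (gap > max_gap) {
    warning(sprintf("chain break: CA(%d)-CA(%d) = %.3f nm exceeds %.2f nm",
                    last_res, min(graft_ids), gap, max_gap))
  }
  out
}

#' Map residue numbering between two constructs by sequence alignment
#'
#' Constructs of the same protein can differ by point mutations or small
#' insertions (e.g. a P->GK insertion before the C-terminal helix), shifting
#' author numbering. This aligns the two one-letter sequences globally and
#' returns the residue-number correspondence, so residues can be compared
#' across constructs in a common numbering.
#'
#' @param s Structure whose numbering is to be mapped.
#' @param reference Structure carrying the reference numbering.
#' @return data.frame with columns `resno` (in `s`) and `ref_resno` (aligned
#'   residue in `reference`); unaligned residues are omitted.
#' @export
mapResidueNumbering <- function(s, reference) {
  seq1 <- structureSequence(s)
  seq2 <- structureSequence(reference)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(seq1$code1, collapse = "")),
    Biostrings::AAString(paste(seq2$code1, collapse = "")),
    type = "global", gapOpening = 10, gapExtension = 0.5
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  q <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  i <- 0L; j <- 0L
  out_i <- integer(0); out_j <- integer(0)
  for (k in seq_along(p)) {
    if (p[k] != "-") i <- i + 1L
    if (q[k] != "-") j <- j + 1L
    if (p[k] != "-" && q[k] != "-") {
      out_i <- c(out_i, i); out_j <- c(out_j, j)
    }
  }
  data.frame(resno = seq1$resno[out_i], ref_resno = seq2$resno[out_j])
}

aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

structureSequence <- function(s) {
  ca <- s$atoms[s$atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  code1 <- unname(aa3to1[ca$resid])
  code1[is.na(code1)] <- "X"
  data.frame(resno = ca$resno, code1 = code1, stringsAsFactors = FALSE)
}
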