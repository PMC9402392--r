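#' Detect native residue-residue contacts in one structure
#'
#' Two detection modes are offered. `all_atom` declares residues i and j in
#' contact when any heavy-atom pair across the two residues lies within
#' `cutoff` (a proximity stand-in for surface-complementarity contact
#' callers); `ca_cutoff` uses the C-alpha pair distance alone, which is the
#' right mode for C-alpha-only models such as the synthetic two-state toy.
#' Either way each detected pair is annotated with its CA-CA distance, because
#' the coarse-grained potential lives at C-alpha resolution.
#'
#' @param s Structure.
#' @param mode `"all_atom"` or `"ca_cutoff"`.
#' @param cutoff contact distance threshold in nm (default 0.45 for
#'   `all_atom`, a standard heavy-atom proximity criterion; use ~0.8 for
#'   `ca_cutoff`).
#' @param min_seq_sep minimum sequence separation `j - i` (default 4: pairs
#'   closer along the chain are the business of bonds/angles/dihedrals).
#' @return data.frame with columns `res_i`, `res_j` (`res_i < res_j`, author
#'   numbering) and `d_ca` (CA-CA distance, nm).
#' @export
detectContacts <- function(s, mode = c("all_atom", "ca_cutoff"),
                           cutoff = 0.45, min_seq_sep = 4L) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be positive")
  ca <- caCoords(s)
  resnos <- as.integer(rownames(ca))
  n <- length(resnos)
  if (mode == "ca_cutoff") {
    dm <- as.matrix(stats::dist(ca))
    idx <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
    res_i <- resnos[idx[, 1]]; res_j <- resnos[idx[, 2]]
    d <- dm[idx]
  } else {
    at <- s$atoms[s$atoms$elesym != "H", , drop = FALSE]
    if (!all(at$resno %in% resnos)) {
      bad <- setdiff(unique(at$resno), resnos)
      stop("residue(s) lack a CA atom: ", paste(bad, collapse = ", "))
    }
    hits <- atomPairResidues(as.matrix(at[, c("x", "y", "z")]),
                             at$resno, cutoff)
    if (nrow(hits) == 0L) {
      res_i <- integer(0); res_j <- integer(0); d <- numeric(0)
    } else {
      res_i <- hits[, 1]; res_j <- hits[, 2]
      ii <- match(res_i, resnos); jj <- match(res_j, resnos)
      d <- sqrt(rowSums((ca[ii, , drop = FALSE] - ca[jj, , drop = FALSE])^2))
    }
  }
  keep <- (res_j - res_i) >= min_seq_sep
  out <- data.frame(res_i = res_i[keep], res_j = res_j[keep], d_ca = d[keep])
  out[order(out$res_i, out$res_j), , drop = FALSE]
}

# residue pairs with any atom-atom distance <= cutoff; grid-free O(n^2) sweep
# done blockwise to bound memory
atomPairResidues <- function(xyz, resno, cutoff) {
  n <- nrow(xyz)
  block <- 2000L
  pairs <- list()
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[rows, , drop = FALSE] %*% t(xyz)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      a <- resno[rows[hit[, 1]]]; b <- resno[hit[, 2]]
      keep <- a < b
      pairs[[length(pairs) + 1L]] <- cbind(a[keep], b[keep])
    }
  }
  if (length(pairs) == 0L) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, pairs))
}

#' Classify contacts of two conformations as common or state-specific
#'
#' Pairs detected in both conformations are `common`. A pair detected only in
#' the closed (open) state is `closed_specific` (`open_specific`) when its
#' CA-CA distance in the other state is *strictly* more than `ratio` times its
#' distance in the state where it is present; single-state pairs failing that
#' ratio are kept in the map as `discarded` and contribute nothing to the
#' potential. Distances are measured in both structures for every pair,
#' regardless of where it was detected.
#'
#' @param open,closed Structures of the two conformations (shared author
#'   numbering).
#' @param mode,cutoff,min_seq_sep passed to [detectContacts].
#' @param ratio state-specificity distance ratio (default 1.5).
#' @param cth_range `c(first, last)` author-numbering interval of the
#'   C-terminal tail, or NULL; contacts touching it get `involves_cth = TRUE`.
#' @return a `ContactMap`: data.frame with columns `res_i`, `res_j`, `d_open`,
#'   `d_closed` (nm), `present_open`, `present_closed`, `class`,
#'   `involves_cth`, carrying the detection parameters as attribute `params`.
#' @export
classifyContacts <- function(open, closed, mode = c("all_atom", "ca_cutoff"),
                             cutoff = 0.45, min_seq_sep = 4L, ratio = 1.5,
                             cth_range = NULL) {
  mode <- match.arg(mode)
  det_o <- detectContacts(open, mode, cutoff, min_seq_sep)
  det_c <- detectContacts(closed, mode, cutoff, min_seq_sep)
  key_o <- paste(det_o$res_i, det_o$res_j)
  key_c <- paste(det_c$res_i, det_c$res_j)
  all_pairs <- unique(rbind(det_o[, c("res_i", "res_j")],
                            det_c[, c("res_i", "res_j")]))
  all_pairs <- all_pairs[order(all_pairs$res_i, all_pairs$res_j), ,
                         drop = FALSE]
  key <- paste(all_pairs$res_i, all_pairs$res_j)
  ca_o <- caCoords(open); ca_c <- caCoords(closed)
  pairDist <- function(ca, i, j) {
    rn <- as.integer(rownames(ca))
    ii <- match(i, rn); jj <- match(j, rn)
    if (anyNA(ii) || anyNA(jj)) {
      bad <- c(i[is.na(ii)], j[is.na(jj)])
      stop("cannot measure pair distance: residue(s) ",
           paste(unique(bad), collapse = ", "), " missing")
    }
    sqrt(rowSums((ca[ii, , drop = FALSE] - ca[jj, , drop = FALSE])^2))
  }
  d_open <- pairDist(ca_o, all_pairs$res_i, all_pairs$res_j)
  d_closed <- pairDist(ca_c, all_pairs$res_i, all_pairs$res_j)
  present_open <- key %in% key_o
  present_closed <- key %in% key_c
  klass <- ifelse(
    present_open & present_closed, "common",
    ifelse(present_closed & d_open > ratio * d_closed, "closed_specific",
    ifelse(present_open & d_closed > ratio * d_open, "open_specific",
           "discarded"))
  )
  involves_cth <- if (is.null(cth_range)) {
    rep(FALSE, nrow(all_pairs))
  } else {
    (all_pairs$res_i >= cth_range[1] & all_pairs$res_i <= cth_range[2]) |
      (all_pairs$res_j >= cth_range[1] & all_pairs$res_j <= cth_range[2])
  }
  cm <- data.frame(
    res_i = all_pairs$res_i, res_j = all_pairs$res_j,
    d_open = d_open, d_closed = d_closed,
    present_open = present_open, present_closed = present_closed,
    class = klass, involves_cth = involves_cth,
    stringsAsFactors = FALSE
  )
  rownames(cm) <- NULL
  attr(cm, "params") <- list(mode = mode, cutoff = cutoff,
                             min_seq_sep = as.integer(min_seq_sep),
                             ratio = ratio, cth_range = cth_range)
  class(cm) <- c("ContactMap", "data.frame")
  cm
}

#' Count contacts by class
#'
#' @param cm ContactMap.
#' @return named integer vector over `common`, `open_specific`,
#'   `closed_specific`, `discarded`, plus `open_specific_cth` (open-specific
#'   contacts that involve the configured C-terminal tail).
#' @export
classCounts <- function(cm) {
  lv <- c("common", "open_specific", "closed_specific", "discarded")
  counts <- table(factor(cm$class, levels = lv))
  out <- setNames(as.integer(counts), lv)
  out["open_specific_cth"] <-
    sum(cm$class == "open_specific" & cm$involves_cth)
  out
}

#' @export
print.ContactMap <- function(x, ...) {
  p <- attr(x, "params")
  cc <- classCounts(x)
  cat(sprintf("ContactMap: %d pairs (%s mode, cutoff %.2f nm, seq sep >= %d, ratio %.2f)\n",
              nrow(x), p$mode, p$cutoff, p$min_seq_sep, p$ratio))
  cat(sprintf("  common %d | open-specific %d (%d via tail) | closed-specific %d | discarded %d\n",
              cc["common"], cc["open_specific"], cc["open_specific_cth"],
              cc["closed_specific"], cc["discarded"]))
  invisible(x)
}

#' Write a contact map as TSV
#'
#' The detection parameters are stored in `#`-prefixed header lines so a
#' round-trip through disk is lossless.
#'
#' @param cm ContactMap.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeContactMap <- function(cm, path) {
  p <- attr(cm, "params")
  hdr <- c(
    sprintf("# mode=%s", p$mode),
    sprintf("# cutoff=%.6f", p$cutoff),
    sprintf("# min_seq_sep=%d", p$min_seq_sep),
    sprintf("# ratio=%.6f", p$ratio),
    sprintf("# cth_range=%s",
            if (is.null(p$cth_range)) "NA"
            else paste(p$cth_range, collapse = ":"))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  out <- cm
  out$d_open <- sprintf("%.6f", out$d_open)
  out$d_closed <- sprintf("%.6f", out$d_closed)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contact map written by [writeContactMap]
#'
#' @param path TSV path.
#' @return ContactMap.
#' @export
readContactMap <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  kv <- sub("^# *", "", hdr)
  getv <- function(key) {
    hit <- kv[startsWith(kv, paste0(key, "="))]
    if (length(hit) == 0L) return(NULL)
    sub("^[^=]*=", "", hit[1L])
  }
  df <- tryCatch(
    read.delim(textConnection(lines[body]), stringsAsFactors = FALSE),
    error = function(e) stop("malformed contact-map table in '", path, "': ",
                             conditionMessage(e))
  )
  needed <- c("res_i", "res_j", "d_open", "d_closed", "present_open",
              "present_closed", "class", "involves_cth")
  if (!all(needed %in% names(df))) {
    stop("contact map '", path, "' lacks column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  bad <- which(!df$class %in% c("common", "open_specific", "closed_specific",
                                "discarded"))
  if (length(bad) > 0L) {
    stop("invalid class at data line ", bad[1L], " of '", path, "'")
  }
  key <- paste(df$res_i, df$res_j)
  if (anyDuplicated(key)) {
    stop("duplicate pair at data line ", which(duplicated(key))[1L],
         " of '", path, "'")
  }
  cth_raw <- getv("cth_range")
  cth <- if (is.null(cth_raw) || cth_raw == "NA") NULL
         else as.integer(strsplit(cth_raw, ":")[[1L]])
  attr(df, "params") <- list(
    mode = getv("mode"),
    cutoff = as.numeric(getv("cutoff")),
    min_seq_sep = as.integer(getv("min_seq_sep")),
    ratio = as.numeric(getv("ratio")),
    cth_range = cth
  )
  class(df) <- c("ContactMap", "data.frame")
  df
}
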