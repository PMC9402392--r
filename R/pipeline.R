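#' Run the full dual-basin SBM pipeline from a configuration
#'
#' Orchestrates the workflow: obtain the two end-state structures (either a
#' generated two-state toy or user PDB files, optionally grafting a swapped
#' C-terminal segment onto the open monomer), detect and classify contacts,
#' assemble the dual-basin topology, simulate (either at a fixed `eps_cs` or
#' by scanning a grid until transitions with balanced populations appear),
#' and analyse the trajectory (reaction coordinate, state assignment,
#' free-energy profile). Every stage writes its output under `out_dir`, and a
#' provenance file records the fully-defaulted configuration, package
#' version, seeds and contact class counts, so a run can be reproduced from
#' the provenance alone.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised blocks (all but `output` optional):
#'   \describe{
#'     \item{toy}{arguments for [toySpec()]; used when no `structures` block.}
#'     \item{structures}{`open`, `closed` PDB paths; optional `graft` with
#'       `dimer`, `chain_a`, `chain_b`, `range = c(first, last)`.}
#'     \item{contacts}{`mode`, `cutoff`, `min_seq_sep`, `ratio`, `cth_range`.}
#'     \item{model}{[sbmParams()] arguments; omit `eps_cs` to trigger a scan.}
#'     \item{simulate}{[integratorParams()] arguments.}
#'     \item{scan}{`eps_grid`, `min_transitions`, `balance`.}
#'     \item{analyze}{`rc_pair`, `open_threshold`, `closed_threshold`,
#'       `pmf_bins`.}
#'     \item{output}{`dir`.}
#'   }
#' @return (invisibly) a list with the stage results: `structures`,
#'   `contacts`, `topology`, `scan` (or NULL), `trajectory`, `analysis`,
#'   `out_dir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output$dir
  if (is.null(out_dir)) stop("config$output$dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(stage, ...) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", out_dir, ")", call. = FALSE)
    })
  }

  # ---- structures ----
  toy <- NULL
  if (!is.null(config$structures)) {
    structures <- stage("structures", {
      open <- readStructure(config$structures$open)
      closed <- readStructure(config$structures$closed)
      g <- config$structures$graft
      if (!is.null(g)) {
        dimer_a <- readStructure(g$dimer, chain = g$chain_a)
        dimer_b <- readStructure(g$dimer, chain = g$chain_b)
        open <- buildMonomerOsCth(open, dimer_a, dimer_b,
                                  graft_range = unlist(g$range))
      }
      list(open = open, closed = closed)
    })
    log_msg("structures", "read open/closed structures")
  } else {
    toy_args <- if (is.null(config$toy)) list() else config$toy
    toy <- stage("structures", makeTwoStateToy(do.call(toySpec, toy_args)))
    structures <- list(open = toy$open, closed = toy$closed)
    log_msg("structures", "generated two-state toy (",
            length(residueNumbers(toy$open)), " beads)")
  }
  writeStructure(structures$open, file.path(out_dir, "open.pdb"))
  writeStructure(structures$closed, file.path(out_dir, "closed.pdb"))

  # ---- contacts ----
  cdef <- list(mode = if (is.null(toy)) "all_atom" else "ca_cutoff",
               cutoff = if (is.null(toy)) 0.45 else 0.8,
               min_seq_sep = 4L, ratio = 1.5, cth_range = NULL)
  if (!is.null(toy)) {
    cdef$cth_range <- attr(toy$contacts, "params")$cth_range
  }
  cpar <- utils::modifyList(cdef, as.list(config$contacts))
  cm <- stage("contacts", classifyContacts(
    structures$open, structures$closed, mode = cpar$mode,
    cutoff = cpar$cutoff, min_seq_sep = cpar$min_seq_sep,
    ratio = cpar$ratio, cth_range = unlist(cpar$cth_range)
  ))
  cc <- classCounts(cm)
  log_msg("contacts", sprintf(
    "common %d | open-specific %d | closed-specific %d | discarded %d",
    cc["common"], cc["open_specific"], cc["closed_specific"], cc["discarded"]))
  writeContactMap(cm, file.path(out_dir, "contacts.tsv"))

  # ---- model ----
  margs <- as.list(config$model)
  if (!is.null(margs$cth_range)) margs$cth_range <- unlist(margs$cth_range)
  if (is.null(margs$cth_range)) margs$cth_range <- unlist(cpar$cth_range)
  need_scan <- is.null(margs$eps_cs)
  params <- do.call(sbmParams, margs[!vapply(margs, is.null, logical(1))])

  # ---- integrator ----
  iargs <- as.list(config$simulate)
  integ <- do.call(integratorParams, iargs)

  # ---- analysis defaults ----
  adef <- list(rc_pair = if (!is.null(toy)) toy$rc_pair else NULL,
               open_threshold = NULL, closed_threshold = NULL, pmf_bins = 50L)
  apar <- utils::modifyList(adef, as.list(config$analyze))
  apar$rc_pair <- unlist(apar$rc_pair)
  if (is.null(apar$rc_pair)) stop("analyze$rc_pair is required for PDB input")
  if (is.null(apar$open_threshold) || is.null(apar$closed_threshold)) {
    d_o <- caDistance(structures$open, apar$rc_pair[1], apar$rc_pair[2])
    d_c <- caDistance(structures$closed, apar$rc_pair[1], apar$rc_pair[2])
    mid <- (d_o + d_c) / 2
    if (is.null(apar$open_threshold)) apar$open_threshold <- mid * 1.25
    if (is.null(apar$closed_threshold)) apar$closed_threshold <- mid * 0.75
  }

  # ---- simulate (scan if eps_cs unset) ----
  scan <- NULL
  if (need_scan) {
    sdef <- list(eps_grid = c(1.1, 1.25, 1.4), min_transitions = 2L,
                 balance = c(0.2, 0.8))
    spar <- utils::modifyList(sdef, as.list(config$scan))
    scan <- stage("scan", tuneEpsilonCS(
      structures$open, cm, params, integ,
      eps_grid = unlist(spar$eps_grid), rc_pair = apar$rc_pair,
      open_threshold = apar$open_threshold,
      closed_threshold = apar$closed_threshold,
      min_transitions = spar$min_transitions,
      balance = unlist(spar$balance)
    ))
    if (is.na(scan$chosen)) {
      utils::write.csv(scan$report, file.path(out_dir, "scan_report.csv"),
                       row.names = FALSE)
      stop("pipeline stage 'scan' failed: no eps_cs grid point met the ",
           "criteria (report kept in ", out_dir, ")")
    }
    params$eps_cs <- scan$chosen
    utils::write.csv(scan$report, file.path(out_dir, "scan_report.csv"),
                     row.names = FALSE)
    log_msg("scan", "chose eps_cs = ", scan$chosen)
  }
  top <- stage("build", buildTopology(structures$open, cm, params))
  exportTopology(top, file.path(out_dir, "model.json"), "native_json")
  log_msg("build", sprintf("%d beads, %d DG + %d specific contacts",
                           top$n_beads, nrow(top$dg),
                           nrow(top$spec_open) + nrow(top$spec_closed)))

  traj <- stage("simulate", runDynamics(top, params = integ))
  writeTrajectory(traj, file.path(out_dir, "traj.dcd"), "dcd")
  write.table(cbind(step = traj$steps, traj$energy),
              file.path(out_dir, "energy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_msg("simulate", nFrames(traj), " frames saved")

  # ---- analyze ----
  analysis <- stage("analyze", {
    rc <- rcSeries(traj, apar$rc_pair[1], apar$rc_pair[2])
    labels <- assignStates(rc, apar$open_threshold, apar$closed_threshold)
    profile <- pmf(rc, temperature = integ$temperature,
                   n_bins = apar$pmf_bins)
    list(rc = rc, labels = labels, profile = profile,
         n_transitions = countTransitions(labels),
         populations = basinPopulations(labels))
  })
  write.table(data.frame(step = analysis$rc$steps, d = analysis$rc$values,
                         state = analysis$labels),
              file.path(out_dir, "rc_series.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(analysis$profile),
              file.path(out_dir, "free_energy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_msg("analyze", analysis$n_transitions, " transitions; populations ",
          sprintf("open %.3f / closed %.3f", analysis$populations["open"],
                  analysis$populations["closed"]))

  # ---- provenance ----
  provenance <- list(
    package_version = as.character(utils::packageVersion("twostateSBM")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    toy = if (!is.null(toy)) unclass(toy$spec) else NULL,
    structures = config$structures,
    contacts = cpar,
    model = unclass(params),
    simulate = unclass(integ),
    scan = if (!is.null(scan)) list(grid = scan$report$eps_cs,
                                    chosen = scan$chosen,
                                    criteria = scan$criteria) else NULL,
    analyze = apar,
    class_counts = as.list(cc)
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(structures = structures, contacts = cm, topology = top,
                 scan = scan, trajectory = traj, analysis = analysis,
                 out_dir = out_dir))
}
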