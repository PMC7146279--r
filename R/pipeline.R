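#' Discard the equilibration stage of a trajectory
#'
#' Keeps the frames with time strictly greater than `equilibration_time`
#' (ns), preserving their times — the "production stage" used for all
#' averaged statistics. Trimming is by time, not frame count, matching how
#' equilibration intervals are reported.
#'
#' @param traj a [trajectory()].
#' @param equilibration_time ns to discard; must be `>= 0` and smaller than
#'   the last frame time.
#' @return the trimmed [trajectory()].
#' @export
trim_equilibration <- function(traj, equilibration_time) {
  stopifnot(inherits(traj, "trajectory"))
  if (equilibration_time < 0)
    hs_stop("invalid_input", "equilibration_time must be >= 0")
  last <- traj$times[n_frames(traj)]
  if (equilibration_time >= last)
    hs_stop("invalid_input",
            "equilibration_time (%.4g ns) is not before the last frame time (%.4g ns)",
            equilibration_time, last)
  keep <- which(traj$times > equilibration_time)
  if (length(keep) < 2L)
    hs_stop("insufficient_frames",
            "trimming at %.4g ns leaves %d frame(s); need at least 2",
            equilibration_time, length(keep))
  subset_frames(traj, keep)
}

# All Calpha atoms on one chain (used for whole-protein RMSD/RMSF fits).
select_all_ca <- function(x, chain_id) {
  atoms <- if (inherits(x, "structure_frame")) x$atoms
           else if (inherits(x, "trajectory")) x$topology
           else as.data.frame(x)
  het <- if (is.null(atoms$is_hetatm)) rep(FALSE, nrow(atoms)) else atoms$is_hetatm
  idx <- which(!het & atoms$atom_name == "CA" & atoms$element == "C" &
                 atoms$chain_id == chain_id)
  if (length(idx) == 0L)
    hs_stop("empty_selection", "no Calpha atoms on chain %s", chain_id)
  idx
}

#' Run the full hinge-bending analysis pipeline
#'
#' Orchestrates the stages of the trajectory analysis: equilibration
#' trimming, per-frame lip distance / state / hinge angle with occupancy
#' and conversion counting, Calpha RMSD against the initial structure
#' (computed on the full, untrimmed trajectory), per-residue Calpha RMSF on
#' the production stage, and (optionally) per-frame hydrogen-bond counts
#' between two selections. All per-frame tables are written as CSV, the
#' summary as JSON, and a provenance echo (configuration, package version,
#' input checksums) as YAML. The run is deterministic given inputs.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{`trajectory`}{path to a multi-MODEL PDB, or a [trajectory()]
#'       object.}
#'     \item{`regions`}{preset name, YAML path, or [region_set()].}
#'     \item{`reference`}{optional path to a reference PDB (or a
#'       [structure_frame()]) for the hinge angle; default: first
#'       production frame.}
#'     \item{`thresholds`}{optional `c(closed_max, open_min)`; default
#'       15, 20.}
#'     \item{`equilibration_time`}{ns to discard (default 0).}
#'     \item{`timestep`}{ns between PDB MODELs (default 1).}
#'     \item{`hbonds`}{optional list with `selection_a_residues`,
#'       `selection_b_residues` (residue-name vectors), and optional
#'       `criteria = c(dist, angle)`, `heavy_atom_mode`.}
#'     \item{`angles`}{compute per-frame hinge angles (default `TRUE`).}
#'     \item{`out_dir`}{output directory (created); omit to skip writing.}
#'   }
#' @return an `analysis_report`: list with `hinge` ([analyze_trajectory()]
#'   result), `rmsd`, `rmsf` (data.frames), `hbonds` (or `NULL`),
#'   `config`, `paths` (written files), `warnings`.
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) hs_stop("io_error", "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) hs_stop("invalid_config", "config must be a list or YAML path")
  warn_log <- character(0)
  note <- function(w) warn_log <<- c(warn_log, conditionMessage(w))

  stage <- "input"
  report <- withCallingHandlers(
    tryCatch({
      traj <- config$trajectory
      if (is.character(traj)) {
        traj <- read_pdb(traj, model_policy = "all",
                         timestep = if (is.null(config$timestep)) 1 else config$timestep)
      }
      if (!inherits(traj, "trajectory"))
        hs_stop("invalid_config", "config$trajectory must be a path or trajectory")
      regions <- config$regions
      if (is.character(regions)) regions <- region_preset(regions)
      if (!inherits(regions, "region_set"))
        hs_stop("invalid_config", "config$regions must be a preset name, path or region_set")
      thr <- if (is.null(config$thresholds)) state_thresholds()
             else state_thresholds(config$thresholds[1], config$thresholds[2])
      eq <- if (is.null(config$equilibration_time)) 0 else config$equilibration_time

      stage <- "trim_equilibration"
      prod <- if (eq > 0) trim_equilibration(traj, eq) else traj
      ref <- config$reference
      if (is.character(ref)) ref <- read_pdb(ref, model_policy = "first")
      if (is.null(ref)) ref <- get_frame(prod, 1L)

      stage <- "hinge_analysis"
      hinge <- analyze_trajectory(prod, regions, thr, reference = ref,
                                  angles = !isFALSE(config$angles))

      stage <- "rmsd"
      ca_all <- select_all_ca(traj, regions$chain_id)
      rmsd <- rmsd_series(traj, reference = 1L, analysis_selection = ca_all)

      stage <- "rmsf"
      rmsf <- rmsf_profile(prod, analysis_selection = select_all_ca(prod, regions$chain_id))

      stage <- "hbonds"
      hb <- NULL
      if (!is.null(config$hbonds)) {
        hc <- config$hbonds
        top <- prod$topology
        selA <- which(top$residue_name %in% hc$selection_a_residues)
        selB <- which(top$residue_name %in% hc$selection_b_residues)
        crit <- if (is.null(hc$criteria)) hbond_criteria()
                else hbond_criteria(hc$criteria[1], hc$criteria[2])
        hb <- hbond_count_series(prod, selA, selB, crit,
                                 heavy_atom_mode = isTRUE(hc$heavy_atom_mode))
      }
      list(traj = traj, prod = prod, hinge = hinge, rmsd = rmsd,
           rmsf = rmsf, hbonds = hb, thresholds = thr)
    }, hingescope_error = function(e) {
      hs_stop("stage_failure", "stage '%s' failed: %s", stage,
              conditionMessage(e))
    }),
    hingescope_warning = function(w) { note(w); invokeRestart("muffleWarning") })

  paths <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_timeseries(report$hinge$table, p("hinge.csv"))
    write_timeseries(report$rmsd, p("rmsd.csv"))
    write_timeseries(report$rmsf, p("rmsf.csv"))
    summary <- list(
      occupancy = as.list(report$hinge$occupancy),
      n_conversions = report$hinge$n_conversions,
      distance_A = summary_stats(report$hinge$table$distance_A),
      angle_deg = if (all(is.na(report$hinge$table$angle_deg))) NULL
                  else summary_stats(report$hinge$table$angle_deg),
      rmsd_A = summary_stats(report$rmsd$rmsd_A))
    if (!is.null(report$hbonds)) {
      write_timeseries(data.frame(time_ns = report$hbonds$times,
                                  n_hbonds = report$hbonds$counts),
                      p("hbonds.csv"))
      summary$hbonds <- list(mean = report$hbonds$mean, sd = report$hbonds$sd,
                             heavy_atom_mode = report$hbonds$heavy_atom_mode)
      paths$hbonds <- p("hbonds.csv")
    }
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    prov <- list(
      package = "hingescope",
      version = as.character(utils::packageVersion("hingescope")),
      config = config_echo(config),
      warnings = warn_log)
    yaml::write_yaml(prov, p("provenance.yaml"))
    paths <- c(paths, list(hinge = p("hinge.csv"), rmsd = p("rmsd.csv"),
                           rmsf = p("rmsf.csv"), summary = p("summary.json"),
                           provenance = p("provenance.yaml")))
  }
  structure(list(hinge = report$hinge, rmsd = report$rmsd, rmsf = report$rmsf,
                 hbonds = report$hbonds, config = config, paths = paths,
                 warnings = warn_log),
            class = "analysis_report")
}

summary_stats <- function(x) list(min = min(x), max = max(x), mean = mean(x))

# Serialisable echo of the configuration (objects replaced by descriptions,
# file inputs checksummed).
config_echo <- function(config) {
  lapply(config, function(v) {
    if (is.character(v) && length(v) == 1L && file.exists(v) && !dir.exists(v))
      list(path = v, md5 = unname(tools::md5sum(v)))
    else if (inherits(v, "trajectory")) "<in-memory trajectory>"
    else if (inherits(v, "region_set")) unclass(v)
    else if (inherits(v, "structure_frame")) "<in-memory structure>"
    else v
  })
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  print(x$hinge)
  cat(sprintf("  RMSD %.2f-%.2f A | RMSF over %d residues%s\n",
              min(x$rmsd$rmsd_A), max(x$rmsd$rmsd_A), nrow(x$rmsf),
              if (is.null(x$hbonds)) "" else
                sprintf(" | H-bonds %.2f +/- %.2f", x$hbonds$mean, x$hbonds$sd)))
  if (length(x$warnings)) cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  invisible(x)
}
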