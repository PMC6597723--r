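# Run-plan bookkeeping and end-to-end analysis orchestration.

#' Construct a run-plan entry
#'
#' One row of an MD production plan: how many runs of which method, length
#' and starting conformation were performed for a given redox / cofactor
#' state.  Lengths are stored internally in 0.1-us units so plan totals are
#' exact rational sums.
#'
#' @param redox_state "oxidized" or "reduced".
#' @param nadp_bound logical: NADP+ bound?
#' @param initial_state "closed" or "open" starting conformation.
#' @param md_method "cMD" or "aMD".
#' @param length_per_run_us length of each run, microseconds (> 0).
#' @param n_runs number of independent runs (>= 1).
#' @return data.frame row; `rbind` rows into a plan.
#' @export
run_plan_entry <- function(redox_state, nadp_bound, initial_state,
                           md_method, length_per_run_us, n_runs) {
  redox_state <- match.arg(redox_state, c("oxidized", "reduced"))
  initial_state <- match.arg(initial_state, c("closed", "open"))
  md_method <- match.arg(md_method, c("cMD", "aMD"))
  stopifnot(isTRUE(nadp_bound) || isFALSE(nadp_bound),
            length_per_run_us > 0, n_runs >= 1)
  tenth_us <- round(length_per_run_us * 10)
  if (abs(tenth_us - length_per_run_us * 10) > 1e-9)
    stop("run lengths are kept on a 0.1-us grid; got ", length_per_run_us)
  data.frame(redox_state = redox_state, nadp_bound = nadp_bound,
             initial_state = initial_state, md_method = md_method,
             length_tenth_us = as.integer(tenth_us),
             n_runs = as.integer(n_runs), stringsAsFactors = FALSE)
}

#' The CPR production run plan
#'
#' The full plan of the CPR study this package analyzes: for each redox
#' state, 16 x 0.2-us cMD runs from the closed form each extended by 1-us
#' aMD, 8 x 0.2-us cMD runs from the open form each extended by 0.4-us aMD,
#' and a 16-run closed-form cMD+aMD set without bound NADP+.  Totals
#' 86.4 us overall; per redox state the NADP+-bound subtotals are 4.8 us of
#' cMD and 19.2 us of aMD.
#'
#' @return data.frame of run-plan entries.
#' @export
cpr_run_plan <- function() {
  rows <- list()
  for (redox in c("oxidized", "reduced")) {
    rows[[length(rows) + 1]] <- run_plan_entry(redox, TRUE, "closed", "cMD", 0.2, 16)
    rows[[length(rows) + 1]] <- run_plan_entry(redox, TRUE, "closed", "aMD", 1.0, 16)
    rows[[length(rows) + 1]] <- run_plan_entry(redox, TRUE, "open", "cMD", 0.2, 8)
    rows[[length(rows) + 1]] <- run_plan_entry(redox, TRUE, "open", "aMD", 0.4, 8)
    rows[[length(rows) + 1]] <- run_plan_entry(redox, FALSE, "closed", "cMD", 0.2, 16)
    rows[[length(rows) + 1]] <- run_plan_entry(redox, FALSE, "closed", "aMD", 1.0, 16)
  }
  do.call(rbind, rows)
}

#' Total simulated length of a (filtered) run plan
#'
#' Sum of length x runs over the entries passing the filters; exact on the
#' 0.1-us grid.  An empty selection totals 0.
#'
#' @param plan run-plan data.frame (see [cpr_run_plan()]).
#' @param redox_state,md_method,initial_state,nadp_bound optional filters.
#' @return Total length in microseconds.
#' @export
plan_total_length <- function(plan, redox_state = NULL, md_method = NULL,
                              initial_state = NULL, nadp_bound = NULL) {
  keep <- rep(TRUE, nrow(plan))
  if (!is.null(redox_state)) keep <- keep & plan$redox_state %in% redox_state
  if (!is.null(md_method)) keep <- keep & plan$md_method %in% md_method
  if (!is.null(initial_state)) keep <- keep & plan$initial_state %in% initial_state
  if (!is.null(nadp_bound)) keep <- keep & plan$nadp_bound == nadp_bound
  sum(as.numeric(plan$length_tenth_us[keep]) * plan$n_runs[keep]) / 10
}

# Turn a selections config block (named list of lists) into selection_spec
# objects.  Supported keys per selection: residue_ranges (list of [first,
# last]), residue_names, atom_names, chain_id.
.selections_from_config <- function(cfg) {
  lapply(stats::setNames(names(cfg), names(cfg)), function(nm) {
    s <- cfg[[nm]]
    if (inherits(s, "selection_spec")) return(s)
    rr <- s$residue_ranges
    if (!is.null(rr) && !is.list(rr)) rr <- list(rr)
    selection_spec(nm, residue_ranges = rr,
                   residue_names = s$residue_names,
                   atom_names = s$atom_names, chain_id = s$chain_id)
  })
}

#' Run the end-to-end analysis described by a config
#'
#' Stages: load trajectory (+ optional Delta-V log) -> optional time window
#' -> snapshot weights -> distance observables -> 1D distributions -> 2D
#' free-energy surface + weighted correlation (when a complex reference
#' provides the FMN-heme axis) -> optional PCA -> manifest.  All numeric
#' outputs are TSV with `#` header comments; a JSON manifest records the
#' full configuration, window, bin edges and effective sample size.  A
#' failure in any stage removes partial outputs and propagates with the
#' stage name.  Identical config + inputs give identical outputs.
#'
#' @param config named list or path to a YAML file with fields:
#'   `trajectory` (PDB path), `selections` (fad_domain / fmn_domain /
#'   fad_ring / fmn_ring blocks), `output_dir`; optional `deltav_log`,
#'   `complex_reference` (path + heme / fad_domain / fmn_ring selection
#'   names resolved on it), `window` (t_start, t_end), `bins` (default 50),
#'   `temperature` (default 310), `pca` (logical or list(k = ...)).
#' @return Invisibly, a list with the distances table, weights, optional
#'   `fel`, `correlation`, `pca`, and output paths.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config lacks output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  fail <- function(stage, e) {
    unlink(written)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  emit <- function(name, header, tab) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    written <<- c(written, path)
    path
  }
  temperature <- config$temperature %||% 310
  nbins <- config$bins %||% 50

  ## -- load ----------------------------------------------------------------
  res <- tryCatch({
    if (!file.exists(config$trajectory))
      stop("trajectory file not found: ", config$trajectory)
    traj <- read_pdb(config$trajectory, times = config$times)
    if (!inherits(traj, "md_trajectory"))
      stop("trajectory file holds a single model")
    dv <- NULL
    if (!is.null(config$deltav_log)) {
      if (!file.exists(config$deltav_log))
        stop("Delta-V log not found: ", config$deltav_log)
      dv <- read_deltav_log(config$deltav_log)
      if (length(dv) != n_frames(traj))
        stop("Delta-V log length ", length(dv), " != frame count ",
             n_frames(traj))
    }
    list(traj = traj, dv = dv)
  }, error = function(e) fail("load", e))
  traj <- res$traj; dv <- res$dv

  ## -- window --------------------------------------------------------------
  keep <- tryCatch({
    if (!is.null(config$window)) {
      select_window(traj$times, config$window$t_start, config$window$t_end)
    } else seq_len(n_frames(traj))
  }, error = function(e) fail("window", e))

  ## -- weights -------------------------------------------------------------
  weights <- tryCatch({
    if (is.null(dv)) rep(1 / length(keep), length(keep))
    else snapshot_weights(dv[keep], temperature)
  }, error = function(e) fail("weights", e))

  ## -- distances -----------------------------------------------------------
  dist_res <- tryCatch({
    sels <- .selections_from_config(config$selections)
    ref <- NULL
    if (!is.null(config$complex_reference)) {
      rc <- config$complex_reference
      if (!file.exists(rc$path))
        stop("complex reference not found: ", rc$path)
      ref_structure <- read_pdb(rc$path)
      ref_sels <- .selections_from_config(rc$selections)
      ref <- complex_reference(ref_structure,
                               fad_domain = ref_sels$fad_domain,
                               fmn_ring = ref_sels$fmn_ring,
                               heme = ref_sels$heme)
    }
    dt <- trajectory_distances(traj, sels, ref = ref)
    dt <- dt[keep, , drop = FALSE]
    emit("distances.tsv",
         paste0("# ", paste(names(dt), collapse = "\t")), dt)
    list(distances = dt, selections = sels, ref = ref)
  }, error = function(e) fail("distances", e))
  dt <- dist_res$distances

  ## -- distributions -------------------------------------------------------
  ess <- effective_sample_size(weights)
  obs <- c("d_interdomain", "d_intercofactor",
           if (!is.null(dt$d_fmn_heme)) "d_fmn_heme")
  hists <- tryCatch({
    lapply(stats::setNames(obs, obs), function(v) {
      edges <- default_edges(dt[[v]], weights, nbins = nbins)
      h <- weighted_histogram(dt[[v]], weights, edges)
      emit(paste0("dist_", v, ".tsv"), "# bin_center\tprobability",
           data.frame(h$mids, h$masses))
      h
    })
  }, error = function(e) fail("distributions", e))

  ## -- free-energy surface + correlation -----------------------------------
  fel <- NULL; corr <- NULL
  if (!is.null(dt$d_fmn_heme)) {
    tryCatch({
      xe <- default_edges(dt$d_interdomain, weights, nbins = nbins)
      ye <- default_edges(dt$d_fmn_heme, weights, nbins = nbins)
      fel <- free_energy_2d(dt$d_interdomain, dt$d_fmn_heme, weights,
                            xe, ye, temperature)
      grid <- expand.grid(x = (xe[-1] + xe[-length(xe)]) / 2,
                          y = (ye[-1] + ye[-length(ye)]) / 2)
      grid$f <- as.vector(fel$f)
      emit("fel.tsv", "# d_interdomain\td_fmn_heme\tfree_energy_kcal_mol",
           grid[as.vector(fel$occupied), , drop = FALSE])
      corr <- weighted_pearson(dt$d_interdomain, dt$d_fmn_heme, weights)
      emit("correlation.tsv", "# observable_x\tobservable_y\tr\tess",
           data.frame("d_interdomain", "d_fmn_heme", corr, ess))
      NULL
    }, error = function(e) fail("correlation", e))
  }

  ## -- pca -----------------------------------------------------------------
  pca_res <- NULL
  if (isTRUE(config$pca) || is.list(config$pca)) {
    pca_res <- tryCatch({
      k <- if (is.list(config$pca)) config$pca$k %||% 3 else 3
      unweighted <- is.list(config$pca) && isTRUE(config$pca$unweighted)
      sub <- md_trajectory(traj$atom, traj$xyz[keep, , drop = FALSE],
                           times = traj$times[keep])
      al <- align_frames(sub)
      cw <- if (unweighted) NULL else weights
      cv <- covariance_matrix(al$trajectory, weights = cw)
      pm <- principal_modes(cv, k = min(k, nrow(cv)))
      emit("pca_eigenvalues.tsv", "# mode\teigenvalue_A2",
           data.frame(seq_along(pm$values), pm$values))
      pm
    }, error = function(e) fail("pca", e))
  }

  ## -- manifest ------------------------------------------------------------
  manifest <- list(
    config = config, temperature = temperature, bins = nbins,
    n_frames_total = n_frames(traj), n_frames_window = length(keep),
    effective_sample_size = ess,
    weighting = if (is.null(dv)) "uniform (cMD)" else "exp(deltaV/kBT) aMD reweighting",
    com_convention = "mass-weighted; heavy atoms only when hydrogens absent",
    correlation = corr)
  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", force = TRUE),
             manifest_path)
  invisible(list(distances = dt, weights = weights, histograms = hists,
                 fel = fel, correlation = corr, pca = pca_res, ess = ess,
                 paths = c(written, manifest_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
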