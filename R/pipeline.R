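# Orchestration of the full comparative analysis: wild-type and mutant
# trajectories in, occupancy/contact/RMSD/PCA reports and a self-describing
# manifest out. Outputs are deterministic for a given config and seed
# (no timestamps), so re-runs are byte-identical.

#' Build a comparison run configuration
#'
#' @param systems named list; each entry is either
#'   `list(topology = <pdb path>, trajectory = <dcd/pdb path>)` or
#'   `list(trajectory = <trajectory object>)`. Names are the system labels.
#' @param reference label of the reference ("WT") system.
#' @param side_a,side_b selection expressions for the two interface sides
#'   (e.g. the receptor and partner chains).
#' @param subdomains named list of selection expressions, one per subdomain
#'   whose time-averaged RMSD is reported.
#' @param pca_selection selection expression for the PCA (default `NULL`:
#'   CA atoms when present, else heavy atoms).
#' @param criteria an [hbond_criteria()].
#' @param contact_kind `"hbond"`, `"vdw"` or `"both"`.
#' @param vdw_cutoff Angstrom.
#' @param bins histogram bin count.
#' @param outdir output directory (created if missing).
#' @param seed integer seed recorded in the manifest.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(systems, reference, side_a, side_b,
                       subdomains = list(), pca_selection = NULL,
                       criteria = hbond_criteria(),
                       contact_kind = "hbond", vdw_cutoff = 4.5,
                       bins = 100, outdir = "mdiface_out", seed = 1) {
  labels <- names(systems)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels) > 0)
    stop("systems must be a named list with unique labels")
  if (!reference %in% labels)
    stop("reference label '", reference, "' is not among the systems")
  for (lab in labels) {
    sys <- systems[[lab]]
    if (!inherits(sys$trajectory, "trajectory")) {
      for (p in c(sys$topology, sys$trajectory))
        if (!file.exists(p)) stop("system '", lab, "': file not found: ", p)
    }
  }
  structure(list(systems = systems, reference = reference,
                 side_a = side_a, side_b = side_b,
                 subdomains = subdomains, pca_selection = pca_selection,
                 criteria = criteria, contact_kind = contact_kind,
                 vdw_cutoff = vdw_cutoff, bins = bins,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a comparison run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `criteria` is given as
#' `max_da_distance` / `min_dha_angle`.
#'
#' @param path YAML config file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  crit <- if (is.null(y$criteria)) hbond_criteria()
          else hbond_criteria(y$criteria$max_da_distance,
                              y$criteria$min_dha_angle)
  run_config(systems = y$systems, reference = y$reference,
             side_a = y$side_a, side_b = y$side_b,
             subdomains = if (is.null(y$subdomains)) list() else y$subdomains,
             pca_selection = y$pca_selection, criteria = crit,
             contact_kind = if (is.null(y$contact_kind)) "hbond" else y$contact_kind,
             vdw_cutoff = if (is.null(y$vdw_cutoff)) 4.5 else y$vdw_cutoff,
             bins = if (is.null(y$bins)) 100 else y$bins,
             outdir = if (is.null(y$outdir)) "mdiface_out" else y$outdir,
             seed = if (is.null(y$seed)) 1 else y$seed)
}

.load_system <- function(sys) {
  if (inherits(sys$trajectory, "trajectory")) return(sys$trajectory)
  topo <- read_structure(sys$topology)$topology
  read_trajectory(sys$trajectory, topo)
}

#' Run the full wild-type versus mutant comparison
#'
#' For every system: interface contact map (atom-level occupancy TSV and
#' residue-pair TSV), subdomain time-averaged RMSD TSV, PCA eigen-summary
#' JSON with projection TSV, and PC1 histogram TSV. For every non-reference
#' system: per-residue reduction TSV, a B-factor PDB colouring the reference
#' frame by per-residue reduction, and the PC1 divergence score. A manifest
#' JSON records the config echo, package version, seed, warnings, and an MD5
#' checksum of every output file.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `systems` (per-system results),
#'   `comparisons` (per-mutant results), `manifest` (the manifest list) and
#'   `manifest_path`.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$systems) < 2) stop("run_compare needs >= 2 systems")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, paste0(...))
  files <- character(0)
  warnings <- character(0)
  labels <- names(config$systems)

  trajs <- lapply(config$systems, .load_system)
  sizes <- vapply(labels, function(lab) {
    topo <- trajs[[lab]]$topology
    .as_selection(topo, config$side_a)$n + .as_selection(topo, config$side_b)$n
  }, numeric(1))
  if (length(unique(sizes)) != 1)
    stop("comparability error: interface selections resolve to different ",
         "atom counts across systems: ",
         paste(sprintf("%s=%d", labels, sizes), collapse = ", "))

  systems <- list()
  for (lab in labels) {
    traj <- trajs[[lab]]
    topo <- traj$topology
    cm <- contact_map(traj, config$side_a, config$side_b,
                      criteria = config$criteria, kind = config$contact_kind,
                      vdw_cutoff = config$vdw_cutoff)
    f1 <- out(lab, "_contact_pairs.tsv"); write_contact_tsv(cm, f1)
    occ <- cm$atom_pairs
    f2 <- out(lab, "_hbond_occupancy.tsv")
    .write_tsv(occ, f2,
               c(sprintf("system: %s", lab),
                 sprintf("max_da_distance_A: %g", config$criteria$max_da_distance),
                 sprintf("min_dha_angle_deg: %g", config$criteria$min_dha_angle)))
    low <- occ$occupancy_pct[occ$occupancy_pct < 5]
    if (length(low) > 0)
      warnings <- c(warnings, sprintf(
        "%s: %d atom-pair occupancies below 5%%", lab, length(low)))

    rmsd_rows <- lapply(names(config$subdomains), function(sd) {
      series <- rmsd_series(traj, fit_selection = config$subdomains[[sd]])
      data.frame(subdomain = sd, selection = config$subdomains[[sd]],
                 time_averaged_rmsd_A = mean(series))
    })
    rmsd_tab <- if (length(rmsd_rows) > 0) do.call(rbind, rmsd_rows)
                else data.frame(subdomain = character(0),
                                selection = character(0),
                                time_averaged_rmsd_A = numeric(0))
    f3 <- out(lab, "_subdomain_rmsd.tsv")
    .write_tsv(rmsd_tab, f3, sprintf("system: %s", lab))

    pca <- trajectory_pca(traj, config$pca_selection,
                          k = min(3, traj$n_frames - 1))
    f4 <- out(lab, "_pca.json")
    f5 <- out(lab, "_pca_projections.tsv")
    write_pca_json(pca, f4, f5)
    f6 <- out(lab, "_pc1_histogram.tsv")
    write_histogram_tsv(pc_histogram(pca, 1, config$bins), f6)

    files <- c(files, f1, f2, f3, f4, f5, f6)
    systems[[lab]] <- list(contact_map = cm, rmsd = rmsd_tab, pca = pca)
  }

  comparisons <- list()
  ref_lab <- config$reference
  ref_traj <- trajs[[ref_lab]]
  for (lab in setdiff(labels, ref_lab)) {
    prof <- reduction_profile(systems[[ref_lab]]$contact_map,
                              systems[[lab]]$contact_map)
    f7 <- out(lab, "_reduction.tsv"); write_reduction_tsv(prof, f7)
    masked <- prof$per_residue$resid[prof$per_residue$masked]
    if (length(masked) > 0)
      warnings <- c(warnings, sprintf(
        "%s: residues masked in reduction profile (zero WT occupancy): %s",
        lab, paste(masked, collapse = " ")))
    vals <- stats::setNames(prof$per_residue$reduction_pct,
                            prof$per_residue$resid)
    f8 <- out(lab, "_reduction_bfactor.pdb")
    write_bfactor_pdb(ref_traj$topology, frame_coords(ref_traj, 1), vals, f8)
    score <- compare_pc1(systems[[ref_lab]]$pca, systems[[lab]]$pca,
                         bins = config$bins)
    comparisons[[lab]] <- list(reduction = prof, pc1_divergence = score)
    files <- c(files, f7, f8)
  }

  manifest <- list(
    package = "mdiface",
    version = as.character(utils::packageVersion("mdiface")),
    seed = config$seed,
    reference = ref_lab,
    config = list(side_a = config$side_a, side_b = config$side_b,
                  subdomains = config$subdomains,
                  pca_selection = config$pca_selection,
                  criteria = unclass(config$criteria),
                  contact_kind = config$contact_kind,
                  vdw_cutoff = config$vdw_cutoff, bins = config$bins),
    overall_reduction_pct = lapply(comparisons, function(x)
      x$reduction$overall_reduction),
    pc1_divergence = lapply(comparisons, function(x) x$pc1_divergence),
    warnings = warnings,
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files)))
  )
  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(systems = systems, comparisons = comparisons,
                 manifest = manifest, manifest_path = manifest_path))
}

#' Fit turnover series from a chase table
#'
#' Input is a TSV/data.frame with columns `time_h`, `raw`, `loading`,
#' `condition`; each condition is normalized to its loading control and
#' t = 0 point, fitted with [fit_decay()], and reported as one JSON fit per
#' condition plus a combined comparison TSV.
#'
#' @param input TSV path or data.frame.
#' @param outdir output directory.
#' @param method passed to [fit_decay()].
#' @return (invisibly) named list of [fit_decay()] results.
#' @export
run_turnover <- function(input, outdir = "mdiface_out",
                         method = "loglinear") {
  df <- if (is.character(input)) {
    utils::read.delim(input, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    as.data.frame(input)
  }
  need <- c("time_h", "raw", "loading", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("turnover input is missing column(s): ", paste(miss, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fits <- list()
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond, , drop = FALSE]
    if (!any(sub$time_h == 0))
      stop("data error: condition '", cond, "' has no t = 0 row")
    series <- normalize_series(sub$raw, sub$loading, sub$time_h,
                               protein = cond)
    fit <- fit_decay(series, method = method)
    jsonlite::write_json(
      list(condition = cond, rate_k_per_h = fit$rate_k,
           half_life_h = fit$half_life, rss = fit$rss,
           n_points = fit$n_points, method = fit$method),
      file.path(outdir, paste0("turnover_", gsub("[^A-Za-z0-9_.-]", "_", cond),
                               ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fits[[cond]] <- fit
  }
  comb <- data.frame(condition = names(fits),
                     rate_k_per_h = vapply(fits, `[[`, numeric(1), "rate_k"),
                     half_life_h = vapply(fits, `[[`, numeric(1), "half_life"))
  .write_tsv(comb, file.path(outdir, "turnover_summary.tsv"))
  invisible(fits)
}
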