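# pipeline_cli: configuration-driven orchestration producing the analysis
# tables (RMSD series, pore profile, contact and coordination summaries,
# descriptor series, PCA projections) with a machine-readable manifest.
# Repeated runs with an identical config are byte-identical.

CONFIG_DEFAULTS <- list(
  models = character(0),        # paths to static PDB models (optional)
  fixture_dir = NULL,           # synthetic fixture directory (optional)
  trajectory = NULL,            # multi-model PDB trajectory path (optional)
  topology = NULL,              # topology PDB for `trajectory`
  frame_dt_ns = 10,
  output_dir = "pentagate-out",
  na_cutoff = 5.0,              # Na+ coordination cutoff, A
  salt_bridge_cutoff = 4.0,     # E243-K248 heavy-atom cutoff, A
  hydration_radial_cutoff = 6.0,
  analysis_window_ns = 300,     # trailing window analyzed
  stride_ns = 10,               # ion-coordination sampling interval
  bootstrap_level = 0.95,
  n_boot = 10000,
  seed = 1,
  ecd_spread_range = c(20, 190),
  ecd_twist_range = c(20, 190),
  tmd_twist_range = c(197, 313),
  ecd_rmsd_ranges = list(c(15, 48), c(66, 192)),
  tmd_rmsd_ranges = list(c(197, 313)),
  lining_range = c(222, 247),
  gate_residue = 233,
  gate_atom = "CB",
  hydration_upper_residue = 237,
  sensor_residue = 35,
  loopf_residue = 158,
  contact_res_a = 243,
  contact_res_b = 248,
  loop_range = c(243, 250),
  loop_core_ranges = list(c(222, 242), c(251, 270)),
  ion_name = "NA"
)

#' Build and validate an analysis configuration
#'
#' Defaults encode the analysis constants (Na+ cutoff 5 A sampled every
#' 10 ns over the trailing 300 ns, salt-bridge cutoff 4 A, hydration radius
#' 6 A, spread residues 20-190, twist TMD 197-313, loop 243-250, bootstrap
#' 95% with 10^4 resamples), so a minimal config lists only inputs. Unknown
#' keys are rejected.
#'
#' @param ... configuration entries overriding the defaults (see
#'   `pentagate:::CONFIG_DEFAULTS` for the full key set).
#' @param file optional YAML file of entries, merged before `...`.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(..., file = NULL) {
  entries <- list()
  if (!is.null(file)) entries <- yaml::read_yaml(file)
  dots <- list(...)
  entries[names(dots)] <- dots
  unknown <- setdiff(names(entries), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- CONFIG_DEFAULTS
  cfg[names(entries)] <- entries
  num_keys <- c("na_cutoff", "salt_bridge_cutoff", "hydration_radial_cutoff",
                "analysis_window_ns", "stride_ns", "bootstrap_level",
                "n_boot", "seed", "frame_dt_ns")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || !is.finite(cfg[[k]])) {
      stop("config error: key '", k, "' must be a single finite number")
    }
  }
  if (cfg$bootstrap_level <= 0 || cfg$bootstrap_level >= 1) {
    stop("config error: bootstrap_level must lie in (0, 1)")
  }
  structure(cfg, class = "analysis_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_table <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
}

#' Run the configured analysis pipeline
#'
#' Loads the configured inputs (a synthetic fixture directory, an explicit
#' trajectory + topology, and/or static models), restricts trajectory
#' observables to the trailing analysis window, and writes per-analysis CSV
#' tables plus a JSON summary and a run manifest (package version, config
#' hash, seeds) to the output directory. All stochastic steps (bootstrap)
#' derive from `config$seed`; two runs with an identical config produce
#' byte-identical artifacts.
#'
#' @param config an [analysis_config()].
#' @return named list of output file paths plus the in-memory results,
#'   invisibly.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  traj <- NULL
  if (!is.null(config$fixture_dir)) {
    if (!dir.exists(config$fixture_dir)) {
      stop("input error: fixture_dir not found: ", config$fixture_dir)
    }
    traj <- read_fixture(config$fixture_dir)
  } else if (!is.null(config$trajectory)) {
    if (!file.exists(config$trajectory)) {
      stop("input error: trajectory not found: ", config$trajectory)
    }
    traj <- read_trajectory(config$trajectory,
                            topology_path = config$topology,
                            dt_ns = config$frame_dt_ns)
  }
  models <- lapply(config$models, function(p) {
    if (!file.exists(p)) stop("input error: model not found: ", p)
    read_pdb(p)
  })
  if (is.null(traj) && length(models) == 0) {
    stop("input error: no trajectory, fixture_dir, or models configured")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  paths <- list()
  summaries <- list()
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  if (!is.null(traj)) {
    ref <- traj$topology
    win <- tail_window(traj, config$analysis_window_ns)
    note("analysis window: ", n_frames(win), " of ", n_frames(traj),
         " frames (trailing ", config$analysis_window_ns, " ns)")
    ecd_sel <- selection(config$ecd_rmsd_ranges, "CA")
    tmd_sel <- selection(config$tmd_rmsd_ranges, "CA")
    rmsd_df <- data.frame(
      time = win$times,
      ecd = per_frame_rmsd(win, ref, ecd_sel)$rmsd,
      tmd = per_frame_rmsd(win, ref, tmd_sel)$rmsd)
    out$rmsd <- rmsd_df
    paths$rmsd <- file.path(config$output_dir, "rmsd.csv")
    write_table(rmsd_df, paths$rmsd,
                c("per-frame RMSD (A) vs topology after CA fit",
                  "ecd residues: 15-48,66-192; tmd residues: 197-313"))

    desc <- descriptor_series(win,
                              spread_sel = selection(config$ecd_spread_range, "CA"),
                              ecd_sel = selection(config$ecd_twist_range, "CA"),
                              tmd_sel = selection(config$tmd_twist_range, "CA"),
                              lining_sel = selection(config$lining_range, "CA"))
    out$descriptors <- desc
    paths$descriptors <- file.path(config$output_dir, "descriptors.csv")
    write_table(desc, paths$descriptors,
                "ECD spread (A) and domain twist (deg) per frame")
    summaries$spread <- descriptor_summary(desc, level = config$bootstrap_level,
                                           n_boot = config$n_boot,
                                           seed = config$seed)$spread
    summaries$twist <- descriptor_summary(desc, level = config$bootstrap_level,
                                          n_boot = config$n_boot,
                                          seed = config$seed)$twist

    ions <- ion_coordination_series(win, residue = config$sensor_residue,
                                    ion_name = config$ion_name,
                                    cutoff = config$na_cutoff,
                                    stride_ns = config$stride_ns)
    ion_df <- data.frame(time = ions$frame_times, pooled = ions$values,
                         ions$per_subunit, check.names = FALSE)
    out$ions <- ion_df
    paths$ions <- file.path(config$output_dir, "ion_coordination.csv")
    write_table(ion_df, paths$ions,
                sprintf("Na+ within %.1f A of residue %d carboxylate, every %g ns",
                        config$na_cutoff, config$sensor_residue,
                        config$stride_ns))
    summaries$ion_contact_fraction <- contact_fraction(ions)

    sb <- salt_bridge_series(win, res_a = config$contact_res_a,
                             res_b = config$contact_res_b,
                             cutoff = config$salt_bridge_cutoff)
    sb_df <- data.frame(time = sb$frame_times, n_subunits = sb$values,
                        sb$per_subunit, check.names = FALSE)
    out$contacts <- sb_df
    paths$contacts <- file.path(config$output_dir, "contacts.csv")
    write_table(sb_df, paths$contacts,
                sprintf("%d-%d salt-bridge state per subunit (cutoff %.1f A)",
                        config$contact_res_a, config$contact_res_b,
                        config$salt_bridge_cutoff))
    summaries$contact_fraction <- contact_fraction(sb)

    hyd <- water_occupancy_series(win,
                                  lower_residue = config$gate_residue,
                                  upper_residue = config$hydration_upper_residue,
                                  radial_cutoff = config$hydration_radial_cutoff,
                                  lining_sel = selection(config$lining_range, "CA"))
    out$hydration <- hyd
    paths$hydration <- file.path(config$output_dir, "hydration.csv")
    write_table(hyd, paths$hydration,
                sprintf("water O between residues %d and %d, radial cutoff %.1f A",
                        config$gate_residue, config$hydration_upper_residue,
                        config$hydration_radial_cutoff))
    summaries$water_occupancy <- bootstrap_median_ci(hyd$count,
                                                     level = config$bootstrap_level,
                                                     n_boot = config$n_boot,
                                                     seed = config$seed)

    ref_axis <- estimate_pore_axis(ref, selection(config$lining_range, "CA"))
    prof <- pore_profile(ref, ref_axis, config$lining_range)
    out$pore_profile <- prof
    paths$pore_profile <- file.path(config$output_dir, "pore_profile.csv")
    write_table(as.data.frame(prof), paths$pore_profile,
                "CA pore radius profile of the topology model")
    summaries$gate_radius <- gate_radius(ref, ref_axis,
                                         residue = config$gate_residue,
                                         atom_name = config$gate_atom)
    note("pore profile over residues ",
         paste(config$lining_range, collapse = "-"), "; gate ",
         config$gate_atom, " radius ",
         format(summaries$gate_radius, digits = 6), " A")
  }

  if (length(models) >= 3) {
    obs <- extract_loop_observations(models, loop = config$loop_range,
                                     core = config$loop_core_ranges)
    pcm <- fit_pca(obs)
    proj <- pc_project(obs, pcm, n_comp = 2)
    proj_df <- data.frame(observation = rownames(obs), proj)
    out$pca <- proj_df
    paths$pca <- file.path(config$output_dir, "pca_projections.csv")
    write_table(proj_df, paths$pca,
                sprintf("loop %s CA PCA; PC1 %.1f%%, PC2 %.1f%% of variance",
                        paste(config$loop_range, collapse = "-"),
                        100 * pcm$explained_fraction[1],
                        100 * pcm$explained_fraction[2]))
    summaries$pc1_explained <- pcm$explained_fraction[1]
    summaries$pc2_explained <- pcm$explained_fraction[2]
    if (!is.null(traj)) {
      tp <- project_trajectory(tail_window(traj, config$analysis_window_ns),
                               pcm)
      paths$pca_trajectory <- file.path(config$output_dir,
                                        "pca_trajectory.csv")
      write_table(tp, paths$pca_trajectory,
                  "trajectory frames projected onto the loop PC model")
      out$pca_trajectory <- tp
    }
  } else if (length(models) > 0) {
    note("PCA skipped: ", length(models), " model(s) configured; need >= 3")
  }

  strip_stat <- function(x) {
    if (inherits(x, "summary_stat")) unclass(x) else x
  }
  summary_path <- file.path(config$output_dir, "summaries.json")
  jsonlite::write_json(lapply(summaries, strip_stat), summary_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$summaries <- summary_path

  manifest <- list(package = "pentagate",
                   version = as.character(utils::packageVersion("pentagate")),
                   config = unclass(config),
                   config_hash = config_hash(config),
                   seed = config$seed,
                   log = log_lines,
                   outputs = lapply(paths, basename))
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$manifest <- manifest_path
  invisible(list(paths = paths, results = out, summaries = summaries,
                 manifest = manifest))
}
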