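#' Assemble a pipeline configuration
#'
#' Missing fields are filled with documented defaults.  The configuration is
#' either fully generated (synthetic 7TM fixture, the default) or file-based:
#' supply \code{structure}, \code{trajectory} and \code{segments} paths, and
#' optionally pre-computed wildtype/mutant decomposition tables
#' (\code{wt_decomposition}, \code{mut_decomposition}) to skip the energy
#' stage's own computation.
#'
#' @param ... fields overriding the defaults; see Details
#' @param config optional list or YAML file path merged under \code{...}
#' @details Fields: \code{out_dir}; \code{seed}; \code{generate} (list:
#'   \code{n_helices}, \code{n_residues}, \code{n_frames}, \code{sigma},
#'   \code{pivot_helices}, \code{mutate_residue}); \code{inputs} (list of
#'   paths); \code{thresholds} (list: \code{exclusion_window},
#'   \code{significance}, \code{hbond_d_max}, \code{hbond_theta_min},
#'   \code{saltbridge_cutoff}, \code{edge_threshold}); \code{energy_frames}
#'   (frames sampled for energy evaluation); \code{contact_frames};
#'   \code{stages} (character subset of geometry, energy, network, report).
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(..., config = NULL) {
  defaults <- list(
    out_dir = "helixnet-out",
    seed = 1L,
    generate = list(n_helices = 7, n_residues = 24, n_frames = 40,
                    sigma = 0.3, energy_sigma = 0.05, pivot_helices = c(6, 7),
                    sequence = c("AAAADAAAKAAASAAADAAAKAAA",
                                 "AAAADAAAKAAASAAADAAAKAAA",
                                 "AAAADAAAKAAASAAADAAAKAAA",
                                 "AAAADAAAKAAASAAADAAAKAAA",
                                 "AAAADAAAKAAASAAADAAAKAAA",
                                 "AAAADAAAKAAASAAADAAAKAAA",
                                 "AAAKAAAAAAAASAAAAAAAAAAA"),
                    mutate_residue = NULL),
    inputs = NULL,
    thresholds = list(exclusion_window = 4, significance = 1.0,
                      hbond_d_max = 3.5, hbond_theta_min = 120,
                      saltbridge_cutoff = 4.0, edge_threshold = 0.5),
    energy_frames = 5, contact_frames = 5,
    stages = c("geometry", "energy", "network", "report"))
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  merge2 <- function(base, upd) {
    for (nm in names(upd))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge2(base[[nm]], upd[[nm]]) else upd[[nm]]
    base
  }
  cfg <- merge2(defaults, if (is.null(config)) list() else config)
  cfg <- merge2(cfg, list(...))
  bad <- setdiff(cfg$stages, c("geometry", "energy", "network", "report"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  th <- cfg$thresholds
  if (th$exclusion_window < 0) stop("thresholds$exclusion_window must be >= 0")
  if (th$hbond_d_max <= 0 || th$saltbridge_cutoff <= 0)
    stop("contact distance cutoffs must be positive")
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(stage, msg, t0) {
  message(sprintf("[%s] %s (%.2fs)", stage, msg,
                  as.numeric(Sys.time()) - t0))
}

structure_with_coords <- function(x, coords) {
  y <- x
  y$coords <- coords
  y
}

write_csv_det <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages run in order geometry -> energetics -> network -> report, each
#' writing CSV/JSON outputs (and SVG figures for report) into
#' \code{out_dir}.  Every figure has a sibling CSV holding exactly the
#' plotted numbers; the run manifest records the package version, the full
#' configuration, seeds, per-stage record counts, and md5 checksums of the
#' tabular outputs, which suffices to reproduce every number in the bundle.
#' With the same configuration and seed, tabular outputs are byte-identical
#' across runs.  On a stage error, partial outputs are kept and a FAILED
#' marker naming the stage is written before the error propagates.
#'
#' @param config \code{\link{pipeline_config}} (or list / YAML path coerced
#'   through it)
#' @return invisibly, a list with the principal in-memory results and the
#'   manifest
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config = config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  manifest <- list(package = "helixnet",
                   version = as.character(utils::packageVersion("helixnet")),
                   seed = config$seed, config = unclass(config),
                   stages = list())
  res <- list()
  current_stage <- "inputs"
  on_fail <- function(e) {
    writeLines(paste("FAILED at stage:", current_stage, "-", conditionMessage(e)),
               file.path(out, "FAILED"))
    stop(e)
  }
  tryCatch({
    # ---- inputs ----
    if (is.null(config$inputs)) {
      g <- config$generate
      bundle <- make_bundle(n_helices = g$n_helices, n_residues = g$n_residues,
                            pivot_helices = g$pivot_helices,
                            sequence = g$sequence %||% "A")
      segdef <- attr(bundle, "definition")
      mut_res <- g$mutate_residue
      if (is.null(mut_res)) {  # default: first non-Ala/Gly/Pro residue
        rt <- residue_table(bundle)
        cand <- rt$residue_number[!rt$residue_name %in% c("ALA", "GLY", "PRO")]
        if (!length(cand)) stop("no mutatable residue in the generated bundle; set generate$mutate_residue")
        mut_res <- cand[1]
      }
      traj <- make_noisy_trajectory(bundle, sigma = g$sigma,
                                    n_frames = g$n_frames, seed = config$seed)
      mut_struct <- truncate_to_alanine(bundle, mut_res)
      # energy snapshots carry much smaller fluctuation than the geometry
      # trajectory, emulating the energy-minimized snapshots decomposition
      # work is run on (raw uncorrelated coordinate noise at contact
      # distances is dominated by the Lennard-Jones wall)
      ene_traj <- make_noisy_trajectory(bundle, sigma = g$energy_sigma,
                                        n_frames = config$energy_frames,
                                        seed = config$seed + 2000L)
      mut_ene_traj <- make_noisy_trajectory(mut_struct, sigma = g$energy_sigma,
                                            n_frames = config$energy_frames,
                                            seed = config$seed + 3000L)
      fx <- file.path(out, "fixtures")
      dir.create(fx, showWarnings = FALSE)
      write_structure(bundle, file.path(fx, "structure.pdb"))
      write_segments(segdef, file.path(fx, "segments.yaml"))
      ref <- bundle
    } else {
      for (f in c("structure", "trajectory", "segments"))
        if (!is.null(config$inputs[[f]]) && !file.exists(config$inputs[[f]]))
          stop("input file missing: inputs$", f, " = ", config$inputs[[f]])
      if (is.null(config$inputs$structure)) stop("inputs$structure is required")
      ref <- read_structure(config$inputs$structure)
      segdef <- read_segments(config$inputs$segments)
      traj <- if (!is.null(config$inputs$trajectory))
        read_trajectory(ref, config$inputs$trajectory) else as_traj(ref)
      mut_struct <- NULL; mut_res <- integer(0)
      ene_traj <- traj; mut_ene_traj <- NULL
    }
    th <- config$thresholds
    # ---- geometry ----
    if ("geometry" %in% config$stages) {
      current_stage <- "geometry"
      aligned <- align_to_reference(traj, ref, definition = segdef)
      series <- angle_rmsd_series(aligned, ref, segdef)
      write_csv_det(series, file.path(out, "angle_rmsd.csv"))
      write_csv_det(attr(series, "means"), file.path(out, "angle_rmsd_means.csv"))
      rp <- rmsf_profile(aligned)
      write_csv_det(rp, file.path(out, "rmsf.csv"))
      res$series <- series; res$rmsf <- rp
      manifest$stages$geometry <- list(n_samples = nrow(series),
                                       n_residues = nrow(rp))
      stage_log("geometry", paste(nrow(series), "angle/RMSD samples"), t0)
      traj <- aligned
    }
    # ---- energetics ----
    if ("energy" %in% config$stages) {
      current_stage <- "energy"
      if (!is.null(config$inputs) && !is.null(config$inputs$wt_decomposition)) {
        wt_mats <- list(import_decomposition(config$inputs$wt_decomposition))
        mut_mats <- if (!is.null(config$inputs$mut_decomposition))
          list(import_decomposition(config$inputs$mut_decomposition)) else NULL
      } else {
        params <- if (!is.null(config$inputs) && !is.null(config$inputs$params))
          read_atom_params(config$inputs$params) else default_atom_params()
        ene_of <- function(st, tr) {
          pick <- unique(round(seq(1, n_frames(tr),
                                   length.out = min(config$energy_frames,
                                                    n_frames(tr)))))
          lapply(pick, function(f) pairwise_interaction_energy(
            structure_with_coords(st, frame_coords(tr, f)), params))
        }
        wt_mats <- ene_of(ref, ene_traj)
        mut_mats <- if (!is.null(mut_ene_traj)) ene_of(mut_struct, mut_ene_traj)
                    else NULL
      }
      wt_mats <- lapply(wt_mats, apply_exclusion, window = th$exclusion_window)
      wt_avg <- average_matrices(wt_mats)
      write_energy_csv(wt_avg, file.path(out, "energy_wt.csv"))
      res$wt <- wt_avg
      if (!is.null(mut_mats)) {
        mut_mats <- lapply(mut_mats, apply_exclusion, window = th$exclusion_window)
        mut_avg <- average_matrices(mut_mats)
        write_energy_csv(mut_avg, file.path(out, "energy_mut.csv"))
        res$mut <- mut_avg
      }
      manifest$stages$energy <- list(n_residue_pairs = sum(!wt_avg$mask) / 2,
                                     n_frames = wt_avg$n,
                                     exclusion_window = th$exclusion_window)
      stage_log("energy", paste(wt_avg$n, "frames averaged"), t0)
    }
    # ---- network ----
    if ("network" %in% config$stages && !is.null(res$wt)) {
      current_stage <- "network"
      gm <- group_matrix(res$wt, segdef)
      gdf <- data.frame(group_i = gm$groups[row(gm$energy)[upper.tri(gm$energy, diag = TRUE)]],
                        group_j = gm$groups[col(gm$energy)[upper.tri(gm$energy, diag = TRUE)]],
                        energy = gm$energy[upper.tri(gm$energy, diag = TRUE)])
      write_csv_det(gdf, file.path(out, "group_matrix.csv"))
      res$group <- gm
      prof_wt <- residue_wise(res$wt)
      write_csv_det(prof_wt, file.path(out, "residue_profile_wt.csv"))
      if (!is.null(res$mut)) {
        prof_mut <- residue_wise(res$mut)
        write_csv_det(prof_mut, file.path(out, "residue_profile_mut.csv"))
        dn <- diff_network(res$wt, res$mut, mutated_residues = mut_res)
        dp <- diff_pairs(dn, threshold = th$edge_threshold)
        write_csv_det(dp, file.path(out, "diff_pairs.csv"))
        sig <- significant_residues(prof_wt, prof_mut, threshold = th$significance)
        sig$threshold <- rep(th$significance, nrow(sig))
        write_csv_det(sig, file.path(out, "significant_residues.csv"))
        res$diff <- dn; res$significant <- sig
      }
      cf <- unique(round(seq(1, n_frames(traj),
                             length.out = min(config$contact_frames, n_frames(traj)))))
      ctraj <- new_trajectory(traj$topology, traj$xyz[cf, , drop = FALSE])
      contacts <- rbind(
        detect_hbonds(ctraj, criteria = hbond_criteria(th$hbond_d_max,
                                                       th$hbond_theta_min)),
        detect_salt_bridges(ctraj, cutoff = th$saltbridge_cutoff))
      write_csv_det(contacts, file.path(out, "contacts.csv"))
      res$contacts <- contacts
      summ <- list(groups = gm$groups,
                   significance_threshold = th$significance,
                   edge_threshold = th$edge_threshold,
                   n_significant = if (!is.null(res$significant)) nrow(res$significant) else 0L,
                   n_contacts = nrow(contacts))
      jsonlite::write_json(summ, file.path(out, "network_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$stages$network <- summ
      stage_log("network", paste(nrow(contacts), "contacts"), t0)
    }
    # ---- report ----
    if ("report" %in% config$stages && !is.null(res$group)) {
      current_stage <- "report"
      if (any(res$group$energy[upper.tri(res$group$energy)] != 0))
        render_group_chord(res$group, file.path(out, "group_chord.svg"))
      if (!is.null(res$diff))
        render_structure_network(ref, res$diff, file.path(out, "diff_network.svg"),
                                 threshold = th$edge_threshold)
      stage_log("report", "figures written", t0)
    }
    current_stage <- "manifest"
    csvs <- list.files(out, pattern = "\\.(csv|json)$", full.names = TRUE)
    csvs <- csvs[basename(csvs) != "manifest.json"]
    manifest$outputs <- lapply(stats::setNames(as.list(unname(tools::md5sum(csvs))),
                                               basename(csvs)), identity)
    manifest$elapsed_s <- round(as.numeric(Sys.time()) - t0, 2)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = on_fail)
  invisible(c(res, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
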