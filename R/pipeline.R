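## cli_pipeline: configuration-driven orchestration of the full analysis
## chain, with logging and provenance. Every artefact is a delimited table
## or JSON file carrying the package version and a config hash, so two runs
## with identical inputs, config and seed are byte-identical.

pipeline_log <- function(..., level = "INFO") {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
}

## md5 of the canonical JSON serialization of the config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Default pipeline configuration
#'
#' Returns the full default configuration; `run_pipeline()` merges the
#' user's config over these values. Defaults: simulation temperature
#' 313.15 K, 60x60 landscape bins, 2 A cluster cutoff, 300 ns stable
#' window with a 0.5 minimum fraction, default interaction criteria and
#' SIE coefficients.
#'
#' @return Named list.
#' @export
default_pipeline_config <- function() {
  list(
    input = NULL,                 # multi-model PDB path
    output_dir = "mdscape_run",
    seed = 1L,
    selection = "backbone",
    temperature_K = 313.15,
    fel = list(n_bins = 60, max_minima = 4, depth_window = 2.0,
               smoothing_bins = 1),
    pocket = list(seed_center = NULL, search_radius = 10,
                  grid_spacing = 0.5, probe_radius = 1.4),
    cluster = list(cutoff = 2.0, max_cluster_frames = 400),
    window = list(length_ns = 300, min_fraction = 0.5),
    criteria = interaction_criteria(),
    ligand = NULL,                # e.g. list(resname = "LIG")
    hbond_residues = NULL,        # residues for H-bond occupancy reports
    replicate_bounds = 1L,
    sie = list(alpha = 0.1048, C = -2.89, gamma = 0.0129,
               eps_in = 2.25, eps_out = 78.5))
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]) &&
        !is.null(names(user[[k]])))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: geometry summaries (RMSD, RMSF), PCA and the
#' free-energy landscape, minima with representative frames, pocket volume
#' at each minimum's representative structure and, when a ligand is
#' configured: clustering, stable-window selection (when frame times
#' exist), hydrogen-bond occupancies, the interaction fingerprint and an
#' SIE estimate. All artefacts are written under `output_dir` together with
#' a JSON manifest recording the stage list, parameters, package version,
#' seed and config hash. Any stage failure aborts with the stage name.
#'
#' @param config Named list (merged over [default_pipeline_config()]) or a
#'   path to a YAML/JSON config file. Instead of `input`, preloaded
#'   `topology` and `trajectory` objects may be supplied directly.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  seed <- as.integer(cfg$seed)
  hash_cfg <- cfg
  ## the hash captures the analysis parameters, not in-memory objects or
  ## the destination directory
  hash_cfg$topology <- NULL; hash_cfg$trajectory <- NULL
  hash_cfg$output_dir <- NULL
  hash <- config_hash(hash_cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  manifest <- list(tool = "mdscape",
                   version = as.character(utils::packageVersion("mdscape")),
                   config_hash = hash, seed = seed)
  run_stage <- function(name, expr) {
    pipeline_log("stage ", name, " start")
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages <<- c(stages, name)
    pipeline_log("stage ", name, " done")
    res
  }
  stamp <- function(path) {
    ## prepend a provenance header comment to a written table
    lines <- readLines(path)
    writeLines(c(sprintf("# mdscape %s config %s seed %d",
                         manifest$version, hash, seed), lines), path)
  }
  set.seed(seed)

  io <- run_stage("load", {
    if (!is.null(cfg$trajectory)) {
      list(topology = cfg$topology, trajectory = cfg$trajectory)
    } else {
      if (is.null(cfg$input) || !file.exists(cfg$input))
        stop("input path missing or not found")
      read_pdb_models(cfg$input)
    }
  })
  top <- io$topology; traj <- io$trajectory
  sel <- if (identical(cfg$selection, "backbone"))
    select_atoms(top, preset = "backbone") else cfg$selection
  lig_sel <- NULL
  if (!is.null(cfg$ligand)) {
    lig_sel <- if (is.list(cfg$ligand) && !is.null(cfg$ligand$resname))
      which(top$atoms$resname %in% cfg$ligand$resname)
    else as.integer(unlist(cfg$ligand))
    if (length(lig_sel) == 0) stop("run_pipeline: ligand selection is empty")
  }

  run_stage("geometry", {
    r <- rmsd_series(traj, 1, sel)
    write_tsv(data.frame(frame = seq_along(r), rmsd = as.numeric(r)),
              file.path(cfg$output_dir, "rmsd.tsv"))
    stamp(file.path(cfg$output_dir, "rmsd.tsv"))
    manifest$rmsd <- list(mean = attr(r, "mean"), sd = attr(r, "sd"))
    if (n_frames(traj) >= 2) {
      prof <- rmsf_profile(traj, top, sel)
      write_tsv(prof, file.path(cfg$output_dir, "rmsf.tsv"))
      stamp(file.path(cfg$output_dir, "rmsf.tsv"))
    }
  })

  ## rigid inputs (e.g. a fixed scaffold) carry no conformational variance:
  ## the landscape and pocket stages are then meaningless and are skipped
  sel_idx <- resolve_selection(sel, n_atoms(traj))
  sel_var <- sum(apply(traj$coords[, sel_idx, , drop = FALSE], c(2, 3),
                       stats::var))
  if (n_frames(traj) < 2 || sel_var < 1e-12) {
    pipeline_log("landscape/pockets skipped: no conformational variance",
                 level = "WARN")
    manifest$landscape <- "skipped (no conformational variance)"
    fel_out <- NULL
  } else {
  fel_out <- run_stage("landscape", {
    model <- pca_fit(traj, sel)
    proj <- pca_project(model, traj, 2)
    surface <- fel_build(proj, n_bins = cfg$fel$n_bins,
                         temperature_K = cfg$temperature_K)
    minima <- find_minima(surface, smoothing_bins = cfg$fel$smoothing_bins,
                          max_minima = cfg$fel$max_minima,
                          depth_window = cfg$fel$depth_window)
    minima$frame <- vapply(seq_len(nrow(minima)), function(i)
      representative_frame(proj, minima[i, ]), integer(1))
    write_tsv(data.frame(component = seq_along(model$variance_fractions),
                         variance_fraction = model$variance_fractions),
              file.path(cfg$output_dir, "pca_variance.tsv"))
    stamp(file.path(cfg$output_dir, "pca_variance.tsv"))
    write_tsv(as.data.frame(surface$dG),
              file.path(cfg$output_dir, "fel_grid.tsv"))
    stamp(file.path(cfg$output_dir, "fel_grid.tsv"))
    jsonlite::write_json(
      list(tool = "mdscape", version = manifest$version, config = hash,
           pc1_edges = surface$pc1_edges, pc2_edges = surface$pc2_edges,
           kT = surface$kT, cap = surface$cap),
      file.path(cfg$output_dir, "fel_meta.json"), digits = NA)
    write_tsv(minima, file.path(cfg$output_dir, "minima.tsv"))
    stamp(file.path(cfg$output_dir, "minima.tsv"))
    manifest$n_minima <- nrow(minima)
    list(model = model, proj = proj, surface = surface, minima = minima)
  })

  run_stage("pockets", {
    radii <- atom_radii(top)
    pockets <- lapply(seq_len(nrow(fel_out$minima)), function(i) {
      fr <- frame_coords(traj, fel_out$minima$frame[i])
      seed_c <- cfg$pocket$seed_center
      if (is.null(seed_c)) seed_c <- colMeans(fr)
      pv <- pocket_volume(fr, radii, seed_c,
                          search_radius = cfg$pocket$search_radius,
                          grid_spacing = cfg$pocket$grid_spacing,
                          probe_radius = cfg$pocket$probe_radius)
      data.frame(minimum = fel_out$minima$rank[i],
                 frame = fel_out$minima$frame[i],
                 volume = pv$volume, seed_blocked = pv$seed_blocked,
                 leak = pv$leak)
    })
    pockets <- do.call(rbind, pockets)
    write_tsv(pockets, file.path(cfg$output_dir, "pockets.tsv"))
    stamp(file.path(cfg$output_dir, "pockets.tsv"))
    manifest$n_pockets <- nrow(pockets)
  })
  }

  if (!is.null(lig_sel)) {
    run_stage("clustering", {
      nf <- n_frames(traj)
      keep <- if (nf > cfg$cluster$max_cluster_frames)
        unique(round(seq(1, nf, length.out = cfg$cluster$max_cluster_frames)))
      else seq_len(nf)
      sub <- trajectory(traj$coords[keep, , , drop = FALSE],
                        traj$times[keep])
      cl <- cluster_frames(sub, sel, cfg$cluster$cutoff)
      write_tsv(data.frame(frame = keep, cluster = cl$labels),
                file.path(cfg$output_dir, "clusters.tsv"))
      stamp(file.path(cfg$output_dir, "clusters.tsv"))
      manifest$largest_cluster_fraction <- cl$largest_fraction
      if (!is.null(sub$times) &&
          cfg$window$length_ns <= diff(range(sub$times))) {
        w <- select_stable_window(cl, sub$times, cfg$window$length_ns,
                                  cfg$window$min_fraction)
        jsonlite::write_json(
          list(tool = "mdscape", version = manifest$version, config = hash,
               start_ns = w$start_ns, end_ns = w$end_ns,
               fraction = w$fraction, stable = w$stable),
          file.path(cfg$output_dir, "window.json"),
          auto_unbox = TRUE, digits = NA)
        manifest$stable_window <- c(w$start_ns, w$end_ns)
      }
    })

    run_stage("interactions", {
      fp <- interaction_fingerprint(traj, top, lig_sel, cfg$criteria)
      write_tsv(fp, file.path(cfg$output_dir, "fingerprint.tsv"))
      stamp(file.path(cfg$output_dir, "fingerprint.tsv"))
      manifest$n_fingerprint_residues <- nrow(fp)
      hb_res <- cfg$hbond_residues
      if (!is.null(hb_res)) {
        hb <- do.call(rbind, lapply(hb_res, function(r) {
          o <- hbond_occupancy(traj, top, r, lig_sel,
                               cfg$replicate_bounds, cfg$criteria)
          data.frame(resid = r, mean = o$mean, sd = o$sd)
        }))
        write_tsv(hb, file.path(cfg$output_dir, "hbonds.tsv"))
        stamp(file.path(cfg$output_dir, "hbonds.tsv"))
      }
    })

    run_stage("sie", {
      coeffs <- sie_coefficients(alpha = cfg$sie$alpha, C = cfg$sie$C,
                                 gamma = cfg$sie$gamma,
                                 eps_in = cfg$sie$eps_in,
                                 eps_out = cfg$sie$eps_out)
      top_sie <- top
      ## heavy-atom topologies without force-field parameters get neutral
      ## placeholders so the geometric terms are still reported
      if (is.null(top_sie$charges))
        top_sie$charges <- rep(0, n_atoms(top_sie))
      if (is.null(top_sie$lj))
        top_sie$lj <- data.frame(epsilon = rep(0.1, n_atoms(top_sie)),
                                 rmin_half = atom_radii(top_sie))
      window <- if (!is.null(manifest$stable_window)) manifest$stable_window
                else NULL
      res <- sie_from_trajectory(traj, top_sie, lig_sel, window = window,
                                 replicate_bounds = cfg$replicate_bounds,
                                 coeffs = coeffs)
      jsonlite::write_json(
        list(tool = "mdscape", version = manifest$version, config = hash,
             dG = res$dG, component_means = as.list(res$component_means),
             component_sds = as.list(res$component_sds),
             n_replicates = res$n_replicates, n_frames = res$n_frames),
        file.path(cfg$output_dir, "sie.json"),
        auto_unbox = TRUE, digits = NA)
      manifest$sie_dG <- res$dG
    })
  }

  manifest$stages <- stages
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log("pipeline complete: ", length(stages), " stages")
  invisible(manifest)
}
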