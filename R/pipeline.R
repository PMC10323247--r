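#' Simulate a full binding dose-response experiment
#'
#' Builds the synthetic counterpart of an importin titration TIRF
#' experiment: for each condition the competition equilibrium
#' ([solve_competition()]) sets the microtubule-competent fraction of the
#' cargo, the number of lattice-bound particles is drawn binomially from
#' that fraction, and ground truth plus (optionally) rendered microtubule
#' and complex channels are produced.
#'
#' @param conditions data.frame with columns `label`, `impB_total`,
#'   `ran_total` (nM) and optionally `replicate`
#' @param config a [scene_config()]; `config$seed` seeds the whole
#'   experiment
#' @param aug_total cargo concentration, nM
#' @param kd_aug_imp,kd_ran_impB competition model constants, nM
#' @param density_per_um lattice-bound particles per micrometre of
#'   microtubule at full (uninhibited) binding
#' @param render if TRUE, attach rendered `image_stack`s (complex +
#'   microtubule channels)
#' @return list of scenes; each scene is a list with `label`, `replicate`,
#'   `condition` (named concentrations), `free_fraction`, `truth`, and when
#'   rendered `complex_stack`, `mt_stack`
#' @export
simulate_binding_experiment <- function(conditions, config,
                                        aug_total = 1,
                                        kd_aug_imp = 13.1,
                                        kd_ran_impB = 0.3,
                                        density_per_um = 2,
                                        render = TRUE) {
  stopifnot(all(c("label", "impB_total", "ran_total") %in% names(conditions)))
  if (is.null(conditions$replicate)) conditions$replicate <- "R1"
  set.seed(config$seed)
  W <- config$image_size[2]
  path <- straight_path(c(8, config$image_size[1] / 2),
                        c(W - 9, config$image_size[1] / 2),
                        pixel_size = config$pixel_size)
  n_full <- round(density_per_um * path$length_um)
  scenes <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    st <- solve_competition(equilibrium_state(
      aug_total = aug_total, impB_total = conditions$impB_total[i],
      ran_total = conditions$ran_total[i],
      kd_aug_imp = kd_aug_imp, kd_ran_impB = kd_ran_impB))
    n_bound <- stats::rbinom(1, n_full, st$free_aug_fraction)
    cfg_i <- config
    cfg_i$seed <- config$seed + 1000L * i    # scene-local stream
    truth <- simulate_tracks(cfg_i, path, n_particles = n_bound)
    sc <- list(label = conditions$label[i],
               replicate = conditions$replicate[i],
               condition = c(augmin = aug_total,
                             importin = conditions$impB_total[i],
                             RanQ69L = conditions$ran_total[i]),
               free_fraction = st$free_aug_fraction,
               n_bound = n_bound, path = path, truth = truth)
    if (render) {
      sc$complex_stack <- render_stack(truth, cfg_i)
      sc$mt_stack <- render_stack(truth, cfg_i, channel = "microtubule")
    }
    scenes[[i]] <- sc
  }
  scenes
}

#' Write a simulated experiment to disk
#'
#' One directory per scene containing `complex.tif` and `microtubule.tif`
#' (16-bit multi-page TIFF), `ground_truth.csv`, and a top-level
#' `manifest.yaml` plus `scene_config.yaml` describing the whole
#' experiment.
#'
#' @param scenes result of [simulate_binding_experiment()] (rendered)
#' @param config the [scene_config()] used
#' @param out_dir output directory (created)
#' @return the manifest (invisibly)
#' @export
write_experiment <- function(scenes, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    d <- file.path(out_dir, sprintf("scene_%02d", i))
    dir.create(d, showWarnings = FALSE)
    write_stack(sc$complex_stack, file.path(d, "complex.tif"))
    write_stack(sc$mt_stack, file.path(d, "microtubule.tif"))
    if (!is.null(sc$truth))
      write_ground_truth(sc$truth, file.path(d, "ground_truth.csv"))
    entries[[i]] <- list(complex = file.path(d, "complex.tif"),
                         microtubule = file.path(d, "microtubule.tif"),
                         label = sc$label, replicate = sc$replicate,
                         condition = as.list(sc$condition))
  }
  manifest <- list(pixel_size = config$pixel_size, dt = config$dt,
                   stacks = entries)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  write_scene_config(config, file.path(out_dir, "scene_config.yaml"))
  invisible(manifest)
}

#' Read an experiment manifest
#'
#' @param path `manifest.yaml` (or `.json`) path
#' @return validated manifest list (`pixel_size`, `dt`, `stacks`)
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
       else yaml::read_yaml(path)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  stopifnot(is.list(m), !is.null(m$stacks), m$pixel_size > 0, m$dt > 0)
  for (i in seq_along(m$stacks)) {
    e <- m$stacks[[i]]
    if (is.null(e$complex) || length(e$complex) != 1)
      stop("manifest stack ", i, " must have exactly one complex channel")
    if (is.null(e$replicate) || !nzchar(e$replicate))
      stop("manifest stack ", i, " has an empty replicate label")
  }
  m
}

#' Run the full TIRF quantification pipeline on an experiment
#'
#' For every stack in the manifest: segments microtubules from the
#' microtubule channel (when present), measures background-corrected
#' per-microtubule intensities in the complex channel, detects and links
#' single-molecule tracks, estimates per-track diffusion coefficients
#' (CVE) with motility classification, and (when a unit intensity is
#' supplied) converts track intensities to molecule counts. Condition-level
#' summaries report medians with distribution-free 95% confidence
#' intervals; pairwise condition differences are tested with the
#' Mann-Whitney U test. When `titration` maps condition labels to a
#' predictor concentration, a hierarchical bootstrap slope is fit.
#'
#' @param manifest list from [read_manifest()] (or built in code): fields
#'   `pixel_size`, `dt`, `stacks` (each with `complex`, optional
#'   `microtubule`, `label`, `replicate`); stack entries may carry in-memory
#'   `image_stack` objects in `complex_stack` / `mt_stack` instead of paths
#' @param psf_sigma,snr_min detection parameters (px, dimensionless)
#' @param max_disp,max_gap linking parameters (px/frame, frames)
#' @param min_steps minimum displacements for a diffusion estimate
#' @param R motion-blur coefficient
#' @param alpha motility classification level
#' @param unit_intensity optional single-fluorophore intensity (ADU) for
#'   molecule counting
#' @param titration optional data.frame `label`, `concentration` declaring
#'   a titration for the bootstrap slope
#' @param seed integer seed (bootstraps, classification null)
#' @param out_dir optional output directory for CSV tables, a JSON summary
#'   and a run log
#' @return list: `binding` (per-microtubule measurements), `tracks`,
#'   `diffusion`, `oligomers`, `summary` (per-condition median + CI),
#'   `pairwise` (Mann-Whitney p-values), `slope` (bootstrap result or NULL),
#'   `provenance`
#' @export
run_pipeline <- function(manifest, psf_sigma = 1.3, snr_min = 4,
                         max_disp = 5, max_gap = 2L, min_steps = 10L,
                         R = 0, alpha = 0.05, unit_intensity = NULL,
                         titration = NULL, seed = 1L, out_dir = NULL) {
  manifest <- validate_manifest(manifest)
  set.seed(seed)
  binding <- list(); tracks <- list(); diffusion <- list(); oligo <- list()
  for (i in seq_along(manifest$stacks)) {
    e <- manifest$stacks[[i]]
    label <- e$label %||% sprintf("stack_%02d", i)
    cx <- e$complex_stack %||%
      read_stack(e$complex, "complex", manifest$pixel_size, manifest$dt)
    mt <- if (!is.null(e$mt_stack)) e$mt_stack
          else if (!is.null(e$microtubule))
            read_stack(e$microtubule, "microtubule", manifest$pixel_size,
                       manifest$dt)
          else NULL
    # binding measurements per microtubule
    if (!is.null(mt)) {
      paths <- withCallingHandlers(segment_microtubules(mt),
                                   warning = function(w) invokeRestart("muffleWarning"))
      if (length(paths)) {
        all_mask <- Reduce(`|`, lapply(paths, `[[`, "mask"))
        for (k in seq_along(paths)) {
          bm <- background_corrected_intensity(cx, paths[[k]]$mask,
                                               exclude_mask = all_mask)
          binding[[length(binding) + 1L]] <-
            cbind(data.frame(label = label, replicate = e$replicate,
                             microtubule_id = k), bm)
        }
      }
    }
    # single-molecule tracking + diffusion
    spots <- detect_stack(cx, psf_sigma_guess = psf_sigma, snr_min = snr_min)
    if (nrow(spots)) {
      tr <- link_tracks(spots, max_disp = max_disp, max_gap = max_gap)
      if (nrow(tr)) {
        tr <- cbind(label = label, replicate = e$replicate, stack = i, tr)
        tracks[[length(tracks) + 1L]] <- tr
        dtab <- estimate_diffusion_table(tr, manifest$pixel_size,
                                         manifest$dt, R = R,
                                         min_steps = min_steps, alpha = alpha)
        diffusion[[length(diffusion) + 1L]] <-
          cbind(label = label, replicate = e$replicate, stack = i, dtab)
        if (!is.null(unit_intensity)) {
          mi <- vapply(split(tr, tr$track_id), track_mean_intensity, numeric(1))
          oc <- count_molecules(unname(mi), unit_intensity,
                                track_id = as.integer(names(mi)))
          oligo[[length(oligo) + 1L]] <-
            cbind(label = label, replicate = e$replicate, stack = i, oc)
        }
      }
    }
  }
  binding <- if (length(binding)) do.call(rbind, binding) else
    data.frame(label = character(0), replicate = character(0),
               microtubule_id = integer(0), mean_bc_intensity = numeric(0),
               mean_mt = numeric(0), mean_bg = numeric(0),
               n_pixels = integer(0), n_bg_pixels = integer(0))
  tracks <- if (length(tracks)) do.call(rbind, tracks) else NULL
  diffusion <- if (length(diffusion)) do.call(rbind, diffusion) else NULL
  oligo <- if (length(oligo)) do.call(rbind, oligo) else NULL

  # condition-level summaries (median + 95% CI where n allows)
  summ <- NULL
  if (nrow(binding)) {
    summ <- do.call(rbind, lapply(split(binding, binding$label), function(g) {
      if (nrow(g) >= 5) {
        ci <- median_ci(g$mean_bc_intensity)
        data.frame(label = g$label[1], n = nrow(g), median = ci$median,
                   ci_low = ci$ci_low, ci_high = ci$ci_high)
      } else {
        data.frame(label = g$label[1], n = nrow(g),
                   median = stats::median(g$mean_bc_intensity),
                   ci_low = NA_real_, ci_high = NA_real_)
      }
    }))
    rownames(summ) <- NULL
  }
  pairwise <- NULL
  if (!is.null(summ) && nrow(summ) >= 2) {
    labs <- summ$label
    combs <- utils::combn(labs, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      a <- binding$mean_bc_intensity[binding$label == combs[1, j]]
      b <- binding$mean_bc_intensity[binding$label == combs[2, j]]
      mw <- mann_whitney_u(a, b)
      data.frame(label_a = combs[1, j], label_b = combs[2, j],
                 U = mw$U, p = mw$p, method = mw$method)
    }))
  }
  slope <- NULL
  if (!is.null(titration) && nrow(binding)) {
    d <- merge(binding, titration, by = "label")
    if (nrow(d) && length(unique(d$concentration)) >= 2) {
      slope <- bootstrap_slope(
        data.frame(replicate = d$replicate, concentration = d$concentration,
                   response = d$mean_bc_intensity),
        seed = seed)
    }
  }
  prov <- list(seed = seed, n_stacks = length(manifest$stacks),
               parameters = list(psf_sigma = psf_sigma, snr_min = snr_min,
                                 max_disp = max_disp, max_gap = max_gap,
                                 min_steps = min_steps, R = R, alpha = alpha),
               package_version = as.character(utils::packageVersion("tirfsm")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  res <- list(binding = binding, tracks = tracks, diffusion = diffusion,
              oligomers = oligo, summary = summ, pairwise = pairwise,
              slope = slope, provenance = prov)
  if (!is.null(out_dir)) write_results_bundle(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_results_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$binding, file.path(out_dir, "binding.csv"),
                   row.names = FALSE)
  if (!is.null(res$tracks))
    write_tracks(res$tracks, file.path(out_dir, "tracks.csv"))
  if (!is.null(res$diffusion))
    utils::write.csv(res$diffusion, file.path(out_dir, "diffusion.csv"),
                     row.names = FALSE)
  if (!is.null(res$oligomers))
    utils::write.csv(res$oligomers, file.path(out_dir, "oligomers.csv"),
                     row.names = FALSE)
  summary_out <- list(summary = res$summary, pairwise = res$pairwise,
                      slope = if (!is.null(res$slope))
                        res$slope[c("slope_median", "ci_low", "ci_high",
                                    "n_boot", "seed")] else NULL,
                      provenance = res$provenance)
  jsonlite::write_json(summary_out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_lines <- c(sprintf("tirfsm run %s", res$provenance$timestamp),
                 sprintf("seed: %d", res$provenance$seed),
                 sprintf("stacks: %d", res$provenance$n_stacks),
                 sprintf("parameters: %s",
                         jsonlite::toJSON(res$provenance$parameters,
                                          auto_unbox = TRUE)))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
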