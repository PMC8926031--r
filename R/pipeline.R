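#' Read and validate a pipeline run configuration
#'
#' Plain-YAML configuration mirroring the CLI flags. All fields are
#' optional; missing ones fall back to the documented defaults.
#'
#' @param path YAML file, or a named list already in memory.
#' @return A validated `run_config` list with components `simulate`
#'   (simulation settings), `jsse` (`grid_points`, `edge_weight`), `sweep`
#'   (`min`, `max`, `step`, `n_nulls`), `classifier` (`c_exponents`,
#'   `beta_step`, `alpha`, `positive`) and `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else if (is.character(path)) yaml::read_yaml(path)
         else path
  pick <- function(section, field, default) {
    v <- raw[[section]][[field]]
    if (is.null(v)) default else v
  }
  cfg <- list(
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    simulate = list(
      n_per_group = pick("simulate", "n_per_group", 20L),
      n_vox = pick("simulate", "n_vox", 200L),
      n_regions = pick("simulate", "n_regions", 90L),
      effect_size = pick("simulate", "effect_size", 3),
      noise_sd = pick("simulate", "noise_sd", 0.1),
      n_effect_pairs = pick("simulate", "n_effect_pairs", 10L)
    ),
    jsse = list(
      grid_points = pick("jsse", "grid_points", 256L),
      edge_weight = pick("jsse", "edge_weight", "similarity")
    ),
    sweep = list(
      min = pick("sweep", "min", 0.02),
      max = pick("sweep", "max", 0.5),
      step = pick("sweep", "step", 0.01),
      n_nulls = pick("sweep", "n_nulls", 100L)
    ),
    classifier = list(
      c_exponents = pick("classifier", "c_exponents", -5:5),
      beta_step = pick("classifier", "beta_step", 0.1),
      alpha = pick("classifier", "alpha", 0.05),
      positive = pick("classifier", "positive", "SZF")
    )
  )
  stopifnot(
    cfg$jsse$edge_weight %in% c("similarity", "divergence"),
    cfg$sweep$step > 0, cfg$sweep$min > 0, cfg$sweep$max <= 1,
    cfg$classifier$positive %in% .group_levels
  )
  structure(cfg, class = "run_config")
}

run_log <- function(out_dir, event, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  event, paste(sprintf("%s=%s", names(list(...)),
                                       unlist(list(...))), collapse = " "))
  cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
  message(line)
}

#' Simulate a phantom cohort to disk
#'
#' Writes one NIfTI volume per synthetic subject, the shared atlas volume,
#' the region-name TSV and a cohort manifest CSV (`subject_id`, `pet_path`,
#' `group`, `seed`), ready for [run_build_networks()].
#'
#' @param config A `run_config` (or path/list accepted by
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$simulate
  n_pairs_max <- floor(sim$n_regions / 2)
  k <- min(sim$n_effect_pairs, n_pairs_max)
  pairs <- if (k > 0) default_effect_pairs()[seq_len(k), , drop = FALSE]
           else NULL
  scfg <- simulation_config(
    n_per_group = sim$n_per_group, n_vox = sim$n_vox,
    n_regions = sim$n_regions, effect_pairs = pairs,
    effect_size = sim$effect_size, noise_sd = sim$noise_sd, seed = cfg$seed
  )
  phantom <- simulate_phantom(scfg)
  atlas_path <- file.path(out_dir, "atlas.nii.gz")
  write_volume(pet_volume(phantom$atlas$labels + 0), atlas_path)
  names_path <- file.path(out_dir, "regions.tsv")
  utils::write.table(
    data.frame(label = seq_len(scfg$n_regions),
               name = phantom$atlas$region_names),
    names_path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  paths <- vapply(seq_len(nrow(phantom$subjects)), function(i) {
    p <- file.path(out_dir, paste0(phantom$subjects$subject_id[i], ".nii.gz"))
    write_volume(phantom$subjects$volume[[i]], p)
    p
  }, character(1))
  manifest <- tibble::tibble(
    subject_id = phantom$subjects$subject_id,
    pet_path = paths,
    group = phantom$subjects$group,
    seed = cfg$seed
  )
  manifest_path <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  run_log(out_dir, "simulate", subjects = nrow(manifest), seed = cfg$seed,
          n_regions = scfg$n_regions, n_vox = scfg$n_vox,
          effect_size = scfg$effect_size)
  invisible(manifest_path)
}

#' Build per-subject connectome files from a manifest
#'
#' Reads each subject's volume, applies global normalization over the
#' atlas mask, extracts per-region samples and writes the Jensen-Shannon
#' connectome as a square CSV matrix. Subjects that fail are reported and
#' skipped; the returned manifest covers the successful ones.
#'
#' @param manifest_path Cohort manifest CSV (columns `subject_id`,
#'   `pet_path`, `group`).
#' @param atlas_path NIfTI atlas path.
#' @param out_dir Output directory.
#' @param config Optional `run_config` for the JSSE options.
#' @param names_path Optional region-name TSV.
#' @param n_regions Number of atlas regions (default 90).
#' @return Path of the network manifest CSV, invisibly.
#' @export
run_build_networks <- function(manifest_path, atlas_path, out_dir,
                               config = NULL, names_path = NULL,
                               n_regions = 90L) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_subject_table(manifest_path)
  atlas <- read_atlas(atlas_path, names_path = names_path,
                      n_regions = n_regions)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$subject_id[i]
    tryCatch({
      vol <- read_volume(manifest$pet_path[i])
      vol <- global_normalize(vol, atlas)
      rs <- extract_roi_samples(vol, atlas, subject_id = sid,
                                group = manifest$group[i])
      net <- build_connectome(rs, grid_points = cfg$jsse$grid_points,
                              edge_weight = cfg$jsse$edge_weight)
      p <- file.path(out_dir, paste0(sid, "_network.csv"))
      write_connectome(net, p)
      tibble::tibble(subject_id = sid, network_path = p,
                     group = manifest$group[i], status = "ok")
    }, error = function(e) {
      warning(sprintf("subject %s failed: %s", sid, conditionMessage(e)),
              call. = FALSE)
      tibble::tibble(subject_id = sid, network_path = NA_character_,
                     group = manifest$group[i], status = "failed")
    })
  })
  out <- dplyr::bind_rows(rows)
  net_manifest <- file.path(out_dir, "networks.csv")
  readr::write_csv(out, net_manifest)
  run_log(out_dir, "build-networks", ok = sum(out$status == "ok"),
          failed = sum(out$status != "ok"))
  if (all(out$status != "ok")) {
    abort("no subject produced a network", class = "jsseconn_io_error")
  }
  invisible(net_manifest)
}

#' Run graph metrics and nested-LOOCV classification on built networks
#'
#' Loads the connectome files of a network manifest, extracts the three
#' feature blocks across the sparsity sweep and runs the nested-LOOCV
#' multi-kernel SVM. Writes `cv_folds.csv`, `roc.csv`,
#' `consensus_connections.csv`, a `result.json` with the performance
#' summary and fold records, and a run log recording seed and grids.
#'
#' @param networks_manifest Network manifest CSV from
#'   [run_build_networks()].
#' @param out_dir Output directory.
#' @param config Optional `run_config`.
#' @return The `jsse_cv` object, invisibly.
#' @export
run_classify <- function(networks_manifest, out_dir, config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- readr::read_csv(networks_manifest, show_col_types = FALSE)
  tbl <- tbl[is.na(tbl$status) | tbl$status == "ok", ]
  if (nrow(tbl) < 4L) {
    abort("need at least 4 subjects with networks",
          class = "jsseconn_cv_error")
  }
  cohort <- tibble::tibble(
    subject_id = tbl$subject_id, group = tbl$group,
    network = lapply(tbl$network_path, read_connectome)
  )
  sparsities <- sparsity_sweep(cfg$sweep$min, cfg$sweep$max, cfg$sweep$step)
  run_log(out_dir, "features", subjects = nrow(cohort),
          thresholds = length(sparsities), n_nulls = cfg$sweep$n_nulls)
  cohort <- add_features(cohort, sparsities = sparsities,
                         n_nulls = cfg$sweep$n_nulls, seed = cfg$seed)
  cv <- nested_loocv(
    cohort, C_grid = 2^cfg$classifier$c_exponents,
    beta_step = cfg$classifier$beta_step, alpha = cfg$classifier$alpha,
    positive = cfg$classifier$positive, seed = cfg$seed
  )
  readr::write_csv(tidy(cv), file.path(out_dir, "cv_folds.csv"))
  readr::write_csv(cv$performance$roc, file.path(out_dir, "roc.csv"))
  readr::write_csv(consensus_connections(cv),
                   file.path(out_dir, "consensus_connections.csv"))
  jsonlite::write_json(
    list(performance = cv$performance[c("accuracy", "sensitivity",
                                        "specificity", "auc")],
         counts = as.list(cv$performance$counts),
         folds = tidy(cv),
         config = cv$config),
    file.path(out_dir, "result.json"),
    auto_unbox = TRUE, digits = NA
  )
  run_log(out_dir, "classify", n = nrow(cohort),
          accuracy = sprintf("%.4f", cv$performance$accuracy),
          auc = sprintf("%.4f", cv$performance$auc),
          C_grid = paste(cv$config$C_grid, collapse = ","),
          beta_step = cfg$classifier$beta_step, seed = cfg$seed)
  invisible(cv)
}

#' Run the full pipeline: simulate, build networks, classify
#'
#' @param config Optional `run_config` (or YAML path).
#' @param out_dir Output directory; subdirectories `cohort/`, `networks/`
#'   and `classification/` are created.
#' @return The `jsse_cv` object, invisibly.
#' @export
run_all <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  manifest <- run_simulate(cfg, file.path(out_dir, "cohort"))
  nets <- run_build_networks(
    manifest, file.path(out_dir, "cohort", "atlas.nii.gz"),
    file.path(out_dir, "networks"), config = cfg,
    names_path = file.path(out_dir, "cohort", "regions.tsv"),
    n_regions = cfg$simulate$n_regions
  )
  run_classify(nets, file.path(out_dir, "classification"), config = cfg)
}
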