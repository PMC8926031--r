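#' Configuration for a synthetic FDG-PET cohort
#'
#' The generator emulates the study conditions the pipeline is designed
#' for: two outcome groups (SZF / SZR), 90 atlas regions per subject, and a
#' controllable between-group difference in the distributional similarity
#' of selected region pairs. Each subject's region `i` intensities are
#' drawn from a Gaussian with mean `mu_i + subject offset` and SD
#' `noise_sd`; the per-subject offset (SD `0.5 * noise_sd`) mimics the
#' global-uptake variation that global normalization removes. In the SZR
#' group the second region of every effect pair is shifted by `effect_size
#' * noise_sd`, which lowers that pair's Jensen-Shannon similarity relative
#' to the SZF group.
#'
#' @param n_per_group Subjects per group (default 20).
#' @param n_vox Voxels per region (default 200).
#' @param n_regions Number of regions (default 90; smaller values are
#'   allowed for fast tests).
#' @param effect_pairs Two-column integer matrix of region pairs carrying
#'   the group effect; default ten disjoint homologous pairs
#'   `(1,2), (3,4), ..., (19,20)`. `NULL` for no effect.
#' @param effect_size Separation `delta` in units of `noise_sd` (default 3).
#' @param noise_sd Within-region intensity SD (default 0.1, i.e. 10% of the
#'   globally normalized mean uptake).
#' @param seed Integer seed; every draw of the cohort is reproducible from
#'   it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_per_group = 20, n_vox = 200, n_regions = 90,
                              effect_pairs = default_effect_pairs(),
                              effect_size = 3, noise_sd = 0.1, seed = 1) {
  if (is.null(effect_pairs)) {
    effect_pairs <- matrix(integer(0), ncol = 2)
  }
  effect_pairs <- matrix(as.integer(effect_pairs), ncol = 2)
  stopifnot(
    n_per_group >= 2, n_vox >= 10, n_regions >= 2,
    effect_size >= 0, noise_sd > 0,
    nrow(effect_pairs) == 0 ||
      (min(effect_pairs) >= 1 && max(effect_pairs) <= n_regions)
  )
  structure(
    list(n_per_group = as.integer(n_per_group), n_vox = as.integer(n_vox),
         n_regions = as.integer(n_regions), effect_pairs = effect_pairs,
         effect_size = effect_size, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @rdname simulation_config
#' @export
default_effect_pairs <- function() {
  cbind(seq(1, 19, by = 2), seq(2, 20, by = 2))
}

# region mean profile: evenly spaced around the normalized grand mean of 1,
# so neighbouring (homologous) regions have nearly identical distributions
region_means <- function(n_regions) {
  seq(0.8, 1.2, length.out = n_regions)
}

# raw (pre-normalization) cohort draw shared by the direct and phantom modes
simulate_raw_samples <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  mu <- region_means(config$n_regions)
  shift <- numeric(config$n_regions)
  if (nrow(config$effect_pairs) > 0) {
    shift[config$effect_pairs[, 2L]] <- config$effect_size * config$noise_sd
  }
  groups <- rep(.group_levels, each = config$n_per_group)
  ids <- sprintf("S%03d", seq_along(groups))
  with_preserved_seed(config$seed, {
    samples <- lapply(seq_along(groups), function(s) {
      offset <- stats::rnorm(1, 0, 0.5 * config$noise_sd)
      lapply(seq_len(config$n_regions), function(i) {
        m <- mu[i] + offset + if (groups[s] == "SZR") shift[i] else 0
        stats::rnorm(config$n_vox, m, config$noise_sd)
      })
    })
    list(ids = ids, groups = groups, samples = samples)
  })
}

#' Simulate a synthetic cohort (direct region-sample mode)
#'
#' Draws seeded per-region voxel-intensity samples for both groups and
#' applies the same proportional global normalization as the imaging path
#' (all of a subject's samples divided by their grand mean), so direct-mode
#' cohorts match what [extract_roi_samples()] yields from the phantom-NIfTI
#' mode of [simulate_phantom()].
#'
#' @param config A [simulation_config()].
#' @return Cohort tibble with columns `subject_id`, `group`, and a
#'   `samples` list-column of `roi_samples` objects.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(
#'   n_per_group = 2, n_regions = 6, n_vox = 20, effect_pairs = NULL))
#' cohort
simulate_cohort <- function(config) {
  raw <- simulate_raw_samples(config)
  region_nm <- default_region_names(config$n_regions)
  samples <- lapply(seq_along(raw$ids), function(s) {
    x <- raw$samples[[s]]
    grand <- mean(unlist(x, use.names = FALSE))
    roi_samples(setNames(lapply(x, function(v) v / grand), region_nm),
                subject_id = raw$ids[s], group = raw$groups[s])
  })
  tibble::tibble(subject_id = raw$ids, group = raw$groups, samples = samples)
}

#' Simulate a phantom-NIfTI cohort
#'
#' Builds a shared label volume (each region is a run of `n_vox`
#' consecutive voxels in raster-scan order, background 0) and one raw
#' intensity volume per subject, filled with the same seeded draws as
#' [simulate_cohort()]. Passing these through [global_normalize()] and
#' [extract_roi_samples()] reproduces the direct-mode cohort exactly.
#'
#' @param config A [simulation_config()].
#' @param grid_shape Optional 3D grid dimensions; must fit
#'   `n_regions * n_vox` voxels. Default: a near-cubic grid just large
#'   enough.
#' @return List with `atlas` (an `atlas_labels`) and `subjects` (tibble
#'   with `subject_id`, `group`, and a `volume` list-column of raw
#'   `pet_volume`s).
#' @export
simulate_phantom <- function(config, grid_shape = NULL) {
  needed <- config$n_regions * config$n_vox
  if (is.null(grid_shape)) {
    side <- ceiling(needed^(1 / 3))
    grid_shape <- c(side, side, ceiling(needed / side^2))
  }
  if (prod(grid_shape) < needed) {
    abort(sprintf("grid %s too small for %d regions of %d voxels",
                  paste(grid_shape, collapse = "x"), config$n_regions,
                  config$n_vox),
          class = "jsseconn_simulate_error")
  }
  lab <- integer(prod(grid_shape))
  lab[seq_len(needed)] <- rep(seq_len(config$n_regions),
                              each = config$n_vox)
  atlas <- atlas_labels(array(lab, dim = grid_shape),
                        n_regions = config$n_regions)
  raw <- simulate_raw_samples(config)
  volumes <- lapply(raw$samples, function(x) {
    v <- numeric(prod(grid_shape))
    v[seq_len(needed)] <- unlist(x, use.names = FALSE)
    pet_volume(array(v, dim = grid_shape))
  })
  list(
    atlas = atlas,
    subjects = tibble::tibble(subject_id = raw$ids, group = raw$groups,
                              volume = volumes)
  )
}

#' Simulate a label-permuted null cohort
#'
#' Same marginal data as [simulate_cohort()] with the group labels randomly
#' permuted (seeded), for classifier calibration: any classifier run on the
#' null cohort should perform at chance.
#'
#' @param config A [simulation_config()]; the permutation uses
#'   `config$seed` too.
#' @return Cohort tibble like [simulate_cohort()]'s, with shuffled `group`
#'   labels (the `samples` keep their original generating group in the
#'   `roi_samples` attribute's stead, relabeled to the permuted group).
#' @export
make_null_cohort <- function(config) {
  cohort <- simulate_cohort(config)
  perm <- with_preserved_seed(config$seed + 1L, sample(nrow(cohort)))
  cohort$group <- cohort$group[perm]
  cohort$samples <- purrr::map2(cohort$samples, cohort$group, function(s, g) {
    attr(s, "group") <- g
    s
  })
  cohort
}
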