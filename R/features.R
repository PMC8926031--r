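#' Assemble the three feature blocks of one subject
#'
#' The classifier consumes three blocks per subject: `connection` — the
#' `n(n-1)/2` upper-triangle connection weights (4005 for 90 regions);
#' `global` — the 11 global graph metrics, each summed across the sparsity
#' sweep; `nodal` — the 5 nodal metrics per node (450 values for 90
#' regions), likewise sweep-summed.
#'
#' @param network A `metabolic_network`.
#' @param sparsities Sparsity thresholds (default [sparsity_sweep()]).
#' @param n_nulls Null-ensemble size per threshold for the normalized
#'   global metrics (default 100).
#' @param seed Seed for the null ensembles.
#' @return A `feature_bundle`: list of named numeric vectors `connection`,
#'   `global`, `nodal`.
#' @export
feature_bundle <- function(network, sparsities = sparsity_sweep(),
                           n_nulls = 100, seed = 1) {
  edges <- tidy(network)
  connection <- setNames(edges$weight,
                         paste(edges$region_i, edges$region_j, sep = "--"))
  auc <- auc_features(sweep_metrics(network, sparsities = sparsities,
                                    n_nulls = n_nulls, seed = seed))
  glob <- auc[is.na(auc$node), ]
  global <- setNames(glob$auc, glob$metric)[.global_metric_names]
  names(global) <- .global_metric_names
  nod <- auc[!is.na(auc$node), ]
  nodal_names <- paste(nod$metric, nod$node, sep = "|")
  nodal <- setNames(nod$auc, nodal_names)
  # fixed ordering: metric-major, nodes in atlas label order
  order_key <- order(match(nod$metric, sort(unique(nod$metric))),
                     match(nod$node, rownames(network)))
  structure(list(connection = connection, global = global,
                 nodal = nodal[order_key]),
            class = "feature_bundle")
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat("<feature_bundle> connection:", length(x$connection),
      "| global:", length(x$global), "| nodal:", length(x$nodal), "\n")
  invisible(x)
}

#' Add connectomes and feature bundles to a cohort table
#'
#' Convenience pipeline steps over a cohort tibble (as produced by
#' [simulate_cohort()]): `add_connectomes()` maps [build_connectome()] over
#' the `samples` column; `add_features()` maps [feature_bundle()] over the
#' `network` column.
#'
#' @param cohort Cohort tibble with a `samples` (resp. `network`)
#'   list-column.
#' @param ... Passed to [build_connectome()] / [feature_bundle()].
#' @return The cohort tibble with a `network` (resp. `features`)
#'   list-column added.
#' @export
add_connectomes <- function(cohort, ...) {
  dplyr::mutate(cohort,
                network = purrr::map(.data$samples, build_connectome, ...))
}

#' @rdname add_connectomes
#' @export
add_features <- function(cohort, ...) {
  dplyr::mutate(cohort,
                features = purrr::map(.data$network, feature_bundle, ...))
}

# stack a cohort's feature bundles into the three design matrices
feature_matrices <- function(cohort) {
  stopifnot("features" %in% names(cohort))
  blocks <- lapply(c("connection", "global", "nodal"), function(b) {
    do.call(rbind, lapply(cohort$features, `[[`, b))
  })
  names(blocks) <- c("connection", "global", "nodal")
  for (b in names(blocks)) rownames(blocks[[b]]) <- cohort$subject_id
  blocks
}
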