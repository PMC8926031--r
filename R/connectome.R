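#' Build an individual metabolic network from ROI samples
#'
#' For every unordered region pair, both regions' intensity PDFs are
#' estimated by Gaussian KDE on a common pair-specific grid (equally spaced
#' points spanning the union of the two sample ranges, padded by 3
#' bandwidths on each side) and the Jensen-Shannon divergence between them
#' is computed in log base 2. The connection weight is the similarity
#' `1 - D_JS` by default (stronger = metabolically more similar), or the raw
#' divergence when `edge_weight = "divergence"`.
#'
#' @param roi_samples A `roi_samples` object (one sample vector per region).
#' @param grid_points Number of evaluation points of the pair grid
#'   (default 256).
#' @param edge_weight `"similarity"` (default, `1 - D_JS`) or
#'   `"divergence"`.
#' @return A `metabolic_network`: symmetric `n x n` matrix with zero
#'   diagonal and entries in `[0, 1]`, with region names as dimnames and
#'   attributes `subject_id`, `group`, `edge_weight`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(
#'   n_per_group = 1, n_regions = 8, n_vox = 40, effect_pairs = NULL, seed = 1))
#' net <- build_connectome(cohort$samples[[1]])
#' net[1:3, 1:3]
build_connectome <- function(roi_samples, grid_points = 256,
                             edge_weight = c("similarity", "divergence")) {
  edge_weight <- match.arg(edge_weight)
  stopifnot(inherits(roi_samples, "roi_samples"))
  n <- length(roi_samples)
  bw <- vapply(roi_samples, silverman_bw, numeric(1))
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- pair_js_divergence(roi_samples[[i]], roi_samples[[j]],
                              bw[i], bw[j], grid_points)
      W[i, j] <- W[j, i] <- if (edge_weight == "similarity") 1 - d else d
    }
  }
  metabolic_network(W, region_names = names(roi_samples),
                    subject_id = attr(roi_samples, "subject_id"),
                    group = attr(roi_samples, "group"),
                    edge_weight = edge_weight)
}

# JS divergence of two sample vectors on their common pair-specific grid
pair_js_divergence <- function(x, y, bw_x, bw_y, grid_points) {
  pad <- 3 * max(bw_x, bw_y)
  lo <- min(x, y) - pad
  hi <- max(x, y) + pad
  grid <- seq(lo, hi, length.out = grid_points)
  P <- estimate_pdf(x, grid, bandwidth = bw_x)
  Q <- estimate_pdf(y, grid, bandwidth = bw_y)
  js_divergence(P, Q)
}

# similarity of one region pair only (used by calibration checks on the
# synthetic generator, where building the full matrix would be wasteful)
pair_similarity <- function(roi_samples, i, j, grid_points = 256) {
  1 - pair_js_divergence(roi_samples[[i]], roi_samples[[j]],
                         silverman_bw(roi_samples[[i]]),
                         silverman_bw(roi_samples[[j]]), grid_points)
}

#' Construct a metabolic network from a weight matrix
#'
#' @param weights Symmetric numeric matrix, zero diagonal, entries in
#'   `[0, 1]`.
#' @param region_names Region names (default AAL-90 when 90 x 90).
#' @param subject_id,group Optional subject metadata.
#' @param edge_weight `"similarity"` or `"divergence"` (bookkeeping only).
#' @return A `metabolic_network` matrix.
#' @export
metabolic_network <- function(weights, region_names = NULL,
                              subject_id = NULL, group = NULL,
                              edge_weight = "similarity") {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) abort("weights must be square",
                                class = "jsseconn_network_error")
  if (max(abs(weights - t(weights))) > 1e-12) {
    abort("weights must be symmetric within 1e-12",
          class = "jsseconn_network_error")
  }
  if (any(diag(weights) != 0)) {
    abort("diagonal must be zero", class = "jsseconn_network_error")
  }
  if (any(weights < 0) || any(weights > 1)) {
    abort("weights must lie in [0, 1]", class = "jsseconn_network_error")
  }
  if (is.null(region_names)) region_names <- default_region_names(n)
  stopifnot(length(region_names) == n)
  dimnames(weights) <- list(region_names, region_names)
  structure(weights, class = c("metabolic_network", "matrix", "array"),
            subject_id = subject_id, group = group, edge_weight = edge_weight)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x), " x ", ncol(x),
      " (", attr(x, "edge_weight"), ")",
      if (!is.null(attr(x, "subject_id")))
        paste0(", subject ", attr(x, "subject_id")),
      "\n", sep = "")
  ut <- x[upper.tri(x)]
  cat("  edge weights: min ", signif(min(ut), 4), ", median ",
      signif(stats::median(ut), 4), ", max ", signif(max(ut), 4), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a metabolic network into a long edge list
#'
#' @param x A `metabolic_network`.
#' @param ... Unused.
#' @return Tibble with columns `region_i`, `region_j`, `weight`, one row per
#'   unordered region pair (i < j in label order).
#' @export
tidy.metabolic_network <- function(x, ...) {
  n <- nrow(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(
    region_i = rownames(x)[idx[, 1L]],
    region_j = colnames(x)[idx[, 2L]],
    weight = x[idx]
  )
}

#' Heatmap of a metabolic network
#'
#' @param object A `metabolic_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metabolic_network <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(nrow(object)), j = seq_len(ncol(object)))
  df$weight <- object[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "region", y = "region",
                  fill = attr(object, "edge_weight")) +
    ggplot2::theme_minimal()
}

#' Write / read a connectome as a square CSV matrix
#'
#' The CSV carries region names as header and first column, so files
#' round-trip through [read_connectome()].
#'
#' @param network A `metabolic_network`.
#' @param path Output CSV path.
#' @return `path` invisibly, or the re-read `metabolic_network`.
#' @export
write_connectome <- function(network, path) {
  df <- as.data.frame(unclass(network))
  df <- cbind(region = rownames(network), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  metabolic_network(m, region_names = df$region)
}

#' Write a connectome as a long edge list CSV
#'
#' @param network A `metabolic_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  readr::write_csv(tidy(network), path)
  invisible(path)
}
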