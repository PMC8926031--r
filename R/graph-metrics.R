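#' Sparsity thresholds of the network sweep
#'
#' The canonical sweep retains the strongest 2% to 50% of connections in
#' steps of 1%, i.e. 49 thresholds; per-metric features are sums of the 49
#' per-threshold values (the "area under the curve" over the sweep).
#'
#' @param min,max,step Sweep limits and increment (defaults 0.02, 0.50,
#'   0.01).
#' @return Numeric vector of thresholds (length 49 at the defaults).
#' @export
sparsity_sweep <- function(min = 0.02, max = 0.5, step = 0.01) {
  round(seq(round(min / step), round(max / step)), 10) * step
}

#' Binarize a network at a sparsity threshold
#'
#' Keeps exactly `floor(sparsity * n_pairs)` strongest-weight edges
#' (`n_pairs = n(n-1)/2`, 4005 for 90 regions) as 1, the rest 0. Ties in
#' weight are broken by lexicographic `(i, j)` pair order so the edge set is
#' reproducible.
#'
#' @param network A `metabolic_network`.
#' @param sparsity Fraction of retained edges, in `(0, 1]`.
#' @return A `binary_graph`: list with `adjacency` (0/1 symmetric matrix,
#'   zero diagonal) and `sparsity`.
#' @export
binarize_at_sparsity <- function(network, sparsity) {
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity <= 0 || sparsity > 1) {
    abort("sparsity must lie in (0, 1]", class = "jsseconn_graph_error")
  }
  n <- nrow(network)
  idx <- which(upper.tri(network), arr.ind = TRUE)
  ord <- order(-network[idx], idx[, 1L], idx[, 2L])
  k <- floor(sparsity * nrow(idx))
  keep <- idx[ord[seq_len(k)], , drop = FALSE]
  A <- matrix(0L, n, n, dimnames = dimnames(network))
  A[keep] <- 1L
  A[keep[, c(2L, 1L), drop = FALSE]] <- 1L
  binary_graph(A, sparsity)
}

# internal constructor; caches the igraph representation so repeated metric
# computations skip the adjacency conversion
binary_graph <- function(adjacency, sparsity) {
  structure(
    list(adjacency = adjacency, sparsity = sparsity,
         graph = igraph::graph_from_adjacency_matrix(adjacency,
                                                     mode = "undirected",
                                                     diag = FALSE)),
    class = "binary_graph"
  )
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("<binary_graph> ", nrow(x$adjacency), " nodes, ",
      sum(x$adjacency) / 2, " edges (sparsity ", x$sparsity, ")\n", sep = "")
  invisible(x)
}

as_igraph <- function(graph) {
  graph$graph %||%
    igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                        diag = FALSE)
}

.global_metric_names <- c("Cp", "Lp", "gamma", "lambda", "sigma",
                          "Eglobal", "Elocal", "Q", "Ar", "Hr", "Sr")

#' Global graph metrics of a binarized network
#'
#' Computes, on the binary undirected graph: mean nodal clustering
#' coefficient `Cp` (nodes with degree < 2 contribute 0), characteristic
#' path length `Lp` (mean shortest path over connected pairs only), global
#' efficiency `Eglobal` and local efficiency `Elocal` (unreachable pairs
#' contribute 0, so both stay finite on disconnected graphs), modularity `Q`
#' of the deterministic greedy-agglomeration partition, degree assortativity
#' `Ar`, hierarchy `Hr` (the slope beta of `log C(k) ~ -beta log k` over
#' nodes with degree > 1 and positive clustering), and synchronization `Sr`
#' (Laplacian eigenratio `lambda_2 / lambda_max`). When a degree-matched
#' null ensemble is supplied, the normalized metrics `gamma = Cp /
#' <Cp_null>`, `lambda = Lp / <Lp_null>` and small-worldness `sigma = gamma
#' / lambda` are added; metrics undefined on a given graph (e.g. `gamma`
#' when the nulls are triangle-free) are `NA`.
#'
#' @param graph A `binary_graph` with at least one edge.
#' @param null_ensemble Optional list of degree-matched `binary_graph`s from
#'   [generate_null_ensemble()].
#' @param metrics Character vector selecting which metrics to compute
#'   (default all 11).
#' @return One-row tibble with the requested metric columns.
#' @export
compute_global_metrics <- function(graph, null_ensemble = NULL,
                                   metrics = .global_metric_names) {
  metrics <- match.arg(metrics, .global_metric_names, several.ok = TRUE)
  if (sum(graph$adjacency) == 0) {
    abort("graph has no edges", class = "jsseconn_graph_error")
  }
  g <- as_igraph(graph)
  out <- list()
  if (any(c("Cp", "gamma", "sigma", "Hr") %in% metrics)) {
    ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    out$Cp <- mean(ci)
  }
  if (any(c("Lp", "lambda", "sigma") %in% metrics)) {
    out$Lp <- igraph::mean_distance(g, unconnected = TRUE)
  }
  if ("Eglobal" %in% metrics) out$Eglobal <- igraph::global_efficiency(g)
  if ("Elocal" %in% metrics) {
    out$Elocal <- mean(igraph::local_efficiency(g))
  }
  if ("Q" %in% metrics) {
    out$Q <- igraph::modularity(igraph::cluster_fast_greedy(g))
  }
  if ("Ar" %in% metrics) out$Ar <- igraph::assortativity_degree(g)
  if ("Hr" %in% metrics) {
    k <- igraph::degree(g)
    sel <- k > 1 & ci > 0
    out$Hr <- if (sum(sel) >= 2 && length(unique(k[sel])) >= 2) {
      -unname(stats::coef(stats::lm(log(ci[sel]) ~ log(k[sel])))[2L])
    } else NA_real_
  }
  if ("Sr" %in% metrics) {
    L <- igraph::laplacian_matrix(g, sparse = FALSE)
    ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    out$Sr <- ev[2L] / ev[length(ev)]
  }
  if (any(c("gamma", "lambda", "sigma") %in% metrics)) {
    if (is.null(null_ensemble) || length(null_ensemble) == 0L) {
      out$gamma <- out$lambda <- out$sigma <- NA_real_
    } else {
      null_cp <- mean(vapply(null_ensemble, function(h) {
        mean(igraph::transitivity(as_igraph(h), type = "localundirected",
                                  isolates = "zero"))
      }, numeric(1)))
      null_lp <- mean(vapply(null_ensemble, function(h) {
        igraph::mean_distance(as_igraph(h), unconnected = TRUE)
      }, numeric(1)))
      out$gamma <- if (null_cp > 0) out$Cp / null_cp else NA_real_
      out$lambda <- if (is.finite(null_lp) && null_lp > 0) out$Lp / null_lp
                    else NA_real_
      out$sigma <- if (!is.na(out$gamma) && !is.na(out$lambda) &&
                       out$lambda > 0) out$gamma / out$lambda else NA_real_
    }
  }
  tibble::as_tibble(out[metrics[metrics %in% names(out)]])
}

#' Nodal graph metrics of a binarized network
#'
#' Degree, betweenness centrality (unnormalized sum over pairs of the
#' fraction of shortest paths through the node), nodal efficiency (mean of
#' `1/d` to the other nodes, 0 for unreachable ones), nodal shortest path
#' length (mean distance to reachable nodes; `NA` for isolated nodes) and
#' nodal clustering coefficient (triangle density among neighbors, 0 for
#' degree < 2).
#'
#' @param graph A `binary_graph`.
#' @return Tibble with columns `region`, `degree`, `betweenness`,
#'   `efficiency`, `path_length`, `clustering`; one row per node.
#' @export
compute_nodal_metrics <- function(graph) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  D <- igraph::distances(g)
  diag(D) <- NA
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  tibble::tibble(
    region = rownames(graph$adjacency) %||% default_region_names(n),
    degree = as.numeric(igraph::degree(g)),
    betweenness = as.numeric(igraph::betweenness(g, directed = FALSE)),
    efficiency = unname(rowSums(inv, na.rm = TRUE)) / (n - 1),
    path_length = apply(D, 1L, function(d) {
      d <- d[is.finite(d)]
      if (length(d) == 0L) NA_real_ else mean(d)
    }),
    clustering = igraph::transitivity(g, type = "localundirected",
                                      isolates = "zero")
  )
}

#' Degree-preserving null ensemble
#'
#' Maslov-Sneppen rewiring: each null is the input graph after `10 * |E|`
#' attempted degree-preserving edge swaps. Seeded, so the ensemble is
#' reproducible.
#'
#' @param graph A `binary_graph` with at least 2 edges.
#' @param n_nulls Ensemble size (default 100).
#' @param seed Integer seed.
#' @return List of `binary_graph`s with the same degree sequence as the
#'   input.
#' @export
generate_null_ensemble <- function(graph, n_nulls = 100, seed = 1) {
  n_edges <- sum(graph$adjacency) / 2
  stopifnot(n_edges >= 2)
  g <- as_igraph(graph)
  with_preserved_seed(seed, {
    lapply(seq_len(n_nulls), function(i) {
      h <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * n_edges))
      A <- igraph::as_adjacency_matrix(h, sparse = FALSE)
      storage.mode(A) <- "integer"
      dimnames(A) <- dimnames(graph$adjacency)
      structure(list(adjacency = A, sparsity = graph$sparsity, graph = h),
                class = "binary_graph")
    })
  })
}

# evaluate `code` under set.seed(seed) without disturbing the caller's RNG
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Graph metrics across the sparsity sweep
#'
#' Binarizes the network at each threshold and computes all global and
#' nodal metrics, returning one tidy table. Normalized global metrics
#' (`gamma`, `lambda`, `sigma`) use a fresh degree-matched null ensemble per
#' threshold.
#'
#' @param network A `metabolic_network`.
#' @param sparsities Thresholds (default [sparsity_sweep()]).
#' @param n_nulls Null-ensemble size per threshold (default 100; 0 skips the
#'   normalized metrics).
#' @param seed Seed for the null ensembles.
#' @return Tibble with columns `sparsity`, `metric`, `node` (`NA` for global
#'   metrics), `value`.
#' @export
sweep_metrics <- function(network, sparsities = sparsity_sweep(),
                          n_nulls = 100, seed = 1) {
  purrr::map_dfr(seq_along(sparsities), function(k) {
    s <- sparsities[k]
    bg <- binarize_at_sparsity(network, s)
    nulls <- if (n_nulls > 0) {
      generate_null_ensemble(bg, n_nulls = n_nulls, seed = seed + k)
    } else NULL
    glob <- compute_global_metrics(bg, null_ensemble = nulls)
    nod <- compute_nodal_metrics(bg)
    dplyr::bind_rows(
      tibble::tibble(sparsity = s, metric = names(glob), node = NA_character_,
                     value = as.numeric(glob[1L, ])),
      tidyr::pivot_longer(nod, -"region", names_to = "metric",
                          values_to = "value") |>
        dplyr::transmute(sparsity = s, metric = .data$metric,
                         node = .data$region, value = unname(.data$value))
    )
  })
}

#' Area-under-the-sweep features
#'
#' Sums each metric's values across the sparsity thresholds (49 at the
#' canonical sweep), yielding a single feature per global metric and per
#' node-metric pair. Thresholds where a metric is undefined (`NA`) are
#' omitted from its sum.
#'
#' @param sweep_tbl Output of [sweep_metrics()].
#' @return Tibble with columns `metric`, `node`, `auc`.
#' @export
auc_features <- function(sweep_tbl) {
  dplyr::summarise(
    dplyr::group_by(sweep_tbl, .data$metric, .data$node),
    auc = sum(.data$value, na.rm = TRUE), .groups = "drop"
  )
}

#' Identify hub nodes
#'
#' A node is a hub when its metric value exceeds the mean plus one standard
#' deviation of the 90 nodal values (population SD by default). With zero
#' variance no node qualifies.
#'
#' @param values Named numeric vector of nodal values (e.g. degree or
#'   betweenness, possibly AUC-summed).
#' @param metric Metric name recorded in the output (`"degree"` or
#'   `"betweenness"` in the standard analysis).
#' @param sd_type `"population"` (divisor `n`, default) or `"sample"`
#'   (divisor `n - 1`).
#' @return Tibble of hubs: columns `metric`, `region`, `value`.
#' @export
identify_hubs <- function(values, metric = "degree",
                          sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(is.finite(values)))
  n <- length(values)
  s <- stats::sd(values)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (is.na(s)) s <- 0
  cut <- mean(values) + s
  hubs <- if (s == 0) integer(0) else which(values > cut)
  nm <- names(values) %||% default_region_names(n)
  tibble::tibble(metric = metric, region = nm[hubs],
                 value = as.numeric(values[hubs]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
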