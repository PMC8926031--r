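test_that("the sparsity sweep is 0.02..0.50 in steps of 0.01", {
  s <- sparsity_sweep()
  expect_length(s, 49)
  expect_equal(s[1], 0.02)
  expect_equal(s[length(s)], 0.50)
  expect_equal(diff(s), rep(0.01, 48), tolerance = 1e-12)
})

test_that("binarization retains exactly floor(s * n_pairs) edges, nested
          across thresholds, with deterministic tie-breaking", {
  net <- standard_subject_network()
  edge_sets <- list()
  for (s in c(0.02, 0.1, 0.37, 0.5, 1)) {
    bg <- binarize_at_sparsity(net, s)
    A <- bg$adjacency
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_identical(sum(A) / 2, floor(s * 4005))
    edge_sets[[as.character(s)]] <- A
  }
  expect_identical(sum(edge_sets[["0.02"]]) / 2, 80)
  expect_identical(sum(edge_sets[["1"]]) / 2, 4005)
  # nested: each edge set is a subset of the next
  for (i in 1:4) {
    expect_true(all(edge_sets[[i]] <= edge_sets[[i + 1]]))
  }
  # all-equal weights: the tie-break alone determines a reproducible set
  W <- matrix(0.5, 6, 6); diag(W) <- 0
  tie <- metabolic_network(W)
  b1 <- binarize_at_sparsity(tie, 0.5)
  b2 <- binarize_at_sparsity(tie, 0.5)
  expect_identical(b1$adjacency, b2$adjacency)
  expect_identical(sum(b1$adjacency) / 2, floor(0.5 * 15))
  # lexicographic order: first pairs (1,2), (1,3), ... retained
  idx <- which(upper.tri(W), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), ]
  expected <- matrix(0L, 6, 6)
  expected[idx[1:7, , drop = FALSE]] <- 1L
  expect_identical(unname(b1$adjacency), expected + t(expected))
  expect_error(binarize_at_sparsity(tie, 0), class = "jsseconn_graph_error")
  expect_error(binarize_at_sparsity(tie, 1.2), class = "jsseconn_graph_error")
})

graph_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) { A[e[1], e[2]] <- A[e[2], e[1]] <- 1L }
  jsseconn:::binary_graph(A, sparsity = sum(A) / (n * (n - 1)))
}

test_that("global metrics match closed forms on canonical graphs", {
  K5 <- graph_from_edges(5, combn(5, 2, simplify = FALSE))
  g5 <- compute_global_metrics(K5, metrics = c("Cp", "Lp", "Eglobal"))
  expect_equal(g5$Cp, 1)
  expect_equal(g5$Lp, 1)
  expect_equal(g5$Eglobal, 1)

  P4 <- graph_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4)))
  g4 <- compute_global_metrics(P4, metrics = c("Lp"))
  expect_equal(g4$Lp, (1 * 3 + 2 * 2 + 3 * 1) / 6)

  S5 <- graph_from_edges(5, lapply(2:5, function(i) c(1, i)))
  expect_equal(compute_global_metrics(S5, metrics = "Cp")$Cp, 0)
  nodal <- compute_nodal_metrics(S5)
  expect_equal(nodal$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(nodal$degree, c(4, 1, 1, 1, 1))

  empty <- graph_from_edges(3, list())
  expect_error(compute_global_metrics(empty), class = "jsseconn_graph_error")
})

test_that("metrics agree with the matrix-power oracle on random graphs,
          including disconnected ones", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    A <- matrix(0L, n, n)
    pairs <- which(upper.tri(A), arr.ind = TRUE)
    m <- sample(seq_len(nrow(pairs) - 1), 1)
    on <- pairs[sample(nrow(pairs), m), , drop = FALSE]
    A[on] <- 1L; A[on[, 2:1, drop = FALSE]] <- 1L
    if (sum(A) == 0) next
    bg <- jsseconn:::binary_graph(A, sparsity = m / nrow(pairs))
    oracle <- brute_graph_metrics(A)
    glob <- compute_global_metrics(bg, metrics = c("Cp", "Lp", "Eglobal"))
    expect_equal(glob$Cp, oracle$Cp, tolerance = 1e-12)
    expect_equal(glob$Lp, oracle$Lp, tolerance = 1e-12)
    expect_equal(glob$Eglobal, oracle$Eglobal, tolerance = 1e-12)
    nodal <- compute_nodal_metrics(bg)
    expect_equal(nodal$degree, oracle$degree, tolerance = 1e-12)
    expect_equal(nodal$betweenness, oracle$betweenness, tolerance = 1e-9)
    expect_equal(nodal$efficiency, oracle$efficiency, tolerance = 1e-12)
    expect_equal(nodal$path_length, oracle$path_length, tolerance = 1e-12)
    expect_equal(nodal$clustering, oracle$clustering, tolerance = 1e-12)
  }
})

test_that("null ensembles preserve degree sequences and are seeded", {
  net <- standard_subject_network()
  bg <- binarize_at_sparsity(net, 0.1)
  nulls <- generate_null_ensemble(bg, n_nulls = 8, seed = 3)
  deg <- rowSums(bg$adjacency)
  for (h in nulls) {
    expect_identical(rowSums(h$adjacency), deg)
    expect_identical(h$adjacency, t(h$adjacency))
    expect_true(all(diag(h$adjacency) == 0))
  }
  nulls2 <- generate_null_ensemble(bg, n_nulls = 8, seed = 3)
  expect_identical(lapply(nulls, `[[`, "adjacency"),
                   lapply(nulls2, `[[`, "adjacency"))
  # most nulls actually differ from the input graph
  moved <- vapply(nulls, function(h) any(h$adjacency != bg$adjacency),
                  logical(1))
  expect_gt(mean(moved), 0.5)

  # complete graphs are rewiring-rigid
  K5 <- graph_from_edges(5, combn(5, 2, simplify = FALSE))
  for (h in generate_null_ensemble(K5, n_nulls = 3, seed = 1)) {
    expect_identical(unname(h$adjacency), unname(K5$adjacency))
  }
})

test_that("gamma, lambda, sigma normalize against the null ensemble", {
  net <- standard_subject_network()
  bg <- binarize_at_sparsity(net, 0.15)
  nulls <- generate_null_ensemble(bg, n_nulls = 10, seed = 4)
  g <- compute_global_metrics(bg, null_ensemble = nulls)
  expect_equal(g$sigma, g$gamma / g$lambda, tolerance = 1e-12)
  expect_true(all(c(g$gamma, g$lambda, g$sigma) > 0))
  # a null member scored against the ensemble sits near 1 in expectation
  gn <- vapply(nulls[1:5], function(h) {
    compute_global_metrics(h, null_ensemble = nulls, metrics = "Cp")$Cp
  }, numeric(1))
  null_cp <- mean(vapply(nulls, function(h) {
    compute_global_metrics(h, metrics = "Cp")$Cp
  }, numeric(1)))
  expect_equal(mean(gn) / null_cp, 1, tolerance = 0.25)
  # without nulls the normalized metrics are flagged undefined
  g0 <- compute_global_metrics(bg)
  expect_true(all(is.na(c(g0$gamma, g0$lambda, g0$sigma))))
})

test_that("sweep metrics and AUC features sum the per-threshold values", {
  cohort <- small_cohort()
  net <- build_connectome(cohort$samples[[1]])
  sw <- sweep_metrics(net, sparsities = c(0.1, 0.2, 0.3), n_nulls = 0)
  expect_setequal(unique(sw$metric),
                  c("Cp", "Lp", "gamma", "lambda", "sigma", "Eglobal",
                    "Elocal", "Q", "Ar", "Hr", "Sr", "degree", "betweenness",
                    "efficiency", "path_length", "clustering"))
  auc <- auc_features(sw)
  # independent loop over thresholds for nodal degree
  for (s in c(0.1, 0.2, 0.3)) {
    bg <- binarize_at_sparsity(net, s)
    expect_equal(
      sw$value[sw$metric == "degree" & sw$sparsity == s],
      unname(rowSums(bg$adjacency))
    )
  }
  deg_auc <- auc$auc[auc$metric == "degree" & !is.na(auc$node)]
  manual <- rowSums(vapply(c(0.1, 0.2, 0.3), function(s) {
    rowSums(binarize_at_sparsity(net, s)$adjacency)
  }, numeric(12)))
  expect_equal(deg_auc[match(rownames(net), auc$node[auc$metric == "degree" &
                                                       !is.na(auc$node)])],
               unname(manual), tolerance = 1e-9)
  # a metric constant across thresholds sums to count * value
  const <- tibble::tibble(sparsity = rep(1:49 / 100, 2),
                          metric = "x", node = NA_character_, value = 2)
  expect_equal(auc_features(const)$auc, 49 * 2 * 2)
})

test_that("hub rule: mean + population SD threshold with its invariances", {
  vals <- c(a = 1, b = 1, c = 1, d = 10)
  hubs <- identify_hubs(vals, "degree")
  expect_identical(hubs$region, "d")
  # hand arithmetic: mean 3.25, population SD sqrt(60.75/4) = 3.897
  expect_equal(3.25 + sqrt((3 * (1 - 3.25)^2 + (10 - 3.25)^2) / 4), 7.147,
               tolerance = 1e-3)
  expect_identical(nrow(identify_hubs(rep(5, 90))), 0L)
  shifted <- identify_hubs(vals + 100, "degree")
  expect_identical(shifted$region, hubs$region)
  # sample-SD variant is stricter or equal
  expect_lte(nrow(identify_hubs(vals, sd_type = "sample")), nrow(hubs))
})
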