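# Independent oracles used across the test files. These deliberately avoid
# the code paths (igraph, the package's divergence and SVM routines) they
# are used to check.

# --- graph metrics from adjacency-matrix powers -------------------------
# Distances d(s,t) = smallest k with (A^k)[s,t] > 0; the number of shortest
# s-t paths is (A^d)[s,t] (minimal-length walks are necessarily simple);
# the number passing through v is the product of the s-v and v-t shortest
# path counts when d(s,v) + d(v,t) = d(s,t).
brute_graph_metrics <- function(A) {
  A <- unname(as.matrix(A))
  n <- nrow(A)
  pows <- vector("list", n)
  pows[[1]] <- A
  for (k in seq_len(n - 1)[-1]) pows[[k]] <- pows[[k - 1]] %*% A
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(n - 1)) {
    newly <- is.infinite(D) & pows[[k]] > 0
    D[newly] <- k
  }
  diag(D) <- 0
  npaths <- function(s, t) {
    d <- D[s, t]
    if (!is.finite(d) || d == 0) return(0)
    pows[[d]][s, t]
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    sig <- npaths(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        btw[v] <- btw[v] + npaths(s, v) * npaths(v, t) / sig
      }
    }
  }
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cv <- ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
  off <- row(D) != col(D)
  finite_off <- off & is.finite(D)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  list(
    distances = D,
    Cp = mean(cv),
    clustering = cv,
    Lp = mean(D[finite_off]),
    Eglobal = sum(inv) / (n * (n - 1)),
    betweenness = btw,
    degree = deg,
    efficiency = rowSums(inv) / (n - 1),
    path_length = vapply(seq_len(n), function(i) {
      d <- D[i, -i]
      d <- d[is.finite(d)]
      if (length(d) == 0) NA_real_ else mean(d)
    }, numeric(1))
  )
}

# --- continuous JS divergence of two Gaussians by numerical integration --
gaussian_js_integral <- function(mu1, sd1, mu2, sd2) {
  f <- function(x) {
    p <- stats::dnorm(x, mu1, sd1)
    q <- stats::dnorm(x, mu2, sd2)
    m <- (p + q) / 2
    tp <- ifelse(p > 0, p * log2(p / m), 0)
    tq <- ifelse(q > 0, q * log2(q / m), 0)
    0.5 * (tp + tq)
  }
  lo <- min(mu1 - 12 * sd1, mu2 - 12 * sd2)
  hi <- max(mu1 + 12 * sd1, mu2 + 12 * sd2)
  stats::integrate(f, lo, hi, rel.tol = 1e-10, subdivisions = 2000L)$value
}

# discrete PDF from an analytic Gaussian density sampled on a fine grid
gaussian_discrete_pdf <- function(mu, sd, grid) {
  y <- stats::dnorm(grid, mu, sd)
  discrete_pdf(grid, y / sum(y))
}

# random PDF pair on a shared grid (Dirichlet via normalized gamma draws)
random_pdf_pair <- function(n_points = 256, concentration = 0.5) {
  grid <- seq(0, 1, length.out = n_points)
  draw <- function() {
    w <- stats::rgamma(n_points, shape = concentration)
    while (sum(w) == 0) w <- stats::rgamma(n_points, shape = concentration)
    discrete_pdf(grid, w / sum(w))
  }
  list(P = draw(), Q = draw())
}

# dual objective of the C-SVC problem, for solver comparisons
svm_dual_objective <- function(K, y, alpha) {
  sum(alpha) - 0.5 * drop((alpha * y) %*% K %*% (alpha * y))
}
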