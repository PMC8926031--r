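#' Estimate a discrete probability mass function by Gaussian KDE
#'
#' Evaluates a Gaussian-kernel density estimate of the sample on the given
#' grid and renormalizes the evaluated values to sum to 1, yielding the
#' discrete PDF the divergence functions consume. Bandwidth follows
#' Silverman's rule ([stats::bw.nrd0()]); zero-variance samples fall back to
#' a degenerate bandwidth of `1e-6 * max(1, |mean|)` so the mass concentrates
#' at the grid points nearest the common value.
#'
#' @param samples Numeric vector of at least 2 finite values.
#' @param grid Strictly increasing numeric vector of evaluation points.
#' @param bandwidth Optional fixed kernel bandwidth; default Silverman.
#' @return A `discrete_pdf`: list with `grid` and `mass` (non-negative,
#'   summing to 1).
#' @export
estimate_pdf <- function(samples, grid, bandwidth = NULL) {
  if (length(samples) < 2L) {
    abort("need at least 2 samples for kernel density estimation",
          class = "jsseconn_pdf_error")
  }
  if (any(!is.finite(samples)) || any(!is.finite(grid))) {
    abort("samples and grid must be finite", class = "jsseconn_pdf_error")
  }
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    abort("grid must be strictly increasing with >= 2 points",
          class = "jsseconn_pdf_error")
  }
  bw <- if (is.null(bandwidth)) silverman_bw(samples) else bandwidth
  step <- diff(grid)
  equal_spaced <- (max(step) - min(step)) <= 1e-8 * mean(step)
  if (equal_spaced) {
    y <- stats::density(samples, bw = bw, kernel = "gaussian",
                        from = grid[1L], to = grid[length(grid)],
                        n = length(grid))$y
  } else {
    # direct evaluation for irregular grids
    y <- vapply(grid, function(g) mean(stats::dnorm(g, samples, bw)),
                numeric(1))
  }
  total <- sum(y)
  if (total <= 0) {
    # grid entirely outside the kernel support; put mass at nearest point
    y <- numeric(length(grid))
    y[which.min(abs(grid - mean(samples)))] <- 1
    total <- 1
  }
  discrete_pdf(grid, y / total)
}

# Silverman's rule-of-thumb bandwidth with a degenerate-sample fallback
silverman_bw <- function(samples) {
  if (stats::var(samples) == 0) {
    return(1e-6 * max(1, abs(mean(samples))))
  }
  stats::bw.nrd0(samples)
}

#' Construct a discrete PDF
#'
#' @param grid Strictly increasing evaluation points.
#' @param mass Non-negative vector of the same length summing to 1
#'   (renormalized if within 1e-9 of 1, rejected otherwise).
#' @return A `discrete_pdf` object.
#' @export
discrete_pdf <- function(grid, mass) {
  stopifnot(length(grid) == length(mass))
  if (any(diff(grid) <= 0)) {
    abort("grid must be strictly increasing", class = "jsseconn_pdf_error")
  }
  if (any(mass < 0) || abs(sum(mass) - 1) > 1e-9) {
    abort("mass must be non-negative and sum to 1",
          class = "jsseconn_pdf_error")
  }
  structure(list(grid = as.numeric(grid), mass = as.numeric(mass) / sum(mass)),
            class = "discrete_pdf")
}

#' @export
print.discrete_pdf <- function(x, ...) {
  cat("<discrete_pdf> ", length(x$grid), " points on [",
      signif(x$grid[1], 4), ", ", signif(x$grid[length(x$grid)], 4), "]\n",
      sep = "")
  invisible(x)
}

check_shared_grid <- function(P, Q) {
  if (!inherits(P, "discrete_pdf") || !inherits(Q, "discrete_pdf")) {
    abort("P and Q must be discrete_pdf objects", class = "jsseconn_pdf_error")
  }
  if (length(P$grid) != length(Q$grid) ||
      any(abs(P$grid - Q$grid) > 1e-12 * (1 + abs(P$grid)))) {
    abort("P and Q must share the same evaluation grid",
          class = "jsseconn_pdf_error")
  }
}

#' Kullback-Leibler divergence (bits)
#'
#' `sum over i with P(i) > 0 of P(i) * log2(P(i) / Q(i))`. Terms with
#' `P(i) = 0` contribute 0; any point with `P(i) > 0` and `Q(i) = 0` makes
#' the divergence `+Inf` (the standard measure-theoretic convention). The KL
#' divergence is asymmetric in its arguments.
#'
#' @param P,Q `discrete_pdf` objects on the same grid.
#' @return Non-negative scalar, possibly `Inf`, in bits.
#' @export
kl_divergence <- function(P, Q) {
  check_shared_grid(P, Q)
  p <- P$mass
  q <- Q$mass
  on <- p > 0
  if (any(q[on] == 0)) return(Inf)
  sum(p[on] * log2(p[on] / q[on]))
}

#' Jensen-Shannon divergence (bits)
#'
#' `0.5 * (KL(P || M) + KL(Q || M))` with mixture `M = (P + Q) / 2`,
#' computed in log base 2 so the value lies in `[0, 1]`: 0 iff `P == Q` and
#' 1 for disjoint supports. Always finite and symmetric in its arguments,
#' unlike the KL divergence, which makes it a convenient similarity basis
#' for region pairs.
#'
#' @param P,Q `discrete_pdf` objects on the same grid.
#' @return Scalar in `[0, 1]` bits.
#' @export
js_divergence <- function(P, Q) {
  check_shared_grid(P, Q)
  M <- discrete_pdf(P$grid, (P$mass + Q$mass) / 2)
  v <- 0.5 * (kl_divergence(P, M) + kl_divergence(Q, M))
  # guard against last-bit rounding outside the theoretical [0, 1] range
  if (v < 0 && v > -1e-9) v <- 0
  if (v > 1 && v < 1 + 1e-9) v <- 1
  v
}
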