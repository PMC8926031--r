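#' Two-sample t-test feature selection mask
#'
#' Keeps features whose pooled-variance two-sided Student t-test between
#' the two training groups has `p < alpha`. Computed on training data only;
#' in the nested cross-validation this is applied to the connection and
#' nodal blocks while the (11-dimensional) global block is always fully
#' retained. Features that are identical in both groups are excluded
#' (`p = 1`); zero pooled variance with differing means is kept (`p = 0`).
#'
#' @param X Feature matrix, subjects in rows.
#' @param y Labels (two classes; any coding).
#' @param alpha Significance level (default 0.05).
#' @return Logical vector, one entry per column of `X`.
#' @export
ttest_select <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  cls <- unique(y)
  if (length(cls) != 2L) {
    abort("ttest_select needs exactly two classes in the training labels",
          class = "jsseconn_cv_error")
  }
  g1 <- y == cls[1L]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(X[!g1, , drop = FALSE], 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  p[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 1, 0)
  unname(p < alpha)
}

# z-score columns by training statistics; zero-variance columns map to 0
standardize_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_standardize <- function(X, st) {
  sweep(sweep(as.matrix(X), 2L, st$center), 2L, st$scale, `/`)
}

# Fit one outer fold: t-test masks, standardization and inner grid search
# use the training subjects only, so the held-out subjects cannot influence
# any of them.
outer_fold_fit <- function(blocks, y, test_idx, C_grid, betas, alpha) {
  train_idx <- setdiff(seq_along(y), test_idx)
  y_tr <- y[train_idx]
  if (length(unique(y_tr)) < 2L) {
    abort("training fold contains a single class",
          class = "jsseconn_cv_error")
  }
  masks <- list(
    connection = ttest_select(blocks$connection[train_idx, , drop = FALSE],
                              y_tr, alpha),
    global = rep(TRUE, ncol(blocks$global)),
    nodal = ttest_select(blocks$nodal[train_idx, , drop = FALSE],
                         y_tr, alpha)
  )
  sel <- lapply(names(masks), function(b) {
    blocks[[b]][train_idx, masks[[b]], drop = FALSE]
  })
  names(sel) <- names(masks)
  stats_tr <- lapply(sel, standardize_train)
  Ztr <- Map(apply_standardize, sel, stats_tr)
  Ktr <- lapply(Ztr, linear_kernel)
  inner_acc <- .mk_inner_loocv(Ktr, y_tr, C_grid, betas)
  # ties: smaller C wins, then earlier row of the beta grid
  best <- c(1L, 1L)
  best_acc <- -Inf
  for (ci in seq_along(C_grid)) {
    for (bi in seq_len(nrow(betas))) {
      if (inner_acc[bi, ci] > best_acc + 1e-12) {
        best_acc <- inner_acc[bi, ci]
        best <- c(bi, ci)
      }
    }
  }
  beta_hat <- betas[best[1L], ]
  C_hat <- C_grid[best[2L]]
  model <- mksvm_train(Ktr, y_tr, beta_hat, C_hat)
  Ztest <- Map(function(b, st) {
    apply_standardize(blocks[[b]][test_idx, masks[[b]], drop = FALSE], st)
  }, names(masks), stats_tr)
  Kx <- Map(linear_kernel, Ztest, Ztr)
  pred <- mksvm_predict(model, unname(Kx))
  list(masks = masks, standardization = stats_tr, C = C_hat,
       betas = beta_hat, inner_accuracy = best_acc, model = model,
       decision = pred$decision, label = pred$label)
}

#' Nested leave-one-out cross-validation of the multi-kernel SVM
#'
#' Outer LOOCV over subjects. Within each outer training set the t-test
#' selection masks and per-feature z-scoring are recomputed, and an inner
#' LOOCV grid search over `C_grid x` the beta simplex picks the
#' hyperparameters with the highest inner accuracy (ties: smaller `C`,
#' then earlier beta in grid order). The final model is refit on the full
#' outer training set and the held-out subject's prediction recorded.
#'
#' @param cohort Cohort tibble with `subject_id`, `group` (SZF/SZR) and a
#'   `features` list-column of [feature_bundle()]s.
#' @param C_grid Regularization grid; default powers of two `2^-5 ... 2^5`.
#' @param beta_step Lattice step of the kernel-weight simplex grid
#'   (default 0.1, i.e. 66 candidate weightings).
#' @param alpha Significance level of the t-test selection (default 0.05).
#' @param positive Positive class for the performance summary
#'   (default `"SZF"`).
#' @param blocks Which feature blocks enter the model: any subset of
#'   `c("connection", "global", "nodal")`. Blocks not listed get kernel
#'   weight 0 (their beta grid dimension is collapsed); with a single block
#'   this is an ordinary single-kernel linear SVM.
#' @param seed Recorded in the result for provenance (the procedure itself
#'   is deterministic).
#' @return A `jsse_cv` object; see [tidy.jsse_cv()], [glance.jsse_cv()],
#'   [consensus_connections()].
#' @export
nested_loocv <- function(cohort, C_grid = 2^(-5:5), beta_step = 0.1,
                         alpha = 0.05, positive = "SZF",
                         blocks = c("connection", "global", "nodal"),
                         seed = 1) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  if (nrow(cohort) < 4L) {
    abort("need at least 4 subjects for nested LOOCV",
          class = "jsseconn_cv_error")
  }
  if (length(unique(cohort$group)) < 2L) {
    abort("cohort contains a single class", class = "jsseconn_cv_error")
  }
  X <- feature_matrices(cohort)
  y <- as_pm1(cohort$group, positive = positive)
  betas <- beta_simplex_grid(beta_step)
  # restrict the simplex to the requested blocks
  block_order <- c("connection", "global", "nodal")
  off <- !(block_order %in% blocks)
  if (any(off)) {
    keep <- rowSums(betas[, off, drop = FALSE]) == 0
    betas <- betas[keep, , drop = FALSE]
  }
  C_grid <- sort(C_grid)
  folds <- lapply(seq_len(nrow(cohort)), function(k) {
    outer_fold_fit(X, y, k, C_grid, betas, alpha)
  })
  result <- tibble::tibble(
    subject_id = cohort$subject_id,
    truth = cohort$group,
    predicted = ifelse(vapply(folds, `[[`, numeric(1), "label") > 0,
                       positive, setdiff(.group_levels, positive)),
    decision = vapply(folds, `[[`, numeric(1), "decision"),
    C = vapply(folds, `[[`, numeric(1), "C"),
    beta_connection = vapply(folds, function(f) f$betas[1L], numeric(1)),
    beta_global = vapply(folds, function(f) f$betas[2L], numeric(1)),
    beta_nodal = vapply(folds, function(f) f$betas[3L], numeric(1))
  )
  perf <- classification_performance(result$truth, result$predicted,
                                     result$decision, positive = positive)
  structure(
    list(folds = result,
         connection_masks = lapply(folds, function(f) f$masks$connection),
         nodal_masks = lapply(folds, function(f) f$masks$nodal),
         feature_names = list(connection = colnames(X$connection),
                              nodal = colnames(X$nodal)),
         performance = perf, positive = positive,
         config = list(C_grid = C_grid, beta_step = beta_step,
                       alpha = alpha, blocks = blocks, seed = seed)),
    class = "jsse_cv"
  )
}

#' Consensus connections across cross-validation folds
#'
#' Connections whose t-test selection passed in every outer fold — the
#' intersection of the per-fold connection masks — reported as region name
#' pairs.
#'
#' @param cv A `jsse_cv` object, or a list of logical per-fold masks (then
#'   `feature_names` must name the connections).
#' @param feature_names Connection names (`"A--B"`) when `cv` is a plain
#'   list of masks.
#' @return Tibble with columns `region_i`, `region_j`.
#' @export
consensus_connections <- function(cv, feature_names = NULL) {
  if (inherits(cv, "jsse_cv")) {
    masks <- cv$connection_masks
    feature_names <- cv$feature_names$connection
  } else {
    masks <- cv
  }
  stopifnot(length(masks) >= 1L, !is.null(feature_names))
  consensus <- Reduce(`&`, masks)
  nm <- feature_names[consensus]
  parts <- strsplit(nm, "--", fixed = TRUE)
  tibble::tibble(
    region_i = vapply(parts, `[[`, character(1), 1L),
    region_j = vapply(parts, `[[`, character(1), 2L)
  )
}

#' Classification performance summary
#'
#' Accuracy, sensitivity (`TP / (TP + FN)`, positive class SZF by default),
#' specificity (`TN / (TN + FP)`), the ROC curve by threshold sweep over
#' the decision values, and its trapezoid AUC (equal to the Mann-Whitney
#' statistic of the decision values).
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param decision Real-valued decision scores (higher = more likely
#'   positive).
#' @param positive Positive class label (default `"SZF"`).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `counts` (TP, FP, TN, FN) and `roc` (tibble `threshold`, `fpr`,
#'   `tpr`).
#' @export
classification_performance <- function(truth, predicted, decision,
                                       positive = "SZF") {
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(decision))
  pos <- truth == positive
  if (all(pos) || !any(pos)) {
    abort("both classes must be present to summarize performance",
          class = "jsseconn_cv_error")
  }
  pred_pos <- predicted == positive
  TP <- sum(pos & pred_pos)
  FN <- sum(pos & !pred_pos)
  TN <- sum(!pos & !pred_pos)
  FP <- sum(!pos & pred_pos)
  roc <- roc_points(pos, decision)
  list(
    accuracy = (TP + TN) / length(truth),
    sensitivity = TP / (TP + FN),
    specificity = TN / (TN + FP),
    auc = trapezoid_auc(roc),
    counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
    roc = roc
  )
}

# ROC by sweeping a threshold over the distinct decision values
roc_points <- function(pos, decision) {
  ord <- order(decision, decreasing = TRUE)
  pos <- pos[ord]
  dec <- decision[ord]
  starts <- which(!duplicated(dec))
  lasts <- c(starts[-1L] - 1L, length(dec))
  cum_tp <- cumsum(pos)
  cum_fp <- cumsum(!pos)
  tibble::tibble(
    threshold = c(Inf, dec[lasts]),
    fpr = c(0, cum_fp[lasts] / sum(!pos)),
    tpr = c(0, cum_tp[lasts] / sum(pos))
  )
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1L]) / 2)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two classifiers evaluated on the same subjects
#' using DeLong's placement-value covariance estimate (via
#' [pROC::roc.test()]). A zero-variance difference (e.g. comparing a
#' decision vector with itself) yields `z = 0`, `p = 1` by convention.
#'
#' @param decisions_A,decisions_B Decision-value vectors of the two
#'   classifiers over the same labeled subjects.
#' @param truth Class labels.
#' @param positive Positive class (default `"SZF"`).
#' @return List with `z`, `p`, `auc_A`, `auc_B`.
#' @export
delong_test <- function(decisions_A, decisions_B, truth, positive = "SZF") {
  stopifnot(length(decisions_A) == length(truth),
            length(decisions_B) == length(truth))
  pos <- truth == positive
  if (all(pos) || !any(pos)) {
    abort("both classes must be present", class = "jsseconn_cv_error")
  }
  resp <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
  rA <- pROC::roc(resp, decisions_A, levels = c("neg", "pos"),
                  direction = "<", quiet = TRUE)
  rB <- pROC::roc(resp, decisions_B, levels = c("neg", "pos"),
                  direction = "<", quiet = TRUE)
  tst <- suppressWarnings(tryCatch(
    pROC::roc.test(rA, rB, method = "delong", paired = TRUE),
    error = function(e) NULL
  ))
  z <- if (is.null(tst) || !is.finite(tst$statistic)) 0
       else unname(tst$statistic)
  p <- if (is.null(tst) || !is.finite(tst$p.value)) 1
       else unname(tst$p.value)
  list(z = z, p = p, auc_A = as.numeric(pROC::auc(rA)),
       auc_B = as.numeric(pROC::auc(rB)))
}

#' @export
print.jsse_cv <- function(x, ...) {
  p <- x$performance
  cat("<jsse_cv> ", nrow(x$folds), " outer folds (LOOCV)\n", sep = "")
  cat(sprintf("  accuracy %.2f%% | sensitivity %.2f%% | specificity %.2f%% | AUC %.4f\n",
              100 * p$accuracy, 100 * p$sensitivity, 100 * p$specificity,
              p$auc))
  cat("  consensus connections:", nrow(consensus_connections(x)), "\n")
  invisible(x)
}

#' Tidy per-fold cross-validation records
#'
#' @param x A `jsse_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per outer fold: subject, truth, prediction,
#'   decision value and chosen hyperparameters.
#' @export
tidy.jsse_cv <- function(x, ...) x$folds

#' One-row cross-validation performance summary
#'
#' @param x A `jsse_cv` object.
#' @param ... Unused.
#' @return Tibble with `n`, `accuracy`, `sensitivity`, `specificity`,
#'   `auc`, `n_consensus`.
#' @export
glance.jsse_cv <- function(x, ...) {
  p <- x$performance
  tibble::tibble(
    n = nrow(x$folds), accuracy = p$accuracy, sensitivity = p$sensitivity,
    specificity = p$specificity, auc = p$auc,
    n_consensus = nrow(consensus_connections(x))
  )
}

#' ROC curve of a cross-validation run
#'
#' @param object A `jsse_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jsse_cv <- function(object, ...) {
  roc <- object$performance$roc
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate (1 - specificity)",
      y = "true positive rate (sensitivity)",
      title = sprintf("LOOCV ROC, AUC = %.4f", object$performance$auc)
    ) +
    ggplot2::theme_minimal()
}
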