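# small synthetic feature cohort used by several classifier tests; the
# first `n_eff` connection features are shifted between groups
toy_feature_cohort <- function(n = 12, n_conn = 30, n_eff = 4, shift = 3,
                               seed = 18) {
  withr::with_seed(seed, {
    conn_names <- paste0("R", sprintf("%02d", 1:n_conn), "a--R",
                         sprintf("%02d", 1:n_conn), "b")
    groups <- rep(c("SZF", "SZR"), each = n / 2)
    feats <- lapply(seq_len(n), function(i) {
      conn <- stats::setNames(rnorm(n_conn), conn_names)
      if (groups[i] == "SZR" && n_eff > 0) {
        conn[seq_len(n_eff)] <- conn[seq_len(n_eff)] + shift
      }
      structure(list(
        connection = conn,
        global = stats::setNames(rnorm(11), paste0("g", 1:11)),
        nodal = stats::setNames(rnorm(15), paste0("m|n", 1:15))
      ), class = "feature_bundle")
    })
    tibble::tibble(subject_id = sprintf("T%02d", seq_len(n)),
                   group = groups, features = feats)
  })
}

test_that("t-test selection matches stats::t.test column by column", {
  set.seed(19)
  X <- matrix(rnorm(20 * 12), 20)
  y <- rep(c("SZF", "SZR"), each = 10)
  X[y == "SZF", 1] <- X[y == "SZF", 1] + 5  # strong effect: always kept
  X[, 2] <- 7                               # identical in both groups
  mask <- ttest_select(X, y, alpha = 0.05)
  p_ref <- apply(X[, -2], 2, function(col) {
    stats::t.test(col[y == "SZF"], col[y == "SZR"], var.equal = TRUE)$p.value
  })
  expect_identical(mask[-2], unname(p_ref < 0.05))
  expect_true(mask[1])
  expect_false(mask[2])
  expect_error(ttest_select(X, rep("SZF", 20)), class = "jsseconn_cv_error")
  # group means 0 vs 5 with tiny SD: t-statistic enormous
  Xs <- cbind(c(rnorm(20, 0, 0.1), rnorm(20, 5, 0.1)))
  expect_true(ttest_select(Xs, rep(c("a", "b"), each = 20))[1])
})

test_that("accuracy, sensitivity and specificity follow from confusion counts", {
  # TP 48, FN 16 (positives), TN 59, FP 5 (negatives)
  truth <- c(rep("SZF", 64), rep("SZR", 64))
  predicted <- c(rep("SZF", 48), rep("SZR", 16), rep("SZR", 59), rep("SZF", 5))
  decision <- ifelse(predicted == "SZF", 1, -1)
  perf <- classification_performance(truth, predicted, decision)
  expect_identical(unname(perf$counts),
                   c(48L, 5L, 59L, 16L)[match(names(perf$counts),
                                              c("TP", "FP", "TN", "FN"))])
  expect_equal(round(100 * perf$accuracy, 2), 83.59)
  expect_equal(round(100 * perf$sensitivity, 2), 75.00)
  expect_equal(round(100 * perf$specificity, 2), 92.19)
})

test_that("trapezoid AUC equals the Mann-Whitney pair count", {
  set.seed(20)
  truth <- rep(c("SZF", "SZR"), each = 5)
  decision <- c(2.5, 1.0, 0.3, 0.3, -0.5, 1.0, 0.1, -0.2, -0.2, -1.3)
  perf <- classification_performance(
    truth, ifelse(decision >= 0, "SZF", "SZR"), decision
  )
  pos <- decision[truth == "SZF"]
  neg <- decision[truth == "SZR"]
  mw <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
  expect_equal(perf$auc, mw, tolerance = 1e-12)
  # perfect separation
  perf2 <- classification_performance(
    truth, rep("SZF", 10), seq(10, 1)
  )
  expect_equal(perf2$auc, 1)
  # cross-check against an independent ROC implementation
  r <- pROC::roc(factor(truth, levels = c("SZR", "SZF")), decision,
                 direction = "<", quiet = TRUE)
  expect_equal(perf$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
})

test_that("DeLong comparison: identity, antisymmetry, and variance close to
          a bootstrap oracle", {
  set.seed(21)
  n <- 30
  truth <- rep(c("SZF", "SZR"), each = n / 2)
  dA <- rnorm(n) + (truth == "SZF") * 1.2
  dB <- 0.6 * dA + rnorm(n) * 0.8 + (truth == "SZF") * 0.5

  self <- delong_test(dA, dA, truth)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)

  ab <- delong_test(dA, dB, truth)
  ba <- delong_test(dB, dA, truth)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  se_delong <- abs(ab$auc_A - ab$auc_B) / abs(ab$z)
  auc_of <- function(d, t) {
    pos <- d[t == "SZF"]; neg <- d[t == "SZR"]
    (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
  }
  set.seed(99)
  boots <- replicate(4000, {
    i <- c(sample(which(truth == "SZF"), replace = TRUE),
           sample(which(truth == "SZR"), replace = TRUE))
    auc_of(dA[i], truth[i]) - auc_of(dB[i], truth[i])
  })
  expect_equal(se_delong / stats::sd(boots), 1, tolerance = 0.1)
})

test_that("a perfectly separable cohort is classified without error", {
  cohort <- toy_feature_cohort(n = 10, shift = 8)
  cv <- nested_loocv(cohort, beta_step = 0.5)
  expect_equal(nrow(tidy(cv)), 10) # one fold per subject
  expect_equal(glance(cv)$accuracy, 1)
  expect_equal(glance(cv)$auc, 1)
  # the injected connections survive every fold's selection
  cc <- consensus_connections(cv)
  injected <- paste0("R", sprintf("%02d", 1:4), "a--R",
                     sprintf("%02d", 1:4), "b")
  expect_true(all(injected %in% paste(cc$region_i, cc$region_j, sep = "--")))
})

test_that("consensus keeps exactly the connections selected in every fold", {
  masks <- list(c(TRUE, TRUE, FALSE, TRUE),
                c(TRUE, FALSE, FALSE, TRUE),
                c(TRUE, TRUE, TRUE, TRUE))
  nm <- c("A--B", "C--D", "E--F", "G--H")
  cc <- consensus_connections(masks, feature_names = nm)
  expect_identical(paste(cc$region_i, cc$region_j, sep = "--"),
                   c("A--B", "G--H"))
  empty <- consensus_connections(list(c(FALSE, TRUE), c(TRUE, FALSE)),
                                 feature_names = c("A--B", "C--D"))
  expect_identical(nrow(empty), 0L)
})

test_that("held-out subjects cannot influence any training-fold computation", {
  cohort <- toy_feature_cohort(n = 12, shift = 2, seed = 23)
  X <- jsseconn:::feature_matrices(cohort)
  y <- jsseconn:::as_pm1(cohort$group)
  betas <- beta_simplex_grid(0.5)
  C_grid <- 2^(-5:5)
  for (k in c(1L, 7L)) {
    ref <- jsseconn:::outer_fold_fit(X, y, k, C_grid, betas, 0.05)
    Xmut <- X
    for (b in names(Xmut)) {
      Xmut[[b]][k, ] <- Xmut[[b]][k, ] * -31 + 1e3 # arbitrary corruption
    }
    mut <- jsseconn:::outer_fold_fit(Xmut, y, k, C_grid, betas, 0.05)
    expect_identical(mut$masks, ref$masks)
    expect_identical(mut$standardization, ref$standardization)
    expect_identical(mut$C, ref$C)
    expect_identical(mut$betas, ref$betas)
    expect_identical(mut$model$alpha, ref$model$alpha)
    # only the held-out prediction may change
    expect_false(isTRUE(all.equal(mut$decision, ref$decision)))
  }
})

test_that("degenerate cohorts are rejected", {
  cohort <- toy_feature_cohort(n = 10)
  expect_error(nested_loocv(cohort[1:3, ]), class = "jsseconn_cv_error")
  one_class <- cohort
  one_class$group <- rep("SZF", 10)
  expect_error(nested_loocv(one_class), class = "jsseconn_cv_error")
  expect_error(
    classification_performance(rep("SZF", 4), rep("SZF", 4), rnorm(4)),
    class = "jsseconn_cv_error"
  )
})

test_that("single-block runs restrict the kernel weights to that block", {
  cohort <- toy_feature_cohort(n = 10, shift = 6, seed = 29)
  cv <- nested_loocv(cohort, beta_step = 0.5, blocks = "connection")
  f <- tidy(cv)
  expect_true(all(f$beta_connection == 1))
  expect_true(all(f$beta_global == 0 & f$beta_nodal == 0))
})
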