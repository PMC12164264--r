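make_pairs <- function(ddg_qb, is_cliff) {
  n <- length(ddg_qb)
  ids_w <- sprintf("W%03d", seq_len(n))
  ids_s <- sprintf("S%03d", seq_len(n))
  pairs <- data.frame(id_weak = ids_w, id_strong = ids_s,
                      similarity = 1, ddg_bind = ifelse(is_cliff, 4, 1),
                      is_cliff = is_cliff, stringsAsFactors = FALSE)
  est <- data.frame(ligand_id = c(ids_w, ids_s),
                    dg_qb = c(ddg_qb, rep(0, n)), sd = 0,
                    stringsAsFactors = FALSE)
  list(pairs = pairs, estimates = est)
}

test_that("pair evaluation applies the -5 kcal/mol rule with summed errors", {
  pairs <- data.frame(id_weak = c("w1", "w2"), id_strong = c("s1", "s2"),
                      similarity = 1, ddg_bind = c(4, 0.5),
                      is_cliff = c(TRUE, FALSE), stringsAsFactors = FALSE)
  est <- data.frame(ligand_id = c("w1", "s1", "w2", "s2"),
                    dg_qb = c(10, 21.9, 15, 15), sd = c(0.5, 0.7, 0.2, 0.3))
  out <- evaluate_pairs(pairs, est)
  expect_equal(out$evaluations$ddg_qb, c(-11.9, 0))
  expect_equal(out$evaluations$predicted_cliff, c(TRUE, FALSE))
  expect_equal(out$evaluations$error, c(1.2, 0.5))
  expect_identical(out$evaluations$outcome, c("TP", "TN"))
  expect_equal(unclass(out$confusion)[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))

  expect_error(evaluate_pairs(pairs, est[-1, ]), "w1")
})

test_that("a perfect synthetic classifier has no off-diagonal counts", {
  set.seed(8)
  lab <- rep(c(TRUE, FALSE), each = 20)
  sc <- ifelse(lab, -8, -1)
  d <- make_pairs(sc, lab)
  cm <- evaluate_pairs(d$pairs, d$estimates)$confusion
  expect_equal(cm$fp + cm$fn, 0L)
  expect_equal(mcc(cm), 1)
})

test_that("MCC reproduces the published pair-set value and conventions", {
  # completed from the printed counts: 207 pairs, 18 cliffs, 29 predicted,
  # 13 true positives, 5 false negatives
  expect_equal(round(mcc(confusion_matrix(tp = 13, fp = 16, tn = 173,
                                          fn = 5)), 2), 0.52)
  expect_equal(mcc(confusion_matrix(5, 0, 7, 0)), 1)
  # all-positive predictor: a zero marginal returns 0 by convention
  expect_equal(mcc(confusion_matrix(18, 189, 0, 0)), 0)
  # symmetry under simultaneous class swap
  cm1 <- confusion_matrix(13, 16, 173, 5)
  cm2 <- confusion_matrix(173, 5, 13, 16)
  expect_equal(mcc(cm1), mcc(cm2))
  expect_equal(round(precision(confusion_matrix(13, 16, 173, 5)), 2), 0.45)
})

test_that("confusion totals are conserved and monotone across thresholds", {
  set.seed(13)
  lab <- runif(80) < 0.3
  sc <- rnorm(80, ifelse(lab, -6, -2), 2)
  d <- make_pairs(sc, lab)
  prev_tp <- prev_fp <- 0
  for (th in seq(-10, 2, by = 1)) {
    cm <- evaluate_pairs(d$pairs, d$estimates, threshold = th)$confusion
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 80L)
    expect_gte(cm$tp, prev_tp)   # relaxing the threshold only adds positives
    expect_gte(cm$fp, prev_fp)
    prev_tp <- cm$tp; prev_fp <- cm$fp
  }
})

test_that("threshold scan yields AUC 1 for separable scores and ~0.5 for noise", {
  lab <- rep(c(TRUE, FALSE), each = 25)
  d <- make_pairs(ifelse(lab, -8, -1), lab)
  scan <- roc_scan(d$pairs, d$estimates)
  expect_equal(scan$auc, 1)
  expect_true(all(diff(scan$scan$tpr) >= 0))
  expect_true(all(diff(scan$scan$fpr) >= 0))
  # the most permissive threshold predicts everything
  last <- tail(scan$scan, 1)
  expect_equal(last$tpr, 1); expect_equal(last$fpr, 1)

  set.seed(17)
  lab2 <- rep(c(TRUE, FALSE), each = 500)
  aucs <- replicate(5, {
    d2 <- make_pairs(rnorm(1000), lab2)
    roc_scan(d2$pairs, d2$estimates)$auc
  })
  expect_true(all(abs(aucs - 0.5) < 0.05))

  one_class <- make_pairs(rnorm(5), rep(TRUE, 5))
  expect_error(roc_scan(one_class$pairs, one_class$estimates), "both")
})

test_that("rank correlations reproduce the benchmark-table values", {
  tb <- table1_vernalis()
  recs <- data.frame(ligand_id = tb$ligand_id, potency_value = tb$kd_nM,
                     potency_units = "nM", k_off = tb$k_off)
  pf <- data.frame(ligand_id = tb$ligand_id, dg_qb = tb$dgqb_pfrosst)
  gaff <- data.frame(ligand_id = tb$ligand_id, dg_qb = tb$dgqb_gaff)

  cc <- rank_correlations(pf, recs, against = "pkd", exclude = "VER45862")
  expect_equal(cc$n, 8L)
  expect_equal(round(cc$pearson_r, 2), 0.69)
  expect_equal(round(cc$spearman_rho, 2), 0.83)

  ck <- rank_correlations(gaff, recs, against = "pkoff",
                          exclude = "VER45862")
  expect_equal(round(ck$pearson_r, 2), 0.85)
  expect_equal(round(ck$spearman_rho, 2), 0.76)

  # unit invariance: K_D in molar shifts pKd by a constant only
  recs_m <- recs
  recs_m$potency_value <- recs$potency_value * 1e-9
  recs_m$potency_units <- "M"
  cm <- rank_correlations(pf, recs_m, against = "pkd", exclude = "VER45862")
  expect_equal(cm$pearson_r, cc$pearson_r)
  expect_equal(cm$spearman_rho, cc$spearman_rho)
})

test_that("degenerate correlation inputs behave predictably", {
  est <- data.frame(ligand_id = c("a", "b", "c"), dg_qb = c(1, 2, 3))
  recs <- data.frame(ligand_id = c("a", "b", "c"),
                     potency_value = c(100, 10, 1), potency_units = "nM")
  cc <- rank_correlations(est, recs, against = "pkd")
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$spearman_rho, 1)
  expect_error(rank_correlations(est[1:2, ], recs, against = "pkd"),
               "at least 3")
})
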