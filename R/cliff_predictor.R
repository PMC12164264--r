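outcome_label <- function(actual, predicted) {
  ifelse(actual & predicted, "TP",
         ifelse(!actual & predicted, "FP",
                ifelse(actual & !predicted, "FN", "TN")))
}

#' Predict activity cliffs from quasi-bound free-energy differences
#'
#' For every pair, computes `ddg_qb = dG_QB(weak) - dG_QB(strong)`; a correct
#' cliff prediction makes the weaker binder's quasi-bound barrier much lower,
#' i.e. a strongly negative ddG_QB. A pair is predicted a cliff when
#' `ddg_qb <= threshold` (default -5 kcal/mol, the best-performing threshold
#' on the reference pair set; the boundary counts as predicted). The
#' propagated per-pair error is the sum of the two bootstrap standard
#' deviations.
#'
#' @param pairs data.frame from [build_pairs()] (needs `id_weak`,
#'   `id_strong`, `is_cliff`).
#' @param estimates data.frame with `ligand_id`, `dg_qb` and optionally `sd`
#'   columns (see [estimates_table()]); `dg_qb` may also be any other
#'   per-ligand score whose pair differences classify cliffs the same way.
#' @param threshold kcal/mol; default -5.
#' @return list with `evaluations` (the pairs plus `ddg_qb`, `error`,
#'   `predicted_cliff`, `outcome`) and `confusion` (a [confusion_matrix()]).
#' @export
evaluate_pairs <- function(pairs, estimates, threshold = -5) {
  need <- unique(c(pairs$id_weak, pairs$id_strong))
  missing <- setdiff(need, estimates$ligand_id)
  if (length(missing))
    stop("no quasi-bound estimate for ligand(s): ",
         paste(missing, collapse = ", "))
  dg <- setNames(estimates$dg_qb, estimates$ligand_id)
  sds <- if (!is.null(estimates$sd)) setNames(estimates$sd, estimates$ligand_id)
         else setNames(rep(0, nrow(estimates)), estimates$ligand_id)
  ev <- pairs
  ev$ddg_qb <- unname(dg[pairs$id_weak] - dg[pairs$id_strong])
  ev$error <- unname(sds[pairs$id_weak] + sds[pairs$id_strong])
  ev$predicted_cliff <- ev$ddg_qb <= threshold
  ev$outcome <- outcome_label(ev$is_cliff, ev$predicted_cliff)
  cm <- confusion_matrix(tp = sum(ev$outcome == "TP"),
                         fp = sum(ev$outcome == "FP"),
                         tn = sum(ev$outcome == "TN"),
                         fn = sum(ev$outcome == "FN"))
  list(evaluations = ev, confusion = cm)
}

#' Confusion matrix of a binary cliff classification
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> TP =", x$tp, " FP =", x$fp, " TN =", x$tn,
      " FN =", x$fn, "\n  MCC =", round(mcc(x), 3),
      " precision =", round(precision(x), 3), "\n")
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' confusion-matrix statistic of choice for imbalanced classification
#' (cliff pair sets run around 15% positives). When any marginal is zero the
#' denominator vanishes and 0 is returned by convention.
#'
#' @param confusion a [confusion_matrix()].
#' @return value in \[-1, 1\].
#' @export
mcc <- function(confusion) {
  tp <- as.numeric(confusion$tp); fp <- as.numeric(confusion$fp)
  tn <- as.numeric(confusion$tn); fn <- as.numeric(confusion$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  ((tp * tn) - (fp * fn)) / sqrt(den)
}

#' Precision (positive predictive value)
#'
#' @param confusion a [confusion_matrix()].
#' @return TP / (TP + FP); 0 when nothing is predicted positive.
#' @export
precision <- function(confusion) {
  if (confusion$tp + confusion$fp == 0) return(0)
  confusion$tp / (confusion$tp + confusion$fp)
}

#' Threshold scan of the ddG_QB cliff classifier
#'
#' Sweeps the decision threshold over a grid, reporting TPR, FPR and MCC per
#' threshold plus the trapezoid area under the (FPR, TPR) curve with (0,0)
#' and (1,1) anchors. The best threshold is the MCC argmax, ties broken
#' toward the most stringent (most negative) threshold.
#'
#' @param pairs data.frame from [build_pairs()]; needs at least one cliff and
#'   one noncliff pair.
#' @param estimates per-ligand score table as in [evaluate_pairs()].
#' @param thresholds numeric grid of thresholds (kcal/mol); default: all
#'   observed ddG_QB values plus outer anchors.
#' @return list with `scan` (data.frame threshold/tp/fp/tn/fn/tpr/fpr/mcc),
#'   `auc`, `best_threshold`.
#' @export
roc_scan <- function(pairs, estimates, thresholds = NULL) {
  if (!any(pairs$is_cliff) || all(pairs$is_cliff))
    stop("threshold scan needs both cliff and noncliff pairs")
  ev <- evaluate_pairs(pairs, estimates, threshold = Inf)$evaluations
  if (is.null(thresholds))
    thresholds <- sort(unique(c(ev$ddg_qb, min(ev$ddg_qb) - 1,
                                max(ev$ddg_qb) + 1)))
  thresholds <- sort(thresholds)
  pos <- sum(ev$is_cliff); neg <- sum(!ev$is_cliff)
  rows <- lapply(thresholds, function(th) {
    pred <- ev$ddg_qb <= th
    tp <- sum(pred & ev$is_cliff); fp <- sum(pred & !ev$is_cliff)
    fn <- pos - tp; tn <- neg - fp
    data.frame(threshold = th, tp = tp, fp = fp, tn = tn, fn = fn,
               tpr = tp / pos, fpr = fp / neg,
               mcc = mcc(confusion_matrix(tp, fp, tn, fn)))
  })
  scan <- do.call(rbind, rows)
  fpr <- c(0, scan$fpr, 1)
  tpr <- c(0, scan$tpr, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  best <- scan$threshold[which.max(scan$mcc)]  # first = most stringent
  list(scan = scan, auc = auc, best_threshold = best)
}

#' Rank correlations of dG_QB against affinity or kinetics
#'
#' Pearson r and Spearman rho (average ranks on ties) between per-ligand
#' quasi-bound free energies and either `pKd = -log10(K_D in molar)` or
#' `pkoff = -log10(k_off in 1/s)`. Stronger binders (higher pKd) and slower
#' dissociators (higher pkoff) are expected to show larger dG_QB.
#'
#' @param estimates data.frame with `ligand_id`, `dg_qb`.
#' @param records data.frame with `ligand_id` and, depending on `against`,
#'   potency columns (`potency_value`, `potency_units`) or `k_off`.
#' @param against `"pkd"` or `"pkoff"`.
#' @param exclude character vector of ligand ids to drop (e.g. a known
#'   outlier).
#' @return list with `pearson_r`, `spearman_rho`, `n`.
#' @export
rank_correlations <- function(estimates, records,
                              against = c("pkd", "pkoff"),
                              exclude = character()) {
  against <- match.arg(against)
  merged <- merge(estimates[, c("ligand_id", "dg_qb")], records,
                  by = "ligand_id")
  merged <- merged[!(merged$ligand_id %in% exclude), , drop = FALSE]
  y <- if (against == "pkd") {
    -log10(potency_to_molar(merged$potency_value, merged$potency_units))
  } else {
    if (is.null(merged$k_off) || anyNA(merged$k_off))
      stop("k_off missing for some ligands")
    -log10(merged$k_off)
  }
  if (nrow(merged) < 3L)
    stop("need at least 3 ligands for rank correlations, got ", nrow(merged))
  list(pearson_r = cor(merged$dg_qb, y, method = "pearson"),
       spearman_rho = cor(merged$dg_qb, y, method = "spearman"),
       n = nrow(merged))
}
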