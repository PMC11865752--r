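#' Best pose score per molecule from ensemble docking output
#'
#' Ensemble docking scores every molecule against many receptor
#' conformations; the molecule's score is the best (most negative)
#' XP GScore across conformations. Molecules with no scored pose are
#' absent from the output ("not recovered").
#'
#' @param records data frame `mol_id, conformation_id, xp_gscore`
#'   (kcal/mol, more negative = better binding).
#' @return data frame `mol_id, xp_gscore_best, n_conformations`, one row
#'   per recovered molecule.
#' @export
best_pose_scores <- function(records) {
  stopifnot(all(c("mol_id", "xp_gscore") %in% names(records)))
  if ("conformation_id" %in% names(records) &&
      anyDuplicated(records[c("mol_id", "conformation_id")])) {
    stopf("duplicate (mol_id, conformation_id) pairs")
  }
  if (any(!is.finite(records$xp_gscore))) stopf("non-finite xp_gscore")
  if (nrow(records) == 0) {
    return(data.frame(mol_id = character(0), xp_gscore_best = numeric(0),
                      n_conformations = integer(0)))
  }
  sp <- split(records$xp_gscore, records$mol_id)
  data.frame(mol_id = names(sp),
             xp_gscore_best = vapply(sp, min, numeric(1)),
             n_conformations = lengths(sp), row.names = NULL)
}

#' Ligand efficiency
#'
#' Negated docking score divided by molecular weight,
#' `LE = -score / MW`; larger is better.
#'
#' @param xp_gscore docking score (kcal/mol).
#' @param mw molecular weight (g/mol), positive.
#' @return ligand efficiency (vectorized).
#' @export
ligand_efficiency <- function(xp_gscore, mw) {
  if (any(mw <= 0)) stopf("mw must be positive")
  -xp_gscore / mw
}

#' YN1 affinity ranking within a cluster
#'
#' YN1 combines computational and experimental inhibition evidence:
#' the min-max normalized ligand efficiency plus the inverted min-max
#' normalized log10 IC50, both normalized within the cluster, so
#' YN1 lies in \[0, 2\] and reaches 2 for a molecule attaining both the
#' cluster's maximal ligand efficiency and minimal IC50. If all ligand
#' efficiencies (or all IC50s) in a cluster coincide the corresponding
#' term is defined as 0 and the result carries a `degenerate` attribute.
#'
#' @param cluster data frame with `mol_id`, `xp_gscore_best`, `mw`,
#'   `ic50_nM` for the recovered molecules of one cluster.
#' @return data frame with columns `mol_id, xp_gscore_best, mw, ic50_nM,
#'   le, le_term, ic50_term, yn1`.
#' @export
yn1 <- function(cluster) {
  stopifnot(all(c("mol_id", "xp_gscore_best", "mw", "ic50_nM") %in%
                  names(cluster)))
  if (any(cluster$ic50_nM <= 0)) stopf("ic50_nM must be positive")
  le <- ligand_efficiency(cluster$xp_gscore_best, cluster$mw)
  lic <- log10(cluster$ic50_nM)
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(structure(rep(0, length(x)), degenerate = TRUE))
    (x - rng[1]) / diff(rng)
  }
  le_term <- norm01(le)
  lic_norm <- norm01(lic)
  ic50_term <- if (isTRUE(attr(lic_norm, "degenerate"))) {
    structure(rep(0, length(lic)), degenerate = TRUE)
  } else {
    1 - lic_norm
  }
  out <- data.frame(mol_id = cluster$mol_id,
                    xp_gscore_best = cluster$xp_gscore_best,
                    mw = cluster$mw, ic50_nM = cluster$ic50_nM,
                    le = le, le_term = as.numeric(le_term),
                    ic50_term = as.numeric(ic50_term),
                    yn1 = as.numeric(le_term) + as.numeric(ic50_term))
  attr(out, "degenerate_le") <- isTRUE(attr(le_term, "degenerate"))
  attr(out, "degenerate_ic50") <- isTRUE(attr(ic50_term, "degenerate"))
  out
}

#' Ensemble phase score of one molecule
#'
#' The highest phase score a molecule obtains across all pharmacophore
#' models of an ensemble; a molecule matching no model scores 0.
#'
#' @param scores numeric phase scores of the matched models (`NA` =
#'   no match); may be empty.
#' @return the ensemble phase score.
#' @export
ensemble_phase_score <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) return(0)
  max(scores)
}

#' YN2 screening parameters
#'
#' The five parameters of YN2-based virtual screening: the minimum and
#' maximum ensemble phase score among known actives, the total numbers of
#' stable- and unstable-conformation pharmacophore models in the
#' ensemble, and (once fitted) the YN2 activity threshold.
#'
#' @param ph_min,ph_max phase-score normalization bounds
#'   (`ph_max >= ph_min`).
#' @param n_stable_total,n_unstable_total model counts (>= 1).
#' @param threshold YN2 activity threshold (NA until optimized).
#' @export
yn2_params <- function(ph_min, ph_max, n_stable_total, n_unstable_total,
                       threshold = NA_real_) {
  stopifnot(ph_max >= ph_min, n_stable_total >= 1, n_unstable_total >= 1)
  structure(list(ph_min = ph_min, ph_max = ph_max,
                 n_stable_total = as.integer(n_stable_total),
                 n_unstable_total = as.integer(n_unstable_total),
                 threshold = threshold),
            class = "yn2_params")
}

#' @export
print.yn2_params <- function(x, ...) {
  cat(sprintf(
    "YN2 params: ph in [%.4g, %.4g], %d stable + %d unstable models, threshold %s\n",
    x$ph_min, x$ph_max, x$n_stable_total, x$n_unstable_total,
    ifelse(is.na(x$threshold), "unset", format(x$threshold))))
  invisible(x)
}

#' YN2 ensemble screening metric
#'
#' The mean of three terms in \[0,1\]: the fraction of stable models
#' matched, the fraction of unstable models matched, and the ensemble
#' phase score normalized between `ph_min` and `ph_max`. A molecule whose
#' ensemble phase score falls below `ph_min` scores exactly 0. Phase
#' scores above `ph_max` (possible on novel libraries) clamp the phase
#' term at 1; a degenerate `ph_max == ph_min` defines the phase term as 1
#' for all molecules at or above `ph_min`. Both conditions set a
#' `clamped`/`degenerate_ph` attribute.
#'
#' @param ph_score ensemble phase score(s).
#' @param c_stable,c_unstable counts of matched stable/unstable models.
#' @param params a [yn2_params()].
#' @return YN2 value(s) in \[0, 1\] (vectorized).
#' @export
yn2 <- function(ph_score, c_stable, c_unstable, params) {
  stopifnot(inherits(params, "yn2_params"))
  if (any(c_stable < 0 | c_stable > params$n_stable_total) ||
      any(c_unstable < 0 | c_unstable > params$n_unstable_total)) {
    stopf("match counts outside 0..total")
  }
  degenerate <- params$ph_max == params$ph_min
  ph_hat <- if (degenerate) {
    rep(1, length(ph_score))
  } else {
    (ph_score - params$ph_min) / (params$ph_max - params$ph_min)
  }
  clamped <- ph_hat > 1
  ph_hat <- pmin(ph_hat, 1)
  out <- (c_stable / params$n_stable_total +
            c_unstable / params$n_unstable_total + ph_hat) / 3
  out[ph_score < params$ph_min] <- 0
  attr(out, "clamped") <- any(clamped)
  attr(out, "degenerate_ph") <- degenerate
  out
}

#' Optimize the YN2 activity threshold
#'
#' Candidate thresholds are the observed YN2 values (a molecule is called
#' active when its score is greater than or equal to the threshold); the
#' returned threshold maximizes recall + specificity, ties going to the
#' smallest threshold. A dense grid can be added for comparison.
#'
#' @param scores numeric YN2 values.
#' @param labels logical (TRUE = active) or a vector with levels
#'   `active`/`decoy`.
#' @param grid optional extra candidate thresholds.
#' @return list with `threshold`, `objective` (recall + specificity at
#'   the optimum) and the full `candidates` data frame.
#' @export
optimize_yn2_threshold <- function(scores, labels, grid = NULL) {
  labels <- as_active_logical(labels)
  if (!any(labels) || all(labels)) stopf("both classes must be present")
  cand <- sort(unique(c(scores, grid)))
  obj <- vapply(cand, function(th) {
    pred <- scores >= th
    recall <- mean(pred[labels])
    spec <- mean(!pred[!labels])
    recall + spec
  }, numeric(1))
  best <- which(obj == max(obj))[1]  # cand sorted: smallest threshold wins
  list(threshold = cand[best], objective = obj[best],
       candidates = data.frame(threshold = cand, objective = obj))
}

as_active_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- tolower(as.character(labels))
  if (!all(l %in% c("active", "decoy"))) {
    stopf("labels must be logical or 'active'/'decoy'")
  }
  l == "active"
}

#' ROC-AUC by rank statistic
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' statistic (ranks with ties averaged), equivalent to trapezoidal
#' integration over all score thresholds.
#'
#' @param scores numeric scores, larger = more active.
#' @param labels logical or `active`/`decoy`.
#' @return AUC in \[0,1\]; `NA` if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_active_logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at a threshold
#'
#' Confusion counts with the rule "active iff score >= threshold", plus
#' recall (sensitivity), specificity, accuracy, balanced accuracy (the
#' mean of recall and specificity) and rank-based ROC-AUC.
#'
#' @param scores numeric scores.
#' @param labels logical or `active`/`decoy` truth.
#' @param threshold decision threshold.
#' @return object of class `metric_report`.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  labels <- as_active_logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 recall = recall, specificity = specificity,
                 accuracy = (tp + tn) / length(labels),
                 bacc = mean(c(recall, specificity)),
                 roc_auc = roc_auc(scores, labels),
                 threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "TP %d FN %d TN %d FP %d | recall %.3f spec %.3f acc %.3f BACC %.3f AUC %s\n",
    x$tp, x$fn, x$tn, x$fp, x$recall, x$specificity, x$accuracy, x$bacc,
    ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc))))
  invisible(x)
}
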