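#' Split active molecules into training and test sets
#'
#' Uniform random split without replacement; the test set size is
#' `floor(n * test_fraction)` and the remainder trains.
#'
#' @param actives a `mol_library` (or data frame with `mol_id`) of active
#'   molecules.
#' @param test_fraction fraction held out for testing (default 0.2).
#' @param seed RNG seed; the same seed reproduces the same split.
#' @return list with `train` and `test` (row subsets of `actives`) and
#'   `seed`.
#' @export
split_actives <- function(actives, test_fraction = 0.2, seed) {
  n <- nrow(actives)
  if (n < 2) stopf("need at least 2 actives to split")
  n_test <- floor(n * test_fraction)
  test_idx <- with_seed(seed, sample.int(n, n_test))
  list(train = actives[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test = actives[sort(test_idx), , drop = FALSE],
       seed = seed)
}

#' Property windows for decoy matching
#'
#' Half-widths of the physicochemical windows within which a pool
#' molecule may serve as decoy for an active: molecular weight (g/mol),
#' logP, H-bond donors/acceptors, and rotatable bonds.
#'
#' @param mw,logp,hbd,hba,rotb window half-widths.
#' @param max_tanimoto structural dissimilarity cap: a decoy must have
#'   Tanimoto similarity strictly below this to every active.
#' @export
decoy_property_bins <- function(mw = 25, logp = 1, hbd = 1, hba = 1,
                                rotb = 2, max_tanimoto = 0.4) {
  structure(list(mw = mw, logp = logp, hbd = hbd, hba = hba, rotb = rotb,
                 max_tanimoto = max_tanimoto),
            class = "decoy_property_bins")
}

#' Generate property-matched decoys from a candidate pool
#'
#' A simplified, self-contained analogue of DUDE-style decoy generation:
#' for each active, up to `ratio` pool molecules are drawn that match the
#' active on binned physicochemical properties but are structurally
#' dissimilar (Tanimoto below the cap to *every* active). Each pool
#' molecule is used at most once; shortfalls are reported. Property
#' columns (`mw`, `logp`, `hbd`, `hba`, `rotb`) must be present in both
#' tables (see [compute_mol_properties()]); absent columns are skipped
#' with a warning.
#'
#' @param actives,pool `mol_library` data frames; the pool must be
#'   disjoint from the actives.
#' @param ratio decoys per active (default 50).
#' @param bins a [decoy_property_bins()].
#' @param seed RNG seed for sampling among eligible candidates.
#' @return list with `decoys` (pool rows, plus a `matched_active`
#'   column) and `shortfall` (data frame `mol_id, requested, found`).
#' @export
generate_decoys <- function(actives, pool, ratio = 50,
                            bins = decoy_property_bins(), seed = 1) {
  if (nrow(pool) == 0) stopf("empty decoy pool")
  if (any(pool$mol_id %in% actives$mol_id)) {
    stopf("pool must be disjoint from actives")
  }
  if (nrow(actives) == 0) {
    return(list(decoys = pool[0, , drop = FALSE],
                shortfall = data.frame(mol_id = character(0),
                                       requested = integer(0),
                                       found = integer(0))))
  }
  props <- c("mw", "logp", "hbd", "hba", "rotb")
  usable <- props[props %in% names(actives) & props %in% names(pool)]
  if (length(usable) < length(props)) {
    warnf("property columns missing, matching on: %s",
          paste(usable, collapse = ", "))
  }
  fp <- fingerprint_matrix(rbind_libs(actives, pool))
  sim <- tanimoto_to_actives(fp, actives$mol_id, pool$mol_id)
  dissimilar <- apply(sim, 2, max) < bins$max_tanimoto
  used <- logical(nrow(pool))
  rows <- list(); short <- list()
  for (i in seq_len(nrow(actives))) {
    ok <- !used & dissimilar
    for (p in usable) {
      ok <- ok & abs(pool[[p]] - actives[[p]][i]) <= bins[[p]]
    }
    cand <- which(ok)
    pick <- if (length(cand) > ratio) {
      sort(with_seed(seed + i, sample(cand, ratio)))
    } else {
      cand
    }
    used[pick] <- TRUE
    if (length(pick) > 0) {
      sel <- pool[pick, , drop = FALSE]
      sel$matched_active <- actives$mol_id[i]
      rows[[length(rows) + 1]] <- sel
    }
    short[[i]] <- data.frame(mol_id = actives$mol_id[i],
                             requested = ratio, found = length(pick))
  }
  decoys <- if (length(rows)) do.call(rbind, rows) else {
    cbind(pool[0, , drop = FALSE], matched_active = character(0))
  }
  rownames(decoys) <- NULL
  list(decoys = decoys, shortfall = do.call(rbind, short))
}

rbind_libs <- function(a, b) {
  cols <- intersect(names(a), names(b))
  rbind(as.data.frame(a)[cols], as.data.frame(b)[cols])
}

tanimoto_to_actives <- function(fp, active_ids, pool_ids) {
  tanimoto_matrix(fp)[active_ids, pool_ids, drop = FALSE]
}

#' Prune correlated molecular descriptors
#'
#' Constant columns are removed first (reported in the `dropped_constant`
#' attribute). Columns are min-max scaled; descriptors with absolute
#' Pearson correlation at or above `r_cut` are grouped by transitive
#' closure, and each group keeps only its member with the highest scaled
#' variance (ties go to the first in column order). Min-max scaling keeps
#' the variance comparison meaningful (standardization would force all
#' variances to 1).
#'
#' @param table numeric data frame or matrix of descriptors (an optional
#'   `mol_id` column is ignored), >= 2 rows.
#' @param r_cut correlation threshold (default 0.9, inclusive).
#' @return character vector of retained descriptor names, with
#'   attributes `dropped_constant` and `groups`.
#' @export
prune_correlated <- function(table, r_cut = 0.9) {
  m <- as.matrix(as.data.frame(table)[setdiff(colnames(table), "mol_id")])
  storage.mode(m) <- "double"
  if (nrow(m) < 2) stopf("need at least 2 rows")
  rng <- apply(m, 2, function(x) diff(range(x)))
  constant <- colnames(m)[rng == 0]
  m <- m[, rng > 0, drop = FALSE]
  if (ncol(m) < 1) stopf("no usable (non-constant) descriptors")
  scaled <- apply(m, 2, function(x) (x - min(x)) / diff(range(x)))
  v <- apply(scaled, 2, var)
  r <- abs(cor(m))
  # union-find over the |r| >= r_cut graph (transitive closure)
  parent <- seq_len(ncol(m))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(ncol(m))) for (j in seq_len(ncol(m))) {
    if (i < j && r[i, j] >= r_cut) {
      parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(ncol(m)), find, integer(1))
  keep <- vapply(split(seq_len(ncol(m)), comp), function(idx) {
    idx[order(-v[idx], idx)][1]
  }, integer(1))
  retained <- colnames(m)[sort(keep)]
  structure(retained, dropped_constant = constant,
            groups = split(colnames(m), comp))
}

#' Select a balanced decoy set by k-means clustering
#'
#' Clusters the (min-max scaled) descriptors of the decoy pool into `k`
#' groups -- `k` equal to the number of training actives -- and keeps the
#' decoy nearest each cluster centroid (Euclidean; ties to the smallest
#' `mol_id`), yielding exactly `k` distinct decoys.
#'
#' @param decoy_table data frame with `mol_id` and numeric descriptor
#'   columns.
#' @param k number of decoys to keep (= number of training actives).
#' @param seed RNG seed for k-means initialization.
#' @param retained optional descriptor subset (e.g. from
#'   [prune_correlated()]).
#' @return character vector of `k` selected decoy `mol_id`s.
#' @export
balance_decoys_kmeans <- function(decoy_table, k, seed = 1, retained = NULL) {
  ids <- decoy_table$mol_id
  cols <- retained %||% setdiff(colnames(decoy_table), "mol_id")
  m <- as.matrix(decoy_table[cols])
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (k > n) stopf("k exceeds number of decoys")
  if (k == n) return(ids)
  scaled <- apply(m, 2, function(x) {
    r <- diff(range(x)); if (r == 0) rep(0, length(x)) else (x - min(x)) / r
  })
  km <- with_seed(seed, kmeans(scaled, centers = k, nstart = 10,
                               iter.max = 50))
  picked <- vapply(seq_len(k), function(j) {
    rows <- which(km$cluster == j)
    dd <- rowSums(sweep(scaled[rows, , drop = FALSE], 2,
                        km$centers[j, ])^2)
    rows <- rows[order(dd, ids[rows])]
    ids[rows[1]]
  }, character(1))
  sort(picked)
}

# Documented, deliberately small hyperparameter grids.
ml_search_spaces <- function(d) {
  list(
    logistic_regression = data.frame(dummy = 1),
    support_vector_machine = expand.grid(cost = c(0.1, 1, 10),
                                         gamma = c(0.01, 0.1, 1)),
    decision_tree = data.frame(cp = c(0.001, 0.01, 0.1)),
    random_forest = data.frame(mtry = unique(pmax(1L, c(1L,
      floor(sqrt(d)), floor(d / 3))))))
}

fit_one <- function(algorithm, hp, x, y, seed) {
  df <- data.frame(x, .y = factor(y, levels = c(FALSE, TRUE)))
  with_seed(seed, switch(algorithm,
    logistic_regression = suppressWarnings(
      glm(.y ~ ., data = df, family = binomial())),
    support_vector_machine = e1071::svm(
      .y ~ ., data = df, kernel = "radial", cost = hp$cost,
      gamma = hp$gamma, probability = TRUE),
    decision_tree = rpart::rpart(
      .y ~ ., data = df, method = "class",
      control = rpart::rpart.control(cp = hp$cp, minsplit = 5)),
    random_forest = randomForest::randomForest(
      .y ~ ., data = df, mtry = hp$mtry, ntree = 300),
    stopf("unknown algorithm '%s'", algorithm)))
}

predict_prob <- function(algorithm, fit, x) {
  df <- data.frame(x)
  switch(algorithm,
    logistic_regression = as.numeric(
      suppressWarnings(predict(fit, newdata = df, type = "response"))),
    support_vector_machine = {
      p <- attr(predict(fit, newdata = df, probability = TRUE),
                "probabilities")
      as.numeric(p[, "TRUE"])
    },
    decision_tree = as.numeric(
      predict(fit, newdata = df, type = "prob")[, "TRUE"]),
    random_forest = as.numeric(
      predict(fit, newdata = df, type = "prob")[, "TRUE"]))
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Train the four family classifiers
#'
#' Trains logistic regression, a radial-kernel support vector machine, a
#' decision tree, and a random forest on a balanced active/decoy
#' descriptor table. Hyperparameters are searched over small documented
#' grids by stratified `cv_folds`-fold cross-validation maximizing mean
#' ROC-AUC; the winning configuration is refit on the full table.
#'
#' @param table data frame with `mol_id`, a `label` column
#'   (`active`/`decoy` or logical), and numeric descriptors.
#' @param cv_folds folds for cross-validation (default 5).
#' @param seed RNG seed controlling folds and stochastic fits.
#' @param retained optional descriptor subset to use.
#' @return list of four objects of class `screen_model`, named by
#'   algorithm; each carries `algorithm`, `fit`, `hyperparameters`,
#'   `retained_descriptors`, `cv_metrics` (a [classification_metrics()]
#'   report on pooled out-of-fold predictions) and `seed`.
#' @export
train_models <- function(table, cv_folds = 5, seed = 1, retained = NULL) {
  y <- as_active_logical(table$label)
  if (!any(y) || all(y)) stopf("both classes must be present")
  if (min(sum(y), sum(!y)) < cv_folds) {
    stopf("fewer members of a class than folds; cannot stratify")
  }
  cols <- retained %||% setdiff(colnames(table), c("mol_id", "label"))
  x <- as.matrix(table[cols]); storage.mode(x) <- "double"
  fold <- stratified_folds(y, cv_folds, seed)
  spaces <- ml_search_spaces(ncol(x))
  models <- list()
  for (alg in names(spaces)) {
    grid <- spaces[[alg]]
    cv_auc <- numeric(nrow(grid))
    oof <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
      p <- rep(NA_real_, length(y))
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        fit <- fit_one(alg, grid[g, , drop = FALSE], x[tr, , drop = FALSE],
                       y[tr], seed + f)
        p[!tr] <- predict_prob(alg, fit, x[!tr, , drop = FALSE])
      }
      cv_auc[g] <- roc_auc(p, y)
      oof[[g]] <- p
    }
    best <- which.max(cv_auc)
    fit <- fit_one(alg, grid[best, , drop = FALSE], x, y, seed)
    models[[alg]] <- structure(
      list(algorithm = alg, fit = fit,
           hyperparameters = as.list(grid[best, , drop = FALSE]),
           retained_descriptors = cols,
           cv_metrics = classification_metrics(oof[[best]], y, 0.5),
           seed = seed),
      class = "screen_model")
  }
  models
}

#' @export
print.screen_model <- function(x, ...) {
  cat(sprintf("screen_model [%s], %d descriptors, CV AUC %.3f\n",
              x$algorithm, length(x$retained_descriptors),
              x$cv_metrics$roc_auc))
  invisible(x)
}

#' Predict activity probabilities with a trained family classifier
#' @param object a `screen_model`.
#' @param newdata data frame containing the model's retained descriptors.
#' @param ... unused.
#' @return numeric vector of active-class probabilities.
#' @export
predict.screen_model <- function(object, newdata, ...) {
  missing <- setdiff(object$retained_descriptors, colnames(newdata))
  if (length(missing)) {
    stopf("missing descriptors: %s", paste(missing, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(newdata)[object$retained_descriptors])
  storage.mode(x) <- "double"
  predict_prob(object$algorithm, object$fit, x)
}

#' Evaluate trained classifiers on an unbalanced test table
#'
#' @param models list of `screen_model`s (from [train_models()]).
#' @param test_table data frame with `mol_id`, `label`, and the retained
#'   descriptors.
#' @param threshold probability threshold for the active call
#'   (default 0.5).
#' @return named list of [classification_metrics()] reports.
#' @export
evaluate_models <- function(models, test_table, threshold = 0.5) {
  y <- as_active_logical(test_table$label)
  lapply(models, function(m) {
    classification_metrics(predict(m, test_table), y, threshold)
  })
}

#' Select the deployment model by the four-term objective
#'
#' The objective is the unweighted sum of four \[0,1\] terms per
#' candidate: test specificity, the true-negative fraction on the decoys
#' excluded when balancing the training set, the recall of family
#' actives, and the rejection rate of non-family binders. Ties are broken
#' by the fixed preference random forest > support vector machine >
#' logistic regression > decision tree.
#'
#' @param models named list of `screen_model`s.
#' @param terms data frame with one row per model (matched by the
#'   `algorithm` column) and columns `specificity`,
#'   `tn_fraction_excluded`, `family_recall`, `nonfamily_rejection`.
#' @return the selected `screen_model`, with the objective value in
#'   attribute `objective` and the full scored table in attribute
#'   `scores`.
#' @export
select_model <- function(models, terms) {
  need <- c("specificity", "tn_fraction_excluded", "family_recall",
            "nonfamily_rejection")
  if (!all(need %in% names(terms))) {
    stopf("terms must contain: %s", paste(need, collapse = ", "))
  }
  if (any(is.na(terms[need]))) stopf("missing objective term")
  if (any(terms[need] < 0 | terms[need] > 1)) {
    stopf("objective terms must lie in [0, 1]")
  }
  pref <- c(random_forest = 1, support_vector_machine = 2,
            logistic_regression = 3, decision_tree = 4)
  terms$objective <- rowSums(terms[need])
  ord <- order(-terms$objective, pref[terms$algorithm])
  winner <- terms$algorithm[ord[1]]
  out <- models[[winner]]
  attr(out, "objective") <- terms$objective[ord[1]]
  attr(out, "scores") <- terms
  out
}

#' Save / load a trained model artifact
#'
#' The artifact embeds the fitted model, its retained descriptor list,
#' hyperparameters and seed, plus a format version for compatibility
#' checks on reload.
#'
#' @param model a `screen_model`.
#' @param path artifact file path (RDS).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "achescreen-model-1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "achescreen-model-1")) {
    stopf("incompatible model artifact at '%s'", path)
  }
  obj$model
}
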