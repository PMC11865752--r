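test_that("active split uses floor() sizing and is seed-deterministic", {
  actives <- data.frame(mol_id = sprintf("a%03d", 1:58))
  sp <- split_actives(actives, 0.2, seed = 5)
  expect_equal(nrow(sp$test), 11)   # floor(58 * 0.2)
  expect_equal(nrow(sp$train), 47)
  expect_length(intersect(sp$train$mol_id, sp$test$mol_id), 0)
  sp10 <- split_actives(data.frame(mol_id = sprintf("a%d", 1:10)), 0.2, 3)
  expect_equal(nrow(sp10$test), 2)
  expect_equal(nrow(sp10$train), 8)
  sp2 <- split_actives(actives, 0.2, seed = 5)
  expect_identical(sp$test$mol_id, sp2$test$mol_id)
  expect_error(split_actives(actives[1, , drop = FALSE], 0.2, 1), "at least 2")
})

test_that("decoy generation respects property bins and dissimilarity", {
  g <- gen_library(4, 10, seed = 41)
  lib <- g$library
  act <- lib[g$truth$family == 1, ]
  pool <- lib[g$truth$family != 1, ]
  out <- generate_decoys(act, pool, ratio = 3, seed = 7)
  expect_gt(nrow(out$decoys), 0)
  # constraint-check oracle: every decoy inside every bin, dissimilar to
  # every active
  bins <- decoy_property_bins()
  for (i in seq_len(nrow(out$decoys))) {
    d <- out$decoys[i, ]
    a <- act[act$mol_id == d$matched_active, ]
    expect_lte(abs(d$mw - a$mw), bins$mw)
    expect_lte(abs(d$logp - a$logp), bins$logp)
    expect_lte(abs(d$hbd - a$hbd), bins$hbd)
    expect_lte(abs(d$hba - a$hba), bins$hba)
    expect_lte(abs(d$rotb - a$rotb), bins$rotb)
  }
  fp <- fingerprint_matrix(rbind_pool <- rbind(
    act[c("mol_id", "smiles")], pool[c("mol_id", "smiles")]))
  sim <- tanimoto_matrix(fp)[act$mol_id, out$decoys$mol_id, drop = FALSE]
  expect_lt(max(sim), bins$max_tanimoto)
  # no decoy used twice; shortfalls reported consistently
  expect_false(anyDuplicated(out$decoys$mol_id) > 0)
  expect_equal(sum(out$shortfall$found), nrow(out$decoys))
  # zero actives -> zero decoys
  expect_equal(nrow(generate_decoys(act[0, ], pool, seed = 1)$decoys), 0)
  expect_error(generate_decoys(act, pool[0, ], seed = 1), "empty")
  expect_error(generate_decoys(act, act, seed = 1), "disjoint")
})

test_that("correlation pruning keeps the highest-variance representative", {
  set.seed(12)
  x <- data.frame(a = rnorm(50))
  x$b <- 2 * x$a          # perfectly correlated, same scaled variance
  x$y <- rnorm(50)
  kept <- prune_correlated(x)
  expect_equal(sort(kept), c("a", "y"))  # tie -> first column order
  # duplicated column: one copy kept
  d <- data.frame(u = rnorm(30)); d$v <- d$u; d$w <- rnorm(30)
  expect_equal(sort(prune_correlated(d)), c("u", "w"))
  # pair with r = 0.85 is below the cut: both kept
  set.seed(13)
  repeat {
    p <- rnorm(200); q <- 0.85 * scale(p) + sqrt(1 - 0.85^2) * rnorm(200)
    if (abs(abs(cor(p, q)) - 0.85) < 0.02 && abs(cor(p, q)) < 0.9) break
  }
  expect_length(prune_correlated(data.frame(p = p, q = as.numeric(q))), 2)
  # constant columns dropped and flagged
  cc <- data.frame(k = rep(1, 20), z = rnorm(20), z2 = rnorm(20))
  kept2 <- prune_correlated(cc)
  expect_equal(attr(kept2, "dropped_constant"), "k")
  # invariant: no retained pair at or above the cut
  set.seed(15)
  big <- as.data.frame(matrix(rnorm(40 * 8), 40))
  big$V9 <- big$V1 + rnorm(40, sd = 0.01)
  big$V10 <- -big$V2 + rnorm(40, sd = 0.01)
  kept3 <- prune_correlated(big)
  r <- abs(cor(big[kept3]))
  expect_true(all(r[upper.tri(r)] < 0.9))
})

test_that("k-means decoy balancing returns k distinct medoid-like decoys", {
  # two planted descriptor blobs -> one decoy per blob, near its center
  set.seed(20)
  dt <- data.frame(mol_id = sprintf("d%02d", 1:20),
                   f1 = c(rnorm(10, 0, 0.05), rnorm(10, 5, 0.05)),
                   f2 = c(rnorm(10, 0, 0.05), rnorm(10, -3, 0.05)))
  sel <- balance_decoys_kmeans(dt, 2, seed = 2)
  expect_length(sel, 2)
  expect_true(any(sel %in% dt$mol_id[1:10]) && any(sel %in% dt$mol_id[11:20]))
  # k = n returns everything; k > n rejected
  expect_equal(sort(balance_decoys_kmeans(dt, 20, seed = 1)), sort(dt$mol_id))
  expect_error(balance_decoys_kmeans(dt, 21, seed = 1), "exceeds")
  # contract: always exactly k distinct ids
  for (k in c(3, 7, 12)) {
    s <- balance_decoys_kmeans(dt, k, seed = 3)
    expect_length(unique(s), k)
  }
})

test_that("planted exemplars are recovered in nearly all replicates", {
  hits <- 0
  for (s in 1:40) {
    set.seed(1000 + s)
    centers <- matrix(c(0, 0, 6, 0, 3, 5), 3, 2, byrow = TRUE)
    dt <- data.frame(mol_id = sprintf("d%02d", 1:30),
                     f1 = rep(centers[, 1], each = 10) + rnorm(30, sd = 0.1),
                     f2 = rep(centers[, 2], each = 10) + rnorm(30, sd = 0.1))
    sel <- balance_decoys_kmeans(dt, 3, seed = s)
    blob <- rep(1:3, each = 10)
    got <- sort(blob[match(sel, dt$mol_id)])
    if (identical(got, 1:3)) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("the four classifiers separate a clean benchmark and are reproducible", {
  set.seed(77)
  n <- 60
  tab <- data.frame(mol_id = sprintf("m%02d", 1:n),
                    label = rep(c("active", "decoy"), each = n / 2),
                    d1 = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
                    d2 = c(rnorm(n / 2, -2), rnorm(n / 2, 2)),
                    d3 = rnorm(n))
  models <- train_models(tab, cv_folds = 5, seed = 9)
  expect_setequal(names(models),
                  c("logistic_regression", "support_vector_machine",
                    "decision_tree", "random_forest"))
  set.seed(78)
  test_tab <- data.frame(mol_id = sprintf("t%03d", 1:200),
                         label = rep(c("active", "decoy"), each = 100),
                         d1 = c(rnorm(100, 3), rnorm(100, -3)),
                         d2 = c(rnorm(100, -2), rnorm(100, 2)),
                         d3 = rnorm(200))
  ev <- evaluate_models(models, test_tab)
  for (m in names(models)) {
    expect_gte(ev[[m]]$roc_auc, 0.99)
  }
  # determinism: same seed -> same hyperparameters and CV metrics
  models2 <- train_models(tab, cv_folds = 5, seed = 9)
  expect_identical(lapply(models, `[[`, "hyperparameters"),
                   lapply(models2, `[[`, "hyperparameters"))
  expect_equal(sapply(models, function(m) m$cv_metrics$roc_auc),
               sapply(models2, function(m) m$cv_metrics$roc_auc))
  expect_error(train_models(tab[tab$label == "decoy", ], seed = 1), "classes")
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  aucs <- sapply(1:8, function(s) {
    set.seed(200 + s)
    n <- 60
    tab <- data.frame(mol_id = sprintf("m%02d", 1:n),
                      label = sample(rep(c("active", "decoy"), each = n / 2)),
                      d1 = rnorm(n), d2 = rnorm(n))
    m <- train_models(tab, cv_folds = 5, seed = s)
    m$logistic_regression$cv_metrics$roc_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("evaluation matches an independent confusion recomputation", {
  set.seed(55)
  n <- 40
  tab <- data.frame(mol_id = sprintf("m%02d", 1:n),
                    label = rep(c("active", "decoy"), each = n / 2),
                    d1 = c(rnorm(n / 2, 2), rnorm(n / 2, -2)),
                    d2 = rnorm(n))
  models <- train_models(tab, cv_folds = 5, seed = 4)
  ev <- evaluate_models(models, tab)
  for (alg in names(models)) {
    p <- predict(models[[alg]], tab)
    lab <- tab$label == "active"
    expect_equal(ev[[alg]]$tp, sum(p >= 0.5 & lab))
    expect_equal(ev[[alg]]$tn, sum(p < 0.5 & !lab))
    expect_equal(ev[[alg]]$recall,
                 sum(p >= 0.5 & lab) / sum(lab))
  }
  expect_error(predict(models[[1]], tab[, 1:2]), "missing descriptors")
})

test_that("model selection maximizes the four-term objective with tie order", {
  models <- setNames(lapply(c("logistic_regression",
                              "support_vector_machine", "decision_tree",
                              "random_forest"), function(a)
    structure(list(algorithm = a), class = "screen_model")),
    c("logistic_regression", "support_vector_machine", "decision_tree",
      "random_forest"))
  terms <- data.frame(
    algorithm = names(models),
    specificity = c(0.8, 0.9, 0.7, 0.8),
    tn_fraction_excluded = c(0.8, 0.9, 0.7, 0.8),
    family_recall = c(0.8, 0.85, 0.75, 0.75),
    nonfamily_rejection = c(0.8, 0.85, 0.75, 0.75))
  sel <- select_model(models, terms)   # sums: 3.2, 3.5, 2.9, 3.1
  expect_equal(sel$algorithm, "support_vector_machine")
  expect_equal(attr(sel, "objective"), 3.5)
  # exact tie -> random forest preferred
  terms2 <- terms
  terms2[c("specificity", "tn_fraction_excluded", "family_recall",
           "nonfamily_rejection")] <- 0.5
  expect_equal(select_model(models, terms2)$algorithm, "random_forest")
  # single candidate is returned as-is
  expect_equal(select_model(models[2], terms[2, ])$algorithm,
               "support_vector_machine")
  terms3 <- terms; terms3$specificity[1] <- NA
  expect_error(select_model(models, terms3), "missing")
})

test_that("model artifacts round-trip with version checking", {
  set.seed(66)
  tab <- data.frame(mol_id = sprintf("m%02d", 1:30),
                    label = rep(c("active", "decoy"), each = 15),
                    d1 = c(rnorm(15, 2), rnorm(15, -2)), d2 = rnorm(30))
  m <- train_models(tab, cv_folds = 5, seed = 2)$random_forest
  tmp <- tempfile(fileext = ".rds")
  save_model(m, tmp)
  m2 <- load_model(tmp)
  expect_equal(predict(m2, tab), predict(m, tab))
  expect_equal(m2$retained_descriptors, m$retained_descriptors)
  saveRDS(list(format = "other"), tmp)
  expect_error(load_model(tmp), "incompatible")
})
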