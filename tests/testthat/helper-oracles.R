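# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths.

# Tanimoto from explicit bit index sets.
oracle_tanimoto <- function(bits_a, bits_b) {
  if (length(bits_a) == 0 && length(bits_b) == 0) return(1)
  length(intersect(bits_a, bits_b)) / length(union(bits_a, bits_b))
}

# Naive O(n^3) unweighted average-linkage agglomeration on a distance
# matrix; returns the sequence of merge heights.
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# ROC-AUC as the Mann-Whitney pair statistic (ties count 1/2).
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive recall+specificity threshold search over observed values.
oracle_best_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  obj <- sapply(cand, function(th) {
    mean(scores[labels] >= th) + mean(scores[!labels] < th)
  })
  list(threshold = cand[which(obj == max(obj))[1]], objective = max(obj))
}

# Independent step-by-step greedy maximin reimplementation.
oracle_greedy_maximin <- function(d, n_keep) {
  m <- nrow(d)
  best <- c(NA, NA); bh <- -Inf
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    if (d[i, j] > bh + 1e-12) { bh <- d[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_keep) {
    cand <- setdiff(1:m, sel)
    md <- sapply(cand, function(i) min(d[i, sel]))
    sel <- c(sel, cand[which(md == max(md))[1]])
  }
  as.integer(sel[seq_len(n_keep)])
}

# Minimum pairwise distance of a subset.
subset_min_dist <- function(d, idx) {
  if (length(idx) < 2) return(Inf)
  min(d[idx, idx][upper.tri(d[idx, idx])])
}

# Block similarity matrix with two planted blobs.
blob_similarity <- function(sizes, within = 0.9, between = 0.1,
                            jitter = 0.02, seed = 1) {
  n <- sum(sizes)
  fam <- rep(seq_along(sizes), sizes)
  set.seed(seed)
  s <- ifelse(outer(fam, fam, "=="), within, between) +
    matrix(runif(n * n, -jitter, jitter), n)
  s <- (s + t(s)) / 2
  s[s < 0] <- 0; s[s > 1] <- 1
  diag(s) <- 1
  dimnames(s) <- list(sprintf("b%02d", 1:n), sprintf("b%02d", 1:n))
  list(sim = s, family = fam)
}

# Adjusted Rand index between two partitions.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab))); sum_b <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Tiny two-family SMILES library (no RNG) for chemistry tests.
tiny_library <- function() {
  mol_library(
    mol_id = c("naph_me", "naph_et", "naph_oh", "thio_me", "thio_et",
               "thio_oh"),
    smiles = c("c1ccc2cc(C)ccc2c1", "c1ccc2cc(CC)ccc2c1",
               "c1ccc2cc(O)ccc2c1", "c1ccc2sc(C)cc2c1",
               "c1ccc2sc(CC)cc2c1", "c1ccc2sc(O)cc2c1"),
    ic50_nM = c(100, 200, 300, 5000, 8000, 11000),
    mw = c(142.2, 156.2, 144.2, 148.2, 162.3, 150.2))
}
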