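#' Average-linkage hierarchical clustering of a similarity matrix
#'
#' Agglomerative clustering on distance = 1 - similarity with unweighted
#' average linkage (UPGMA), cut at `k` clusters. Merge heights are
#' non-decreasing by construction.
#'
#' @param sim symmetric similarity matrix in \[0,1\] with `mol_id`
#'   dimnames (see [fingerprint_similarity()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @return object of class `inhibitor_clustering`: list with `assignment`
#'   (named character vector mol_id -> cluster id `"C<j>"`), `k`, `hc`
#'   (the `hclust` tree) and `dist` (the distance object).
#' @export
average_linkage_cluster <- function(sim, k) {
  n <- nrow(sim)
  if (is.null(rownames(sim))) stopf("sim needs mol_id dimnames")
  if (k < 1 || k > n) stopf("k must be in 1..%d", n)
  d <- as.dist(1 - sim)
  hc <- hclust(d, method = "average")
  cut <- cutree(hc, k = k)
  structure(list(assignment = setNames(paste0("C", cut), names(cut)),
                 k = k, hc = hc, dist = d),
            class = "inhibitor_clustering")
}

#' @export
print.inhibitor_clustering <- function(x, ...) {
  cat(sprintf("Average-linkage clustering: %d molecules in %d clusters\n",
              length(x$assignment), x$k))
  print(table(x$assignment))
  invisible(x)
}

#' Kelley penalty profile for cluster-count selection
#'
#' For each candidate cut level `k`, the average spread is the mean over
#' all clusters with more than one member of their mean within-cluster
#' pairwise distance. Spreads are linearly rescaled across levels onto
#' \[1, n-1\] and the penalty is the rescaled spread plus `k`; the
#' returned optimum is the smallest `k` attaining the minimum penalty.
#' Levels where no cluster has more than one member have undefined spread
#' and are excluded from the rescaling (reported as `NA`).
#'
#' @param clustering an `inhibitor_clustering` (the cut level `k` used to
#'   build it is irrelevant; the full merge tree is consulted).
#' @param k_range integer vector of candidate cluster counts within
#'   `2..(n-1)` (default the whole range).
#' @return object of class `kelley_profile`: data frame with columns `k`,
#'   `spread`, `rescaled`, `penalty`, and attribute `k_opt`.
#' @export
kelley_penalty <- function(clustering, k_range = NULL) {
  hc <- clustering$hc
  dmat <- as.matrix(clustering$dist)
  n <- nrow(dmat)
  if (is.null(k_range)) k_range <- 2:(n - 1)
  if (any(k_range < 2 | k_range > n - 1)) stopf("k_range must lie in [2, n-1]")
  spread <- vapply(k_range, function(k) {
    cut <- cutree(hc, k = k)
    per <- vapply(split(names(cut), cut), function(members) {
      if (length(members) < 2) return(NA_real_)
      sub <- dmat[members, members]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
  }, numeric(1))
  ok <- !is.na(spread)
  rescaled <- rep(NA_real_, length(spread))
  if (any(ok)) {
    rng <- range(spread[ok])
    rescaled[ok] <- if (diff(rng) == 0) {
      1
    } else {
      (spread[ok] - rng[1]) / diff(rng) * (n - 2) + 1
    }
  }
  penalty <- rescaled + k_range
  prof <- data.frame(k = k_range, spread = spread,
                     rescaled = rescaled, penalty = penalty)
  k_opt <- if (any(ok)) k_range[which.min(penalty)] else NA_integer_
  structure(prof, k_opt = k_opt, class = c("kelley_profile", "data.frame"))
}

#' @export
print.kelley_profile <- function(x, ...) {
  cat(sprintf("Kelley penalty profile over k = %d..%d; optimum k = %d\n",
              min(x$k), max(x$k), attr(x, "k_opt")))
  NextMethod()
}

#' Per-cluster IC50 statistics
#'
#' Mean, sample standard deviation (n-1 denominator; 0 for singletons,
#' flagged), coefficient of variation (sd/mean) and size for each cluster.
#'
#' @param clustering an `inhibitor_clustering`, or a named character
#'   vector mol_id -> cluster id.
#' @param lib a `mol_library` with `ic50_nM` for every clustered molecule.
#' @return data frame `cluster_id, mean_ic50, sd_ic50, cv_ic50, size,
#'   singleton`.
#' @export
cluster_stats <- function(clustering, lib) {
  assignment <- if (inherits(clustering, "inhibitor_clustering")) {
    clustering$assignment
  } else {
    clustering
  }
  if (is.null(lib$ic50_nM)) stopf("missing ic50_nM column in library")
  ic50 <- setNames(lib$ic50_nM, lib$mol_id)[names(assignment)]
  if (any(is.na(ic50))) {
    stopf("missing ic50_nM for: %s",
          paste(names(assignment)[is.na(ic50)], collapse = ", "))
  }
  out <- do.call(rbind, lapply(split(ic50, assignment), function(v) {
    m <- mean(v)
    s <- if (length(v) > 1) sd(v) else 0
    data.frame(mean_ic50 = m, sd_ic50 = s,
               cv_ic50 = if (m > 0) s / m else NA_real_,
               size = length(v), singleton = length(v) == 1)
  }))
  data.frame(cluster_id = rownames(out), out, row.names = NULL)
}

#' Cluster retention criteria
#'
#' The four family-selection criteria applied to cluster IC50 statistics,
#' all strict inequalities: mean IC50 below `max_mean_ic50`, IC50
#' standard deviation under `max_sd_ic50`, population exceeding
#' `min_size`, and coefficient of variation less than `max_cv`. A cluster
#' is retained when it meets at least `min_criteria_met` of the four.
#'
#' @param max_mean_ic50 nM, default 10000.
#' @param max_sd_ic50 nM, default 14900.
#' @param min_size molecules (strict >), default 58.
#' @param max_cv dimensionless, default 1.7.
#' @param min_criteria_met 1..4, default 3.
#' @return a `cluster_filter_criteria` list.
#' @export
cluster_filter_criteria <- function(max_mean_ic50 = 10000,
                                    max_sd_ic50 = 14900,
                                    min_size = 58, max_cv = 1.7,
                                    min_criteria_met = 3) {
  stopifnot(max_mean_ic50 > 0, max_sd_ic50 > 0, min_size > 0, max_cv > 0,
            min_criteria_met %in% 1:4)
  structure(list(max_mean_ic50 = max_mean_ic50, max_sd_ic50 = max_sd_ic50,
                 min_size = min_size, max_cv = max_cv,
                 min_criteria_met = min_criteria_met),
            class = "cluster_filter_criteria")
}

#' Filter clusters on the four IC50 criteria
#'
#' @param stats data frame from [cluster_stats()].
#' @param criteria a [cluster_filter_criteria()].
#' @return `stats` augmented with logical columns `crit_mean`, `crit_sd`,
#'   `crit_size`, `crit_cv`, integer `criteria_met`, logical `all_four`
#'   and `retained`. Row order is preserved.
#' @export
filter_clusters <- function(stats, criteria = cluster_filter_criteria()) {
  if (nrow(stats) == 0) stopf("empty cluster stats")
  out <- stats
  out$crit_mean <- stats$mean_ic50 < criteria$max_mean_ic50
  out$crit_sd <- stats$sd_ic50 < criteria$max_sd_ic50
  out$crit_size <- stats$size > criteria$min_size
  out$crit_cv <- stats$cv_ic50 < criteria$max_cv
  out$criteria_met <- out$crit_mean + out$crit_sd + out$crit_size + out$crit_cv
  out$all_four <- out$criteria_met == 4L
  out$retained <- out$criteria_met >= criteria$min_criteria_met
  out
}

#' Representative (centroid) molecule of each cluster
#'
#' The representative of a cluster is the member minimizing the mean
#' distance (1 - similarity) to all other members; ties go to the
#' lexicographically smallest `mol_id`; a singleton represents itself.
#'
#' @param clustering an `inhibitor_clustering` or named assignment vector.
#' @param sim similarity matrix covering all clustered molecules.
#' @return named character vector cluster_id -> representative mol_id.
#' @export
cluster_centroid <- function(clustering, sim) {
  assignment <- if (inherits(clustering, "inhibitor_clustering")) {
    clustering$assignment
  } else {
    clustering
  }
  if (!all(names(assignment) %in% rownames(sim))) {
    stopf("assignment contains molecules absent from sim")
  }
  groups <- split(names(assignment), assignment)
  reps <- vapply(groups, function(members) {
    if (length(members) == 0) stopf("empty cluster")
    if (length(members) == 1) return(members)
    d <- 1 - sim[members, members]
    meandist <- rowSums(d) / (length(members) - 1)
    members <- members[order(meandist, members)]
    members[1]
  }, character(1))
  reps
}

#' Write cluster assignment and filtered statistics to CSV
#' @param clustering an `inhibitor_clustering`.
#' @param stats output of [filter_clusters()] (optional).
#' @param assignment_path,stats_path output files (NULL to skip).
#' @export
write_cluster_output <- function(clustering, stats = NULL,
                                 assignment_path = NULL, stats_path = NULL) {
  if (!is.null(assignment_path)) {
    utils::write.csv(data.frame(mol_id = names(clustering$assignment),
                                cluster_id = unname(clustering$assignment)),
                     assignment_path, row.names = FALSE)
  }
  if (!is.null(stats_path) && !is.null(stats)) {
    cols <- c("cluster_id", "mean_ic50", "sd_ic50", "cv_ic50", "size",
              "criteria_met", "all_four")
    utils::write.csv(stats[intersect(cols, names(stats))], stats_path,
                     row.names = FALSE)
  }
  invisible(NULL)
}
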