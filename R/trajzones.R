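#' Construct an RMSD trace
#'
#' A per-frame deviation time series from one trajectory: integer frame
#' indices from 0, strictly increasing times in ns, and non-negative RMSD
#' values in Angstrom.
#'
#' @param values numeric RMSD values (Angstrom).
#' @param times numeric times (ns); defaults to 0.01 ns per frame.
#' @param frames integer frame indices; defaults to `0:(n-1)`.
#' @return object of class `rmsd_trace` (a data frame `frame, time_ns,
#'   value`).
#' @export
rmsd_trace <- function(values, times = NULL, frames = NULL) {
  n <- length(values)
  if (n == 0) stopf("empty trace")
  if (any(values < 0)) stopf("RMSD values must be >= 0")
  frames <- frames %||% (0:(n - 1))
  times <- times %||% (frames * 0.01)
  if (length(times) != n || length(frames) != n) stopf("length mismatch")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  structure(data.frame(frame = as.integer(frames), time_ns = times,
                       value = values),
            class = c("rmsd_trace", "data.frame"))
}

#' Read an RMSD trace from the CSV contract `frame,time_ns,value`
#' @param path CSV file.
#' @export
read_rmsd_trace <- function(path) {
  df <- read.csv(path)
  rmsd_trace(df$value, times = df$time_ns, frames = df$frame)
}

#' Statistical extraction of seven frames from an RMSD trace
#'
#' Selects, in fixed order, the frames nearest to the mean RMSD, the mean
#' minus and plus twice the (sample) standard deviation, then the two
#' lowest and the two highest RMSD values. Each selector takes the
#' best-matching frame not yet taken, with ties broken by the earliest
#' frame, so exactly seven distinct frames are always returned.
#'
#' @param trace an `rmsd_trace` (or numeric vector of RMSD values).
#' @return integer vector of 7 distinct frame indices, in selector order.
#' @export
extract_statistical_frames <- function(trace) {
  values <- if (inherits(trace, "rmsd_trace")) trace$value else trace
  frames <- if (inherits(trace, "rmsd_trace")) trace$frame else
    seq_along(values) - 1L
  n <- length(values)
  if (n < 7) stopf("trace must have at least 7 frames")
  m <- mean(values)
  s <- sd(values)
  taken <- logical(n)
  take_nearest <- function(target) {
    cand <- which(!taken)
    cand <- cand[order(abs(values[cand] - target), cand)]
    taken[cand[1]] <<- TRUE
    cand[1]
  }
  take_rank <- function(decreasing) {
    cand <- which(!taken)
    cand <- cand[order(if (decreasing) -values[cand] else values[cand], cand)]
    taken[cand[1]] <<- TRUE
    cand[1]
  }
  idx <- c(take_nearest(m), take_nearest(m - 2 * s), take_nearest(m + 2 * s),
           take_rank(FALSE), take_rank(FALSE),
           take_rank(TRUE), take_rank(TRUE))
  frames[idx]
}

#' Pairwise RMSD between two coordinate sets
#'
#' Root-mean-square deviation between matched atoms; with
#' `superpose = TRUE` the optimal rigid-body superposition (Kabsch,
#' centroid translation + SVD rotation) is applied first.
#'
#' @param a,b n x 3 coordinate matrices (Angstrom) with matching rownames
#'   (atom labels), or data frames `label,x,y,z`.
#' @param superpose apply optimal rigid superposition first.
#' @return RMSD in Angstrom.
#' @export
pairwise_rmsd <- function(a, b, superpose = FALSE) {
  a <- as_coords(a); b <- as_coords(b)
  if (nrow(a) != nrow(b)) stopf("coordinate sets differ in atom count")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stopf("atom label mismatch")
  }
  if (superpose) {
    ac <- scale(a, scale = FALSE)
    bc <- scale(b, scale = FALSE)
    s <- svd(t(ac) %*% bc)
    d <- sign(det(s$v %*% t(s$u)))
    rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    a <- ac %*% t(rot)
    b <- bc
  }
  sqrt(mean(rowSums((a - b)^2)))
}

as_coords <- function(x) {
  if (is.data.frame(x)) {
    m <- as.matrix(x[, c("x", "y", "z")])
    rownames(m) <- if ("label" %in% names(x)) as.character(x$label) else NULL
    return(m)
  }
  stopifnot(is.matrix(x), ncol(x) == 3)
  x
}

#' Read coordinates from a CSV `label,x,y,z` or a PDB file
#' @param path input file; PDB is inferred from the `.pdb` extension.
#' @return n x 3 coordinate matrix with atom-label rownames.
#' @export
read_coordinates <- function(path) {
  if (tolower(tools::file_ext(path)) == "pdb") {
    lines <- readLines(path)
    lines <- lines[grepl("^(ATOM|HETATM)", lines)]
    m <- cbind(x = as.numeric(substr(lines, 31, 38)),
               y = as.numeric(substr(lines, 39, 46)),
               z = as.numeric(substr(lines, 47, 54)))
    rownames(m) <- trimws(substr(lines, 13, 16))
    return(m)
  }
  as_coords(read.csv(path))
}

#' Greedy maximin diversity selection
#'
#' Seeds with the globally most distant pair, then repeatedly adds the
#' item whose minimum distance to the already-chosen set is largest.
#' Ties take the smallest index. Used to reduce the 7 statistical
#' conformations per trajectory to the 5 most diverse.
#'
#' @param d symmetric distance matrix over m items.
#' @param n_keep number of items to select (`<= m`).
#' @return integer vector of `n_keep` 1-based item indices in selection
#'   order.
#' @export
diversity_select <- function(d, n_keep) {
  d <- as.matrix(d)
  m <- nrow(d)
  if (n_keep > m) stopf("n_keep exceeds number of items")
  if (n_keep < 1) stopf("n_keep must be >= 1")
  if (m == 1 || n_keep == 1) return(1L)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- pairs[order(-d[upper.tri(d)], pairs[, 1], pairs[, 2]), ,
                 drop = FALSE]
  sel <- as.integer(pairs[1, c(1, 2)])
  while (length(sel) < n_keep) {
    cand <- setdiff(seq_len(m), sel)
    mind <- vapply(cand, function(i) min(d[i, sel]), numeric(1))
    sel <- c(sel, cand[order(-mind, cand)][1])
  }
  sel[seq_len(n_keep)]
}

#' Rank residues by RMSF
#'
#' @param rmsf named numeric vector residue -> RMSF (Angstrom); names are
#'   residue numbers or identifiers.
#' @param n_top number of residues to return (default 6).
#' @return character vector of the `n_top` residues, RMSF descending,
#'   ties by ascending residue number.
#' @export
rank_rmsf <- function(rmsf, n_top = 6) {
  if (length(rmsf) == 0) stopf("empty RMSF map")
  if (n_top > length(rmsf)) stopf("n_top exceeds number of residues")
  num <- suppressWarnings(as.numeric(names(rmsf)))
  key <- if (any(is.na(num))) rank(names(rmsf)) else num
  names(rmsf)[order(-rmsf, key)][seq_len(n_top)]
}

#' Exponential moving average
#'
#' Recursive EMA with smoothing factor `alpha = 2 / (period + 1)`,
#' initialized at the first observation; output has the input length.
#'
#' @param x numeric series.
#' @param period EMA period (>= 1); period 1 returns `x` unchanged.
#' @return smoothed series.
#' @export
ema <- function(x, period) {
  if (length(x) == 0) stopf("empty series")
  if (period < 1) stopf("period must be >= 1")
  alpha <- 2 / (period + 1)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

#' Min-max normalization onto \[0, 1\]
#'
#' `(x - min) / (max - min)`; a zero-range series maps to all zeros with
#' attribute `degenerate = TRUE` so constant traces segment as fully
#' stable downstream.
#'
#' @param x numeric series.
#' @return normalized series, possibly with a `degenerate` attribute.
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0) stopf("empty series")
  rng <- range(x)
  if (diff(rng) == 0) {
    return(structure(rep(0, length(x)), degenerate = TRUE))
  }
  (x - rng[1]) / diff(rng)
}

#' Absolute forward-difference derivative
#'
#' `|x[i+1] - x[i]| / spacing` for each point; the last point copies its
#' predecessor so the output length equals the input length.
#'
#' @param x numeric series of length >= 2.
#' @param spacing grid spacing (> 0), default 1 frame.
#' @return series of absolute derivative estimates.
#' @export
abs_forward_difference <- function(x, spacing = 1) {
  if (length(x) < 2) stopf("series must have length >= 2")
  if (spacing <= 0) stopf("spacing must be > 0")
  d <- abs(diff(x)) / spacing
  c(d, d[length(d)])
}

#' Smoothing and thresholding parameters for zone segmentation
#'
#' @param ema_period EMA period in frames (default 5000, one tenth of a
#'   50,000-frame production trajectory).
#' @param threshold threshold in (0,1) applied to the min-max normalized
#'   derivative of the normalized moving average (default 0.6).
#' @param gap_frac flagged-frame runs separated by gaps shorter than
#'   `gap_frac * n` frames are merged into one unstable interval
#'   (default 0.01).
#' @param normalize_derivative normalize the derivative before
#'   thresholding (default TRUE; with FALSE the raw per-frame derivative
#'   is compared to `threshold`).
#' @export
smoothing_params <- function(ema_period = 5000, threshold = 0.6,
                             gap_frac = 0.01, normalize_derivative = TRUE) {
  stopifnot(ema_period >= 1, threshold > 0, threshold < 1, gap_frac >= 0)
  structure(list(ema_period = ema_period, threshold = threshold,
                 gap_frac = gap_frac,
                 normalize_derivative = normalize_derivative),
            class = "smoothing_params")
}

#' Segment a trajectory into stable and unstable time zones
#'
#' Per trace the pipeline is: EMA smoothing, min-max normalization,
#' absolute forward difference, min-max normalization of the derivative.
#' A frame is flagged unstable when the normalized derivative of the
#' normalized moving average exceeds the threshold (the moving average is
#' then in transit by construction). Flags are OR-combined across the
#' bundle; gaps shorter than the gap-merge window are closed and flagged
#' runs shorter than the same window are discarded as isolated noise
#' spikes. The surviving runs become unstable intervals; the complement
#' of the span is stable.
#'
#' @param traces an `rmsd_trace` or a list of traces sharing one time
#'   grid (e.g. per-residue RMSD series of the same trajectory).
#' @param params a [smoothing_params()].
#' @return object of class `zone_segmentation`: list with data frames
#'   `stable` and `unstable` (`t_start_ns`, `t_end_ns`, `n_frames`), the
#'   per-frame logical `unstable_flag`, and the shared `time_ns` grid.
#' @export
segment_zones <- function(traces, params = smoothing_params()) {
  if (inherits(traces, "rmsd_trace")) traces <- list(traces)
  times <- traces[[1]]$time_ns
  for (tr in traces) {
    if (!isTRUE(all.equal(tr$time_ns, times))) {
      stopf("traces do not share a time grid")
    }
  }
  n <- length(times)
  flag <- rep(FALSE, n)
  for (tr in traces) {
    sm <- minmax_normalize(ema(tr$value, params$ema_period))
    dv <- abs_forward_difference(sm)
    if (params$normalize_derivative) dv <- minmax_normalize(dv)
    if (isTRUE(attr(sm, "degenerate")) || isTRUE(attr(dv, "degenerate"))) next
    flag <- flag | (dv > params$threshold)
  }
  gap <- max(1L, floor(params$gap_frac * n))
  flag <- drop_short_runs(flag, ceiling(gap / 10))
  flag <- close_gaps(flag, gap)
  runs <- flag_runs(flag)
  mk <- function(r) {
    if (nrow(r) == 0) {
      return(data.frame(t_start_ns = numeric(0), t_end_ns = numeric(0),
                        n_frames = integer(0)))
    }
    data.frame(t_start_ns = times[r$start], t_end_ns = times[r$end],
               n_frames = r$end - r$start + 1L)
  }
  structure(list(stable = mk(runs[!runs$value, , drop = FALSE]),
                 unstable = mk(runs[runs$value, , drop = FALSE]),
                 unstable_flag = flag, time_ns = times),
            class = "zone_segmentation")
}

#' @export
print.zone_segmentation <- function(x, ...) {
  cat(sprintf("Zone segmentation over [%.4g, %.4g] ns: %d stable, %d unstable\n",
              min(x$time_ns), max(x$time_ns),
              nrow(x$stable), nrow(x$unstable)))
  invisible(x)
}

# Drop isolated TRUE runs shorter than `gap` frames: single noise spikes
# in the derivative do not constitute a conformational transition.
drop_short_runs <- function(flag, gap) {
  r <- flag_runs(flag)
  for (i in seq_len(nrow(r))) {
    if (r$value[i] && (r$end[i] - r$start[i] + 1) < gap) {
      flag[r$start[i]:r$end[i]] <- FALSE
    }
  }
  flag
}

# Close FALSE gaps shorter than `gap` frames between TRUE runs.
close_gaps <- function(flag, gap) {
  r <- flag_runs(flag)
  if (nrow(r) < 3) return(flag)
  for (i in 2:(nrow(r) - 1)) {
    if (!r$value[i] && r$value[i - 1] && r$value[i + 1] &&
        (r$end[i] - r$start[i] + 1) < gap) {
      flag[r$start[i]:r$end[i]] <- TRUE
    }
  }
  flag
}

flag_runs <- function(flag) {
  r <- rle(flag)
  end <- cumsum(r$lengths)
  data.frame(value = r$values, start = end - r$lengths + 1L, end = end)
}

#' Write a zone segmentation to the CSV contract
#' @param zones a `zone_segmentation`.
#' @param path output CSV `zone_type,t_start_ns,t_end_ns,n_frames_extracted`.
#' @export
write_segmentation <- function(zones, path) {
  df <- rbind(cbind(zone_type = "stable", zones$stable),
              cbind(zone_type = "unstable", zones$unstable))
  names(df)[names(df) == "n_frames"] <- "n_frames_extracted"
  df <- df[order(df$t_start_ns), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Sample representative frames from stable and unstable zones
#'
#' A simplified stand-in for trajectory pocket-analysis tooling: per
#' stable zone, k-means clustering of per-frame feature vectors (the RMSD
#' value, or user-supplied descriptors) returns the medoid frame of each
#' cluster; per unstable zone, frames whose descriptor z-score magnitude
#' (computed within the zone) exceeds `z_cut` are returned as atypical.
#'
#' @param trace an `rmsd_trace`.
#' @param zones a `zone_segmentation` for that trace.
#' @param descriptors optional numeric matrix, one row per frame.
#' @param k_stable clusters per stable zone (default 3).
#' @param z_cut z-score magnitude cut for unstable frames (default 2).
#' @param seed RNG seed for k-means initialization.
#' @return list with integer vectors `stable` and `unstable` of frame
#'   indices (the trace's `frame` values).
#' @export
sample_zone_frames <- function(trace, zones, descriptors = NULL,
                               k_stable = 3, z_cut = 2, seed = 1) {
  feats <- if (is.null(descriptors)) {
    matrix(trace$value, ncol = 1)
  } else {
    as.matrix(descriptors)
  }
  if (nrow(feats) != nrow(trace)) stopf("descriptor rows must match frames")
  in_zone <- function(z) {
    which(trace$time_ns >= z[["t_start_ns"]] & trace$time_ns <= z[["t_end_ns"]])
  }
  stable_frames <- integer(0)
  for (i in seq_len(nrow(zones$stable))) {
    idx <- in_zone(zones$stable[i, ])
    if (length(idx) == 0) { warnf("empty stable zone skipped"); next }
    f <- feats[idx, , drop = FALSE]
    k <- min(k_stable, nrow(unique(f)))
    med <- if (k == 1) {
      ctr <- colMeans(f)
      idx[which.min(rowSums(sweep(f, 2, ctr)^2))]
    } else {
      km <- with_seed(seed, kmeans(f, centers = k, nstart = 5))
      vapply(seq_len(k), function(j) {
        rows <- which(km$cluster == j)
        dd <- rowSums(sweep(f[rows, , drop = FALSE], 2, km$centers[j, ])^2)
        idx[rows[order(dd, rows)][1]]
      }, integer(1))
    }
    stable_frames <- c(stable_frames, sort(unique(med)))
  }
  unstable_frames <- integer(0)
  for (i in seq_len(nrow(zones$unstable))) {
    idx <- in_zone(zones$unstable[i, ])
    if (length(idx) == 0) { warnf("empty unstable zone skipped"); next }
    f <- feats[idx, , drop = FALSE]
    z <- scale(f)
    z[is.nan(z)] <- 0
    hit <- idx[apply(abs(z) > z_cut, 1, any)]
    unstable_frames <- c(unstable_frames, hit)
  }
  list(stable = trace$frame[stable_frames],
       unstable = trace$frame[unstable_frames])
}
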