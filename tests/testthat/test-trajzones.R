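test_that("statistical frame extraction: 7 distinct frames, tie handling", {
  # hand-evaluated: values 1..10, sample sd 3.028; selector order
  # mean, mean-2sd, mean+2sd, lowest, 2nd-lowest, highest, 2nd-highest
  expect_equal(extract_statistical_frames(rmsd_trace(1:10)),
               c(4L, 0L, 9L, 1L, 2L, 8L, 7L))
  # constant trace: all ties, earliest-first backfill
  expect_equal(sort(extract_statistical_frames(rmsd_trace(rep(2, 100)))),
               0:6)
  expect_error(extract_statistical_frames(rmsd_trace(1:6)), "at least 7")
  # property: always 7 distinct frames on random traces
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(7:200, 1)
    fr <- extract_statistical_frames(rmsd_trace(abs(rnorm(n))))
    expect_length(unique(fr), 7)
    expect_true(all(fr %in% 0:(n - 1)))
  }
})

test_that("pairwise RMSD with and without superposition", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  rownames(a) <- c("CA1", "CA2")
  expect_equal(pairwise_rmsd(a, a), 0)
  # hand arithmetic: sqrt(mean(c(0, 1))) = 1/sqrt(2)
  b <- rbind(c(0, 0, 0), c(2, 0, 0)); rownames(b) <- rownames(a)
  expect_equal(pairwise_rmsd(a, b), sqrt(0.5), tolerance = 1e-12)
  # rigid translation removed by superposition
  expect_equal(pairwise_rmsd(a, a + 5, superpose = TRUE), 0,
               tolerance = 1e-10)
  # rigid rotation removed; cross-check against bio3d
  set.seed(2)
  x <- matrix(rnorm(12), 4, 3)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  y <- x %*% rot + 3
  expect_equal(pairwise_rmsd(x, y, superpose = TRUE), 0, tolerance = 1e-8)
  skip_if_not_installed("bio3d")
  z <- x + matrix(rnorm(12, sd = 0.3), 4, 3)
  # bio3d rounds its RMSD to three decimals
  expect_equal(pairwise_rmsd(x, z, superpose = TRUE),
               bio3d::rmsd(as.vector(t(x)), as.vector(t(z)),
                           fit = TRUE),
               tolerance = 1e-3)
  bad <- a; rownames(bad) <- c("CA2", "CA1")
  expect_error(pairwise_rmsd(a, bad), "label mismatch")
})

test_that("greedy maximin diversity selection", {
  # identical items: all distances equal, tie rule keeps smallest indices
  expect_equal(sort(diversity_select(matrix(0, 7, 7), 5)), 1:5)
  # hand-traced 1-D greedy: {0,6,3,1,2} (0-based)
  d <- as.matrix(dist(0:6))
  expect_equal(diversity_select(d, 5) - 1L, c(0L, 6L, 3L, 1L, 2L))
  expect_error(diversity_select(d, 8), "n_keep")
  # step-by-step equivalence with an independent greedy reimplementation,
  # and near-optimal separation against enumeration of all 5-subsets of 7
  set.seed(5)
  for (rep in 1:20) {
    p <- matrix(rnorm(14), 7, 2)
    dm <- as.matrix(dist(p))
    sel <- diversity_select(dm, 5)
    expect_identical(sel, oracle_greedy_maximin(dm, 5))
    best <- max(apply(combn(7, 5), 2, function(s) subset_min_dist(dm, s)))
    expect_lte(subset_min_dist(dm, sel), best + 1e-9)
  }
})

test_that("RMSF ranking orders by fluctuation with residue-number ties", {
  expect_equal(rank_rmsf(c("10" = 0.5, "20" = 1.2, "30" = 0.9), 2),
               c("20", "30"))
  expect_equal(rank_rmsf(c("5" = 0.7), 1), "5")
  expect_equal(rank_rmsf(c("12" = 1.0, "3" = 1.0), 2), c("3", "12"))
  expect_error(rank_rmsf(numeric(0), 1), "empty")
})

test_that("EMA recursion, bounds, and degenerate inputs", {
  expect_equal(ema(rep(3, 10), 5), rep(3, 10))        # fixed point
  x <- rnorm(20)
  expect_equal(ema(x, 1), x)                          # alpha = 1 identity
  expect_equal(ema(c(1, 1, 1, 4), 3), c(1, 1, 1, 2.5))  # hand recursion
  expect_error(ema(x, 0), "period")
  # bounded by running min/max
  set.seed(3)
  for (rep in 1:10) {
    v <- rnorm(100)
    e <- ema(v, 10)
    expect_true(all(e <= cummax(v) + 1e-12 & e >= cummin(v) - 1e-12))
  }
})

test_that("min-max normalization and the forward-difference derivative", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  z <- minmax_normalize(rep(5, 4))
  expect_equal(as.numeric(z), rep(0, 4))
  expect_true(attr(z, "degenerate"))
  set.seed(9)
  v <- runif(50)
  nn <- minmax_normalize(v)
  expect_equal(minmax_normalize(nn), nn)              # idempotent
  expect_equal(which.min(nn), which.min(v))
  expect_equal(which.max(nn), which.max(v))
  expect_equal(abs_forward_difference(c(0, 1, 0), 1), c(1, 1, 1))
  expect_equal(abs_forward_difference(seq(0, 10, by = 2), 1),
               rep(2, 6))                             # linear ramp
  expect_equal(abs_forward_difference(rep(1, 5), 1), rep(0, 5))
  expect_error(abs_forward_difference(1, 1), "length")
})

test_that("zone segmentation recovers planted transitions", {
  p <- smoothing_params(ema_period = 500)
  # strictly constant trace: one stable interval, nothing unstable
  z0 <- segment_zones(rmsd_trace(rep(2, 5000)), p)
  expect_equal(nrow(z0$unstable), 0)
  expect_equal(nrow(z0$stable), 1)
  expect_equal(z0$stable$n_frames, 5000L)
  # one planted step: one unstable interval containing the change point
  g1 <- gen_trace(5000, 0.5, levels = c(2, 4), seed = 21)
  z1 <- segment_zones(g1$trace, p)
  expect_equal(nrow(z1$unstable), 1)
  expect_equal(nrow(z1$stable), 2)
  span <- diff(range(g1$trace$time_ns))
  cp <- g1$truth$change_point_ns
  expect_true(z1$unstable$t_start_ns - 0.02 * span <= cp &&
                cp <= z1$unstable$t_end_ns + 0.02 * span)
  # two planted transitions: three stable / two unstable, order preserved
  g2 <- gen_trace(5000, c(0.3, 0.7), levels = c(2, 4, 2), seed = 22)
  z2 <- segment_zones(g2$trace, p)
  expect_equal(nrow(z2$unstable), 2)
  expect_equal(nrow(z2$stable), 3)
  expect_true(all(diff(rbind(z2$stable, z2$unstable)$t_start_ns[
    order(rbind(z2$stable, z2$unstable)$t_start_ns)]) > 0))
  # stable and unstable intervals tile the span
  all_iv <- rbind(z2$stable, z2$unstable)
  all_iv <- all_iv[order(all_iv$t_start_ns), ]
  expect_equal(all_iv$t_start_ns[1], min(g2$trace$time_ns))
  expect_equal(all_iv$t_end_ns[nrow(all_iv)], max(g2$trace$time_ns))
  expect_equal(sum(all_iv$n_frames), nrow(g2$trace))
  # mismatched grids rejected
  tr_a <- gen_trace(1000, numeric(0), levels = 2, seed = 1)$trace
  tr_b <- gen_trace(999, numeric(0), levels = 2, seed = 1)$trace
  expect_error(segment_zones(list(tr_a, tr_b), p), "time grid")
})

test_that("zone frame sampling returns planted structure", {
  # stable zone with 3 planted value levels -> the 3 medoids
  vals <- c(rep(1, 30), rep(5, 30), rep(9, 30))
  tr <- rmsd_trace(vals)
  zones <- structure(list(
    stable = data.frame(t_start_ns = min(tr$time_ns),
                        t_end_ns = max(tr$time_ns), n_frames = 90L),
    unstable = data.frame(t_start_ns = numeric(0), t_end_ns = numeric(0),
                          n_frames = integer(0)),
    unstable_flag = rep(FALSE, 90), time_ns = tr$time_ns),
    class = "zone_segmentation")
  out <- sample_zone_frames(tr, zones, k_stable = 3, seed = 2)
  expect_length(out$stable, 3)
  expect_equal(sort(vals[out$stable + 1]), c(1, 5, 9))
  # identical frames collapse to a single representative
  tr2 <- rmsd_trace(rep(2, 50))
  zones2 <- zones
  zones2$stable <- data.frame(t_start_ns = min(tr2$time_ns),
                              t_end_ns = max(tr2$time_ns), n_frames = 50L)
  zones2$time_ns <- tr2$time_ns
  out2 <- sample_zone_frames(tr2, zones2, k_stable = 3, seed = 2)
  expect_length(out2$stable, 1)
  # unstable zone: a planted z > 2 outlier is extracted
  set.seed(8)
  v3 <- rnorm(60, 3, 0.1); v3[25] <- 3 + 5 * 0.1 * 10
  tr3 <- rmsd_trace(abs(v3))
  zones3 <- zones
  zones3$stable <- zones3$stable[0, ]
  zones3$unstable <- data.frame(t_start_ns = min(tr3$time_ns),
                                t_end_ns = max(tr3$time_ns), n_frames = 60L)
  zones3$time_ns <- tr3$time_ns
  out3 <- sample_zone_frames(tr3, zones3, z_cut = 2)
  expect_true(24L %in% out3$unstable)  # frame index of the outlier
})

test_that("traces and segmentations round-trip through the CSV contracts", {
  g <- gen_trace(500, 0.5, levels = c(2, 4), seed = 4)
  tmp <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(g$trace), tmp, row.names = FALSE)
  tr2 <- read_rmsd_trace(tmp)
  expect_equal(tr2$value, g$trace$value)
  expect_equal(tr2$time_ns, g$trace$time_ns)
  z <- segment_zones(tr2, smoothing_params(ema_period = 50))
  tmp2 <- tempfile(fileext = ".csv")
  write_segmentation(z, tmp2)
  back <- read.csv(tmp2)
  expect_equal(nrow(back), nrow(z$stable) + nrow(z$unstable))
  expect_equal(sum(back$n_frames_extracted), nrow(tr2))
})
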