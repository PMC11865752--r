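#' Initial velocity from a kinetic absorbance trace
#'
#' Least-squares slope over the early linear portion of an Ellman-type
#' kinetic read (absorbance at 407 nm versus time). The default window
#' rule evaluates every prefix of at least `min_points` points, capped at
#' `max_time_s`, and picks the prefix with the highest R-squared, ties
#' going to the longest prefix (a perfectly flat trace has R-squared 1 by
#' convention and yields slope 0).
#'
#' @param times seconds, strictly increasing (typically a 45 s grid over
#'   15 min).
#' @param absorbance AU, same length.
#' @param min_points minimum window length (default 3).
#' @param max_time_s cap on the window end (default 300 s).
#' @return slope in AU/s, with the chosen window length in attribute
#'   `n_points` and its R-squared in `r_squared`.
#' @export
initial_velocity <- function(times, absorbance, min_points = 3,
                             max_time_s = 300) {
  stopifnot(length(times) == length(absorbance))
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  usable <- which(times <= max_time_s)
  n_max <- max(length(usable), min_points)
  n_max <- min(n_max, length(times))
  if (n_max < min_points) stopf("window must contain >= %d points", min_points)
  best <- NULL
  for (n in min_points:n_max) {
    t <- times[1:n]; a <- absorbance[1:n]
    fit <- lm(a ~ t)
    sst <- sum((a - mean(a))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
    if (is.null(best) || r2 >= best$r2 - 1e-12) {
      best <- list(slope = unname(coef(fit)[2]), r2 = r2, n = n)
    }
  }
  structure(best$slope, n_points = best$n, r_squared = best$r2)
}

#' Percent inhibition from initial velocities
#'
#' `(1 - V0_sample / V0_control) * factor`, with `factor = 100` to place
#' the result on the percent scale.
#'
#' @param v0_sample initial velocity with the test compound (AU/s).
#' @param v0_control uninhibited initial velocity (AU/s, > 0).
#' @param factor scale factor (default 100).
#' @return percent inhibition (vectorized over `v0_sample`).
#' @export
percent_inhibition <- function(v0_sample, v0_control, factor = 100) {
  if (v0_control <= 0) stopf("v0_control must be positive")
  (1 - v0_sample / v0_control) * factor
}

#' IC50 from a dose-response table
#'
#' Default method `"interpolation"` finds the concentration at which 50%
#' inhibition is crossed, log-linearly interpolating between the
#' bracketing pair of concentrations (replicates are averaged per
#' concentration first). Method `"four_param"` fits a four-parameter
#' logistic by least squares and returns its midpoint, falling back to
#' interpolation (flagged) if the fit does not converge. When replicates
#' are present, a per-replicate spread of interpolated IC50s is reported.
#'
#' @param concentrations positive concentrations (consistent unit).
#' @param inhibition_pct percent inhibition, same length.
#' @param replicate optional replicate identifiers.
#' @param method `"interpolation"` or `"four_param"`.
#' @return list with `ic50`, `method` (the method actually used), `sd`
#'   (across replicates, or `NA`), `n_replicates`, and `fallback` flag.
#' @export
ic50 <- function(concentrations, inhibition_pct, replicate = NULL,
                 method = c("interpolation", "four_param")) {
  method <- match.arg(method)
  stopifnot(length(concentrations) == length(inhibition_pct))
  if (any(concentrations <= 0)) stopf("concentrations must be positive")
  agg <- aggregate(list(inh = inhibition_pct),
                   by = list(conc = concentrations), FUN = mean)
  agg <- agg[order(agg$conc), ]
  sd_rep <- NA_real_
  n_rep <- 1L
  if (!is.null(replicate)) {
    reps <- split(seq_along(concentrations), replicate)
    n_rep <- length(reps)
    if (n_rep > 1) {
      per <- vapply(reps, function(i) {
        tryCatch(interp_ic50(concentrations[i], inhibition_pct[i]),
                 error = function(e) NA_real_)
      }, numeric(1))
      if (sum(!is.na(per)) > 1) sd_rep <- sd(per, na.rm = TRUE)
    }
  }
  fallback <- FALSE
  value <- if (method == "four_param") {
    if (length(unique(agg$conc)) < 4) {
      stopf("four_param needs >= 4 concentrations")
    }
    fit <- tryCatch(fit_4pl(agg$conc, agg$inh), error = function(e) NULL)
    if (is.null(fit)) {
      fallback <- TRUE
      method <- "interpolation"
      interp_ic50(agg$conc, agg$inh)
    } else {
      fit
    }
  } else {
    interp_ic50(agg$conc, agg$inh)
  }
  list(ic50 = value, method = method, sd = sd_rep, n_replicates = n_rep,
       fallback = fallback)
}

interp_ic50 <- function(conc, inh) {
  ord <- order(conc)
  conc <- conc[ord]; inh <- inh[ord]
  exact <- which(inh == 50)
  if (length(exact)) return(conc[exact[1]])
  cross <- which(inh[-length(inh)] < 50 & inh[-1] >= 50)
  if (length(cross) == 0) {
    stopf("inhibition does not bracket 50%%; cannot interpolate")
  }
  i <- cross[1]
  lc <- log10(conc)
  10^(lc[i] + (50 - inh[i]) / (inh[i + 1] - inh[i]) * (lc[i + 1] - lc[i]))
}

fit_4pl <- function(conc, inh) {
  start <- list(bottom = min(inh), top = max(inh), hill = 1,
                mid = exp(mean(log(range(conc)))))
  fit <- minpack.lm::nlsLM(
    inh ~ bottom + (top - bottom) / (1 + (mid / conc)^hill),
    start = start,
    lower = c(bottom = -50, top = 10, hill = 0.1, mid = min(conc) / 100),
    upper = c(bottom = 49, top = 200, hill = 10, mid = max(conc) * 100),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  unname(coef(fit)[["mid"]])
}

#' Convert a mass concentration to nanomolar
#'
#' `conc / mw * 1e6` converts ug/mL to nM; with `round_nearest_100` the
#' result is rounded to the nearest 100 nM, matching how assay
#' concentrations are conventionally reported.
#'
#' @param conc concentration in ug/mL (> 0).
#' @param mw molecular weight in g/mol (> 0).
#' @param round_nearest_100 round to the nearest 100 nM (default FALSE).
#' @return concentration in nM (vectorized).
#' @export
ug_per_ml_to_nM <- function(conc, mw, round_nearest_100 = FALSE) {
  if (any(conc <= 0) || any(mw <= 0)) stopf("conc and mw must be positive")
  out <- conc / mw * 1e6
  if (round_nearest_100) out <- round(out / 100) * 100
  out
}

#' Read kinetic plate reads from the long CSV contract
#'
#' Columns: `well_id, compound_id, concentration, conc_unit, time_s,
#' absorbance`.
#'
#' @param path CSV file.
#' @export
read_plate_reads <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "compound_id", "concentration", "conc_unit",
            "time_s", "absorbance")
  if (!all(need %in% names(df))) {
    stopf("plate CSV needs columns: %s", paste(need, collapse = ", "))
  }
  df
}

#' Analyze an Ellman plate: velocities, inhibition, IC50 per compound
#'
#' Wells with `compound_id == control_id` define the uninhibited initial
#' velocity (averaged across control wells). For every other compound,
#' per-well initial velocities are converted to percent inhibition and an
#' IC50 is interpolated from the dose-response.
#'
#' @param reads long plate table (see [read_plate_reads()]).
#' @param control_id compound id of the uninhibited control
#'   (default `"control"`).
#' @param method passed to [ic50()].
#' @return data frame `compound_id, ic50, ic50_unit, method,
#'   n_replicates, sd`.
#' @export
analyze_plate <- function(reads, control_id = "control",
                          method = "interpolation") {
  v0_by_well <- function(df) {
    wells <- split(df, df$well_id)
    vapply(wells, function(w) {
      w <- w[order(w$time_s), ]
      as.numeric(initial_velocity(w$time_s, w$absorbance))
    }, numeric(1))
  }
  ctrl <- reads[reads$compound_id == control_id, , drop = FALSE]
  if (nrow(ctrl) == 0) stopf("no control wells ('%s')", control_id)
  v0c <- mean(v0_by_well(ctrl))
  out <- list()
  for (cmp in setdiff(unique(reads$compound_id), control_id)) {
    sub <- reads[reads$compound_id == cmp, , drop = FALSE]
    wells <- unique(sub[c("well_id", "concentration", "conc_unit")])
    v0 <- v0_by_well(sub)
    inh <- percent_inhibition(v0[wells$well_id], v0c)
    rep_id <- ave(wells$concentration, wells$concentration,
                  FUN = seq_along)
    fit <- ic50(wells$concentration, inh, replicate = rep_id,
                method = method)
    out[[cmp]] <- data.frame(compound_id = cmp, ic50 = fit$ic50,
                             ic50_unit = wells$conc_unit[1],
                             method = fit$method,
                             n_replicates = fit$n_replicates, sd = fit$sd)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
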