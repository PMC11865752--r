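# Seeded generators for every external input the cascade consumes:
# family-structured inhibitor libraries, RMSD traces with planted change
# points, ensemble-docking score tables, phase-score matrices, and
# Ellman kinetic plates. Each generator is a pure function of its
# arguments (seed included) and returns the ground truth needed to score
# recovery tests.

# Scaffold templates (one per family) and decoration side chains used to
# build family-structured SMILES: within-family pairs share a scaffold,
# so their circular-fingerprint Tanimoto similarity exceeds
# between-family pairs.
family_scaffolds <- function() {
  c("c1ccc2cc(%s)ccc2c1",      # naphthalene
    "c1ccc2c(c1)c(%s)c[nH]2",  # indole
    "c1ccc2nc(%s)ccc2c1",      # quinoline
    "c1ccc2oc(%s)cc2c1",       # benzofuran
    "c1ccc2sc(%s)cc2c1",       # benzothiophene
    "c1ccc2[nH]c(%s)nc2c1",    # benzimidazole
    "C1CCN(c2ccc(%s)cc2)CC1",  # 4-phenylpiperidine
    "c1ccc(-c2ccc(%s)cc2)cc1", # biphenyl
    "c1ccc2sc(%s)nc2c1",       # benzothiazole
    "c1ccc2nc(%s)cnc2c1")      # quinoxaline
}

# Short substituents, so scaffold bits dominate the fingerprints and
# within-family similarity stays above between-family similarity.
decoration_chains <- function() {
  c("C", "CC", "CCC", "O", "OC", "OCC", "N", "NC", "F", "Cl", "Br",
    "C(C)C", "C#N", "C(=O)C", "C(=O)OC", "CO", "CN", "CCO", "CC(C)C",
    "C(=O)N", "CCN", "OC(C)C", "CCl", "CF", "CCCC", "OCCC", "NCC",
    "C(C)O", "C(C)N", "COC", "CNC", "CCOC", "C(=O)OCC", "C(=O)NC",
    "N(C)C", "CCF", "CC#N", "OCC(C)C", "CC(=O)C", "CCCO", "CCCN",
    "C(C)CC", "OCCN", "CC(C)O", "CCNC")
}

#' Generate a family-structured synthetic inhibitor library
#'
#' Families are built from distinct aromatic/aliphatic scaffolds with
#' enumerated side-chain decorations, so within-family Tanimoto
#' similarity exceeds between-family similarity. IC50s are log-normal
#' within each family around the configured geometric mean. Molecular
#' properties (mw, logp, hbd, hba, rotb) are computed from the
#' structures.
#'
#' @param n_families number of families (<= 10).
#' @param family_size molecules per family (recycled; <= 45).
#' @param ic50_geomean_nM per-family geometric mean IC50 (nM), recycled.
#' @param ic50_sdlog log-scale standard deviation of IC50 (default 0.8,
#'   a typical within-series assay spread).
#' @param seed RNG seed (mandatory).
#' @return list with `library` (a `mol_library` with properties and
#'   `ic50_nM`) and `truth` (list with `family`, a named vector mol_id ->
#'   family index, and the configured IC50 parameters).
#' @export
gen_library <- function(n_families = 3, family_size = 20,
                        ic50_geomean_nM = c(500, 5000, 20000),
                        ic50_sdlog = 0.8, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  scaffolds <- family_scaffolds()
  if (n_families > length(scaffolds)) {
    stopf("at most %d families supported", length(scaffolds))
  }
  sizes <- rep_len(family_size, n_families)
  geo <- rep_len(ic50_geomean_nM, n_families)
  chains <- decoration_chains()
  if (any(sizes > length(chains))) {
    stopf("family_size must be <= %d", length(chains))
  }
  rows <- list()
  fam_of <- character(0)
  for (f in seq_len(n_families)) {
    smi <- sprintf(scaffolds[f], chains[seq_len(sizes[f])])
    ids <- sprintf("F%02d_M%03d", f, seq_len(sizes[f]))
    rows[[f]] <- data.frame(mol_id = ids, smiles = smi,
                            family = f, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  ic50 <- with_seed(seed, rlnorm(nrow(df),
                                 meanlog = log(geo)[df$family],
                                 sdlog = ic50_sdlog))
  lib <- mol_library(df$mol_id, df$smiles, ic50_nM = ic50)
  lib <- compute_mol_properties(lib)
  list(library = lib,
       truth = list(family = setNames(df$family, df$mol_id),
                    ic50_geomean_nM = geo, ic50_sdlog = ic50_sdlog,
                    seed = seed))
}

#' Generate an RMSD trace with planted change points
#'
#' Piecewise-stationary Gaussian segments joined by linear transition
#' ramps at the planted change points, emulating a backbone-RMSD series
#' whose level shifts when the binding site changes conformation.
#'
#' @param n_frames trace length (default 5000).
#' @param change_points change-point positions as fractions of the span
#'   in (0, 1); empty for a single stationary segment.
#' @param levels segment mean RMSD levels (Angstrom), length
#'   `length(change_points) + 1`.
#' @param noise_sd within-segment Gaussian noise (default 0.15 A).
#' @param ramp_frac transition ramp width as a fraction of the span
#'   (default 0.01).
#' @param dt_ns time step per frame (default 0.01 ns).
#' @param seed RNG seed (mandatory).
#' @return list with `trace` (an [rmsd_trace()]) and `truth` (planted
#'   change-point times in ns and segment levels).
#' @export
gen_trace <- function(n_frames = 5000, change_points = numeric(0),
                      levels = NULL, noise_sd = 0.15, ramp_frac = 0.01,
                      dt_ns = 0.01, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  cp <- sort(change_points)
  if (any(cp <= 0 | cp >= 1)) stopf("change points must lie in (0, 1)")
  ramp <- max(1L, round(ramp_frac * n_frames))
  if (length(cp) > 1 && any(diff(round(cp * n_frames)) <= ramp)) {
    stopf("change points overlap at this ramp width")
  }
  levels <- levels %||% (2 + 2 * (seq_len(length(cp) + 1) %% 2 == 0))
  if (length(levels) != length(cp) + 1) {
    stopf("need %d levels for %d change points", length(cp) + 1, length(cp))
  }
  base <- rep(levels[1], n_frames)
  bounds <- round(cp * n_frames)
  for (i in seq_along(bounds)) {
    lo <- bounds[i]
    hi <- min(n_frames, lo + ramp)
    if (lo > 1) base[lo:hi] <- seq(levels[i], levels[i + 1],
                                   length.out = hi - lo + 1)
    if (hi < n_frames) base[(hi + 1):n_frames] <- levels[i + 1]
  }
  values <- with_seed(seed, pmax(0, base + rnorm(n_frames, sd = noise_sd)))
  tr <- rmsd_trace(values, times = (0:(n_frames - 1)) * dt_ns)
  list(trace = tr,
       truth = list(change_point_ns = (bounds - 1) * dt_ns,
                    levels = levels, ramp_frames = ramp, seed = seed))
}

#' Generate ensemble-docking score records
#'
#' Per molecule and receptor conformation, XP GScores are Gaussian around
#' a base mean, with actives shifted by `gap` kcal/mol (negative gap =
#' stronger binding for actives). A configured fraction of molecules is
#' emitted with no poses at all, exercising "not recovered" semantics.
#'
#' @param lib a `mol_library`.
#' @param active named logical vector (mol_id -> active) or NULL for all
#'   inactive.
#' @param n_conformations receptor conformations (default 5).
#' @param base_mean mean XP GScore of inactives (default -6 kcal/mol).
#' @param gap additive shift for actives (default -3 kcal/mol).
#' @param score_sd per-pose score spread (default 1).
#' @param drop_frac fraction of molecules with no poses (default 0.1).
#' @param seed RNG seed (mandatory).
#' @return list with `records` (`mol_id, conformation_id, xp_gscore`) and
#'   `truth` (`dropped` ids, `active` labels).
#' @export
gen_docking_scores <- function(lib, active = NULL, n_conformations = 5,
                               base_mean = -6, gap = -3, score_sd = 1,
                               drop_frac = 0.1, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  ids <- lib$mol_id
  if (is.null(active)) active <- setNames(rep(FALSE, length(ids)), ids)
  recs <- with_seed(seed, {
    dropped <- sample(ids, round(drop_frac * length(ids)))
    kept <- setdiff(ids, dropped)
    mu <- base_mean + gap * as.numeric(active[kept])
    df <- data.frame(
      mol_id = rep(kept, each = n_conformations),
      conformation_id = rep(sprintf("conf%02d", seq_len(n_conformations)),
                            length(kept)),
      xp_gscore = rnorm(length(kept) * n_conformations,
                        mean = rep(mu, each = n_conformations),
                        sd = score_sd))
    list(df = df, dropped = dropped)
  })
  list(records = recs$df,
       truth = list(dropped = recs$dropped, active = active, seed = seed))
}

#' Generate a phase-score matrix over stable/unstable models
#'
#' Per molecule and pharmacophore model, a Bernoulli match with origin-
#' and label-dependent probability; matched scores are Gaussian with
#' label-dependent means (truncated at 0.05), so actives stochastically
#' dominate decoys.
#'
#' @param mol_ids molecule identifiers (rows).
#' @param active logical per molecule.
#' @param n_stable,n_unstable model counts per origin (defaults 4 and 2).
#' @param p_match_active,p_match_decoy match probabilities
#'   `c(stable=, unstable=)`.
#' @param score_mean_active,score_mean_decoy matched-score means.
#' @param score_sd matched-score spread (default 0.25).
#' @param seed RNG seed (mandatory).
#' @return list with `matrix` (a [phase_matrix()]) and `truth`.
#' @export
gen_phase_matrix <- function(mol_ids, active,
                             n_stable = 4, n_unstable = 2,
                             p_match_active = c(stable = 0.8, unstable = 0.7),
                             p_match_decoy = c(stable = 0.15, unstable = 0.1),
                             score_mean_active = 1.6, score_mean_decoy = 0.9,
                             score_sd = 0.25, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  stopifnot(n_stable >= 1, n_unstable >= 1,
            length(active) == length(mol_ids))
  origins <- c(rep("stable", n_stable), rep("unstable", n_unstable))
  model_ids <- sprintf("%s%02d", ifelse(origins == "stable", "S", "U"),
                       c(seq_len(n_stable), seq_len(n_unstable)))
  n <- length(mol_ids); m <- length(origins)
  scores <- with_seed(seed, {
    p <- matrix(0, n, m)
    p[active, origins == "stable"] <- p_match_active[["stable"]]
    p[active, origins == "unstable"] <- p_match_active[["unstable"]]
    p[!active, origins == "stable"] <- p_match_decoy[["stable"]]
    p[!active, origins == "unstable"] <- p_match_decoy[["unstable"]]
    hit <- matrix(rbinom(n * m, 1, as.vector(p)), n, m) == 1
    mu <- ifelse(active, score_mean_active, score_mean_decoy)
    s <- matrix(pmax(0.05, rnorm(n * m, mean = rep(mu, m), sd = score_sd)),
                n, m)
    s[!hit] <- NA_real_
    s
  })
  dimnames(scores) <- list(mol_ids, model_ids)
  list(matrix = phase_matrix(scores, origins),
       truth = list(active = setNames(active, mol_ids), seed = seed))
}

#' Generate a synthetic Ellman kinetic plate
#'
#' Kinetic absorbance traces on a 45 s grid over 15 min for a 1:1
#' dilution series of one compound plus uninhibited control wells. The
#' uninhibited initial velocity is attenuated per well by a logistic
#' (Hill) inhibition curve with the configured true IC50; traces are
#' linear in the early phase with multiplicative velocity noise and
#' additive read noise.
#'
#' @param true_ic50 true IC50, in the units of `top_conc`.
#' @param top_conc highest concentration of the 1:1 series
#'   (default 450, e.g. ug/mL).
#' @param n_dilutions wells in the series (default 9, reaching ~1.76 from
#'   450).
#' @param conc_unit unit tag (default "ug/mL").
#' @param hill Hill coefficient (default 1).
#' @param v0_control uninhibited slope (default 0.0015 AU/s).
#' @param n_replicates replicate wells per concentration (default 3).
#' @param velocity_noise_frac multiplicative velocity noise (default
#'   0.02).
#' @param read_noise_au additive absorbance noise (default 0.001 AU).
#' @param seed RNG seed (mandatory).
#' @return list with `reads` (long plate table, see
#'   [read_plate_reads()]) and `truth` (`true_ic50`).
#' @export
gen_assay_plate <- function(true_ic50, top_conc = 450, n_dilutions = 9,
                            conc_unit = "ug/mL", hill = 1,
                            v0_control = 0.0015, n_replicates = 3,
                            velocity_noise_frac = 0.02,
                            read_noise_au = 0.001, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  times <- seq(0, 900, by = 45)
  conc <- top_conc / 2^(seq_len(n_dilutions) - 1)
  wells <- rbind(
    expand.grid(compound_id = "cmpd", concentration = conc,
                replicate = seq_len(n_replicates),
                stringsAsFactors = FALSE),
    expand.grid(compound_id = "control", concentration = 0,
                replicate = seq_len(n_replicates),
                stringsAsFactors = FALSE))
  wells$well_id <- sprintf("W%03d", seq_len(nrow(wells)))
  reads <- with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(wells))) {
      cc <- wells$concentration[i]
      inh <- if (cc > 0) 1 / (1 + (true_ic50 / cc)^hill) else 0
      v0 <- v0_control * (1 - inh) *
        (1 + rnorm(1, sd = velocity_noise_frac))
      a <- 0.05 + v0 * times + rnorm(length(times), sd = read_noise_au)
      out[[i]] <- data.frame(well_id = wells$well_id[i],
                             compound_id = wells$compound_id[i],
                             concentration = cc, conc_unit = conc_unit,
                             time_s = times, absorbance = a)
    }
    do.call(rbind, out)
  })
  rownames(reads) <- NULL
  list(reads = reads, truth = list(true_ic50 = true_ic50, hill = hill,
                                   v0_control = v0_control, seed = seed))
}
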