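#' Configure the sequential screening cascade
#'
#' The cascade applies, in order: a molecular-weight cap, the per-family
#' machine-learning classifiers (union of accepted molecules, duplicates
#' removed, with multi-family fan-out), the ligand-based pharmacophore
#' filter (an externally produced match table; a molecule passes with at
#' least one hypothesis match), and the ensemble + YN2 stage ranking the
#' survivors and keeping the top `top_n` per family.
#'
#' @param families named list, one entry per family; each entry is a list
#'   with elements `model` (a `screen_model`, or a function mol_id ->
#'   probability), `ligand_matches` (character vector of mol_ids matching
#'   at least one ligand-based hypothesis for that family), `phase`
#'   (a [phase_matrix()] for the screening library) and `params`
#'   (a fitted [yn2_params()]).
#' @param descriptors data frame with `mol_id` and the descriptor
#'   columns the ML models need.
#' @param mw_cap molecular weight cap in Da (default 500).
#' @param top_n final list size per family (default 500).
#' @param ml_threshold probability threshold for the ML active call
#'   (default 0.5).
#' @param stages character subset of
#'   `c("mw", "ml", "ligand", "ensemble")`; a stage left out acts as the
#'   identity filter at its position.
#' @export
cascade_config <- function(families, descriptors = NULL, mw_cap = 500,
                           top_n = 500, ml_threshold = 0.5,
                           stages = c("mw", "ml", "ligand", "ensemble")) {
  stopifnot(is.list(families), length(names(families)) == length(families))
  bad <- setdiff(stages, c("mw", "ml", "ligand", "ensemble"))
  if (length(bad)) stopf("unknown stages: %s", paste(bad, collapse = ", "))
  structure(list(families = families, descriptors = descriptors,
                 mw_cap = mw_cap, top_n = top_n,
                 ml_threshold = ml_threshold, stages = stages),
            class = "cascade_config")
}

#' Run the sequential virtual-screening cascade
#'
#' @param lib a `mol_library` of the screening database (needs `mw` for
#'   the weight cap).
#' @param config a [cascade_config()].
#' @return object of class `cascade_report`: list with `stages` (data
#'   frame `stage, n_in, n_out, pct_retained`), `final` (named list of
#'   per-family ranked data frames from [screen_ensemble()]), and
#'   `family_members` (the per-family molecule sets after fan-out).
#' @export
run_cascade <- function(lib, config) {
  stopifnot(inherits(config, "cascade_config"))
  ids <- lib$mol_id
  stages <- list()
  log_stage <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out,
      pct_retained = if (n_in > 0) n_out / n_in * 100 else 0)
    if (n_out == 0) warnf("stage '%s' retained no molecules", stage)
  }
  current <- ids
  if ("mw" %in% config$stages) {
    kept <- lib$mol_id[!is.na(lib$mw) & lib$mw <= config$mw_cap]
    out <- intersect(current, kept)
    log_stage("mw_filter", length(current), length(out))
    current <- out
  }
  # ML stage: each family model accepts molecules; union with dedup, and
  # each molecule is assigned to every family whose model accepted it.
  family_members <- setNames(vector("list", length(config$families)),
                             names(config$families))
  if ("ml" %in% config$stages && length(current) > 0) {
    accepted <- character(0)
    for (fam in names(config$families)) {
      model <- config$families[[fam]]$model
      prob <- if (is.function(model)) {
        model(current)
      } else {
        desc <- config$descriptors
        rows <- match(current, desc$mol_id)
        if (any(is.na(rows))) stopf("descriptors missing for some molecules")
        predict(model, desc[rows, , drop = FALSE])
      }
      fam_ids <- current[prob >= config$ml_threshold]
      family_members[[fam]] <- fam_ids
      accepted <- union(accepted, fam_ids)
    }
    out <- current[current %in% accepted]  # dedup preserving order
    log_stage("ml_models", length(current), length(out))
    current <- out
  } else {
    for (fam in names(config$families)) family_members[[fam]] <- current
  }
  if ("ligand" %in% config$stages && length(current) > 0) {
    accepted <- character(0)
    for (fam in names(config$families)) {
      hits <- intersect(family_members[[fam]],
                        config$families[[fam]]$ligand_matches)
      family_members[[fam]] <- hits
      accepted <- union(accepted, hits)
    }
    out <- current[current %in% accepted]
    log_stage("ligand_pharmacophore", length(current), length(out))
    current <- out
  }
  final <- setNames(vector("list", length(config$families)),
                    names(config$families))
  if ("ensemble" %in% config$stages && length(current) > 0) {
    n_in <- length(current)
    accepted <- character(0)
    for (fam in names(config$families)) {
      fc <- config$families[[fam]]
      rows <- intersect(family_members[[fam]], rownames(fc$phase$scores))
      if (length(rows) == 0) {
        final[[fam]] <- NULL
        next
      }
      sub <- phase_matrix(fc$phase$scores[rows, , drop = FALSE],
                          fc$phase$origins)
      final[[fam]] <- screen_ensemble(sub, fc$params, top_n = config$top_n)
      accepted <- union(accepted, final[[fam]]$mol_id)
    }
    out <- current[current %in% accepted]
    log_stage("ensemble_yn2", n_in, length(out))
    current <- out
  }
  structure(list(stages = do.call(rbind, stages), final = final,
                 family_members = family_members, n_final = length(current)),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}

#' Render a cascade report
#'
#' @param cascade a `cascade_report`.
#' @param format `"markdown"` or `"json"`; both renderings carry the same
#'   numbers.
#' @return a character vector (markdown lines) or a JSON string.
#' @export
report <- function(cascade, format = c("markdown", "json")) {
  format <- match.arg(format)
  if (format == "markdown") return(report_markdown(cascade))
  jsonlite::toJSON(list(
    stages = cascade$stages,
    final_counts = lapply(cascade$final, function(f)
      if (is.null(f)) 0L else nrow(f))),
    auto_unbox = TRUE, digits = NA)
}

report_markdown <- function(cascade) {
  st <- cascade$stages
  lines <- c("| stage | in | out | retained (%) |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(st))) {
    warn_mark <- if (st$n_out[i] == 0) " (!)" else ""
    lines <- c(lines, sprintf("| %s | %d | %d | %.1f%s |",
                              st$stage[i], st$n_in[i], st$n_out[i],
                              st$pct_retained[i], warn_mark))
  }
  for (fam in names(cascade$final)) {
    n <- if (is.null(cascade$final[[fam]])) 0L else nrow(cascade$final[[fam]])
    lines <- c(lines, sprintf("- family %s: %d ranked candidates", fam, n))
  }
  lines
}
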