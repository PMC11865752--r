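#' Construct a phase-score matrix
#'
#' Molecules x pharmacophore-models table of phase scores. `NA` encodes
#' "no match". Every model (column) is labeled by its origin: derived
#' from a stable or an unstable binding-site conformation.
#'
#' @param scores numeric matrix (rows = molecules, columns = models) with
#'   mol_id rownames and model_id colnames; `NA` = no match.
#' @param origins character vector `"stable"`/`"unstable"`, one per
#'   column.
#' @return object of class `phase_matrix`.
#' @export
phase_matrix <- function(scores, origins) {
  stopifnot(is.matrix(scores), length(origins) == ncol(scores))
  if (!all(origins %in% c("stable", "unstable"))) {
    stopf("origins must be 'stable' or 'unstable'")
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stopf("scores needs mol_id rownames and model_id colnames")
  }
  if (anyDuplicated(colnames(scores))) stopf("duplicate model_id")
  if (any(!is.na(scores) & !is.finite(scores))) stopf("non-finite scores")
  structure(list(scores = scores, origins = origins),
            class = "phase_matrix")
}

#' @export
print.phase_matrix <- function(x, ...) {
  cat(sprintf("phase_matrix: %d molecules x %d models (%d stable, %d unstable)\n",
              nrow(x$scores), ncol(x$scores),
              sum(x$origins == "stable"), sum(x$origins == "unstable")))
  invisible(x)
}

#' Read / write the phase-score matrix TSV contract
#'
#' The TSV carries `mol_id` in the first column, a first header row of
#' model ids, and a second header row of origins (`stable`/`unstable`).
#' No-match is encoded as an empty cell.
#'
#' @param path TSV file.
#' @export
read_phase_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 2), "\t")
  model_ids <- header[[1]][-1]
  origins <- header[[2]][-1]
  df <- read.delim(path, skip = 2, header = FALSE, na.strings = "",
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(as.character(df[[1]]), model_ids)
  phase_matrix(m, origins)
}

#' @rdname read_phase_matrix
#' @param pm a `phase_matrix`.
#' @export
write_phase_matrix <- function(pm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("mol_id", colnames(pm$scores)), collapse = "\t"), con)
  writeLines(paste(c("origin", pm$origins), collapse = "\t"), con)
  body <- apply(pm$scores, 1, function(r) {
    paste(ifelse(is.na(r), "", format(r, trim = TRUE)), collapse = "\t")
  })
  writeLines(paste(rownames(pm$scores), body, sep = "\t"), con)
  invisible(path)
}

#' Per-molecule match counts and ensemble phase score
#'
#' @param pm a `phase_matrix`.
#' @return data frame `mol_id, c_stable, c_unstable, ph_score`: counts of
#'   matched models per origin and the row's ensemble phase score
#'   (maximum matched score, 0 when nothing matches).
#' @export
match_counts <- function(pm) {
  stable <- pm$origins == "stable"
  matched <- !is.na(pm$scores)
  data.frame(
    mol_id = rownames(pm$scores),
    c_stable = as.integer(rowSums(matched[, stable, drop = FALSE])),
    c_unstable = as.integer(rowSums(matched[, !stable, drop = FALSE])),
    ph_score = apply(pm$scores, 1, ensemble_phase_score),
    row.names = NULL)
}

#' OR-combination activity call
#'
#' A molecule is called active when at least one pharmacophore model of
#' the ensemble matches it.
#'
#' @param pm a `phase_matrix`.
#' @return named logical vector per molecule.
#' @export
is_active_or <- function(pm) {
  setNames(rowSums(!is.na(pm$scores)) >= 1, rownames(pm$scores))
}

#' Validate a pharmacophore ensemble against actives and decoys
#'
#' In `plain` mode the activity call is the OR rule (at least one model
#' matched) and the ROC-AUC is computed from the ensemble phase score.
#' In `yn2` mode, phase-score normalization bounds are fitted from the
#' known actives, YN2 is computed for every molecule, the YN2 threshold
#' is optimized for recall + specificity, and metrics are reported at
#' that threshold.
#'
#' @param pm a `phase_matrix` covering actives and decoys.
#' @param labels logical or `active`/`decoy`, aligned with the matrix
#'   rows.
#' @param mode `"yn2"` (default) or `"plain"`.
#' @return list with `metrics` (a [classification_metrics()] report),
#'   `counts` (the [match_counts()] table, with a `yn2` column in yn2
#'   mode), and in yn2 mode the fitted `params` (a [yn2_params()] with
#'   the optimized threshold) and `objective`.
#' @export
validate_ensemble <- function(pm, labels, mode = c("yn2", "plain")) {
  mode <- match.arg(mode)
  labels <- as_active_logical(labels)
  if (length(labels) != nrow(pm$scores)) stopf("labels/rows mismatch")
  if (!any(labels) || all(labels)) stopf("both classes must be present")
  counts <- match_counts(pm)
  if (mode == "plain") {
    pred_score <- counts$ph_score
    # OR rule: active iff >= 1 match; smallest positive threshold on the
    # ensemble phase score reproduces it only when all matched scores are
    # positive, so use the match counts directly for the confusion table.
    matched <- counts$c_stable + counts$c_unstable >= 1
    met <- classification_metrics(as.numeric(matched), labels, 1)
    met$roc_auc <- roc_auc(pred_score, labels)
    return(list(metrics = met, counts = counts))
  }
  act_ph <- counts$ph_score[labels]
  params <- yn2_params(ph_min = min(act_ph), ph_max = max(act_ph),
                       n_stable_total = sum(pm$origins == "stable"),
                       n_unstable_total = sum(pm$origins == "unstable"))
  counts$yn2 <- as.numeric(yn2(counts$ph_score, counts$c_stable,
                               counts$c_unstable, params))
  opt <- optimize_yn2_threshold(counts$yn2, labels)
  params$threshold <- opt$threshold
  list(metrics = classification_metrics(counts$yn2, labels, opt$threshold),
       counts = counts, params = params, objective = opt$objective)
}

#' Screen a library with a fitted ensemble and YN2
#'
#' Computes YN2 for every molecule of the screening matrix, keeps the
#' molecules at or above the fitted YN2 threshold, and returns the top
#' `top_n` ranked by descending YN2 (ties by ascending `mol_id`).
#'
#' @param pm a `phase_matrix` for the screening library.
#' @param params a fitted [yn2_params()] (threshold set).
#' @param top_n maximum number of molecules returned (default 500).
#' @return data frame `rank, mol_id, c_stable, c_unstable, ph_score, yn2`.
#' @export
screen_ensemble <- function(pm, params, top_n = 500) {
  if (is.na(params$threshold)) stopf("params$threshold is not fitted")
  counts <- match_counts(pm)
  counts$yn2 <- as.numeric(yn2(counts$ph_score, counts$c_stable,
                               counts$c_unstable, params))
  hits <- counts[counts$yn2 >= params$threshold, , drop = FALSE]
  hits <- hits[order(-hits$yn2, hits$mol_id), , drop = FALSE]
  hits <- head(hits, top_n)
  if (nrow(hits)) hits <- cbind(rank = seq_len(nrow(hits)), hits)
  rownames(hits) <- NULL
  hits
}

#' Ensemble definition bookkeeping
#'
#' An ensemble definition records the pharmacophore models (ids and
#' stable/unstable origins, optionally their source time intervals and
#' feature summaries), the fitted YN2 parameters, and the provenance
#' family id. Feature summaries are annotation only and never affect
#' computation.
#'
#' @param models data frame with `model_id` and `origin` columns
#'   (optional `t_start_ns`, `t_end_ns`, `features`).
#' @param yn2_params a [yn2_params()] or NULL.
#' @param provenance family/cluster identifier string.
#' @export
ensemble_definition <- function(models, yn2_params = NULL,
                                provenance = NA_character_) {
  stopifnot(all(c("model_id", "origin") %in% names(models)))
  if (anyDuplicated(models$model_id)) stopf("duplicate model_id")
  structure(list(models = models, yn2_params = yn2_params,
                 provenance = provenance),
            class = "ensemble_definition")
}

#' Write / read an ensemble definition as JSON
#' @param def an `ensemble_definition`.
#' @param path JSON file.
#' @export
write_ensemble_definition <- function(def, path) {
  jsonlite::write_json(
    list(models = def$models,
         yn2_params = if (!is.null(def$yn2_params))
           unclass(def$yn2_params),
         provenance = def$provenance),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ensemble_definition
#' @export
read_ensemble_definition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- if (!is.null(obj$yn2_params)) {
    do.call(yn2_params, obj$yn2_params)
  }
  ensemble_definition(obj$models, params, obj$provenance %||% NA_character_)
}
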