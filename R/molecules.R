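#' Assemble a molecule library
#'
#' A molecule library is a plain `data.frame` with one row per compound and
#' at least the columns `mol_id` (unique identifier) and `smiles`
#' (structure). `ic50_nM` (experimental inhibition, nanomolar) and `mw`
#' (molecular weight, g/mol) are required by the clustering statistics and
#' the YN1 ranking respectively; additional physicochemical property
#' columns (`logp`, `hbd`, `hba`, `rotb`, ...) are carried along and used
#' by the decoy generator when present.
#'
#' @param mol_id character vector of unique identifiers.
#' @param smiles SMILES structure strings.
#' @param ic50_nM optional positive inhibition values (nM).
#' @param mw optional positive molecular weights (g/mol).
#' @param ... further per-molecule columns (recycled by `data.frame`).
#' @return a `data.frame` of class `mol_library`.
#' @export
mol_library <- function(mol_id, smiles, ic50_nM = NULL, mw = NULL, ...) {
  mol_id <- as.character(mol_id)
  if (anyDuplicated(mol_id)) {
    stopf("duplicate mol_id: %s",
          paste(unique(mol_id[duplicated(mol_id)]), collapse = ", "))
  }
  lib <- data.frame(mol_id = mol_id, smiles = as.character(smiles),
                    stringsAsFactors = FALSE)
  if (!is.null(ic50_nM)) {
    if (any(!is.na(ic50_nM) & ic50_nM <= 0)) stopf("ic50_nM must be positive")
    lib$ic50_nM <- as.numeric(ic50_nM)
  }
  if (!is.null(mw)) {
    if (any(!is.na(mw) & mw <= 0)) stopf("mw must be positive")
    lib$mw <- as.numeric(mw)
  }
  extra <- list(...)
  for (nm in names(extra)) lib[[nm]] <- extra[[nm]]
  class(lib) <- c("mol_library", "data.frame")
  lib
}

#' Read a molecule library from CSV, SMILES, or SDF
#'
#' CSV files must carry a header `mol_id,smiles,ic50_nM,mw` (extra columns
#' kept). SMILES files are two-column `smiles<TAB>mol_id`. SDF files are
#' read with ChemmineR; `ic50_nM` and `mw` are taken from the data block
#' when present.
#'
#' @param path file path; format inferred from the extension
#'   (`.csv`, `.smi`/`.smiles`, `.sdf`) unless `format` is given.
#' @param format one of `"csv"`, `"smiles"`, `"sdf"`.
#' @return a `mol_library` data frame.
#' @export
read_mol_library <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", smi = "smiles", smiles = "smiles",
                     sdf = "sdf", stopf("cannot infer format from '%s'", path))
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("mol_id", "smiles") %in% names(df))) {
      stopf("CSV library needs mol_id and smiles columns")
    }
    args <- c(list(mol_id = df$mol_id, smiles = df$smiles,
                   ic50_nM = df$ic50_nM, mw = df$mw),
              df[setdiff(names(df), c("mol_id", "smiles", "ic50_nM", "mw"))])
    return(do.call(mol_library, args))
  }
  if (format == "smiles") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stopf("SMILES file needs 'smiles<TAB>mol_id'")
    return(mol_library(mol_id = df[[2]], smiles = df[[1]]))
  }
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    db <- ChemmineR::datablock(sdf)
    pick <- function(key) {
      vapply(db, function(d) {
        if (key %in% names(d)) as.numeric(d[[key]]) else NA_real_
      }, numeric(1))
    }
    return(mol_library(mol_id = ChemmineR::sdfid(sdf),
                       smiles = as.character(ChemmineR::sdf2smiles(sdf)),
                       ic50_nM = pick("ic50_nM"), mw = pick("mw")))
  }
  stopf("unknown format '%s'", format)
}

#' Write a molecule library to the CSV contract
#' @param lib a `mol_library`.
#' @param path output file.
#' @export
write_mol_library <- function(lib, path) {
  utils::write.csv(as.data.frame(lib), path, row.names = FALSE)
  invisible(path)
}

# Parse SMILES into an SDFset, reporting the offending mol_ids on failure.
# Molecules whose SDF is structurally degenerate (no bonds, e.g. methane)
# are returned as invalid rather than an error; callers treat them as
# empty fingerprints.
parse_smiles <- function(smiles, mol_id) {
  stopifnot(length(smiles) == length(mol_id))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, mol_id))),
    error = function(e) NULL)
  if (is.null(sdf)) {
    bad <- character(0)
    for (i in seq_along(smiles)) {
      ok <- tryCatch({
        suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles[i], mol_id[i])))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) bad <- c(bad, mol_id[i])
    }
    stopf("unparseable structures for: %s", paste(bad, collapse = ", "))
  }
  if (length(sdf) < length(smiles)) {
    # Open Babel silently drops structures it cannot parse
    bad <- setdiff(mol_id, ChemmineR::sdfid(sdf))
    stopf("unparseable structures for: %s", paste(bad, collapse = ", "))
  }
  valid <- suppressWarnings(ChemmineR::validSDF(sdf))
  list(sdf = sdf, valid = valid)
}

#' Compute physicochemical properties from structures
#'
#' Uses Open Babel (via ChemmineOB) for molecular weight, logP, H-bond
#' donor/acceptor counts and TPSA. Rotatable bonds are counted from the
#' connection table as non-ring single bonds between non-terminal heavy
#' atoms (amide bonds are not excluded; the count is approximate).
#'
#' @param lib a `mol_library` or data frame with `mol_id` and `smiles`.
#' @return `lib` with columns `mw`, `logp`, `hbd`, `hba`, `tpsa`, `rotb`
#'   filled in (existing values overwritten).
#' @export
compute_mol_properties <- function(lib) {
  p <- parse_smiles(lib$smiles, lib$mol_id)
  n <- nrow(lib)
  mw <- logp <- tpsa <- rep(NA_real_, n)
  hbd <- hba <- rotb <- rep(NA_integer_, n)
  if (any(p$valid)) {
    pr <- ChemmineR::propOB(p$sdf[p$valid])
    mw[p$valid] <- pr$MW
    logp[p$valid] <- pr$logP
    tpsa[p$valid] <- pr$TPSA
    hbd[p$valid] <- as.integer(pr$HBD)
    hba[p$valid] <- as.integer(pr$HBA1)
    rotb[p$valid] <- vapply(which(p$valid), function(i) {
      count_rotatable(p$sdf[[i]])
    }, integer(1))
  }
  lib$mw <- mw; lib$logp <- logp; lib$hbd <- hbd
  lib$hba <- hba; lib$tpsa <- tpsa; lib$rotb <- rotb
  lib
}

count_rotatable <- function(sdf_mol) {
  bb <- ChemmineR::bondblock(sdf_mol)
  if (is.null(dim(bb)) || nrow(bb) == 0) return(0L)
  from <- bb[, 1]; to <- bb[, 2]; order <- bb[, 3]
  deg <- table(factor(c(from, to), levels = seq_len(max(c(from, to)))))
  ring_bonds <- ring_bond_keys(sdf_mol)
  keys <- paste(pmin(from, to), pmax(from, to))
  sum(order == 1 & !(keys %in% ring_bonds) &
        deg[as.character(from)] > 1 & deg[as.character(to)] > 1)
}

ring_bond_keys <- function(sdf_mol) {
  rings <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf_mol, type = "all", arom = FALSE)),
    error = function(e) NULL)
  if (is.null(rings) || length(rings) == 0) return(character(0))
  out <- character(0)
  for (r in rings) {
    idx <- as.integer(sub("^[^_]*_", "", r))
    m <- length(idx)
    a <- idx; b <- idx[c(2:m, 1)]
    out <- c(out, paste(pmin(a, b), pmax(a, b)))
  }
  unique(out)
}
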