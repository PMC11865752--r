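#' Circular fingerprints for a molecule library
#'
#' Computes hashed circular (ECFP-style) fingerprints through Open Babel.
#' `radius` is the bond radius of the atom environments (radius 2 =
#' ECFP4). Open Babel hashes into 4096 bits; smaller `n_bits` are obtained
#' by folding (OR-ing the two halves), so `n_bits` must be 4096 divided by
#' a power of two. Molecules whose structure parses but has no bonds
#' (single heavy atoms) receive an empty fingerprint.
#'
#' @param lib a `mol_library` or data frame with `mol_id` and `smiles`.
#' @param radius circular environment radius (default 2).
#' @param n_bits fingerprint length after folding (default 2048).
#' @return a logical matrix, one row per molecule, rownames = `mol_id`.
#' @export
fingerprint_matrix <- function(lib, radius = 2, n_bits = 2048) {
  if (anyDuplicated(lib$mol_id)) {
    stopf("duplicate mol_id: %s",
          paste(unique(lib$mol_id[duplicated(lib$mol_id)]), collapse = ", "))
  }
  if (!radius %in% 0:5) stopf("radius must be an integer in 0..5")
  if (!(4096 %% n_bits == 0 && bitwAnd(n_bits, n_bits - 1L) == 0)) {
    stopf("n_bits must be 4096 / 2^j")
  }
  p <- parse_smiles(lib$smiles, lib$mol_id)
  m <- matrix(FALSE, nrow(lib), 4096, dimnames = list(lib$mol_id, NULL))
  if (any(p$valid)) {
    fp <- ChemmineR::fingerprintOB(p$sdf[p$valid],
                                   paste0("ECFP", 2 * radius))
    fpm <- methods::slot(fp, "fpma") > 0
    m[rownames(fpm), ] <- fpm
  }
  while (ncol(m) > n_bits) {
    h <- ncol(m) / 2
    m <- m[, 1:h, drop = FALSE] | m[, (h + 1):(2 * h), drop = FALSE]
  }
  m
}

#' Tanimoto similarity matrix from fingerprints
#'
#' Tanimoto similarity |A intersect B| / |A union B| over fingerprint bit
#' sets. A pair in which one fingerprint is empty has similarity 0; a pair
#' of two empty fingerprints is defined as similarity 1.
#'
#' @param lib a `mol_library`, or a logical fingerprint matrix as returned
#'   by [fingerprint_matrix()].
#' @param radius,n_bits passed to [fingerprint_matrix()] when `lib` is a
#'   library.
#' @return symmetric similarity matrix in \[0, 1\] with unit diagonal,
#'   dimnames = `mol_id`.
#' @export
fingerprint_similarity <- function(lib, radius = 2, n_bits = 2048) {
  fp <- if (is.matrix(lib)) lib else fingerprint_matrix(lib, radius, n_bits)
  tanimoto_matrix(fp)
}

#' Tanimoto similarities between the rows of a bit matrix
#' @param fp logical/0-1 matrix, one fingerprint per row.
#' @return symmetric matrix of Tanimoto similarities.
#' @export
tanimoto_matrix <- function(fp) {
  m <- matrix(as.numeric(fp > 0), nrow(fp), ncol(fp),
              dimnames = dimnames(fp))
  inter <- m %*% t(m)
  n_on <- rowSums(m)
  uni <- outer(n_on, n_on, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 1)  # both-empty pair -> 1
  one_empty <- outer(n_on == 0, n_on == 0, "xor")
  sim[one_empty] <- 0
  diag(sim) <- 1
  sim
}
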