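# ECFP6 fingerprints (radius 3, folded to 2048 bits), Tanimoto similarity,
# all-by-all matrices and nearest-neighbor diversity statistics.

#' Circular-substructure fingerprints
#'
#' Computes radius-3 circular (ECFP6-type) fingerprints hashed and folded to
#' a fixed 2048-bit binary vector per molecule. Deterministic: the same
#' SMILES always yields the same bits.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional row labels (defaults to `smiles`).
#' @return Logical matrix `length(smiles) x 2048`, one row per molecule.
#' @export
morgan_fp <- function(smiles, ids = NULL) {
  stopifnot(length(smiles) >= 1)
  fp <- ob_fp(smiles, nbits = 2048L)
  rownames(fp) <- ids %||% smiles
  fp
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`. When both vectors are all-zero the similarity is
#' defined as 0 with a warning (degenerate case).
#'
#' @param a,b Logical fingerprint vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  un <- sum(a | b)
  if (un == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / un
}

#' All-by-all Tanimoto similarity matrix
#'
#' Builds the square similarity matrix over a set of molecules (typically
#' truncates, or intact BBs for intralibrary similarity). When several BB
#' sets are analyzed together, pass their concatenated SMILES so downstream
#' projections share one joint frame.
#'
#' @param smiles Character vector (length >= 2) of SMILES, or a logical
#'   fingerprint matrix from [morgan_fp()].
#' @param ids Row/column labels; defaults to names or SMILES.
#' @return Symmetric numeric matrix with unit diagonal, entries in `[0, 1]`,
#'   class `c("similarity_matrix", "matrix")`.
#' @export
similarity_matrix <- function(smiles, ids = NULL) {
  fp <- if (is.matrix(smiles)) smiles else morgan_fp(smiles, ids = ids)
  if (nrow(fp) < 2) stop("need at least 2 molecules", call. = FALSE)
  if (!is.null(ids)) rownames(fp) <- ids
  x <- matrix(as.numeric(fp), nrow = nrow(fp))
  inter <- tcrossprod(x)
  nbits <- rowSums(x)
  un <- outer(nbits, nbits, `+`) - inter
  sim <- ifelse(un > 0, inter / un, 0)
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(fp), rownames(fp))
  class(sim) <- c("similarity_matrix", "matrix")
  sim
}

#' Convert similarity to distance
#'
#' Chemical distance is `1 - Tanimoto similarity`, ranging from 0 (identical
#' fingerprints) to 1 (disjoint).
#'
#' @param sim A [similarity_matrix()].
#' @return Matrix of the same shape with zero diagonal.
#' @export
distance_matrix <- function(sim) {
  stopifnot(is.matrix(sim))
  d <- 1 - unclass(sim)
  diag(d) <- 0
  d
}

#' Nearest-neighbor Tanimoto scores
#'
#' For each member of a set, the maximum off-diagonal similarity to any other
#' member; the set median summarizes internal redundancy (higher = more
#' internally similar, lower = more diverse).
#'
#' @param sim A [similarity_matrix()].
#' @param subset Optional character vector of ids restricting the set.
#' @return List with `scores` (named numeric) and `median`.
#' @export
nn_tanimoto <- function(sim, subset = NULL) {
  stopifnot(is.matrix(sim))
  m <- unclass(sim)
  if (!is.null(subset)) {
    miss <- setdiff(subset, rownames(m))
    if (length(miss))
      stop("unknown ids in subset: ", paste(utils::head(miss, 3), collapse = ", "),
           call. = FALSE)
    m <- m[subset, subset, drop = FALSE]
  }
  if (nrow(m) < 2) stop("nearest-neighbor scores need at least 2 members", call. = FALSE)
  diag(m) <- -Inf
  scores <- apply(m, 1L, max)
  list(scores = scores, median = stats::median(scores))
}
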