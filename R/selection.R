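# The three BB selection strategies: random, diversity (greedy max-min on
# fingerprint Tanimoto distance) and uniform (minimum-distance thinning in
# embedding space). All are deterministic given their seed.

new_selection <- function(method, chosen, k, seed, threshold = NA_real_, pool_n) {
  structure(list(method = method, chosen = chosen, k = k, seed = seed,
                 threshold = threshold, pool_n = pool_n),
            class = "bb_selection")
}

#' @export
print.bb_selection <- function(x, ...) {
  cat(sprintf("<bb_selection> %s: %d of %d pool members (seed %d%s)\n",
              x$method, length(x$chosen), x$pool_n, x$seed,
              if (!is.na(x$threshold)) sprintf(", final threshold %.4g", x$threshold)
              else ""))
  invisible(x)
}

#' Random BB selection
#'
#' Uniform sampling without replacement from the (already filtered) pool.
#'
#' @param pool Character vector of candidate ids.
#' @param k Number of BBs to select.
#' @param seed Integer seed; the same seed reproduces the same selection.
#' @return A `bb_selection` with the chosen ids.
#' @export
select_random <- function(pool, k, seed = 1L) {
  if (length(pool) < k)
    stop("pool exhausted: ", length(pool), " candidates for k = ", k, call. = FALSE)
  chosen <- withr::with_seed(seed, sample(pool, k))
  new_selection("random", chosen, k, seed, pool_n = length(pool))
}

#' Diversity (greedy max-min) BB selection
#'
#' Seeds the selection with a randomly chosen pool member, then iteratively
#' adds the candidate whose minimum Tanimoto distance to the already-chosen
#' set is largest (ties broken by lowest pool index), until `k` members are
#' selected. This minimizes nearest-neighbor similarity within the pick.
#'
#' @param sim A [similarity_matrix()] over the pool (row names are the pool
#'   ids), or a precomputed distance matrix via `distance = TRUE`.
#' @param k Number of BBs to select (`1 <= k <=` pool size).
#' @param seed Integer seed determining the starting member.
#' @param distance If `TRUE`, `sim` is already a distance matrix.
#' @return A `bb_selection`; `chosen` is in pick order (first = seed pick).
#' @export
select_diverse <- function(sim, k, seed = 1L, distance = FALSE) {
  stopifnot(is.matrix(sim), k >= 1)
  d <- if (distance) unclass(sim) else 1 - unclass(sim)
  n <- nrow(d)
  ids <- rownames(d) %||% as.character(seq_len(n))
  if (n < k) stop("pool exhausted: ", n, " candidates for k = ", k, call. = FALSE)
  start <- withr::with_seed(seed, sample.int(n, 1L))
  chosen <- integer(k)
  chosen[1L] <- start
  if (k > 1L) {
    mind <- d[, start]
    mind[start] <- -Inf
    for (step in 2:k) {
      nxt <- which.max(mind) # ties -> lowest index
      chosen[step] <- nxt
      mind <- pmin(mind, d[, nxt])
      mind[nxt] <- -Inf
    }
  }
  new_selection("diversity", ids[chosen], k, seed, pool_n = n)
}

#' Uniform BB selection in embedding space
#'
#' Greedy acceptance over a seeded random permutation of the pool: a
#' candidate is accepted when its Euclidean distance in the embedding to
#' every already-accepted point is at least the current threshold. If a full
#' pass accepts fewer than `k` points, the threshold is multiplied by
#' `relax` and the remaining candidates are revisited, until `k` points are
#' accepted or the threshold falls below `floor`.
#'
#' @param embedding A [embed_chemspace()] (or [subset_view()]) covering the
#'   pool.
#' @param k Number of BBs to select.
#' @param threshold Initial minimum distance in embedding units.
#' @param seed Integer seed for the candidate permutation.
#' @param pool Optional id subset of the embedding to select from.
#' @param relax Geometric relaxation factor applied when a pass falls short.
#' @param floor Threshold floor; going below raises a convergence error.
#' @return A `bb_selection`; `threshold` records the final (possibly
#'   relaxed) value, and all pairwise embedded distances among `chosen` are
#'   `>=` that value.
#' @export
select_uniform <- function(embedding, k, threshold, seed = 1L, pool = NULL,
                           relax = 0.9, floor = 1e-6) {
  stopifnot(inherits(embedding, "chem_embedding"), k >= 1, threshold >= 0)
  emb <- if (is.null(pool)) embedding else subset_view(embedding, pool)
  ids <- emb$ids
  n <- length(ids)
  if (n < k) stop("pool exhausted: ", n, " candidates for k = ", k, call. = FALSE)
  perm <- withr::with_seed(seed, sample.int(n))
  xy <- emb$coords
  if (k == n) {
    # selecting the whole pool: the thinning constraint is vacuous; report
    # the realized minimum pairwise distance as the threshold
    pd <- stats::dist(xy)
    return(new_selection("uniform", ids[perm], k, seed,
                         threshold = if (n > 1) min(pd) else threshold,
                         pool_n = n))
  }
  accepted <- integer(0)
  remaining <- perm
  thr <- threshold
  while (length(accepted) < k) {
    still <- integer(0)
    for (i in remaining) {
      if (length(accepted) == k) { still <- c(still, i); next }
      if (!length(accepted)) { accepted <- i; next }
      dmin <- min(sqrt((xy[accepted, 1] - xy[i, 1])^2 +
                       (xy[accepted, 2] - xy[i, 2])^2))
      if (dmin >= thr) accepted <- c(accepted, i) else still <- c(still, i)
    }
    remaining <- still
    if (length(accepted) < k) {
      if (!length(remaining))
        stop("pool exhausted after thinning: ", length(accepted), " < k", call. = FALSE)
      thr <- thr * relax
      if (thr < floor && threshold > 0)
        stop("uniform selection failed to reach k = ", k,
             " before the threshold floor", call. = FALSE)
    }
  }
  new_selection("uniform", ids[accepted], k, seed, threshold = thr, pool_n = n)
}
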