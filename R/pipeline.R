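# End-to-end experiment drivers: truncate-space comparison across BB
# classes, cost/MW stratification, selection-strategy comparison, and the
# cost-tiered 192 x 192 library comparison. Each returns a structured
# report; every figure-ready quantity is available as a table.

#' Compare truncate chemical space across BB classes
#'
#' Truncates each catalog (after the nitrogen-chemotype class filter),
#' builds one joint similarity matrix and embedding over all truncates, and
#' reports per-class truncate counts, unique-truncate tallies and pairwise
#' overlap/unique counts (the Venn-style comparison), plus per-class
#' embedding views.
#'
#' @param catalogs Named list of [bb_catalog()]s (e.g. from
#'   [generate_paired_catalogs()]).
#' @param seed Seed recorded in the embedding.
#' @return A `bb_report` list: `counts`, `overlaps`, `embedding`, `views`,
#'   `unique_sets`, `truncates`.
#' @export
run_truncate_space_comparison <- function(catalogs, seed = 42L) {
  stopifnot(is.list(catalogs), length(catalogs) >= 2, !is.null(names(catalogs)))
  trunc <- lapply(names(catalogs), function(nm) {
    cf <- class_filter(catalogs[[nm]])
    tr <- truncate_catalog(cf$catalog)
    tr <- tr[!is.na(tr$smiles), , drop = FALSE]
    tr$set <- nm
    tr
  })
  names(trunc) <- names(catalogs)
  uniq <- lapply(trunc, function(tr) unique_truncates(tr$smiles))
  sets <- lapply(uniq, `[[`, "smiles")
  nms <- names(catalogs)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  overlaps <- do.call(rbind, lapply(pairs, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    data.frame(set_a = p[1], set_b = p[2],
               n_a = length(a), n_b = length(b),
               shared = length(intersect(a, b)),
               unique_a = length(setdiff(a, b)),
               unique_b = length(setdiff(b, a)))
  }))
  all_tr <- do.call(rbind, trunc)
  ids <- sprintf("%s:%s", all_tr$set, all_tr$parent_id)
  sim <- similarity_matrix(all_tr$smiles, ids = ids)
  emb <- embed_chemspace(distance_matrix(sim), seed = seed)
  views <- lapply(nms, function(nm) subset_view(emb, ids[all_tr$set == nm]))
  names(views) <- nms
  counts <- data.frame(
    set = nms,
    n_bb = vapply(catalogs, nrow, integer(1)),
    n_truncates = vapply(trunc, nrow, integer(1)),
    n_unique_truncates = vapply(uniq, nrow, integer(1)))
  structure(list(counts = counts, overlaps = overlaps, embedding = emb,
                 views = views, unique_sets = uniq, truncates = all_tr),
            class = "bb_report")
}

#' Stratify a catalog by cost or molecular weight
#'
#' Applies ascending thresholds along one axis (cost per 250 mg pack, or the
#' inclusive MW cutoff; Fmoc-AAs weighed ignoring Fmoc) and reports
#' per-threshold retained counts and fractions. The filtered sets are nested
#' by construction.
#'
#' @param catalog A [bb_catalog()].
#' @param axis `"cost"` or `"mw"`.
#' @param thresholds Ascending numeric thresholds (defaults: cost
#'   `c(100, 250, 500)` USD; mw `c(200, 250, 300)` Da).
#' @return A `bb_report` list: `table` (threshold, n_retained,
#'   retained_fraction) and `members` (id lists per threshold).
#' @export
run_stratification <- function(catalog, axis = c("cost", "mw"),
                               thresholds = NULL) {
  axis <- match.arg(axis)
  if (is.null(thresholds))
    thresholds <- if (axis == "cost") c(100, 250, 500) else c(200, 250, 300)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending", call. = FALSE)
  members <- lapply(thresholds, function(t) {
    f <- if (axis == "cost") cost_filter(catalog, t)
         else pcp_filter(catalog, "mw_cutoff", mw_cutoff = t)
    f$catalog$id
  })
  names(members) <- as.character(thresholds)
  tab <- data.frame(threshold = thresholds,
                    n_retained = lengths(members),
                    retained_fraction = lengths(members) / nrow(catalog))
  structure(list(axis = axis, n_total = nrow(catalog), table = tab,
                 members = members), class = "bb_report")
}

#' Compare the three BB selection strategies on one pool
#'
#' Runs random, diversity and uniform selection of `k` BBs from the
#' class-filtered pool and summarizes each pick's nearest-neighbor Tanimoto
#' scores (fingerprints on intact BB structures) and, for the uniform
#' method, the realized embedding-space threshold.
#'
#' @param catalog Pool [bb_catalog()].
#' @param k Number of BBs per selection (the default 192 is two 96-well
#'   plates).
#' @param seed Integer seed shared by the three methods.
#' @param uniform_threshold Initial minimum embedded distance; default is
#'   set from the pool's coordinate spread.
#' @param sim Optional precomputed [similarity_matrix()] over the pool ids.
#' @param embedding Optional precomputed joint embedding covering the pool.
#' @return A `bb_report` list: `selections`, `nn_medians`, `sim`,
#'   `embedding`.
#' @export
run_selection_comparison <- function(catalog, k = 192L, seed = 1L,
                                     uniform_threshold = NULL, sim = NULL,
                                     embedding = NULL) {
  pool <- class_filter(catalog)$catalog
  if (nrow(pool) < k)
    stop("pool after filtering (", nrow(pool), ") smaller than k = ", k,
         call. = FALSE)
  if (is.null(sim)) sim <- similarity_matrix(pool$smiles, ids = pool$id)
  if (is.null(embedding)) embedding <- embed_chemspace(distance_matrix(sim),
                                                       seed = seed)
  if (is.null(uniform_threshold)) {
    spread <- mean(apply(embedding$coords, 2, stats::sd))
    uniform_threshold <- spread * sqrt(nrow(pool) / k) / 2
  }
  sel <- list(
    random = select_random(pool$id, k, seed = seed),
    diversity = select_diverse(sim, k, seed = seed),
    uniform = select_uniform(embedding, k, threshold = uniform_threshold,
                             seed = seed, pool = pool$id))
  nn <- vapply(sel, function(s) nn_tanimoto(sim, subset = s$chosen)$median,
               numeric(1))
  structure(list(selections = sel, nn_medians = nn, sim = sim,
                 embedding = embedding, k = k, seed = seed),
            class = "bb_report")
}

#' Cost-tiered two-cycle library comparison
#'
#' For each cost tier: filter both cycles by cost and by the MW cutoff
#' (inclusive, default 250 Da), randomly select `k` BBs per cycle, enumerate
#' the full library, and report product property summaries, per-cycle
#' median nearest-neighbor Tanimoto (intact-BB fingerprints), and total BB
#' cost per cycle. With `replicates > 1`, the BB selection and nn-Tanimoto
#' medians are re-sampled over consecutive seeds (the enumeration-based
#' product summary uses the base seed).
#'
#' @param amine_catalog,acid_catalog [bb_catalog()]s for cycles 1 and 2.
#' @param cost_tiers Ascending cost ceilings (USD per 250 mg).
#' @param mw_cutoff Inclusive BB MW cutoff in Da.
#' @param k BBs per cycle per tier.
#' @param seed Base seed.
#' @param replicates Number of selection replicates per tier.
#' @return A `bb_report` list with one entry per tier: selection ids, the
#'   `del_library`, `pcp_summary`, `nn_median_amine`, `nn_median_acid`,
#'   `total_cost_amine`, `total_cost_acid`, `replicate_nn` table; plus the
#'   overall `tiers` summary data.frame. Tiers whose filtered pool is
#'   smaller than `k` are reported as skipped, and the run continues.
#' @export
run_library_comparison <- function(amine_catalog, acid_catalog,
                                   cost_tiers = c(100, 250, 500),
                                   mw_cutoff = 250, k = 192L, seed = 1L,
                                   replicates = 1L) {
  stopifnot(catalog_class(amine_catalog) == "PRIMARY_AMINE",
            catalog_class(acid_catalog) == "CARBOXYLIC_ACID")
  pool_am <- class_filter(amine_catalog)$catalog
  pool_ac <- class_filter(acid_catalog)$catalog
  pool_am <- pcp_filter(pool_am, "mw_cutoff", mw_cutoff = mw_cutoff)$catalog
  pool_ac <- pcp_filter(pool_ac, "mw_cutoff", mw_cutoff = mw_cutoff)$catalog
  sim_am <- similarity_matrix(pool_am$smiles, ids = pool_am$id)
  sim_ac <- similarity_matrix(pool_ac$smiles, ids = pool_ac$id)

  tiers <- vector("list", length(cost_tiers))
  names(tiers) <- paste0("<=", cost_tiers)
  for (t in seq_along(cost_tiers)) {
    am <- cost_filter(pool_am, cost_tiers[t])$catalog
    ac <- cost_filter(pool_ac, cost_tiers[t])$catalog
    if (nrow(am) < k || nrow(ac) < k) {
      tiers[[t]] <- list(skipped = TRUE,
                         reason = sprintf("pool exhausted (%d amines, %d acids, k = %d)",
                                          nrow(am), nrow(ac), k))
      next
    }
    sel_am <- select_random(am$id, k, seed = seed)
    sel_ac <- select_random(ac$id, k, seed = seed + 1L)
    cyc1 <- catalog_subset(am, match(sel_am$chosen, am$id))
    cyc2 <- catalog_subset(ac, match(sel_ac$chosen, ac$id))
    lib <- enumerate_library(library_design("DEL2", cyc1, cyc2))
    reps <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      s1 <- select_random(am$id, k, seed = seed + 10L * r)
      s2 <- select_random(ac$id, k, seed = seed + 10L * r + 1L)
      data.frame(replicate = r,
                 nn_median_amine = nn_tanimoto(sim_am, subset = s1$chosen)$median,
                 nn_median_acid = nn_tanimoto(sim_ac, subset = s2$chosen)$median)
    }))
    tiers[[t]] <- list(
      skipped = FALSE,
      selection_amine = sel_am, selection_acid = sel_ac,
      library = lib,
      pcp_summary = library_pcp_summary(lib),
      nn_median_amine = nn_tanimoto(sim_am, subset = sel_am$chosen)$median,
      nn_median_acid = nn_tanimoto(sim_ac, subset = sel_ac$chosen)$median,
      total_cost_amine = sum(cyc1$cost),
      total_cost_acid = sum(cyc2$cost),
      replicate_nn = reps)
  }
  done <- !vapply(tiers, `[[`, logical(1), "skipped")
  summary_tab <- data.frame(
    tier = cost_tiers,
    skipped = !done,
    n_products = vapply(tiers, function(x)
      if (isTRUE(x$skipped)) NA_integer_ else nrow(x$library$products), integer(1)),
    nn_median_amine = vapply(tiers, function(x)
      if (isTRUE(x$skipped)) NA_real_ else x$nn_median_amine, numeric(1)),
    nn_median_acid = vapply(tiers, function(x)
      if (isTRUE(x$skipped)) NA_real_ else x$nn_median_acid, numeric(1)),
    total_cost_amine = vapply(tiers, function(x)
      if (isTRUE(x$skipped)) NA_real_ else x$total_cost_amine, numeric(1)),
    total_cost_acid = vapply(tiers, function(x)
      if (isTRUE(x$skipped)) NA_real_ else x$total_cost_acid, numeric(1)))
  structure(list(tiers = tiers, summary = summary_tab, k = k, seed = seed,
                 mw_cutoff = mw_cutoff), class = "bb_report")
}

#' Compare enumerated products against a reference compound set
#'
#' Intra-set and cross-set nearest-neighbor Tanimoto distributions for a
#' (sampled) product set versus a user-supplied reference collection, e.g.
#' a lead-like screening set.
#'
#' @param products Product SMILES (or a `del_library`).
#' @param reference_smiles Non-empty character vector of reference SMILES.
#' @param sample_fraction Fraction of products sampled for the comparison.
#' @param seed Sampling seed.
#' @return A `bb_report` list with `cross` (per-product max similarity to
#'   the reference), `intra_products`, `intra_reference` and their medians.
#' @export
compare_to_reference <- function(products, reference_smiles,
                                 sample_fraction = 1, seed = 1L) {
  if (inherits(products, "del_library")) products <- products$products$smiles
  if (!length(reference_smiles)) stop("empty reference set", call. = FALSE)
  stopifnot(sample_fraction > 0, sample_fraction <= 1)
  if (sample_fraction < 1) {
    n <- max(2L, round(length(products) * sample_fraction))
    products <- withr::with_seed(seed, sample(products, n))
  }
  fp_p <- morgan_fp(products, ids = sprintf("p%d", seq_along(products)))
  fp_r <- morgan_fp(reference_smiles, ids = sprintf("r%d", seq_along(reference_smiles)))
  xp <- matrix(as.numeric(fp_p), nrow = nrow(fp_p))
  xr <- matrix(as.numeric(fp_r), nrow = nrow(fp_r))
  inter <- tcrossprod(xp, xr)
  un <- outer(rowSums(xp), rowSums(xr), `+`) - inter
  cross <- apply(ifelse(un > 0, inter / un, 0), 1L, max)
  intra <- function(fp) {
    if (nrow(fp) < 2) return(NA_real_)
    nn_tanimoto(similarity_matrix(fp))$median
  }
  structure(list(cross = cross, cross_median = stats::median(cross),
                 intra_products = intra(fp_p), intra_reference = intra(fp_r)),
            class = "bb_report")
}

#' @export
print.bb_report <- function(x, ...) {
  cat("<bb_report>\n")
  flat <- x[vapply(x, function(el) is.data.frame(el) || (is.atomic(el) && length(el) <= 12),
                   logical(1))]
  for (nm in names(flat)) {
    cat("$", nm, "\n", sep = "")
    print(flat[[nm]])
    cat("\n")
  }
  invisible(x)
}
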