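# Truncation (defining functional group -> H) and the catalog filters:
# class (SMARTS), cost, and physicochemical property rules.

# perform the class-specific removals on one molgraph; returns
# list(mol, n_replaced) or an error condition message in $error
truncate_mol <- function(mol, bb_class) {
  n_replaced <- 0L
  if (bb_class == "FMOC_AA") {
    # remove the Fmoc carbamate wholesale (N-side retained), then the freed
    # amine and the carboxylic acid, all simultaneously with respect to the
    # original structure
    carb <- find_carbamates(mol)
    drop <- integer(0)
    for (cb in carb) {
      side <- mol_component_of(mol, cb$C, blocked = cb$N)
      drop <- c(drop, cb$N, side)
      n_replaced <- n_replaced + 1L
    }
    cooh <- find_cooh(mol)
    for (g in cooh) {
      drop <- c(drop, g)
      n_replaced <- n_replaced + 1L
    }
    # any free primary amines too (deprotected inputs)
    am <- find_primary_amines(mol)
    drop <- c(drop, am)
    n_replaced <- n_replaced + length(am)
    if (!length(drop)) return(list(error = "no_defining_group"))
    mol <- mol_delete_atoms(mol, drop)
  } else if (bb_class == "PRIMARY_AMINE") {
    am <- find_primary_amines(mol)
    if (!length(am)) return(list(error = "no_defining_group"))
    n_replaced <- length(am)
    mol <- mol_delete_atoms(mol, am)
  } else {
    cooh <- find_cooh(mol)
    if (!length(cooh)) return(list(error = "no_defining_group"))
    n_replaced <- length(cooh)
    mol <- mol_delete_atoms(mol, unlist(cooh))
  }
  if (length(mol$elem) == 0) return(list(error = "empty_truncate"))
  if (mol_n_components(mol) != 1) return(list(error = "disconnected_truncate"))
  list(mol = mol, n_replaced = n_replaced)
}

#' Truncate a single building block
#'
#' Replaces every instance of the class's defining functional group(s) with
#' hydrogen: amines lose -NH2, acids lose -COOH, and Fmoc-amino acids lose
#' the whole Fmoc carbamate, the (freed) alpha-amine and the -COOH. The
#' result isolates the diversity scaffold used for similarity analysis.
#'
#' @param smiles A single SMILES string.
#' @param bb_class One of [bb_classes()].
#' @return A list with `smiles` (canonical truncate), `n_replaced` (instances
#'   replaced) and `polyfunctional` (`TRUE` when more than one defining-group
#'   instance was replaced).
#' @examples
#' \dontrun{
#' truncate_bb("CCN", "PRIMARY_AMINE")          # ethylamine -> ethane
#' truncate_bb("OC(=O)c1ccccc1", "CARBOXYLIC_ACID")  # benzoic acid -> benzene
#' }
#' @export
truncate_bb <- function(smiles, bb_class) {
  bb_class <- match_bb_class(bb_class)
  stopifnot(length(smiles) == 1)
  mol <- mols_from_smiles(smiles)[[1]]
  res <- truncate_mol(mol, bb_class)
  if (!is.null(res$error))
    stop("truncation failed (", res$error, ") for: ", smiles, call. = FALSE)
  out <- mols_to_smiles(list(res$mol))
  poly_thresh <- if (bb_class == "FMOC_AA") 2L else 1L
  list(smiles = out, n_replaced = res$n_replaced,
       polyfunctional = res$n_replaced > poly_thresh)
}

#' Truncate every member of a catalog
#'
#' Vectorized [truncate_bb()] over a catalog. Members whose truncation fails
#' (for example, disconnected results) are reported with an `NA` truncate and
#' a reason; nothing is silently dropped.
#'
#' @param catalog A [bb_catalog()].
#' @return data.frame with columns `parent_id`, `smiles` (canonical truncate,
#'   `NA` on failure), `n_replaced`, `polyfunctional`, `reason` (`NA` unless
#'   failed).
#' @export
truncate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "bb_catalog"))
  bb_class <- catalog_class(catalog)
  n <- nrow(catalog)
  if (n == 0)
    return(data.frame(parent_id = character(0), smiles = character(0),
                      n_replaced = integer(0), polyfunctional = logical(0),
                      reason = character(0)))
  mols <- mols_from_smiles(catalog$smiles)
  res <- lapply(mols, truncate_mol, bb_class = bb_class)
  failed <- vapply(res, function(r) !is.null(r$error), logical(1))
  smi <- rep(NA_character_, n)
  if (any(!failed))
    smi[!failed] <- mols_to_smiles(lapply(res[!failed], `[[`, "mol"))
  nrep <- vapply(res, function(r) if (is.null(r$error)) r$n_replaced else NA_integer_,
                 integer(1))
  poly_thresh <- if (bb_class == "FMOC_AA") 2L else 1L
  data.frame(parent_id = catalog$id, smiles = smi, n_replaced = nrep,
             polyfunctional = !is.na(nrep) & nrep > poly_thresh,
             reason = ifelse(failed,
                             vapply(res, function(r) r$error %||% NA_character_,
                                    character(1)),
                             NA_character_),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove the Fmoc protecting group
#'
#' Cleaves the fluorenylmethyloxycarbonyl carbamate, leaving the free
#' primary amine. Used for the "ignoring Fmoc" molecular weight convention
#' and to prepare Fmoc-amino acids for coupling.
#'
#' @param smiles Character vector of Fmoc-protected SMILES.
#' @return Character vector of canonical deprotected SMILES.
#' @export
remove_fmoc <- function(smiles) {
  if (!length(smiles)) return(character(0))
  mols <- mols_from_smiles(smiles)
  out <- lapply(seq_along(mols), function(i) {
    mol <- mols[[i]]
    carb <- find_carbamates(mol)
    if (!length(carb))
      stop("no Fmoc-type carbamate found in: ", smiles[i], call. = FALSE)
    drop <- integer(0)
    for (cb in carb) drop <- c(drop, mol_component_of(mol, cb$C, blocked = cb$N))
    mol_delete_atoms(mol, drop)
  })
  mols_to_smiles(out)
}

new_filter_report <- function(n_in, rejected) {
  structure(list(n_in = n_in, n_out = n_in - nrow(rejected), rejected = rejected),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d in, %d out, %d rejected\n",
              x$n_in, x$n_out, nrow(x$rejected)))
  if (nrow(x$rejected)) print(table(x$rejected$reason))
  invisible(x)
}

apply_filter <- function(catalog, keep, reasons) {
  rejected <- data.frame(id = catalog$id[!keep],
                         reason = reasons[!keep], stringsAsFactors = FALSE)
  list(catalog = catalog_subset(catalog, which(keep)),
       report = new_filter_report(nrow(catalog), rejected))
}

#' Filter out unsuitable nitrogen chemotypes
#'
#' Removes building blocks containing secondary amines, proline-like
#' secondary amino acids, or aniline nitrogens (substructure patterns in
#' [bb_class_patterns()]`$reject`). These chemotypes either compete in, or
#' are unreactive toward, the amide-forming chemistry.
#'
#' @param catalog A [bb_catalog()].
#' @return List with the filtered `catalog` and a `report`
#'   (class `filter_report`, with per-id rejection reasons).
#' @export
class_filter <- function(catalog) {
  stopifnot(inherits(catalog, "bb_catalog"))
  pats <- bb_class_patterns()$reject
  reasons <- rep(NA_character_, nrow(catalog))
  if (nrow(catalog)) {
    for (nm in names(pats)) {
      hit <- ob_matches(catalog$smiles, pats[[nm]])
      reasons[is.na(reasons) & hit] <- nm
    }
  }
  apply_filter(catalog, is.na(reasons), reasons)
}

#' Filter by cost per 250 mg pack
#'
#' Retains members with known cost `<= max_cost` (boundary inclusive).
#' Members with missing cost are rejected with reason `"cost_missing"` — the
#' conservative purchasing assumption.
#'
#' @param catalog A [bb_catalog()].
#' @param max_cost Positive cost ceiling in USD per 250 mg; `Inf` keeps every
#'   member with a known cost.
#' @return List of filtered `catalog` and `report`, as [class_filter()].
#' @export
cost_filter <- function(catalog, max_cost) {
  stopifnot(inherits(catalog, "bb_catalog"), max_cost > 0)
  missing <- is.na(catalog$cost)
  over <- !missing & catalog$cost > max_cost
  reasons <- rep(NA_character_, nrow(catalog))
  reasons[missing] <- "cost_missing"
  reasons[over] <- "cost_above_threshold"
  apply_filter(catalog, !missing & !over, reasons)
}

#' Filter by physicochemical property rule
#'
#' Applies rule-of-3 (`MW < 300, clogP <= 3, HBD <= 3, HBA <= 3`), rule-of-5
#' (`MW < 500, clogP < 5, HBD <= 5, HBA <= 10`) — both with strict MW
#' bounds — or a standalone inclusive MW cutoff (`MW <= mw_cutoff`). For
#' Fmoc-amino acids every MW comparison uses the weight of the Fmoc-removed
#' form.
#'
#' @param catalog A [bb_catalog()].
#' @param rule `"RO3"`, `"RO5"`, or `"mw_cutoff"`.
#' @param mw_cutoff Cutoff in Da, required when `rule = "mw_cutoff"`.
#' @return List of filtered `catalog` and `report`, as [class_filter()].
#' @export
pcp_filter <- function(catalog, rule = c("RO3", "RO5", "mw_cutoff"),
                       mw_cutoff = NULL) {
  stopifnot(inherits(catalog, "bb_catalog"))
  rule <- match.arg(rule)
  mw <- effective_mw(catalog)
  keep <- switch(rule,
    RO3 = mw < 300 & catalog$clogp <= 3 & catalog$hbd <= 3 & catalog$hba <= 3,
    RO5 = mw < 500 & catalog$clogp < 5 & catalog$hbd <= 5 & catalog$hba <= 10,
    mw_cutoff = {
      if (is.null(mw_cutoff)) stop("mw_cutoff must be supplied", call. = FALSE)
      mw <= mw_cutoff
    })
  reasons <- ifelse(keep, NA_character_, paste0("fails_", tolower(rule)))
  apply_filter(catalog, keep, reasons)
}

# MW used in property filtering; Fmoc-AAs are weighed in deprotected form
effective_mw <- function(catalog) {
  if (catalog_class(catalog) != "FMOC_AA" || nrow(catalog) == 0)
    return(catalog$mw)
  if (!is.null(catalog$mw_nofmoc)) return(catalog$mw_nofmoc)
  dep <- remove_fmoc(catalog$smiles)
  ob_props(dep)$mw
}

#' Deduplicate truncates with multiplicity
#'
#' Collapses a set of canonical truncate SMILES to unique structures while
#' preserving how many parents map to each (depth-vs-breadth analysis).
#'
#' @param truncate_smiles Character vector of canonical truncate SMILES
#'   (e.g. the `smiles` column of [truncate_catalog()]; `NA`s are dropped).
#' @return data.frame with columns `smiles` and `multiplicity`, ordered by
#'   decreasing multiplicity.
#' @export
unique_truncates <- function(truncate_smiles) {
  truncate_smiles <- truncate_smiles[!is.na(truncate_smiles)]
  if (!length(truncate_smiles))
    return(data.frame(smiles = character(0), multiplicity = integer(0)))
  tab <- table(truncate_smiles)
  out <- data.frame(smiles = names(tab), multiplicity = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$multiplicity, out$smiles), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
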