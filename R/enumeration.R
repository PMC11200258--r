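# Two-cycle library enumeration: amide coupling of cycle-1 amines with
# cycle-2 acids, product property calculation, and the DEL1-vs-DEL2
# constant-adduct comparison.

WATER_MW <- 18.0153 # average atomic weights

# prepare a molgraph for coupling: locate the unique reactive sites
coupling_sites <- function(mol, role = c("amine", "acid")) {
  role <- match.arg(role)
  if (role == "amine") {
    sites <- find_primary_amines(mol, aliphatic_only = TRUE)
    if (length(sites) != 1)
      return(list(error = if (length(sites)) "multiple_amine_sites" else "no_amine_site"))
    list(site = sites[[1]])
  } else {
    sites <- find_cooh(mol)
    if (length(sites) != 1)
      return(list(error = if (length(sites)) "multiple_acid_sites" else "no_acid_site"))
    list(site = sites[[1]])
  }
}

# graph-level condensation: amine N bonds to the acid carbonyl carbon, the
# acid hydroxyl leaves as water
couple_mols <- function(amine_mol, n_idx, acid_mol, cooh) {
  acyl <- mol_delete_atoms(acid_mol, cooh[["OH"]])
  shift <- function(i) i - as.integer(cooh[["OH"]] < i)
  merged <- mol_merge(amine_mol, acyl)
  mol_add_bond(merged, n_idx, length(amine_mol$elem) + shift(cooh[["C"]]), 1L)
}

#' Couple an amine and a carboxylic acid to an amide
#'
#' Condensation with loss of water. The amine must contain exactly one
#' primary aliphatic amine and the acid exactly one carboxylic acid, so the
#' product is unique; violations raise an ambiguity error naming the input.
#'
#' @param amine_smiles,acid_smiles Single SMILES strings.
#' @return Canonical SMILES of the amide product.
#' @examples
#' \dontrun{
#' couple_amide("CCN", "CC(=O)O") # N-ethylacetamide
#' }
#' @export
couple_amide <- function(amine_smiles, acid_smiles) {
  mols <- mols_from_smiles(c(amine_smiles, acid_smiles))
  am <- coupling_sites(mols[[1]], "amine")
  if (!is.null(am$error))
    stop("ambiguous or missing reaction site (", am$error, ") in amine: ",
         amine_smiles, call. = FALSE)
  ac <- coupling_sites(mols[[2]], "acid")
  if (!is.null(ac$error))
    stop("ambiguous or missing reaction site (", ac$error, ") in acid: ",
         acid_smiles, call. = FALSE)
  prod <- couple_mols(mols[[1]], am$site, mols[[2]], ac$site)
  if (mol_n_components(prod) != 1)
    stop("coupling produced a disconnected structure", call. = FALSE)
  mols_to_smiles(list(prod))
}

#' Define a two-cycle library design
#'
#' `DEL2` couples primary amines (cycle 1) with carboxylic acids (cycle 2)
#' and the released product carries only the BB-connecting amide. `DEL1`
#' uses Fmoc-amino acids in cycle 1 (deprotected at enumeration time) and
#' every released product additionally carries the pendant primary amide
#' -C(=O)NH2 left by photocleavage at the amino acid's carboxylate.
#'
#' @param scheme `"DEL1"` or `"DEL2"`.
#' @param cycle1,cycle2 [bb_catalog()]s of the appropriate classes (cycle 2
#'   is always carboxylic acids).
#' @return A `library_design` list.
#' @export
library_design <- function(scheme = c("DEL2", "DEL1"), cycle1, cycle2) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cycle1, "bb_catalog"), inherits(cycle2, "bb_catalog"))
  want1 <- if (scheme == "DEL1") "FMOC_AA" else "PRIMARY_AMINE"
  if (catalog_class(cycle1) != want1)
    stop(scheme, " cycle 1 must be a ", want1, " catalog", call. = FALSE)
  if (catalog_class(cycle2) != "CARBOXYLIC_ACID")
    stop("cycle 2 must be a CARBOXYLIC_ACID catalog", call. = FALSE)
  if (nrow(cycle1) == 0 || nrow(cycle2) == 0)
    stop("both cycles must be non-empty", call. = FALSE)
  structure(list(scheme = scheme, cycle1 = cycle1, cycle2 = cycle2),
            class = "library_design")
}

# cycle-1 preprocessing for DEL1: deprotect the Fmoc amine and convert the
# alpha-carboxylate to the pendant primary amide (the photocleavage product)
prepare_cycle1 <- function(design) {
  cat1 <- design$cycle1
  if (design$scheme == "DEL2") return(cat1$smiles)
  mols <- mols_from_smiles(cat1$smiles)
  res <- rep(NA_character_, length(mols))
  mols2 <- vector("list", length(mols))
  ok <- logical(length(mols))
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    carb <- find_carbamates(mol)
    if (length(carb) != 1) next
    mol <- mol_delete_atoms(mol, mol_component_of(mol, carb[[1]]$C,
                                                  blocked = carb[[1]]$N))
    cooh <- find_cooh(mol)
    if (length(cooh) != 1) next
    mols2[[i]] <- mol_set_elem(mol, cooh[[1]][["OH"]], "N") # -COOH -> -C(=O)NH2
    ok[i] <- TRUE
  }
  if (any(ok)) res[ok] <- mols_to_smiles(mols2[ok])
  res
}

#' Enumerate all products of a two-cycle library
#'
#' Full cross product: one amide product per (cycle-1, cycle-2) pair, with
#' physicochemical properties computed for every product. Pairs that cannot
#' be coupled (ambiguous or missing reaction sites, disconnected results)
#' are logged in the `failures` element, never silently dropped, so
#' `nrow(products) == n1 * n2 - nrow(failures)`.
#'
#' @param design A [library_design()].
#' @return Object of class `del_library`: list with `products` (data.frame:
#'   `amine_id`, `acid_id`, `smiles`, `mw`, `clogp`, `tpsa`, `hbd`, `hba`),
#'   `failures` (data.frame: `amine_id`, `acid_id`, `reason`) and `design`
#'   metadata.
#' @export
enumerate_library <- function(design) {
  stopifnot(inherits(design, "library_design"))
  cyc1_smiles <- prepare_cycle1(design)
  cyc2_smiles <- design$cycle2$smiles
  id1 <- design$cycle1$id
  id2 <- design$cycle2$id

  fail1 <- is.na(cyc1_smiles)
  amol <- vector("list", length(cyc1_smiles))
  asite <- rep(NA_integer_, length(cyc1_smiles))
  areason <- ifelse(fail1, "cycle1_preparation_failed", NA_character_)
  if (any(!fail1)) {
    mols <- mols_from_smiles(cyc1_smiles[!fail1])
    j <- 0L
    for (i in which(!fail1)) {
      j <- j + 1L
      s <- coupling_sites(mols[[j]], "amine")
      if (is.null(s$error)) { amol[[i]] <- mols[[j]]; asite[i] <- s$site }
      else areason[i] <- s$error
    }
  }
  cmols <- mols_from_smiles(cyc2_smiles)
  csite <- vector("list", length(cyc2_smiles))
  creason <- rep(NA_character_, length(cyc2_smiles))
  for (i in seq_along(cmols)) {
    s <- coupling_sites(cmols[[i]], "acid")
    if (is.null(s$error)) csite[[i]] <- s$site else creason[i] <- s$error
  }

  ok1 <- is.na(areason)
  ok2 <- is.na(creason)
  failures <- rbind(
    if (any(!ok1)) data.frame(amine_id = rep(id1[!ok1], each = length(id2)),
                              acid_id = rep(id2, sum(!ok1)),
                              reason = rep(areason[!ok1], each = length(id2))),
    if (any(ok1) && any(!ok2))
      data.frame(amine_id = rep(id1[ok1], each = sum(!ok2)),
                 acid_id = rep(id2[!ok2], sum(ok1)),
                 reason = rep(creason[!ok2], sum(ok1)))
  )
  if (is.null(failures))
    failures <- data.frame(amine_id = character(0), acid_id = character(0),
                           reason = character(0))

  # assemble one molblock per valid pair and run a single property pass
  records <- character(0)
  titles <- character(0)
  if (any(ok1) && any(ok2)) {
    acyl <- lapply(which(ok2), function(i) {
      g <- csite[[i]]
      m <- mol_delete_atoms(cmols[[i]], g[["OH"]])
      list(mol = m, C = g[["C"]] - as.integer(g[["OH"]] < g[["C"]]))
    })
    aidx <- which(ok1)
    blocks <- vector("list", length(aidx))
    for (ii in seq_along(aidx)) {
      i <- aidx[ii]
      a <- amol[[i]]
      na <- length(a$elem)
      pair_lines <- lapply(seq_along(acyl), function(jj) {
        b <- acyl[[jj]]$mol
        bonds <- rbind(a$bonds,
                       cbind(b$bonds[, 1:2, drop = FALSE] + na,
                             b$bonds[, 3, drop = FALSE]),
                       c(asite[i], na + acyl[[jj]]$C, 1L))
        mol <- list(elem = c(a$elem, b$elem), bonds = bonds)
        mol_to_molblock_lines(mol, title = sprintf("%d_%d", i, which(ok2)[jj]))
      })
      blocks[[ii]] <- unlist(pair_lines)
    }
    records <- unlist(blocks)
    titles <- sprintf("%d_%d", rep(aidx, each = sum(ok2)),
                      rep(which(ok2), length(aidx)))
  }
  products <- data.frame(amine_id = character(0), acid_id = character(0),
                         smiles = character(0), mw = numeric(0),
                         clogp = numeric(0), tpsa = numeric(0),
                         hbd = integer(0), hba = integer(0))
  if (length(titles)) {
    props <- ob_props(records, input = "sdf")
    m <- match(titles, rownames(props))
    bad <- is.na(m) | is.na(props$cansmi[m])
    if (any(bad)) {
      ij <- strsplit(titles[bad], "_", fixed = TRUE)
      failures <- rbind(failures, data.frame(
        amine_id = id1[as.integer(vapply(ij, `[`, "", 1L))],
        acid_id = id2[as.integer(vapply(ij, `[`, "", 2L))],
        reason = "product_canonicalization_failed"))
    }
    keep <- !bad
    ij <- strsplit(titles[keep], "_", fixed = TRUE)
    mk <- m[keep]
    products <- data.frame(
      amine_id = id1[as.integer(vapply(ij, `[`, "", 1L))],
      acid_id = id2[as.integer(vapply(ij, `[`, "", 2L))],
      smiles = props$cansmi[mk], mw = props$mw[mk], clogp = props$clogp[mk],
      tpsa = props$tpsa[mk], hbd = props$hbd[mk], hba = props$hba[mk],
      stringsAsFactors = FALSE)
  }
  structure(list(products = products, failures = failures,
                 scheme = design$scheme,
                 n_cycle1 = nrow(design$cycle1), n_cycle2 = nrow(design$cycle2)),
            class = "del_library")
}

#' @export
print.del_library <- function(x, ...) {
  cat(sprintf("<del_library> %s: %d x %d -> %d products (%d failure(s))\n",
              x$scheme, x$n_cycle1, x$n_cycle2, nrow(x$products),
              nrow(x$failures)))
  invisible(x)
}

#' Constant-adduct property difference between two designs
#'
#' Every DEL1 product carries the pendant primary amide -C(=O)NH2 left by
#' photocleavage; DEL2 products carry no constant adduct beyond the
#' BB-connecting amide. The difference is computed from the adduct fragment
#' itself (composition CH2NO): its formula weight, and the donor/acceptor
#' counts of the capped fragment under the package's counting conventions.
#'
#' @param design_a,design_b `"DEL1"`/`"DEL2"` scheme labels or
#'   [library_design()] objects.
#' @return data.frame with one row: `delta_mw` (Da), `delta_hbd`,
#'   `delta_hba` for A relative to B.
#' @export
scaffold_delta <- function(design_a = "DEL1", design_b = "DEL2") {
  scheme <- function(d) if (inherits(d, "library_design")) d$scheme else
    match.arg(d, c("DEL1", "DEL2"))
  adduct <- function(s) {
    if (s == "DEL2") return(c(mw = 0, hbd = 0, hba = 0))
    # -C(=O)NH2 measured on the capped fragment formamide HC(=O)NH2 minus
    # the capping hydrogen; donors/acceptors are atom-based so the cap does
    # not alter them
    p <- compute_pcp("NC=O")
    c(mw = p$mw - ATOMIC_WEIGHT[["H"]], hbd = p$hbd, hba = p$hba)
  }
  a <- adduct(scheme(design_a))
  b <- adduct(scheme(design_b))
  data.frame(delta_mw = a[["mw"]] - b[["mw"]],
             delta_hbd = a[["hbd"]] - b[["hbd"]],
             delta_hba = a[["hba"]] - b[["hba"]])
}

#' Summarize product physicochemical properties
#'
#' Per-property density summaries and medians for enumerated products (MW,
#' clogP, TPSA, HBD), plus the rule-of-5 compliance fraction
#' (`MW < 500, clogP < 5, HBD <= 5, HBA <= 10`).
#'
#' @param library A `del_library` from [enumerate_library()], or its
#'   products data.frame.
#' @param ro5_lines If `TRUE`, attach the RO5 threshold per property for
#'   plotting.
#' @return List with `medians`, `ro5_pass_fraction`, `densities` (per
#'   property, `stats::density` objects; HBD as a count table) and
#'   optionally `ro5_thresholds`.
#' @export
library_pcp_summary <- function(library, ro5_lines = TRUE) {
  products <- if (inherits(library, "del_library")) library$products else library
  if (!is.data.frame(products) || nrow(products) == 0)
    stop("no products to summarize", call. = FALSE)
  medians <- c(mw = stats::median(products$mw),
               clogp = stats::median(products$clogp),
               tpsa = stats::median(products$tpsa),
               hbd = stats::median(products$hbd))
  ro5 <- products$mw < 500 & products$clogp < 5 & products$hbd <= 5 &
    products$hba <= 10
  densities <- list(
    mw = if (nrow(products) > 1 && stats::sd(products$mw) > 0)
      stats::density(products$mw) else NULL,
    clogp = if (nrow(products) > 1 && stats::sd(products$clogp) > 0)
      stats::density(products$clogp) else NULL,
    tpsa = if (nrow(products) > 1 && stats::sd(products$tpsa) > 0)
      stats::density(products$tpsa) else NULL,
    hbd = table(products$hbd))
  out <- list(medians = medians, ro5_pass_fraction = mean(ro5),
              densities = densities, n = nrow(products))
  if (ro5_lines)
    out$ro5_thresholds <- c(mw = 500, clogp = 5, hbd = 5, hba = 10)
  out
}
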