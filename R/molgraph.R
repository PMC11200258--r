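# Internal molecular-graph layer used for structure editing: truncation
# (functional group -> H), Fmoc deprotection, pendant-amide conversion and
# amide coupling. Molecules are parsed to kekulized connection tables via
# ChemmineR/OpenBabel, edited as plain atom/bond tables, then re-serialized
# as V2000 molblocks and canonicalized by OpenBabel. Neutral organics only.

STANDARD_VALENCE <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), Cl = 1L, Se = c(2L, 4L, 6L), Br = 1L, I = 1L
)

ATOMIC_WEIGHT <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.065, Cl = 35.453, Se = 78.971,
  Br = 79.904, I = 126.904
)

# Parse a batch of SMILES into a list of molgraphs:
#   list(elem = character, bonds = matrix[, c(a, b, order)], nH = integer)
mols_from_smiles <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  names(smiles) <- sprintf("i%d", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  if (length(sdf) != length(smiles))
    stop("SMILES parsing failed for ", length(smiles) - length(sdf), " input(s)",
         call. = FALSE)
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  lapply(seq_along(smiles), function(i) {
    elem <- sub("_.*$", "", rownames(ab[[i]]))
    b <- bb[[i]]
    bonds <- if (is.null(dim(b)) || nrow(b) == 0) {
      matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a", "b", "order")))
    } else {
      m <- unname(cbind(b[, 1], b[, 2], b[, 3]))
      storage.mode(m) <- "integer"
      colnames(m) <- c("a", "b", "order")
      m
    }
    mol_finalize(list(elem = elem, bonds = bonds))
  })
}

mol_finalize <- function(mol) {
  mol$nH <- mol_implicit_h(mol)
  mol
}

mol_bond_sum <- function(mol) {
  bs <- integer(length(mol$elem))
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      bs[mol$bonds[r, 1]] <- bs[mol$bonds[r, 1]] + mol$bonds[r, 3]
      bs[mol$bonds[r, 2]] <- bs[mol$bonds[r, 2]] + mol$bonds[r, 3]
    }
  }
  bs
}

mol_implicit_h <- function(mol) {
  bs <- mol_bond_sum(mol)
  vapply(seq_along(mol$elem), function(i) {
    v <- STANDARD_VALENCE[[mol$elem[i]]]
    if (is.null(v)) return(0L)
    v <- v[v >= bs[i]]
    if (!length(v)) return(0L)
    as.integer(min(v) - bs[i])
  }, integer(1))
}

mol_degree <- function(mol) {
  d <- integer(length(mol$elem))
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds[, 1], nbins = length(d))
    t2 <- tabulate(mol$bonds[, 2], nbins = length(d))
    d <- t1 + t2
  }
  d
}

mol_neighbors <- function(mol, i) {
  b <- mol$bonds
  rows <- which(b[, 1] == i | b[, 2] == i)
  if (!length(rows)) return(data.frame(atom = integer(0), order = integer(0)))
  other <- ifelse(b[rows, 1] == i, b[rows, 2], b[rows, 1])
  data.frame(atom = other, order = b[rows, 3])
}

mol_mw <- function(mol) {
  sum(ATOMIC_WEIGHT[mol$elem]) + sum(mol$nH) * ATOMIC_WEIGHT[["H"]]
}

mol_n_components <- function(mol) {
  if (length(mol$elem) <= 1) return(length(mol$elem))
  g <- igraph::graph_from_edgelist(mol$bonds[, 1:2, drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(mol$elem) - igraph::vcount(g)))
  igraph::components(g)$no
}

mol_component_of <- function(mol, start, blocked = integer(0)) {
  # atoms reachable from `start` without passing through `blocked`
  seen <- c(start)
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(i) mol_neighbors(mol, i)$atom)))
    nxt <- setdiff(nxt, c(seen, blocked))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

mol_delete_atoms <- function(mol, idx) {
  idx <- unique(idx)
  keep <- setdiff(seq_along(mol$elem), idx)
  remap <- integer(length(mol$elem))
  remap[keep] <- seq_along(keep)
  b <- mol$bonds
  if (nrow(b)) {
    drop <- b[, 1] %in% idx | b[, 2] %in% idx
    b <- b[!drop, , drop = FALSE]
    b[, 1] <- remap[b[, 1]]
    b[, 2] <- remap[b[, 2]]
  }
  mol_finalize(list(elem = mol$elem[keep], bonds = b))
}

mol_add_bond <- function(mol, i, j, order = 1L) {
  mol$bonds <- rbind(mol$bonds, c(i, j, as.integer(order)))
  mol_finalize(mol)
}

mol_set_elem <- function(mol, i, elem) {
  mol$elem[i] <- elem
  mol_finalize(mol)
}

# Merge two molgraphs; atom indices of `b` are offset by length(a$elem).
mol_merge <- function(a, b) {
  off <- length(a$elem)
  bb <- b$bonds
  if (nrow(bb)) bb[, 1:2] <- bb[, 1:2] + off
  mol_finalize(list(elem = c(a$elem, b$elem), bonds = rbind(a$bonds, bb)))
}

# ---- substructure detectors -------------------------------------------------

# Primary amine nitrogens: neutral N, one heavy neighbor (a carbon), two
# implicit H. `aliphatic_only` additionally requires the carbon to be sp3
# (no multiple bonds), which excludes anilines and vinyl amines; primary
# amides (N-C=O) are always excluded.
find_primary_amines <- function(mol, aliphatic_only = FALSE) {
  deg <- mol_degree(mol)
  out <- integer(0)
  for (i in which(mol$elem == "N" & deg == 1L & mol$nH == 2L)) {
    nb <- mol_neighbors(mol, i)
    if (nb$order != 1L || mol$elem[nb$atom] != "C") next
    cnb <- mol_neighbors(mol, nb$atom)
    carbonyl <- any(cnb$order == 2L & mol$elem[cnb$atom] == "O")
    if (carbonyl) next
    if (aliphatic_only && any(cnb$order > 1L)) next
    out <- c(out, i)
  }
  out
}

# Carboxylic acids: returns a list of integer triples c(C, O_carbonyl, O_hydroxyl).
find_cooh <- function(mol) {
  deg <- mol_degree(mol)
  res <- list()
  for (i in which(mol$elem == "C")) {
    nb <- mol_neighbors(mol, i)
    ocarb <- nb$atom[nb$order == 2L & mol$elem[nb$atom] == "O" & deg[nb$atom] == 1L]
    ohyd <- nb$atom[nb$order == 1L & mol$elem[nb$atom] == "O" &
                      deg[nb$atom] == 1L & mol$nH[nb$atom] >= 1L]
    if (length(ocarb) == 1L && length(ohyd) == 1L)
      res[[length(res) + 1L]] <- c(C = i, O2 = ocarb, OH = ohyd)
  }
  res
}

# Fmoc-type carbamates: N-C(=O)-O-CH2-C(...). Returns list of
# list(N = ..., C = carbamate carbon). The fluorenylmethyl side is taken as
# the whole component attached through the carbamate carbon.
find_carbamates <- function(mol) {
  deg <- mol_degree(mol)
  res <- list()
  for (i in which(mol$elem == "C")) {
    nb <- mol_neighbors(mol, i)
    ocarb <- nb$atom[nb$order == 2L & mol$elem[nb$atom] == "O" & deg[nb$atom] == 1L]
    oest <- nb$atom[nb$order == 1L & mol$elem[nb$atom] == "O" & deg[nb$atom] == 2L]
    nat <- nb$atom[nb$order == 1L & mol$elem[nb$atom] == "N"]
    if (length(ocarb) != 1L || length(oest) != 1L || length(nat) != 1L) next
    onb <- mol_neighbors(mol, oest)
    ch2 <- setdiff(onb$atom, i)
    if (length(ch2) != 1L || mol$elem[ch2] != "C" || mol$nH[ch2] != 2L) next
    res[[length(res) + 1L]] <- list(N = nat, C = i)
  }
  res
}

# ---- serialization ----------------------------------------------------------

ZERO_COORDS <- "    0.0000    0.0000    0.0000"

mol_to_molblock_lines <- function(mol, title = "") {
  na <- length(mol$elem)
  nb <- nrow(mol$bonds)
  c(title, "", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
    sprintf("%s %-3s 0  0", ZERO_COORDS, mol$elem),
    if (nb) sprintf("%3d%3d%3d  0", mol$bonds[, 1], mol$bonds[, 2], mol$bonds[, 3]),
    "M  END", "$$$$")
}

# Canonical SMILES for a list of molgraphs (single obabel batch call).
mols_to_smiles <- function(mols) {
  lines <- unlist(lapply(seq_along(mols), function(i)
    mol_to_molblock_lines(mols[[i]], title = sprintf("i%d", i))))
  out <- ob_run(lines, "-ocan", in_ext = "sdf")
  p <- ob_parse_titled(out)
  p$payload[match(sprintf("i%d", seq_along(mols)), p$title)]
}
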