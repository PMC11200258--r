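# Synthetic BB catalogs with the statistical structure of commercial
# amine / acid / Fmoc-amino-acid collections: chemotype-clustered scaffolds,
# class-specific MW medians, and bimodal (two-component log-normal) costs.

# ---- scaffold grammar -------------------------------------------------------
# Each variant is a SMILES fragment whose FIRST atom is the attachment point.
# Fragments for amine and Fmoc-AA classes always start with an sp3 carbon so
# that attachment yields a primary aliphatic amine / alpha-carbon; acids may
# also attach directly to (hetero)aromatic carbons. Fragments never contain
# amine, COOH or carbamate groups, keeping defining groups unambiguous.

scaffold_grammar <- function() {
  chain <- function(n) strrep("C", n)
  # combinatorial template expansion; empty substituent slots "()" collapse
  expand <- function(pre, template, subs) {
    g <- expand.grid(pre = pre, sub = subs, stringsAsFactors = FALSE)
    gsub("()", "", paste0(g$pre, sprintf(template, g$sub)), fixed = TRUE)
  }
  pre14 <- vapply(1:4, chain, "")
  pre15 <- vapply(1:5, chain, "")

  lin <- c(vapply(1:15, chain, ""),
           "CC(C)C", "CC(C)CC", "CCC(C)CC", "CC(C)(C)C", "CC(CC)CC",
           "CC(C)CCC", "CCCC(C)C", "CCCCC(C)CC", "CC(C)CCCCC",
           "CCCCCC(C)CC", "CCCCCCCC(C)C", "CCCCCCCCCC(C)CC",
           "CC(C)CCCCCCCC", "CCC(CC)CCCCCC")

  ring_var <- function(r, pre, dec) {
    core <- switch(dec,
      none = paste0("C1", strrep("C", r - 1), "1"),
      me2 = if (r >= 4) paste0("C1C(C)", strrep("C", r - 2), "1") else NA,
      mid = if (r >= 5) paste0("C1C", strrep("C", floor(r / 2) - 1), "C(C)",
                               strrep("C", r - floor(r / 2) - 2), "1") else NA,
      et2 = if (r >= 5) paste0("C1C(CC)", strrep("C", r - 2), "1") else NA)
    if (is.na(core)) NA_character_ else paste0(pre, core)
  }
  cyc <- unlist(lapply(3:7, function(r)
    lapply(c("", pre15), function(p)
      vapply(c("none", "me2", "mid", "et2"), function(d) ring_var(r, p, d), ""))))
  cyc <- c(cyc, as.vector(outer(c("", "C", "CC", "CCC"),
                                c("C1CCC(O)CC1", "C1CCC(CO)CC1", "C1CCC(OC)CC1",
                                  "C1CC(O)CC1", "C1CCC(C(=O)C)CC1"), paste0)))
  cyc <- unique(cyc[!is.na(cyc)])

  sub1 <- c("", "F", "Cl", "C", "OC", "CC", "OCC", "C#N", "C(F)(F)F",
            "O", "CO", "C(=O)C", "C(=O)OC", "S(C)(=O)=O", "OC(F)F")
  benz <- unique(c(
    expand(pre15, "c1ccc(%s)cc1", sub1),                  # para
    expand(pre14, "c1cccc(%s)c1", sub1[-1]),              # meta
    expand(pre14, "c1cc(C)cc(%s)c1", c("C", "F", "OC", "Cl", "CC", "O", "C#N")),
    expand(pre14, "c1cc(F)cc(%s)c1", c("F", "OC", "Cl", "C#N", "CO")),
    expand(pre14, "c1cc(OC)cc(%s)c1", c("OC", "O", "C", "CO")),
    expand(c("C", "CC"), "c1ccc(%s)c(F)c1", c("F", "C", "OC", "O"))))

  tails <- c("CO", "COC", "CC#N", "CSC", "C(=O)C", "COCC", "C(C)O",
             "CS(C)(=O)=O", "C(=O)OC", "COCCOC")
  polar <- unique(c(
    paste0(rep(vapply(1:6, chain, ""), each = length(tails)), tails),
    "CC(C)O", "CCOCC", "CCOCCOC", "CCCC(=O)CC", "CC(C)CO", "CCC(C)OC"))

  het_cores <- c("c1ccncc1" = "c1ccnc(%s)c1", "c1cccnc1" = "c1ccc(%s)nc1",
                 "c1ccccn1" = "c1ccc(%s)cn1", "c1cccs1" = "c1ccc(%s)s1",
                 "c1ccsc1" = "c1cc(%s)sc1", "c1ccco1" = "c1ccc(%s)o1",
                 "c1cnn(C)c1" = "c1cc(%s)nn1C", "c1csc(C)n1" = "c1csc(%s)n1",
                 "c1ccnnc1" = "c1cc(%s)nnc1", "c1cncnc1" = "c1ncc(%s)nc1")
  het_subs <- c("C", "CC", "Cl", "OC", "C#N", "CO", "C(=O)C", "CCC")
  het <- unique(unlist(lapply(seq_along(het_cores), function(i)
    c(paste0(pre14, names(het_cores)[i]),
      expand(pre14, het_cores[[i]], het_subs)))))

  dhbf <- unique(c(expand(vapply(1:3, chain, ""), "c1ccc2c(c1%s)CCO2", c("", "C")),
                   expand(vapply(1:3, chain, ""), "c1ccc2c(c1%s)OCC2", c("", "C")),
                   "CCCCCc1ccc2c(c1)CCO2"))

  naph <- unique(c(expand(pre15, "c1ccc2cc(%s)ccc2c1",
                          c("", "C", "F", "OC", "Cl", "C#N", "O", "CO")),
                   "Cc1cccc2ccccc12", "CCc1cccc2ccccc12"))

  alk13 <- vapply(1:3, chain, "")
  sulf <- unique(c(expand(alk13, "S(=O)(=O)NCc1ccc(%s)cc1",
                          c("", "F", "C", "OC", "Cl", "C#N")),
                   expand(alk13, "NS(=O)(=O)c1ccc(%s)cc1",
                          c("", "F", "C", "OC", "Cl", "C#N")),
                   expand(alk13, "CS(=O)(=O)NCc1ccc(%s)cc1", c("", "F", "C")),
                   "CCCCS(=O)(=O)NCc1ccc(C)cc1"))

  biph <- unique(c(expand(alk13, "c1ccc(-c2ccc(%s)cc2)cc1",
                          c("", "F", "C", "OC", "C#N", "O")),
                   expand(alk13, "c1cccc(-c2ccc(%s)cc2)c1",
                          c("", "F", "C", "OC", "C#N")),
                   "CCCCc1ccc(-c2ccccc2)cc1"))

  bicy <- unique(c(expand(c("", "C", "CC"), "C1Cc2cc(%s)ccc2C1",
                          c("", "C", "F", "OC", "O", "C#N")),
                   expand(c("", "C", "CC"), "C1Cc2cc(%s)ccc2CC1",
                          c("", "C", "F", "OC", "O", "C#N")),
                   "CCCCC1CCc2ccccc2C1"))

  fam <- list(linear = lin, cycloalkane = cyc, benzene = benz, polar = polar,
              heteroaromatic = het, dihydrobenzofuran = dhbf,
              naphthalene = naph, sulfonamide = sulf, biphenyl = biph,
              fused_bicyclic = bicy)
  data.frame(
    family = rep(names(fam), lengths(fam)),
    frag = unlist(fam, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# chemotype-family sampling weights per class; chosen so Fmoc-AAs concentrate
# in linear/cycloalkane/benzene space while amines and acids also populate
# the fused, heteroaromatic, sulfonamide and biphenyl families
scaffold_family_weights <- function(bb_class) {
  w <- switch(bb_class,
    FMOC_AA = c(linear = 0.28, cycloalkane = 0.24, benzene = 0.24,
                polar = 0.12, heteroaromatic = 0.05, dihydrobenzofuran = 0.02,
                naphthalene = 0.02, sulfonamide = 0.01, biphenyl = 0.01,
                fused_bicyclic = 0.01),
    PRIMARY_AMINE = c(linear = 0.14, cycloalkane = 0.14, benzene = 0.18,
                      polar = 0.05, heteroaromatic = 0.12,
                      dihydrobenzofuran = 0.07, naphthalene = 0.07,
                      sulfonamide = 0.08, biphenyl = 0.08, fused_bicyclic = 0.07),
    CARBOXYLIC_ACID = c(linear = 0.10, cycloalkane = 0.12, benzene = 0.20,
                        polar = 0.03, heteroaromatic = 0.15,
                        dihydrobenzofuran = 0.08, naphthalene = 0.10,
                        sulfonamide = 0.07, biphenyl = 0.08,
                        fused_bicyclic = 0.07))
  w / sum(w)
}

# wrap a fragment with the class head group
wrap_fragment <- function(frag, bb_class, via_ch2 = FALSE) {
  if (via_ch2) frag <- paste0("C", frag)
  switch(bb_class,
    PRIMARY_AMINE = paste0("N", frag),
    CARBOXYLIC_ACID = paste0("OC(=O)", frag),
    FMOC_AA = paste0("OC(=O)C(", frag, ")NC(=O)OCC1c2ccccc2-c2ccccc21"))
}

# For MW-median calibration: full-molecule weight = fragment weight + delta.
# For FMOC_AA the calibration target refers to the Fmoc-removed amino acid
# H2N-CH(R)-COOH, per the convention that Fmoc is ignored in MW analyses.
.grammar_cache <- new.env(parent = emptyenv())

grammar_with_mw <- function() {
  if (!is.null(.grammar_cache$tab)) return(.grammar_cache$tab)
  g <- scaffold_grammar()
  # fragment weight measured on the free hydrocarbon frag-H
  p <- ob_props(g$frag)
  g$frag_mw <- p$mw
  g$frag_clogp <- p$clogp
  .grammar_cache$tab <- g
  g
}

class_mw_delta <- function(bb_class) {
  switch(bb_class,
    PRIMARY_AMINE = 15.015,      # +NH (replace one H by NH2)
    CARBOXYLIC_ACID = 44.009,    # +COOH - H
    FMOC_AA = 73.050)            # + CH(NH2)COOH - H (deprotected form)
}

# clogP shift of the head group relative to the bare fragment, measured on
# an ethyl reference (FMOC_AA in deprotected amino acid form)
class_clogp_delta <- function(bb_class) {
  if (is.null(.grammar_cache$clogp_delta)) {
    p <- ob_props(c("CC", "NCC", "OC(=O)CC", "NC(C(=O)O)CC"))
    .grammar_cache$clogp_delta <- c(
      PRIMARY_AMINE = p$clogp[2] - p$clogp[1],
      CARBOXYLIC_ACID = p$clogp[3] - p$clogp[1],
      FMOC_AA = p$clogp[4] - p$clogp[1])
  }
  .grammar_cache$clogp_delta[[bb_class]]
}

#' Specify a synthetic BB catalog
#'
#' Bundles the generation parameters for one synthetic catalog: class, size,
#' the target median molecular weight (for Fmoc-AAs this refers to the
#' Fmoc-removed amino acid, the convention used for all MW analyses of that
#' class), a target median clogP (steered only through the class's chemotype
#' family mix), and a two-component log-normal cost mixture in USD per
#' 250 mg pack.
#'
#' @param bb_class One of [bb_classes()].
#' @param n Number of building blocks to generate.
#' @param mw_median_target Target median MW in Da.
#' @param clogp_median_target Informational target median clogP.
#' @param cost_modes data.frame with columns `mean` (component median, USD),
#'   `sdlog` (log-scale sd) and `weight` (mixing weights summing to 1).
#' @param seed Integer RNG seed.
#' @return A `catalog_spec` list.
#' @export
catalog_spec <- function(bb_class, n,
                         mw_median_target = c(FMOC_AA = 171, PRIMARY_AMINE = 174,
                                              CARBOXYLIC_ACID = 220)[[bb_class]],
                         clogp_median_target = c(FMOC_AA = -1.8, PRIMARY_AMINE = 0.69,
                                                 CARBOXYLIC_ACID = 1.1)[[bb_class]],
                         cost_modes = data.frame(mean = c(70, 400),
                                                 sdlog = c(0.45, 0.40),
                                                 weight = c(0.5, 0.5)),
                         seed = 1L) {
  bb_class <- match_bb_class(bb_class)
  stopifnot(n >= 0, nrow(cost_modes) == 2, all(cost_modes$sdlog > 0),
            abs(sum(cost_modes$weight) - 1) < 1e-8)
  structure(list(bb_class = bb_class, n = as.integer(n),
                 mw_median_target = mw_median_target,
                 clogp_median_target = clogp_median_target,
                 cost_modes = cost_modes, seed = as.integer(seed)),
            class = "catalog_spec")
}

# Mixture component probabilities are modulated by chemotype family: common
# chemotypes (linear aliphatics, cycloalkanes, benzenes) fall mostly in the
# cheap mode, exotic ones (naphthalenes, sulfonamides, biphenyls, fused
# bicyclics) mostly in the expensive mode. This couples price to structure,
# so cost filtering changes which chemical space remains accessible.
family_cheap_multiplier <- c(
  linear = 1.5, cycloalkane = 1.4, benzene = 1.4, polar = 1.3,
  heteroaromatic = 1.0, dihydrobenzofuran = 0.7, naphthalene = 0.55,
  sulfonamide = 0.55, biphenyl = 0.5, fused_bicyclic = 0.6)

sample_costs <- function(n, cost_modes, family = NULL, repeated = NULL) {
  p1 <- rep(cost_modes$weight[1], n)
  if (!is.null(family)) {
    m <- family_cheap_multiplier[family]
    m[is.na(m)] <- 1
    p1 <- p1 * m
  }
  # catalog depth is cheap: repeat copies of an already-present scaffold
  # land mostly in the budget mode, structurally fresh additions mostly in
  # the premium mode (commercial pricing tracks compound popularity)
  if (!is.null(repeated)) p1 <- p1 * ifelse(repeated, 1.6, 0.82)
  p1 <- pmin(0.95, pmax(0.05, p1))
  comp <- ifelse(stats::runif(n) < p1, 1L, 2L)
  round(stats::rlnorm(n, meanlog = log(cost_modes$mean[comp]),
                      sdlog = cost_modes$sdlog[comp]), 2)
}

# draw fragments so the realized full-molecule MW distribution is centred on
# the class target: sample a family, draw a target fragment weight, then pick
# uniformly among that family's variants inside a +-20 Da window (nearest
# variant when the window is empty)
sample_fragments <- function(n, bb_class, mw_median_target,
                             clogp_median_target = NULL, mw_sd = 45) {
  g <- grammar_with_mw()
  w <- scaffold_family_weights(bb_class)
  fams <- sample(names(w), n, replace = TRUE, prob = w)
  mu <- mw_median_target - class_mw_delta(bb_class)
  clogp_mu <- if (is.null(clogp_median_target)) NULL else
    clogp_median_target - class_clogp_delta(bb_class)
  draws <- stats::rnorm(n, mean = mu, sd = mw_sd)
  by_fam <- split(seq_len(nrow(g)), g$family)
  idx <- integer(n)
  used <- logical(nrow(g))
  for (i in seq_len(n)) {
    cand <- by_fam[[fams[i]]]
    d <- abs(g$frag_mw[cand] - draws[i])
    inwin <- cand[d <= 20]
    # prefer variants not yet drawn so catalogs are mostly structure-unique
    fresh <- inwin[!used[inwin]]
    pool <- if (length(fresh)) fresh else if (length(inwin)) inwin else
      cand[which.min(d)]
    p <- if (is.null(clogp_mu)) NULL else
      exp(-abs(g$frag_clogp[pool] - clogp_mu) / 0.45)
    idx[i] <- pool[sample.int(length(pool), 1L, prob = p)]
    used[idx[i]] <- TRUE
  }
  out <- g[idx, , drop = FALSE]
  out$repeated <- duplicated(idx)
  out
}

#' Generate a synthetic BB catalog
#'
#' Builds `n` chemically valid building blocks of the requested class by
#' attaching the class's defining group (NH2, COOH, or the Fmoc carbamate
#' plus COOH on an alpha-carbon) to scaffolds drawn from a parameterized
#' fragment grammar spanning the chemotype families seen in commercial
#' collections (linear/branched aliphatics, cycloalkanes, substituted
#' benzenes, dihydrobenzofurans, naphthalenes, benzylsulfonamides, biphenyls,
#' heteroaromatics, fused bicyclics). Costs are drawn from the spec's bimodal
#' log-normal mixture. Deterministic given `spec$seed`.
#'
#' @param spec A [catalog_spec()].
#' @return A [bb_catalog()] with provenance `"synthetic"`.
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "catalog_spec"))
  prefix <- c(FMOC_AA = "FA", PRIMARY_AMINE = "AM", CARBOXYLIC_ACID = "CA")[[spec$bb_class]]
  if (spec$n == 0) {
    empty <- data.frame(id = character(0), smiles = character(0), cost = numeric(0),
                        mw = numeric(0), clogp = numeric(0), tpsa = numeric(0),
                        hbd = integer(0), hba = integer(0))
    return(structure(empty, class = c("bb_catalog", "data.frame"),
                     bb_class = spec$bb_class, provenance = "synthetic",
                     rejections = data.frame(id = character(0), reason = character(0))))
  }
  withr::with_seed(spec$seed, {
    frags <- sample_fragments(spec$n, spec$bb_class, spec$mw_median_target,
                              spec$clogp_median_target)
    costs <- sample_costs(spec$n, spec$cost_modes, frags$family, frags$repeated)
  })
  smiles <- wrap_fragment(frags$frag, spec$bb_class)
  members <- data.frame(id = sprintf("%s-%05d", prefix, seq_len(spec$n)),
                        smiles = smiles, cost = costs, stringsAsFactors = FALSE)
  bb_catalog(members, spec$bb_class, provenance = "synthetic")
}

#' Generate a matched trio of synthetic catalogs
#'
#' Emulates the relative structure of commercial BB collections: the Fmoc-AA
#' set is the smallest of the three, and a configurable fraction of amine
#' scaffolds duplicates Fmoc-AA scaffolds so that the two classes share
#' truncate structures (the amine built on a shared scaffold R is
#' H2N-CH2-R, whose truncate CH3-R equals the truncate of the Fmoc amino
#' acid with side chain R).
#'
#' @param seed Integer seed controlling all randomness.
#' @param n Named integer vector of set sizes; the Fmoc-AA entry must be the
#'   smallest.
#' @param overlap_fraction Fraction of amine members drawn from the realized
#'   Fmoc-AA scaffold set (0-1).
#' @param cost_modes Passed to [catalog_spec()].
#' @return Named list of three [bb_catalog()]s
#'   (`FMOC_AA`, `PRIMARY_AMINE`, `CARBOXYLIC_ACID`).
#' @export
generate_paired_catalogs <- function(seed = 1L,
                                     n = c(FMOC_AA = 400, PRIMARY_AMINE = 1200,
                                           CARBOXYLIC_ACID = 800),
                                     overlap_fraction = 0.25,
                                     cost_modes = data.frame(mean = c(70, 400),
                                                             sdlog = c(0.45, 0.40),
                                                             weight = c(0.5, 0.5))) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            n[["FMOC_AA"]] <= n[["PRIMARY_AMINE"]],
            n[["FMOC_AA"]] <= n[["CARBOXYLIC_ACID"]])
  specs <- lapply(bb_classes(), function(cl)
    catalog_spec(cl, n = n[[cl]], cost_modes = cost_modes,
                 seed = seed + match(cl, bb_classes())))
  names(specs) <- bb_classes()
  fmoc <- generate_catalog(specs$FMOC_AA)
  acid <- generate_catalog(specs$CARBOXYLIC_ACID)
  # side-chain fragments actually realized in the Fmoc set (same seeded draw
  # as generate_catalog, which consumes fragments before costs)
  fmoc_frags <- unique(withr::with_seed(specs$FMOC_AA$seed,
    sample_fragments(specs$FMOC_AA$n, "FMOC_AA",
                     specs$FMOC_AA$mw_median_target,
                     specs$FMOC_AA$clogp_median_target))$frag)
  # amines: a share of members is built on Fmoc side chains via a benzylic/
  # methylene attachment so the truncates coincide (H2N-CH2-R vs Fmoc-AA(R)
  # both truncate to CH3-R)
  spec_am <- specs$PRIMARY_AMINE
  withr::with_seed(spec_am$seed, {
    frags <- sample_fragments(spec_am$n, "PRIMARY_AMINE", spec_am$mw_median_target,
                              spec_am$clogp_median_target)
    costs <- sample_costs(spec_am$n, spec_am$cost_modes, frags$family, frags$repeated)
    n_shared <- round(overlap_fraction * spec_am$n)
    shared_idx <- if (n_shared > 0) sample.int(spec_am$n, n_shared) else integer(0)
    pick <- if (n_shared > 0) {
      if (overlap_fraction == 1 && n_shared >= length(fmoc_frags)) {
        # the limit case guarantees every Fmoc scaffold is covered
        c(fmoc_frags, sample(fmoc_frags, n_shared - length(fmoc_frags), replace = TRUE))
      } else sample(fmoc_frags, n_shared, replace = TRUE)
    } else character(0)
  })
  smiles <- wrap_fragment(frags$frag, "PRIMARY_AMINE")
  if (length(shared_idx))
    smiles[shared_idx] <- wrap_fragment(pick, "PRIMARY_AMINE", via_ch2 = TRUE)
  if (overlap_fraction == 0) {
    # enforce the zero-overlap limit: drop incidental truncate collisions
    # between plain amine scaffolds (truncate R-H) and Fmoc ones (CH3-R)
    fm_tr <- unique(ob_canonical(paste0("C", fmoc_frags)))
    am_tr <- ob_canonical(frags$frag)
    clash <- am_tr %in% fm_tr
    if (any(clash)) {
      g <- grammar_with_mw()
      safe <- g$frag[!ob_canonical(g$frag) %in% fm_tr]
      withr::with_seed(spec_am$seed + 7L,
        repl <- sample(safe, sum(clash), replace = TRUE))
      smiles[clash] <- wrap_fragment(repl, "PRIMARY_AMINE")
    }
  }
  members <- data.frame(id = sprintf("AM-%05d", seq_len(spec_am$n)),
                        smiles = smiles, cost = costs, stringsAsFactors = FALSE)
  amine <- bb_catalog(members, "PRIMARY_AMINE", provenance = "synthetic")
  list(FMOC_AA = fmoc, PRIMARY_AMINE = amine, CARBOXYLIC_ACID = acid)
}
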