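test_that("truncation replaces defining groups with hydrogen", {
  expect_equal(truncate_bb("CCN", "PRIMARY_AMINE")$smiles, "CC")
  expect_equal(truncate_bb("OC(=O)c1ccccc1", "CARBOXYLIC_ACID")$smiles,
               "c1ccccc1")
  # Fmoc-alanine: stripping Fmoc -> NH2 -> H and COOH -> H leaves ethane
  fmoc_ala <- "OC(=O)C(C)NC(=O)OCC1c2ccccc2-c2ccccc21"
  tr <- truncate_bb(fmoc_ala, "FMOC_AA")
  expect_equal(tr$smiles, "CC")
  expect_equal(tr$n_replaced, 2)
  expect_false(tr$polyfunctional)
})

test_that("multi-instance replacement is counted and flagged polyfunctional", {
  tr <- truncate_bb("NCCCCN", "PRIMARY_AMINE") # 1,4-diaminobutane
  expect_equal(tr$smiles, "CCCC")
  expect_equal(tr$n_replaced, 2)
  expect_true(tr$polyfunctional)
})

test_that("truncation strictly reduces mass and leaves no defining groups", {
  for (cl in bb_classes()) {
    catx <- generate_catalog(catalog_spec(cl, 25, seed = 17))
    tr <- truncate_catalog(catx)
    expect_true(all(is.na(tr$reason)))
    p <- compute_pcp(tr$smiles)
    expect_true(all(p$mw < catx$mw))
    # idempotence: no defining group remains in any truncate
    pats <- bb_class_patterns()$defining
    expect_false(any(bbdesign:::ob_matches(tr$smiles, pats$PRIMARY_AMINE[1])))
    expect_false(any(bbdesign:::ob_matches(tr$smiles, pats$CARBOXYLIC_ACID[1])))
    expect_false(any(bbdesign:::ob_matches(tr$smiles, pats$FMOC_AA[1])))
  }
})

test_that("class_filter removes the documented nitrogen chemotypes", {
  catx <- bb_catalog(data.frame(
    id = c("sec", "anil", "ok"),
    smiles = c("CCCCNC", "Nc1ccccc1", "NC1CCCCC1"),
    cost = c(1, 1, 1)), "PRIMARY_AMINE")
  f <- class_filter(catx)
  expect_equal(f$catalog$id, "ok")
  expect_setequal(f$report$rejected$reason,
                  c("secondary_amine", "aniline_nitrogen"))
  # proline-like secondary amino acid
  aa <- bb_catalog(data.frame(id = "pro", smiles = "OC(=O)C1CCCN1", cost = 1),
                   "CARBOXYLIC_ACID")
  expect_equal(class_filter(aa)$report$rejected$reason, "secondary_amino_acid")
})

test_that("cost filter is boundary-inclusive, rejects missing costs, and nests", {
  catx <- tiny_amine_catalog(costs = c(80, 250, 400, NA, 55))
  f <- cost_filter(catx, 250)
  expect_equal(nrow(f$catalog), 3) # 80, 250 (inclusive), 55
  expect_true("cost_missing" %in% f$report$rejected$reason)
  expect_equal(f$report$n_in, f$report$n_out + nrow(f$report$rejected))
  # +Inf retains everything with a known cost
  expect_equal(nrow(cost_filter(catx, Inf)$catalog), 4)
  # monotone nesting across the standard tiers
  tiers <- lapply(c(100, 250, 500), function(t) cost_filter(catx, t)$catalog$id)
  expect_true(all(tiers[[1]] %in% tiers[[2]]))
  expect_true(all(tiers[[2]] %in% tiers[[3]]))
})

test_that("class and cost filters commute", {
  catx <- fixture_amine(80)
  a <- cost_filter(class_filter(catx)$catalog, 250)$catalog
  b <- class_filter(cost_filter(catx, 250)$catalog)$catalog
  expect_identical(a$id, b$id)
})

test_that("pcp_filter applies strict RO bounds and inclusive MW cutoffs", {
  catx <- bb_catalog(data.frame(
    id = c("a", "b"), smiles = c("CCN", "CCCN"), cost = c(1, 1),
    mw = c(300, 250), clogp = c(1, 1), tpsa = c(10, 10),
    hbd = c(1L, 1L), hba = c(1L, 1L)), "PRIMARY_AMINE")
  expect_false("a" %in% pcp_filter(catx, "RO3")$catalog$id)       # strict < 300
  expect_true("b" %in% pcp_filter(catx, "mw_cutoff", 250)$catalog$id) # <= 250
  allpass <- pcp_filter(tiny_amine_catalog(), "RO5")
  expect_equal(nrow(allpass$report$rejected), 0)
})

test_that("Fmoc-AA property filtering weighs the deprotected form", {
  fa <- generate_catalog(catalog_spec("FMOC_AA", 20, seed = 21))
  # full-molecule MW includes ~222 Da of Fmoc; the filter must ignore it
  dep_mw <- compute_pcp(remove_fmoc(fa$smiles))$mw
  cut <- stats::median(dep_mw)
  kept <- pcp_filter(fa, "mw_cutoff", mw_cutoff = cut)$catalog$id
  expect_setequal(kept, fa$id[dep_mw <= cut])
  expect_gt(length(kept), 0)
})

test_that("unique_truncates keeps multiplicity and supports set arithmetic", {
  u <- unique_truncates(c("CC", "CC", "CCC"))
  expect_equal(u$smiles, c("CC", "CCC"))
  expect_equal(u$multiplicity, c(2L, 1L))
  expect_equal(nrow(unique_truncates(character(0))), 0)
  # set difference on a small two-class fixture matches hand enumeration
  a <- c("CC", "CCC", "CCCC", "c1ccccc1")
  b <- c("CC", "c1ccccc1", "CCCCC", "C1CCCC1")
  expect_equal(sort(setdiff(unique_truncates(a)$smiles,
                            unique_truncates(b)$smiles)),
               c("CCC", "CCCC"))
})
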