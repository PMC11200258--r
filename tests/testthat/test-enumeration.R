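test_that("amide coupling condenses with loss of water", {
  prod <- couple_amide("CCN", "CC(=O)O")
  expect_equal(prod, bbdesign:::ob_canonical("CCNC(C)=O")) # N-ethylacetamide
  p <- compute_pcp(c("CCN", "CC(=O)O", prod))
  expect_equal(p$mw[3], p$mw[1] + p$mw[2] - 18.02, tolerance = 0.01)
  # ambiguous substrates are refused with a named error
  expect_error(couple_amide("NCCCCN", "CC(=O)O"), "ambiguous|amine")
  expect_error(couple_amide("CCN", "OC(=O)CC(=O)O"), "ambiguous|acid")
  expect_error(couple_amide("CCO", "CC(=O)O"), "amine")
})

test_that("enumeration yields the full cross product with logged failures", {
  am <- tiny_amine_catalog(costs = c(10, 20, 30))
  ac <- tiny_acid_catalog(4)
  lib <- enumerate_library(library_design("DEL2", am, ac))
  expect_equal(nrow(lib$products), 12)
  expect_equal(nrow(lib$failures), 0)
  # a diamine in cycle 1 fails for every acid and is logged, never dropped
  am2 <- bb_catalog(data.frame(id = c("ok", "diamine"),
                               smiles = c("CCN", "NCCCCN"), cost = c(1, 1)),
                    "PRIMARY_AMINE")
  lib2 <- enumerate_library(library_design("DEL2", am2, ac))
  expect_equal(nrow(lib2$products), 4)
  expect_equal(nrow(lib2$failures), 4)
  expect_true(all(lib2$failures$amine_id == "diamine"))
  expect_equal(nrow(lib2$products) + nrow(lib2$failures), 2 * 4)
})

test_that("mass balance holds for every enumerated product", {
  am <- bbdesign:::catalog_subset(fixture_amine(40), 1:20)
  ac <- bbdesign:::catalog_subset(fixture_acid(40), 1:20)
  lib <- enumerate_library(library_design("DEL2", am, ac))
  expect_equal(nrow(lib$products) + nrow(lib$failures), 400)
  mwa <- am$mw[match(lib$products$amine_id, am$id)]
  mwc <- ac$mw[match(lib$products$acid_id, ac$id)]
  expect_true(all(abs(lib$products$mw - (mwa + mwc - 18.0153)) <= 0.01))
})

test_that("DEL1 products carry the pendant primary amide and DEL2 do not", {
  fa <- bbdesign:::catalog_subset(
    generate_catalog(catalog_spec("FMOC_AA", 8, seed = 31)), 1:8)
  ac <- bbdesign:::catalog_subset(fixture_acid(40), 1:6)
  lib1 <- enumerate_library(library_design("DEL1", fa, ac))
  expect_equal(nrow(lib1$products), 48)
  amide_pat <- "[CX3](=O)[NX3;H2]"
  expect_true(all(bbdesign:::ob_matches(lib1$products$smiles, amide_pat)))
  am <- bbdesign:::catalog_subset(fixture_amine(40), 1:6)
  lib2 <- enumerate_library(library_design("DEL2", am, ac))
  expect_false(any(bbdesign:::ob_matches(lib2$products$smiles, amide_pat)))
  # scheme/class mismatches are refused
  expect_error(library_design("DEL1", am, ac), "FMOC_AA")
  expect_error(library_design("DEL2", am, am), "CARBOXYLIC_ACID")
})

test_that("the DEL1-vs-DEL2 constant adduct is CH2NO: 44 Da, +1 HBD, +2 HBA", {
  d <- scaffold_delta("DEL1", "DEL2")
  expect_equal(round(d$delta_mw), 44)
  expect_equal(d$delta_hbd, 1)
  expect_equal(d$delta_hba, 2)
  same <- scaffold_delta("DEL2", "DEL2")
  expect_true(all(unlist(same) == 0))
})

test_that("BB-level MW cutoffs bound product MW compositionally", {
  am <- pcp_filter(fixture_amine(80), "mw_cutoff", 250)$catalog
  ac <- pcp_filter(fixture_acid(80), "mw_cutoff", 250)$catalog
  lib <- enumerate_library(library_design(
    "DEL2", bbdesign:::catalog_subset(am, 1:10),
    bbdesign:::catalog_subset(ac, 1:10)))
  expect_true(all(lib$products$mw <= 250 + 250 - 18.0153 + 0.01))
})

test_that("product property summaries match a sort-and-middle oracle", {
  am <- bbdesign:::catalog_subset(fixture_amine(40), 1:10)
  ac <- bbdesign:::catalog_subset(fixture_acid(40), 1:10)
  lib <- enumerate_library(library_design("DEL2", am, ac))
  s <- library_pcp_summary(lib)
  byhand <- function(v) { v <- sort(v); n <- length(v)
    if (n %% 2) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2 }
  expect_equal(unname(s$medians["mw"]), byhand(lib$products$mw))
  expect_equal(unname(s$medians["clogp"]), byhand(lib$products$clogp))
  expect_equal(unname(s$medians["tpsa"]), byhand(lib$products$tpsa))
  # duplication leaves the summary unchanged
  s2 <- library_pcp_summary(rbind(lib$products, lib$products))
  expect_equal(s2$medians, s$medians)
  expect_equal(s2$ro5_pass_fraction, s$ro5_pass_fraction)
  one <- library_pcp_summary(lib$products[1, ])
  expect_equal(unname(one$medians["mw"]), lib$products$mw[1])
  expect_error(library_pcp_summary(lib$products[0, ]), "no products")
})
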