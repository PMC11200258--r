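test_that("compute_pcp follows the atom-based donor/acceptor conventions", {
  p <- compute_pcp(c("O", "CC(=O)N", "c1ccccc1"))
  # water: one donor atom, one N+O acceptor
  expect_equal(p$hbd[1], 1)
  expect_equal(p$hba[1], 1)
  expect_equal(p$mw[1], 18.02, tolerance = 0.01)
  # acetamide: the -C(=O)NH2 group counts one donor, two acceptors
  expect_equal(p$hbd[2], 1)
  expect_equal(p$hba[2], 2)
  # benzene: nothing polar
  expect_equal(p$hbd[3], 0)
  expect_equal(p$hba[3], 0)
  expect_equal(p$tpsa[3], 0)
  expect_error(compute_pcp("not_a_smiles"), "unparsable")
})

test_that("compute_pcp is deterministic and matches independent atom-sum MW", {
  smis <- unique(fixture_amine(60)$smiles)[1:20]
  p1 <- compute_pcp(smis)
  p2 <- compute_pcp(smis)
  expect_identical(p1, p2)
  # independent oracle: sum of average atomic weights over the parsed graph
  mols <- bbdesign:::mols_from_smiles(smis)
  mw_oracle <- vapply(mols, bbdesign:::mol_mw, numeric(1))
  expect_equal(p1$mw, mw_oracle, tolerance = 0.01)
  # donor/acceptor counts against a graph-based recount
  for (i in seq_along(smis)) {
    mol <- mols[[i]]
    is_no <- mol$elem %in% c("N", "O")
    expect_equal(p1$hbd[i], sum(is_no & mol$nH >= 1))
    expect_equal(p1$hba[i], sum(is_no))
  }
})

test_that("SDF catalogs read with field mapping; bad records go to the rejection log", {
  path <- tempfile(fileext = ".sdf")
  write_fixture_sdf(path,
                    smiles = c("CCN", "NCCc1ccccc1", "NC1CCCCC1", "Nc1ccccc1"),
                    ids = c("AM1", "AM2", "AM3", "AN1"),
                    costs = c(85, 120, NA, 60))
  cat <- read_catalog_sdf(path, "PRIMARY_AMINE",
                          field_map = c(id = "Catalog_ID", cost = "Price_250mg"))
  expect_s3_class(cat, "bb_catalog")
  expect_equal(nrow(cat), 3)               # aniline has no aliphatic NH2
  expect_equal(rejections(cat)$id, "AN1")
  expect_equal(rejections(cat)$reason, "missing_defining_group")
  expect_true(is.na(cat$cost[cat$id == "AM3"])) # missing cost is NA, not 0
  expect_equal(cat$cost[cat$id == "AM1"], 85)
})

test_that("degenerate SDF inputs are fatal", {
  empty <- tempfile(fileext = ".sdf")
  writeLines(character(0), empty)
  expect_error(read_catalog_sdf(empty, "PRIMARY_AMINE"), "records|parsable")
  expect_error(read_catalog_sdf(tempfile(), "PRIMARY_AMINE"), "not found")
})

test_that("CSV round trip preserves ids, canonical smiles and costs in order", {
  cat5 <- tiny_amine_catalog()
  path <- tempfile(fileext = ".csv")
  write_catalog_csv(cat5, path)
  back <- read_catalog_csv(path, "PRIMARY_AMINE")
  expect_identical(back$id, cat5$id)
  expect_identical(back$smiles, cat5$smiles)
  expect_identical(back$cost, cat5$cost)
  # truncate column is additive
  path2 <- tempfile(fileext = ".csv")
  write_catalog_csv(cat5, path2, include_truncate = TRUE)
  expect_true("truncate_smiles" %in% names(utils::read.csv(path2)))
  expect_error(write_catalog_csv(cat5[0, ], path), "empty|bb_catalog")
})

test_that("CSV schema violations are fatal and missing cost column gives NAs", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = c("CCN", "CCCN"), id = c("a", "a")), p,
            row.names = FALSE)
  expect_error(read_catalog_csv(p, "PRIMARY_AMINE"), "duplicate")
  write.csv(data.frame(smiles = c("CCN", "CCCN"), id = c("a", "b")), p,
            row.names = FALSE)
  cat2 <- read_catalog_csv(p, "PRIMARY_AMINE")
  expect_true(all(is.na(cat2$cost)))
  write.csv(data.frame(x = 1), p, row.names = FALSE)
  expect_error(read_catalog_csv(p, "PRIMARY_AMINE"), "mandatory")
})

test_that("catalogs reject salts and enforce id uniqueness", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = c("CCN", "CCN.Cl"), id = c("a", "b"),
                       cost = c(1, 2)), p, row.names = FALSE)
  cat2 <- read_catalog_csv(p, "PRIMARY_AMINE")
  expect_equal(nrow(cat2), 1)
  expect_equal(rejections(cat2)$reason, "multi_fragment")
  expect_error(
    bb_catalog(data.frame(id = c("x", "x"), smiles = c("CCN", "CCCN")),
               "PRIMARY_AMINE"),
    "duplicate")
})
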