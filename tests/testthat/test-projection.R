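make_embedding <- function(coords, ids = rownames(coords)) {
  structure(list(ids = ids, coords = `dimnames<-`(coords, list(ids, c("x", "y"))),
                 params = list(method = "pcoa", k = 2L, seed = 42L)),
            class = "chem_embedding")
}

test_that("embedding is deterministic and returns one coordinate pair per id", {
  smis <- unique(fixture_amine(60)$smiles)[1:25]
  sim <- similarity_matrix(smis, ids = sprintf("m%d", seq_along(smis)))
  d <- distance_matrix(sim)
  e1 <- embed_chemspace(d)
  e2 <- embed_chemspace(d)
  expect_identical(e1$coords, e2$coords)
  expect_equal(dim(e1$coords), c(length(smis), 2))
  expect_error(embed_chemspace(d[1:2, 1:2]), "at least 3")
})

test_that("well-separated chemotype clusters stay separated in the embedding", {
  # linear alkanes vs substituted naphthalenes: very low cross-class
  # fingerprint similarity by construction
  alk <- paste0("C", strrep("C", 3:10))
  nap <- c("Cc1ccc2ccccc2c1", "CCc1ccc2ccccc2c1", "Cc1ccc2cc(C)ccc2c1",
           "Cc1ccc2cc(F)ccc2c1", "CCCc1ccc2ccccc2c1", "Cc1cccc2ccccc12",
           "Cc1ccc2cc(OC)ccc2c1", "CCc1cccc2ccccc12")
  ids <- c(sprintf("alk%d", seq_along(alk)), sprintf("nap%d", seq_along(nap)))
  sim <- similarity_matrix(c(alk, nap), ids = ids)
  emb <- embed_chemspace(distance_matrix(sim))
  grp <- rep(c("alk", "nap"), c(length(alk), length(nap)))
  cen <- apply(emb$coords, 2, function(v) tapply(v, grp, mean))
  inter <- sqrt(sum((cen[1, ] - cen[2, ])^2))
  spread <- mean(tapply(seq_along(ids), grp, function(i)
    mean(sqrt(rowSums(sweep(emb$coords[i, ], 2, colMeans(emb$coords[i, ]))^2)))))
  expect_gt(inter, spread)
})

test_that("duplicate structures land among the closest embedded pairs", {
  smis <- c(unique(fixture_acid(40)$smiles)[1:10], "OC(=O)CCCCC", "OC(=O)CCCCC")
  ids <- sprintf("m%d", seq_along(smis))
  sim <- similarity_matrix(smis, ids = ids)
  emb <- embed_chemspace(distance_matrix(sim))
  pd <- as.matrix(dist(emb$coords))
  dup <- pd["m11", "m12"]
  offdiag <- pd[upper.tri(pd)]
  expect_lte(dup, sort(offdiag)[3]) # within the 3 smallest pairwise distances
})

test_that("subset views are exact restrictions of the joint fit", {
  smis <- unique(fixture_amine(60)$smiles)[1:15]
  ids <- sprintf("m%d", seq_along(smis))
  emb <- embed_chemspace(distance_matrix(similarity_matrix(smis, ids = ids)))
  v <- subset_view(emb, ids[3:12])
  expect_identical(v$coords, emb$coords[ids[3:12], ])
  expect_identical(subset_view(emb, ids)$coords, emb$coords)
  # concatenated partition views rebuild the joint embedding exactly
  parts <- list(ids[1:5], ids[6:10], ids[11:15])
  rebuilt <- do.call(rbind, lapply(parts, function(p) subset_view(emb, p)$coords))
  expect_identical(rebuilt[emb$ids, ], emb$coords)
  expect_error(subset_view(emb, character(0)), "empty")
  expect_error(subset_view(emb, "nope"), "unknown")
})

test_that("the density surface is a normalized Gaussian KDE", {
  set.seed(9)
  coords <- cbind(c(rnorm(30, 0, 0.2), rnorm(30, 5, 0.2)),
                  c(rnorm(30, 0, 0.2), rnorm(30, 5, 0.2)))
  rownames(coords) <- sprintf("p%d", 1:60)
  den <- chem_density(make_embedding(coords), n = 80)
  expect_true(all(den$z >= 0))
  dx <- diff(den$x[1:2]); dy <- diff(den$y[1:2])
  expect_equal(sum(den$z) * dx * dy, 1, tolerance = 0.05)
  # a single tight cluster puts the mode at the centroid
  tight <- cbind(rnorm(40, 2, 0.05), rnorm(40, -1, 0.05))
  rownames(tight) <- sprintf("q%d", 1:40)
  dt <- chem_density(make_embedding(tight), n = 60)
  peak <- which(dt$z == max(dt$z), arr.ind = TRUE)
  expect_equal(dt$x[peak[1]], mean(tight[, 1]), tolerance = 0.2)
  expect_equal(dt$y[peak[2]], mean(tight[, 2]), tolerance = 0.2)
  # direct KDE evaluation at the peak grid node agrees
  hx <- dt$h[1] / 4; hy <- dt$h[2] / 4 # kde2d bandwidth convention
  direct <- mean(dnorm(dt$x[peak[1]], tight[, 1], hx) *
                 dnorm(dt$y[peak[2]], tight[, 2], hy))
  expect_equal(dt$z[peak], direct, tolerance = 1e-8, ignore_attr = TRUE)
  # degenerate spread errors
  flat <- cbind(rep(1, 5), 1:5)
  rownames(flat) <- sprintf("f%d", 1:5)
  expect_error(chem_density(make_embedding(flat)), "degenerate")
})
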