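grid_embedding <- function(nx = 10, ny = 10, spacing = 1) {
  g <- expand.grid(x = seq_len(nx) * spacing, y = seq_len(ny) * spacing)
  coords <- as.matrix(g)
  rownames(coords) <- sprintf("g%d", seq_len(nrow(g)))
  structure(list(ids = rownames(coords), coords = coords,
                 params = list(method = "grid")), class = "chem_embedding")
}

test_that("random selection is uniform without replacement and seeded", {
  pool <- sprintf("b%d", 1:10)
  all_of_it <- select_random(pool, 10, seed = 3)
  expect_setequal(all_of_it$chosen, pool)
  expect_identical(select_random(pool, 4, seed = 9)$chosen,
                   select_random(pool, 4, seed = 9)$chosen)
  expect_error(select_random(pool, 11), "exhausted")
  # pair frequencies over repeated draws: within 3 sigma of uniform
  pool4 <- letters[1:4]
  draws <- vapply(1:1000, function(s)
    paste(sort(select_random(pool4, 2, seed = s)$chosen), collapse = ""),
    character(1))
  tab <- table(draws)
  expect_equal(length(tab), 6)
  p <- 1 / 6
  sigma <- sqrt(1000 * p * (1 - p))
  expect_true(all(abs(tab - 1000 * p) <= 3 * sigma))
})

test_that("diversity selection does greedy max-min with index tie-breaks", {
  # 3-member pool with known distances: starting from A, the farthest is C
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.9
  d["B", "C"] <- d["C", "B"] <- 0.8
  seedA <- which(vapply(1:50, function(s)
    withr::with_seed(s, sample.int(3, 1)) == 1L, logical(1)))[1]
  sel <- select_diverse(d, k = 2, seed = seedA, distance = TRUE)
  expect_identical(sel$chosen, c("A", "C"))
  expect_identical(select_diverse(d, k = 1, seed = seedA, distance = TRUE)$chosen, "A")
})

test_that("diversity selection equals the brute-force oracle for every seed", {
  smis <- unique(fixture_amine(80)$smiles)[1:25]
  sim <- similarity_matrix(smis, ids = sprintf("m%d", 1:25))
  d <- distance_matrix(sim)
  for (s in 1:25) {
    sel <- select_diverse(sim, k = 10, seed = s)
    start <- withr::with_seed(s, sample.int(25, 1))
    oracle <- bf_greedy_maxmin(unclass(d), start, 10)
    expect_identical(sel$chosen, rownames(d)[oracle])
  }
})

test_that("uniform selection respects and reports its distance threshold", {
  emb <- grid_embedding(10, 10, spacing = 1)
  # k = 25 at threshold 2 is the optimum packing on this grid; a greedy
  # maximal packing over a random order may fall short and must then relax,
  # while still reporting a threshold every chosen pair respects
  sel <- select_uniform(emb, k = 25, threshold = 2.0, seed = 1)
  expect_equal(length(sel$chosen), 25)
  pd <- as.matrix(dist(emb$coords[sel$chosen, ]))
  expect_true(all(pd[upper.tri(pd)] >= sel$threshold))
  # well below the packing bound no relaxation is needed
  sel12 <- select_uniform(emb, k = 12, threshold = 2.0, seed = 1)
  expect_equal(sel12$threshold, 2.0)
  pd12 <- as.matrix(dist(emb$coords[sel12$chosen, ]))
  expect_true(all(pd12[upper.tri(pd12)] >= 2.0))
  # threshold 0 accepts the first k of the seeded permutation
  sel0 <- select_uniform(emb, k = 5, threshold = 0, seed = 4)
  perm <- withr::with_seed(4, sample.int(100))
  expect_identical(sel0$chosen, emb$ids[perm[1:5]])
})

test_that("duplicate coordinates are never co-selected at a positive threshold", {
  coords <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 2), c(3, 8), c(7, 7))
  rownames(coords) <- sprintf("p%d", 1:6)
  emb <- structure(list(ids = rownames(coords), coords = coords,
                        params = list()), class = "chem_embedding")
  for (s in 1:10) {
    sel <- select_uniform(emb, k = 5, threshold = 0.5, seed = s)
    expect_false(all(c("p1", "p2") %in% sel$chosen))
  }
  # a pick that must contain both copies of some point can never satisfy a
  # positive threshold: the relaxation bottoms out in a convergence error
  coords7 <- rbind(coords, c(5, 5))
  rownames(coords7) <- sprintf("p%d", 1:7)
  emb7 <- structure(list(ids = rownames(coords7), coords = coords7,
                         params = list()), class = "chem_embedding")
  expect_error(select_uniform(emb7, k = 6, threshold = 0.5, seed = 1),
               "floor|exhausted")
})

test_that("relaxation reports the final threshold and satisfies the contract", {
  set.seed(5)
  coords <- cbind(runif(40), runif(40))
  rownames(coords) <- sprintf("r%d", 1:40)
  emb <- structure(list(ids = rownames(coords), coords = coords,
                        params = list()), class = "chem_embedding")
  sel <- select_uniform(emb, k = 20, threshold = 0.5, seed = 2)
  expect_lt(sel$threshold, 0.5) # must have relaxed on a dense cloud
  pd <- as.matrix(dist(coords[sel$chosen, ]))
  expect_true(all(pd[upper.tri(pd)] >= sel$threshold))
})
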