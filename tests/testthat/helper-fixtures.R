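# Shared fixtures (built in code, memoized across test files) and
# independent brute-force oracles.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

fixture_paired <- function() memo("paired", generate_paired_catalogs(seed = 101))

fixture_amine <- function(n = 300, seed = 103)
  memo(sprintf("amine_%d_%d", n, seed),
       generate_catalog(catalog_spec("PRIMARY_AMINE", n, seed = seed)))

fixture_acid <- function(n = 300, seed = 104)
  memo(sprintf("acid_%d_%d", n, seed),
       generate_catalog(catalog_spec("CARBOXYLIC_ACID", n, seed = seed)))

# hand-built tiny catalog (all valid primary aliphatic amines)
tiny_amine_catalog <- function(costs = c(80, 250, 400, NA, 55)) {
  bb_catalog(data.frame(
    id = sprintf("A%d", seq_along(costs)),
    smiles = c("CCN", "NCCc1ccccc1", "NC1CCCCC1", "NCCO", "NCCCC")[seq_along(costs)],
    cost = costs), "PRIMARY_AMINE", provenance = "fixture")
}

tiny_acid_catalog <- function(n = 4) {
  smis <- c("CC(=O)O", "OC(=O)c1ccccc1", "OC(=O)CC1CCCC1", "OC(=O)CCO",
            "OC(=O)CCCC")[seq_len(n)]
  bb_catalog(data.frame(id = sprintf("C%d", seq_len(n)), smiles = smis,
                        cost = seq_len(n) * 50), "CARBOXYLIC_ACID",
             provenance = "fixture")
}

# SDF fixture writer: converts SMILES via OpenBabel and appends data fields
write_fixture_sdf <- function(path, smiles, ids, costs = NULL) {
  lines <- bbdesign:::ob_run(paste(smiles, ids), "-osdf", in_ext = "smi")
  rec_end <- which(lines == "$$$$")
  out <- character(0)
  start <- 1L
  for (r in seq_along(rec_end)) {
    body <- lines[start:(rec_end[r] - 1L)]
    fields <- c(sprintf(">  <Catalog_ID>"), ids[r], "")
    if (!is.null(costs) && !is.na(costs[r]))
      fields <- c(fields, ">  <Price_250mg>", format(costs[r]), "")
    out <- c(out, body, fields, "$$$$")
    start <- rec_end[r] + 1L
  }
  writeLines(out, path)
  path
}

# ---- brute-force oracles ----------------------------------------------------

bf_tanimoto <- function(a, b) {
  i <- sum(a & b); u <- sum(a | b)
  if (u == 0) 0 else i / u
}

bf_sim_matrix <- function(fp) {
  n <- nrow(fp)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- bf_tanimoto(fp[i, ], fp[j, ])
  dimnames(m) <- list(rownames(fp), rownames(fp))
  m
}

bf_nn_scores <- function(sim) {
  vapply(seq_len(nrow(sim)), function(i) max(sim[i, -i]), numeric(1))
}

# plain-as-possible greedy max-min on a distance matrix, seeded start
bf_greedy_maxmin <- function(d, start, k) {
  chosen <- start
  while (length(chosen) < k) {
    cand <- setdiff(seq_len(nrow(d)), chosen)
    score <- vapply(cand, function(i) min(d[i, chosen]), numeric(1))
    chosen <- c(chosen, cand[which.max(score)])
  }
  chosen
}
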