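---
title: "Building-block-centric design of two-cycle DNA-encoded libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building-block-centric design of two-cycle DNA-encoded libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

DNA-encoded libraries (DELs) are combinatorial small-molecule collections in
which every member carries a DNA barcode recording its building-block (BB)
combination. For a two-cycle amide-coupled DEL, the design questions are
almost entirely BB-centric: which monomer classes to use (Fmoc-protected
amino acids vs. primary amines in cycle 1, carboxylic acids in cycle 2), how
to filter candidate BBs by cost and physicochemical properties (PCPs), and
how to pick a plate-sized subset (typically 192 = two 96-well plates) from
pools of thousands. `bbdesign` implements this workflow end to end:

1. **Catalogs** — SDF/CSV ingest with canonicalization, rejection logging,
   and PCP computation (`read_catalog_sdf()`, `read_catalog_csv()`,
   `compute_pcp()`).
2. **Truncates** — each BB's class-defining group is replaced by H
   (`truncate_bb()`), isolating the diversity scaffold so that similarity
   reflects the part of the molecule that survives into the library.
3. **Similarity** — radius-3 circular (ECFP6-type) fingerprints folded to
   2048 bits, all-by-all Tanimoto matrices, nearest-neighbor (nn) scores
   (`morgan_fp()`, `similarity_matrix()`, `nn_tanimoto()`).
4. **Projection** — a joint 2D embedding of the truncate distance matrix
   with Gaussian-KDE coverage surfaces (`embed_chemspace()`,
   `chem_density()`).
5. **Selection** — random, diversity (greedy max-min) and uniform
   (embedding-space thinning) strategies (`select_*()`).
6. **Enumeration** — full cross-product amide coupling with per-product
   PCPs and mass-balance guarantees (`enumerate_library()`).
7. **Pipelines** — the comparative experiments (`run_*()` functions).

## Chemistry engine

All parsing, canonicalization, descriptor calculation, SMARTS matching and
fingerprinting are delegated to OpenBabel (in-process through
ChemmineR/ChemmineOB, and through the `obabel` executable for batches of
thousands of molecules, where a single C++ pass replaces a per-molecule R
loop). Structure *editing* — truncation, Fmoc deprotection, conversion of a
carboxylate to the pendant primary amide, and amide coupling — operates on
kekulized connection tables parsed from SDF blocks: groups are located by
graph patterns, atoms are deleted or retyped, and the result is
re-serialized as a V2000 molblock and canonicalized by OpenBabel. The layer
assumes neutral, single-fragment organic molecules; salts and multi-fragment
records are rejected at ingest and logged.

Two conventions matter downstream:

* **Donor/acceptor counting is atom-based.** A donor is one N or O heavy
  atom bearing at least one H; acceptors are the Lipinski N+O count. Under
  these conventions a primary amide -C(=O)NH2 contributes exactly one donor
  and two acceptors, and the DEL1-vs-DEL2 constant-adduct difference
  (`scaffold_delta()`) computes to +44 Da (CH2NO), +1 HBD, +2 HBA.
* **One logP estimator everywhere.** The same atom-contribution
  (Crippen-type) estimate is used for BB filtering and for product
  properties; mixing calculators would make the RO3/RO5 filters and the
  product summaries incommensurable.

Fmoc-amino acids are always *weighed ignoring Fmoc*: property filters and
the generator's MW calibration use the Fmoc-removed form, since the
protecting group never reaches the library product.

## Filters

`class_filter()` removes secondary amines, proline-like secondary amino
acids, and aniline nitrogens (unreactive or competing in amide chemistry).
The SMARTS patterns are exported via `bb_class_patterns()`; they restrict
to aliphatic N (`[NX3;A...]`) so aromatic ring nitrogens are not mistaken
for anilines, and they exempt amides and sulfonamides. The more specific
amino-acid pattern is evaluated first so rejection reasons are informative.

`cost_filter()` is boundary-inclusive (a $250 BB passes the ≤$250 tier) and
rejects missing costs — the conservative purchasing assumption; a BB you
cannot price is a BB you cannot order. `pcp_filter()` applies RO3
(MW < 300, clogP ≤ 3, HBD ≤ 3, HBA ≤ 3) and RO5 (MW < 500, clogP < 5,
HBD ≤ 5, HBA ≤ 10) with *strict* MW bounds, while standalone MW cutoffs
(≤200/250/300 Da) are inclusive. All filters are pointwise predicates, so
they commute and their threshold tiers produce nested subsets — both
properties are tested.

BBs carrying more than one instance of their defining group are flagged
polyfunctional by `truncate_catalog()`: all instances are replaced in the
truncate (they remain usable for chemical-space analysis), but coupling
refuses them (`couple_amide()` raises an ambiguity error), since the product
would not be unique.

## The 2D embedding

Chemical-space views are produced by classical metric multidimensional
scaling (principal coordinates) of the 1 − Tanimoto distance matrix,
computed **once, jointly** over all BB sets under comparison; per-set
figures are `subset_view()`s of that joint fit and are never re-fitted, so
every panel shares one coordinate frame. PCoA was chosen because it is
deterministic and hyperparameter-free: identical inputs give identical
coordinates with no stochastic layout step, which makes the pipeline's
end-to-end reproducibility contract exact rather than seed-dependent.

Low-dimensional embeddings of fingerprint distances preserve cluster-level
topology for well-separated chemotypes, but embedded distances are not
quantitatively proportional to Tanimoto distances. Accordingly the test
suite asserts only cluster-level properties (separated scaffold families
stay separated; duplicate structures land together) and never metric
preservation. The KDE coverage surface uses the normal-reference bandwidth
rule per axis (configurable), with grid limits padded by 0.8 bandwidths so
the density integrates to ≈1 over the grid.

## Selection strategies

* `select_random()` — uniform sampling without replacement; the baseline
  that follows commercial abundance.
* `select_diverse()` — greedy max-min: seed with a random member, then
  repeatedly add the candidate whose minimum distance to the chosen set is
  largest. Ties break to the lowest pool index; that rule plus the seed make
  the output reproducible, and the implementation is verified against a
  plain re-implementation on every seed of small pools.
* `select_uniform()` — greedy acceptance over a seeded permutation, keeping
  a candidate only if it is at least `threshold` away (Euclidean, embedding
  space) from everything already kept. If a pass cannot reach `k`, the
  threshold relaxes geometrically (factor 0.9) over the remaining
  candidates until `k` is reached or the threshold floor (1e-6) is hit.
  The realized threshold is reported, and every chosen pair is at least
  that far apart. A greedy pass yields a *maximal*, not maximum, packing:
  when `k` is at the packing bound for the requested threshold the method
  may relax even though an optimal arrangement exists. Selecting the whole
  pool (`k` = pool size) is treated as the vacuous case and reports the
  realized minimum pairwise distance.

## The synthetic catalog generator

Commercial BB exports cannot be redistributed, so `generate_catalog()`
fabricates catalogs with the *statistical shape* the pipeline cares about,
from a scaffold grammar of ~600 fragment variants across ten chemotype
families (linear/branched aliphatics, cycloalkanes, substituted benzenes,
short polar aliphatics, heteroaromatics, dihydrobenzofurans, naphthalenes,
benzylsulfonamides, biphenyls, fused bicyclics). Every fragment attaches
through an sp3 carbon (for amines and amino acids) so the defining group is
always a primary *aliphatic* amine, and fragments never contain amines,
acids or carbamates — each generated BB carries exactly one unambiguous
defining group by construction (real catalogs violate this; the truncate
and enumeration modules handle that generically).

Calibrated and configurable conditions (defaults in `catalog_spec()`):

* **Class MW medians** 171 / 174 / 220 Da (Fmoc-AA weighed ignoring Fmoc):
  fragment weights are drawn from a normal centred on the target minus the
  head-group increment (sd 45 Da) and matched to grammar variants within a
  ±20 Da window. Realized medians land within ±15 Da at n ≥ 2000.
* **Class clogP medians** −1.8 / 0.69 / 1.1 steer variant choice within the
  MW window (exponential weight on clogP closeness). The grammar is
  hydrocarbon-dominant to keep defining groups unambiguous, so realized
  clogP medians sit above the commercial targets (~1.5–3); MW is the
  calibrated axis, clogP a directional bias. Consequently enumerated
  synthetic products run more lipophilic than commercial-catalog products.
* **Bimodal cost** — a two-component log-normal mixture, component medians
  $70 and $400 per 250 mg (sdlog 0.45/0.40, equal weights). Component
  membership is tilted by chemotype commonness (linear/cycloalkane/benzene
  cheap-leaning, naphthalene/sulfonamide/biphenyl premium-leaning) and by
  structural redundancy: repeat copies of an already-drawn scaffold price
  mostly into the budget mode, mirroring how popular compounds are cheap.
  This coupling is what gives cost filtering its chemical-space
  consequences — the budget tier is enriched in redundant common scaffolds,
  so its random picks have higher nn-Tanimoto medians, with diminishing
  change from the middle to the top tier. The mixture mode locations remain
  recoverable within 20% by a two-component fit (`estimate_cost_modes()`).
* **Set sizes** — `generate_paired_catalogs()` defaults to 400 Fmoc-AAs <
  800 acids < 1200 amines, preserving the commercial ordering (amino acids
  are by far the smallest class) at desk scale. A configurable fraction
  (default 0.25) of amine scaffolds duplicates Fmoc-AA side chains through
  a methylene attachment, so H2N-CH2-R and the amino acid with side chain R
  truncate to the same CH3-R — reproducing the observation that few amino
  acid truncates are unique relative to the amine pool. The 0 and 1 limit
  cases are exact (enforced disjointness / guaranteed coverage).

What the generator does **not** emulate: real catalogs' absolute pool sizes
(tens of thousands), their much lower structural redundancy at scale,
stereochemistry, salts and polyfunctional members, and vendor-specific
pricing. Passing tests therefore demonstrate the pipeline's correctness and
its qualitative comparative behavior, not the commercial catalogs'
quantitative statistics (absolute nn-Tanimoto medians, truncate counts and
dollar totals will differ from any published analysis of vendor data).

## Library enumeration

`enumerate_library()` forms every (cycle-1, cycle-2) amide product. For the
DEL2 scheme cycle 1 is a primary amine; for DEL1 it is an Fmoc-amino acid
that is deprotected and whose carboxylate becomes the pendant -C(=O)NH2
left by photocleavage, so released DEL1 products carry that constant adduct
in addition to the BB-connecting amide. Products are represented as the
released (off-DNA) compound — the PCP-relevant species — ignoring the
linker attachment point. Every product obeys condensation mass balance
(MW_product = MW_amine + MW_acid − 18.0153 Da, to ±0.01), enumerated counts
equal |cycle1|×|cycle2| minus logged failures, and nothing is dropped
silently. A 192 × 192 enumeration (36,864 products) with full property
calculation runs in well under two minutes on one CPU.

## Problem sizes and numerical choices

Tests and the acceptance script run the generator at its default paired
sizes (400/800/1200; joint truncate matrices ≈ 2,400 molecules), parameter
recovery at n = 2000 per class, oracle-equivalence checks at n ≤ 50, and
selection comparisons at k = 48–192 over ≥ 20 seeds — sizes chosen so each
stage's behavior is measurable at interactive timescales. Ties in greedy
max-min resolve to the lowest pool index; all randomness flows through
explicit seeds (`withr::with_seed`), so every pipeline output is a pure
function of its inputs and seed. Degenerate inputs fail loudly: empty
catalogs, singleton nn-sets, all-identical embeddings and all-zero
fingerprints raise informative errors (all-zero pairs define Tanimoto 0
with a warning).

## Known limitations

* Neutral organics only in the graph-edit layer; charged species raise
  truncation errors rather than being mis-edited.
* Binary fingerprints only (no counts, no chirality flags); stereochemistry
  is ignored throughout.
* The uniform selector's greedy packing is order-dependent (by design,
  for determinism) and may relax below an achievable threshold.
* The embedding is a global linear-algebraic summary; fine local structure
  visible to nonlinear methods may be smoothed out, which is acceptable for
  the coverage-comparison use the pipeline makes of it.
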