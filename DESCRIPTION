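Package: bbdesign
Title: Building-Block-Centric Design of DNA-Encoded Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building-block (BB) centric design of DNA-encoded
    libraries (DELs). Reads and writes BB catalogs (SDF/CSV), truncates BBs by
    replacing class-defining functional groups (primary amine, carboxylic
    acid, Fmoc carbamate) with hydrogen, computes physicochemical properties
    and ECFP6/Tanimoto similarity matrices, embeds truncate chemical space in
    two dimensions with a kernel density view, selects BBs by random,
    diversity (greedy max-min) and uniform (embedding-space thinning)
    strategies, enumerates two-cycle amide-coupled libraries, and compares
    cost- and property-stratified library designs. Includes a seeded
    synthetic-catalog generator emulating commercial amine, acid and
    Fmoc-amino-acid collections so every stage runs without vendor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    MASS,
    igraph,
    mclust,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: OpenBabel (>= 3.0, 'obabel' on the PATH)
Config/testthat/edition: 3
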