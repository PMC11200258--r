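#' Building-block classes
#'
#' The three building-block (BB) classes handled by the package, as used in
#' two-cycle DEL designs: Fmoc-protected amino acids (bifunctional), primary
#' aliphatic amines and carboxylic acids. Each class has one defining
#' functional group pattern (see [bb_class_patterns()]).
#'
#' @return Character vector of the three class labels.
#' @export
bb_classes <- function() c("FMOC_AA", "PRIMARY_AMINE", "CARBOXYLIC_ACID")

#' Defining-group and filter SMARTS patterns
#'
#' SMARTS patterns used to recognize each class's defining functional group at
#' catalog ingest, and the substructure patterns used by [class_filter()]
#' (secondary amines, proline-like secondary amino acids, aniline nitrogens).
#' Exposed so that the exact patterns in force are user-visible.
#'
#' @return Named list with elements `defining` (per class; FMOC_AA has two
#'   patterns that must both match) and `reject` (named by rejection reason).
#' @export
bb_class_patterns <- function() {
  list(
    defining = list(
      PRIMARY_AMINE = "[NX3;H2;!$([NX3]C=O)][CX4]",
      CARBOXYLIC_ACID = "[CX3](=O)[OX2H1]",
      FMOC_AA = c("[NX3][CX3](=O)[OX2][CH2]", "[CX3](=O)[OX2H1]")
    ),
    reject = c(
      # order matters for the reported reason: the more specific
      # amino-acid pattern is checked before the generic secondary amine
      secondary_amino_acid = "[NX3;A;H1;!$([NX3]C=O);!$([NX3]S(=O)=O)][CX4][CX3](=O)[OX2H1]",
      secondary_amine = "[NX3;A;H1;!$([NX3]C=O);!$([NX3]S(=O)=O)]([#6])[#6]",
      aniline_nitrogen = "[NX3;A;!$([NX3]C=O);!$([NX3]S(=O)=O)][c]"
    )
  )
}

match_bb_class <- function(bb_class) {
  match.arg(bb_class, bb_classes())
}

#' Compute physicochemical properties for molecules
#'
#' Computes the PCP set used throughout the package: average-atomic-weight
#' molecular weight (Da), an atom-contribution octanol-water partition
#' estimate (clogP), topological polar surface area (A^2), hydrogen bond
#' donors (count of N/O heavy atoms bearing at least one H) and acceptors
#' (Lipinski N+O count). Donor counting is atom-based, so a primary amide
#' -C(=O)NH2 contributes one donor and two acceptors.
#'
#' @param smiles Character vector of SMILES.
#' @return A data.frame with one row per input: `smiles` (canonical), `mw`,
#'   `clogp`, `tpsa`, `hbd`, `hba`.
#' @examples
#' \dontrun{
#' compute_pcp(c("O", "CC(=O)N", "c1ccccc1"))
#' }
#' @export
compute_pcp <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles))
    return(data.frame(smiles = character(0), mw = numeric(0), clogp = numeric(0),
                      tpsa = numeric(0), hbd = integer(0), hba = integer(0)))
  p <- ob_props(smiles)
  if (anyNA(p$cansmi))
    stop("unparsable SMILES: ", paste(smiles[is.na(p$cansmi)], collapse = ", "),
         call. = FALSE)
  data.frame(smiles = p$cansmi, mw = p$mw, clogp = p$clogp, tpsa = p$tpsa,
             hbd = p$hbd, hba = p$hba, stringsAsFactors = FALSE)
}

#' Construct a BB catalog
#'
#' A catalog is a data.frame of building blocks of one class with columns
#' `id`, `smiles` (canonical), `cost` (USD per 250 mg pack; `NA` when
#' unknown), and the PCP columns `mw`, `clogp`, `tpsa`, `hbd`, `hba`.
#'
#' @param members data.frame with at least `id` and `smiles`; PCP columns are
#'   computed when absent.
#' @param bb_class One of [bb_classes()].
#' @param provenance Free-text source tag.
#' @param rejections data.frame of `(id, reason)` for records dropped during
#'   ingest; retrievable with [rejections()].
#' @return An object of class `bb_catalog` (a data.frame).
#' @export
bb_catalog <- function(members, bb_class, provenance = "user",
                       rejections = data.frame(id = character(0), reason = character(0))) {
  bb_class <- match_bb_class(bb_class)
  stopifnot(is.data.frame(members), all(c("id", "smiles") %in% names(members)))
  if (anyDuplicated(members$id))
    stop("duplicate ids in catalog: ",
         paste(unique(members$id[duplicated(members$id)]), collapse = ", "),
         call. = FALSE)
  if (!"cost" %in% names(members)) members$cost <- NA_real_
  pcp_cols <- c("mw", "clogp", "tpsa", "hbd", "hba")
  if (!all(pcp_cols %in% names(members)) && nrow(members) > 0) {
    p <- compute_pcp(members$smiles)
    members$smiles <- p$smiles # canonical form
    members[pcp_cols] <- p[pcp_cols]
  }
  keep <- c("id", "smiles", "cost", pcp_cols,
            intersect("truncate_smiles", names(members)))
  members <- members[, keep, drop = FALSE]
  rownames(members) <- NULL
  structure(members,
            class = c("bb_catalog", "data.frame"),
            bb_class = bb_class, provenance = provenance, rejections = rejections)
}

#' @export
print.bb_catalog <- function(x, ...) {
  cat(sprintf("<bb_catalog> %s: %d building blocks (%s)\n",
              attr(x, "bb_class"), nrow(x), attr(x, "provenance")))
  rej <- rejections(x)
  if (nrow(rej)) cat(sprintf("  %d record(s) rejected at ingest\n", nrow(rej)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' @export
summary.bb_catalog <- function(object, ...) {
  cat(sprintf("BB catalog (%s), n = %d, provenance = %s\n",
              attr(object, "bb_class"), nrow(object), attr(object, "provenance")))
  if (nrow(object)) {
    cat(sprintf("  median MW %.1f Da, median clogP %.2f, cost known for %d/%d\n",
                stats::median(object$mw), stats::median(object$clogp),
                sum(!is.na(object$cost)), nrow(object)))
  }
  invisible(object)
}

#' Catalog class and ingest rejections
#'
#' @param x A `bb_catalog`.
#' @return `catalog_class()` returns the BB class label; `rejections()` the
#'   data.frame of records excluded at ingest with their reasons.
#' @export
catalog_class <- function(x) attr(x, "bb_class")

#' @rdname catalog_class
#' @export
rejections <- function(x) {
  r <- attr(x, "rejections")
  if (is.null(r)) data.frame(id = character(0), reason = character(0)) else r
}

# Shared ingest path: canonicalize, compute/trust PCPs, enforce the
# connected-molecule and defining-group invariants, log rejections.
ingest_members <- function(raw, bb_class, provenance, trust_pcp = FALSE) {
  if (nrow(raw) == 0)
    stop("no parsable records in input", call. = FALSE)
  p <- ob_props(raw$smiles)
  rej <- data.frame(id = character(0), reason = character(0))
  bad_parse <- is.na(p$cansmi)
  multi <- !bad_parse & grepl(".", p$cansmi, fixed = TRUE)
  ok <- !bad_parse & !multi
  def <- rep(FALSE, nrow(raw))
  if (any(ok)) {
    pats <- bb_class_patterns()$defining[[bb_class]]
    m <- rep(TRUE, sum(ok))
    for (pat in pats) m <- m & ob_matches(p$cansmi[ok], pat)
    def[ok] <- m
  }
  add_rej <- function(which, reason)
    data.frame(id = as.character(raw$id[which]), reason = reason)
  rej <- rbind(rej,
               if (any(bad_parse)) add_rej(bad_parse, "unparsable_structure"),
               if (any(multi)) add_rej(multi, "multi_fragment"),
               if (any(ok & !def)) add_rej(ok & !def, "missing_defining_group"))
  keep <- ok & def
  if (!any(keep))
    stop("no valid records of class ", bb_class, " in input", call. = FALSE)
  members <- data.frame(id = as.character(raw$id[keep]),
                        smiles = p$cansmi[keep],
                        cost = raw$cost[keep], stringsAsFactors = FALSE)
  pcp_cols <- c("mw", "clogp", "tpsa", "hbd", "hba")
  if (trust_pcp && all(pcp_cols %in% names(raw))) {
    members[pcp_cols] <- raw[keep, pcp_cols]
  } else {
    members[pcp_cols] <- p[keep, c("mw", "clogp", "tpsa", "hbd", "hba")]
  }
  if ("truncate_smiles" %in% names(raw))
    members$truncate_smiles <- raw$truncate_smiles[keep]
  bb_catalog(members, bb_class, provenance, rejections = rej)
}

#' Read a BB catalog from an SDF file
#'
#' Reads an MDL SDF (V2000/V3000) catalog export. Structures that fail to
#' parse, are multi-fragment (salts), or lack the class's defining functional
#' group are excluded and recorded in the rejection log ([rejections()]).
#' Missing cost fields are recorded as `NA`, never zero.
#'
#' @param path Path to the SDF file.
#' @param bb_class One of [bb_classes()].
#' @param field_map Named character vector mapping roles to SDF data-field
#'   names, e.g. `c(id = "Catalog_ID", cost = "Price_250mg")`. The `id` entry
#'   is required; when absent from a record the molecule title is used.
#' @return A [bb_catalog()].
#' @export
read_catalog_sdf <- function(path, bb_class,
                             field_map = c(id = "id", cost = "cost")) {
  bb_class <- match_bb_class(bb_class)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 1, warn = FALSE)) == 0)
    stop("no records in SDF file: ", path, call. = FALSE)
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) stop("unreadable SDF file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  if (length(sdf) == 0) stop("no records in SDF file: ", path, call. = FALSE)
  valid <- ChemmineR::validSDF(sdf)
  sdf <- sdf[valid]
  if (length(sdf) == 0) stop("no parsable records in SDF file: ", path, call. = FALSE)
  blocks <- ChemmineR::datablock(sdf)
  get_field <- function(bl, key) {
    if (!is.na(key) && key %in% names(bl)) bl[[key]] else NA_character_
  }
  ids <- vapply(seq_along(sdf), function(i)
    get_field(blocks[[i]], field_map[["id"]]), character(1))
  titles <- ChemmineR::sdfid(sdf)
  ids[is.na(ids) | ids == ""] <- titles[is.na(ids) | ids == ""]
  costs <- if ("cost" %in% names(field_map)) {
    suppressWarnings(as.numeric(vapply(seq_along(sdf), function(i)
      get_field(blocks[[i]], field_map[["cost"]]), character(1))))
  } else rep(NA_real_, length(sdf))
  # recover SMILES through one obabel pass over the raw records
  txt <- unlist(lapply(seq_along(sdf), function(i) {
    lines <- ChemmineR::sdf2str(sdf[[i]])
    lines[1] <- sprintf("i%d", i)
    lines
  }))
  out <- ob_run(txt, "-ocan", in_ext = "sdf")
  pp <- ob_parse_titled(out)
  smi <- pp$payload[match(sprintf("i%d", seq_along(sdf)), pp$title)]
  raw <- data.frame(id = ids, smiles = smi, cost = costs, stringsAsFactors = FALSE)
  raw$smiles[is.na(raw$smiles)] <- "*invalid*"
  ingest_members(raw, bb_class, provenance = path)
}

#' Read a BB catalog from a CSV file
#'
#' The CSV must have a header row. Default column names are `smiles`, `id`,
#' `cost`, optionally the PCP columns `mw`, `clogp`, `tpsa`, `hbd`, `hba`
#' (trusted as given when all present) and `truncate_smiles`.
#'
#' @inheritParams read_catalog_sdf
#' @param column_map Optional named character vector renaming roles to CSV
#'   columns, e.g. `c(smiles = "SMILES", id = "Vendor_ID", cost = "price")`.
#' @return A [bb_catalog()].
#' @export
read_catalog_csv <- function(path, bb_class, column_map = NULL) {
  bb_class <- match_bb_class(bb_class)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (role in names(column_map)) {
      cm <- column_map[[role]]
      if (!cm %in% names(df))
        stop("column '", cm, "' not present in ", path, call. = FALSE)
      names(df)[names(df) == cm] <- role
    }
  }
  for (must in c("smiles", "id")) {
    if (!must %in% names(df))
      stop("mandatory column '", must, "' missing in ", path, call. = FALSE)
  }
  if (anyDuplicated(df$id))
    stop("duplicate id values in ", path, call. = FALSE)
  if (!"cost" %in% names(df)) df$cost <- NA_real_
  df$cost <- suppressWarnings(as.numeric(df$cost))
  pcp_cols <- c("mw", "clogp", "tpsa", "hbd", "hba")
  ingest_members(df, bb_class, provenance = path,
                 trust_pcp = all(pcp_cols %in% names(df)))
}

#' Write a BB catalog to CSV
#'
#' Round-trip safe with [read_catalog_csv()]: ids, canonical SMILES and costs
#' are preserved in order.
#'
#' @param catalog A non-empty [bb_catalog()].
#' @param path Output file path.
#' @param include_truncate If `TRUE`, adds a `truncate_smiles` column
#'   (computed with [truncate_catalog()] when not already present).
#' @return `path`, invisibly.
#' @export
write_catalog_csv <- function(catalog, path, include_truncate = FALSE) {
  stopifnot(inherits(catalog, "bb_catalog"))
  if (nrow(catalog) == 0) stop("refusing to write an empty catalog", call. = FALSE)
  df <- as.data.frame(catalog)
  if (include_truncate && !"truncate_smiles" %in% names(df)) {
    tr <- truncate_catalog(catalog)
    df$truncate_smiles <- tr$smiles[match(df$id, tr$parent_id)]
  }
  if (!include_truncate) df$truncate_smiles <- NULL
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write catalog to ", path, call. = FALSE)
  invisible(path)
}

# internal: subset a catalog preserving attributes
catalog_subset <- function(catalog, keep_idx) {
  out <- as.data.frame(catalog)[keep_idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("bb_catalog", "data.frame"),
            bb_class = attr(catalog, "bb_class"),
            provenance = attr(catalog, "provenance"),
            rejections = attr(catalog, "rejections"))
}
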