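# Internal bridge to OpenBabel's `obabel` CLI for batch chemistry.
# Small/structural operations go through ChemmineR/ChemmineOB in-process;
# anything that touches thousands of molecules goes through one obabel call.

ob_available <- function() nzchar(Sys.which("obabel"))

ob_assert <- function() {
  if (!ob_available())
    stop("OpenBabel's 'obabel' executable was not found on the PATH", call. = FALSE)
}

# Run obabel on `input` (character vector of lines), return output lines.
# `args` must include the output format; input/output via temp files.
ob_run <- function(input, args, in_ext = "smi") {
  ob_assert()
  fin <- tempfile(fileext = paste0(".", in_ext))
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input, fin)
  res <- suppressWarnings(
    system2("obabel", shQuote(c(fin, args, "-O", fout)), stdout = TRUE, stderr = TRUE)
  )
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("obabel failed (exit ", status, "): ", paste(utils::tail(res, 3), collapse = " "),
         call. = FALSE)
  if (!file.exists(fout)) return(character(0))
  readLines(fout, warn = FALSE)
}

# Tag molecules with index titles i1..iN so skipped records can be detected.
ob_titles <- function(n) sprintf("i%d", seq_len(n))

ob_parse_titled <- function(lines) {
  # each line: "<payload>\t<title>[ appended fields...]"
  parts <- regmatches(lines, regexpr("\t", lines), invert = TRUE)
  payload <- vapply(parts, `[`, "", 1L)
  rest <- vapply(parts, function(x) if (length(x) > 1) x[2] else "", "")
  toks <- strsplit(trimws(rest), "[ \t]+")
  list(payload = payload,
       title = vapply(toks, `[`, "", 1L),
       fields = lapply(toks, function(x) x[-1L]))
}

# Canonical SMILES + physicochemical properties in one pass.
# Returns a data.frame aligned with `smiles`; unparsable entries are NA rows.
ob_props <- function(smiles, input = c("smi", "sdf")) {
  input <- match.arg(input)
  n_expected <- if (input == "smi") length(smiles) else NA_integer_
  if (input == "smi") {
    if (length(smiles) == 0)
      return(data.frame(cansmi = character(0), mw = numeric(0), clogp = numeric(0),
                        tpsa = numeric(0), hbd = integer(0), hba = integer(0)))
    titles <- ob_titles(length(smiles))
    src <- paste(smiles, titles)
  } else {
    src <- smiles # already SDF text with index titles on the name line
    titles <- NULL
  }
  out <- ob_run(src, c("-ocan", "--append", "MW logP TPSA HBD HBA2"), in_ext = input)
  p <- ob_parse_titled(out)
  vals <- do.call(rbind, lapply(p$fields, function(f) suppressWarnings(as.numeric(f[1:5]))))
  got <- data.frame(cansmi = p$payload, mw = vals[, 1], clogp = vals[, 2],
                    tpsa = vals[, 3], hbd = as.integer(vals[, 4]),
                    hba = as.integer(vals[, 5]), row.names = NULL,
                    stringsAsFactors = FALSE)
  if (is.null(titles)) {
    rownames(got) <- p$title
    return(got)
  }
  idx <- match(titles, p$title)
  res <- got[idx, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ECFP6 (radius-3 circular) fingerprints folded to `nbits`. Returns a logical
# matrix [n x nbits]; rows of all-NA input or failed parses are flagged NA.
ob_fp <- function(smiles, nbits = 2048L) {
  stopifnot(length(smiles) >= 1)
  titles <- ob_titles(length(smiles))
  out <- ob_run(paste(smiles, titles), c("-ofps", "-xfECFP6"), in_ext = "smi")
  out <- out[!startsWith(out, "#")]
  p <- ob_parse_titled(out)
  hex2bits <- .hex_bit_table()
  mat <- matrix(FALSE, nrow = length(smiles), ncol = 4096L)
  ok <- rep(FALSE, length(smiles))
  idx <- match(p$title, titles)
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (is.na(i)) next
    chars <- strsplit(p$payload[k], "", fixed = TRUE)[[1]]
    bits <- as.vector(hex2bits[, match(chars, colnames(hex2bits))])
    if (length(bits) == 4096L) {
      mat[i, ] <- bits
      ok[i] <- TRUE
    }
  }
  if (!all(ok))
    stop("fingerprint generation failed for input(s): ",
         paste(utils::head(smiles[!ok], 5), collapse = ", "), call. = FALSE)
  folded <- mat[, 1:nbits, drop = FALSE] | mat[, (nbits + 1):(2 * nbits), drop = FALSE]
  folded
}

.hex_bit_table <- function() {
  chars <- c(0:9, letters[1:6], LETTERS[1:6])
  vals <- c(0:15, 10:15)
  m <- vapply(vals, function(v) as.logical(bitwAnd(v, c(8L, 4L, 2L, 1L))), logical(4))
  colnames(m) <- as.character(chars)
  m
}

# SMARTS screen: TRUE where the molecule contains the pattern.
ob_matches <- function(smiles, smarts) {
  if (length(smiles) == 0) return(logical(0))
  titles <- ob_titles(length(smiles))
  out <- ob_run(paste(smiles, titles), c("-osmi", "-s", smarts), in_ext = "smi")
  p <- ob_parse_titled(out)
  titles %in% p$title
}

# Canonical SMILES only; NA where parsing fails.
ob_canonical <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  res <- ob_props(smiles)
  res$cansmi
}
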