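#' @include AllClasses.R
NULL

#' Construct a molecular graph
#'
#' @param types character vector of atom type labels (1-based atom order).
#' @param bonds two-column matrix (or list of pairs) of bonded atom indices.
#' @param charges optional numeric vector of 3-decimal partial charges in e.
#' @param totalCharge target total charge in e; when \code{NULL} and charges
#'   are given, defaults to their 3-decimal-rounded sum.
#' @param identifier molecule name.
#' @return a \linkS4class{MolecularGraph}
#' @examples
#' m <- molecularGraph(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)),
#'                     charges = c(-0.8, 0.4, 0.4), identifier = "water")
#' nAtoms(m)
#' @export
molecularGraph <- function(types, bonds = matrix(integer(0), 0, 2),
                           charges = NULL, totalCharge = NULL,
                           identifier = "molecule") {
  if (is.list(bonds)) bonds <- do.call(rbind, lapply(bonds, as.integer))
  if (is.null(bonds) || length(bonds) == 0L) {
    bonds <- matrix(integer(0), 0, 2)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    bonds <- bonds[!duplicated(paste(bonds[, 1], bonds[, 2])), , drop = FALSE]
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  if (is.null(charges)) charges <- rep(NA_real_, length(types))
  if (is.null(totalCharge)) {
    totalCharge <- if (all(!is.na(charges))) round(sum(charges), 3) else NA_real_
  }
  new("MolecularGraph",
      atoms = data.frame(type = as.character(types), charge = as.numeric(charges),
                         stringsAsFactors = FALSE),
      bonds = bonds, totalCharge = as.numeric(totalCharge),
      identifier = as.character(identifier))
}

# ---------------------------------------------------------------------------
# SDF dialect (V2000): one molecule per record, charges in > <PARTIAL_CHARGES>
# (one 3-decimal value per atom, atom order), total charge in > <TOTAL_CHARGE>,
# optional per-atom type labels in > <ATOM_TYPES>.
# ---------------------------------------------------------------------------

.parseError <- function(record, line, msg) {
  stop(sprintf("SDF parse error in record %d (line %d): %s", record, line, msg),
       call. = FALSE)
}

.parseSdfRecord <- function(lines, recIdx, offset) {
  if (length(lines) < 4L)
    .parseError(recIdx, offset + length(lines), "truncated header")
  counts <- lines[4]
  nA <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nB <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nA) || is.na(nB) || nA < 1L)
    .parseError(recIdx, offset + 4, "bad counts line")
  if (length(lines) < 4L + nA + nB)
    .parseError(recIdx, offset + length(lines), "connection table truncated")
  atomLines <- lines[4L + seq_len(nA)]
  types <- trimws(substr(atomLines, 32, 34))
  if (any(!nzchar(types)))
    .parseError(recIdx, offset + 4L + which(!nzchar(types))[1], "missing atom symbol")
  bonds <- matrix(integer(0), 0, 2)
  if (nB > 0L) {
    bondLines <- lines[4L + nA + seq_len(nB)]
    bi <- suppressWarnings(as.integer(substr(bondLines, 1, 3)))
    bj <- suppressWarnings(as.integer(substr(bondLines, 4, 6)))
    if (anyNA(bi) || anyNA(bj))
      .parseError(recIdx, offset + 4L + nA + which(is.na(bi) | is.na(bj))[1],
                  "bad bond line")
    bonds <- cbind(bi, bj)
  }
  # data fields
  fields <- list()
  i <- 4L + nA + nB + 1L
  while (i <= length(lines) && !startsWith(lines[i], "M  END")) i <- i + 1L
  i <- i + 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^>\\s*<.+>", ln)) {
      tag <- sub("^>\\s*<([^>]+)>.*$", "\\1", ln)
      j <- i + 1L
      body <- character(0)
      while (j <= length(lines) && nzchar(trimws(lines[j]))) {
        body <- c(body, lines[j]); j <- j + 1L
      }
      fields[[tag]] <- body
      i <- j
    }
    i <- i + 1L
  }
  name <- trimws(lines[1])
  charges <- NULL
  if (!is.null(fields[["PARTIAL_CHARGES"]])) {
    toks <- unlist(strsplit(trimws(fields[["PARTIAL_CHARGES"]]), "\\s+"))
    toks <- toks[nzchar(toks)]
    charges <- suppressWarnings(as.numeric(toks))
    if (anyNA(charges))
      .parseError(recIdx, offset + 1, "non-numeric value in PARTIAL_CHARGES")
    if (length(charges) != nA)
      .parseError(recIdx, offset + 1,
                  sprintf("PARTIAL_CHARGES has %d values for %d atoms",
                          length(charges), nA))
    bad <- which(!vapply(charges, .isMulti001, logical(1)))
    if (length(bad))
      .parseError(recIdx, offset + 1,
                  sprintf("charge %g of atom %d is not a multiple of 0.001",
                          charges[bad[1]], bad[1]))
  }
  total <- NULL
  if (!is.null(fields[["TOTAL_CHARGE"]])) {
    total <- suppressWarnings(as.numeric(trimws(fields[["TOTAL_CHARGE"]][1])))
    if (is.na(total))
      .parseError(recIdx, offset + 1, "non-numeric TOTAL_CHARGE")
  }
  if (!is.null(fields[["ATOM_TYPES"]])) {
    toks <- unlist(strsplit(trimws(fields[["ATOM_TYPES"]]), "\\s+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) != nA)
      .parseError(recIdx, offset + 1,
                  sprintf("ATOM_TYPES has %d tokens for %d atoms", length(toks), nA))
    types <- toks
  }
  if (is.null(total) && is.null(charges))
    stop(sprintf("record %d ('%s'): neither TOTAL_CHARGE nor PARTIAL_CHARGES present",
                 recIdx, name), call. = FALSE)
  molecularGraph(types, bonds, charges = charges, totalCharge = total,
                 identifier = if (nzchar(name)) name else sprintf("record%d", recIdx))
}

#' Read molecules from an SDF or JSON file
#'
#' The SDF dialect is a V2000 connection table with partial charges in a
#' \code{PARTIAL_CHARGES} data field (one 3-decimal value per atom, file
#' atom order), the target total charge in \code{TOTAL_CHARGE}, and atom
#' type labels defaulting to the element symbol with an optional
#' \code{ATOM_TYPES} override. The JSON schema is
#' \code{{identifier, atoms: [{type, charge?}], bonds: [[i, j]], total_charge}},
#' one molecule or an array of molecules per file.
#'
#' @param path input file.
#' @param format \code{"sdf"} or \code{"json"}; guessed from the extension
#'   by default.
#' @return list of \linkS4class{MolecularGraph}, atom order as in the file.
#' @export
readMolecules <- function(path, format = c("auto", "sdf", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sdf"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") return(.readMoleculesJson(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  delim <- which(trimws(lines) == "$$$$")
  starts <- c(1L, delim + 1L)
  ends <- c(delim - 1L, length(lines))
  out <- list()
  rec <- 0L
  for (b in seq_along(starts)) {
    if (starts[b] > ends[b]) next
    chunk <- lines[starts[b]:ends[b]]
    if (all(!nzchar(trimws(chunk)))) next
    rec <- rec + 1L
    out[[rec]] <- .parseSdfRecord(chunk, rec, starts[b] - 1L)
  }
  out
}

.readMoleculesJson <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(x) && !is.null(x$atoms)) x <- list(x)
  lapply(seq_along(x), function(i) {
    rec <- x[[i]]
    if (is.null(rec$atoms)) stop(sprintf("JSON record %d: missing 'atoms'", i))
    types <- vapply(rec$atoms, function(a) as.character(a$type), character(1))
    charges <- vapply(rec$atoms, function(a)
      if (is.null(a$charge)) NA_real_ else as.numeric(a$charge), numeric(1))
    if (all(is.na(charges))) charges <- NULL
    bonds <- if (length(rec$bonds))
      do.call(rbind, lapply(rec$bonds, as.integer)) else matrix(integer(0), 0, 2)
    total <- rec$total_charge
    if (is.null(total) && is.null(charges))
      stop(sprintf("JSON record %d: neither total_charge nor charges present", i))
    molecularGraph(types, bonds, charges = charges, totalCharge = total,
                   identifier = if (is.null(rec$identifier)) sprintf("record%d", i)
                                else rec$identifier)
  })
}

.formatSdfRecord <- function(mol) {
  types <- atomTypes(mol)
  elements <- substr(.elementOf(types), 1, 3)  # V2000 symbol field width
  nA <- nAtoms(mol)
  nB <- nrow(mol@bonds)
  out <- c(mol@identifier, "", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nA, nB))
  out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, elements))
  if (nB > 0L)
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          mol@bonds[, 1], mol@bonds[, 2], 1L))
  out <- c(out, "M  END")
  ch <- atomCharges(mol)
  if (all(!is.na(ch)))
    out <- c(out, "> <PARTIAL_CHARGES>", sprintf("%.3f", ch), "")
  if (!is.na(mol@totalCharge))
    out <- c(out, "> <TOTAL_CHARGE>", sprintf("%.3f", mol@totalCharge), "")
  if (!identical(types, elements))
    out <- c(out, "> <ATOM_TYPES>", types, "")
  c(out, "$$$$")
}

#' Write molecules to the SDF dialect
#'
#' @param molecules list of \linkS4class{MolecularGraph} (or a single one).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeMolecules <- function(molecules, path) {
  if (is(molecules, "MolecularGraph")) molecules <- list(molecules)
  txt <- unlist(lapply(molecules, .formatSdfRecord))
  writeLines(txt, path)
  invisible(path)
}

#' Write a molecule with assigned charges
#'
#' Emits the SDF dialect with the \code{PARTIAL_CHARGES} field populated;
#' reading the output back round-trips atoms, bonds and charges exactly.
#'
#' @param molecule a \linkS4class{MolecularGraph}.
#' @param charges numeric vector, one 3-decimal charge per atom.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeCharges <- function(molecule, charges, path) {
  atomCharges(molecule) <- charges   # validates length and 0.001 precision
  molecule@totalCharge <- if (is.na(molecule@totalCharge))
    round(sum(charges), 3) else molecule@totalCharge
  writeMolecules(list(molecule), path)
}
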