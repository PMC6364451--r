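#' @include AllClasses.R histogram.R neighbourhood.R
NULL

.entryName <- function(shell, key) paste0(shell, "/", key)

.makeEntry <- function(key, shell, values, sources, keepSources) {
  new("EnvironmentEntry",
      key = key, shell = as.integer(shell),
      histogram = buildHistogram(values),
      nMolecules = length(unique(sources)),
      sources = if (keepSources) sources else character(0))
}

# core builder; also returns the per-molecule canonical-key cache so the
# leave-one-out harness does not recompute keys.
.buildDatabaseCore <- function(molecules, k, trackSources) {
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0")
  values <- list(); sources <- list()
  keyCache <- list()
  for (mol in molecules) {
    ch <- atomCharges(mol)
    if (any(is.na(ch)))
      stop("molecule '", identifier(mol), "' is missing atom charges")
    keys <- .keyMatrix(mol, k)
    keyCache[[identifier(mol)]] <- keys
    ch <- round(ch, 3)
    for (v in seq_len(nAtoms(mol))) {
      for (s in 0:k) {
        nm <- .entryName(s, keys[v, s + 1L])
        values[[nm]] <- c(values[[nm]], ch[v])
        sources[[nm]] <- c(sources[[nm]], identifier(mol))
      }
    }
  }
  entries <- list()
  for (nm in names(values)) {
    shell <- as.integer(sub("/.*$", "", nm))
    key <- sub("^[0-9]+/", "", nm)
    entries[[nm]] <- .makeEntry(key, shell, values[[nm]], sources[[nm]],
                                trackSources)
  }
  alphabet <- sort(unique(unlist(lapply(molecules, atomTypes))))
  db <- new("EnvironmentDatabase", entries = entries, kMax = k,
            alphabet = as.character(alphabet),
            trackSources = isTRUE(trackSources))
  list(db = db, keyCache = keyCache)
}

#' Build an environment charge database from a charged corpus
#'
#' Iterates over every atom of every molecule and, for every shell size
#' 0..k, appends the atom's 3-decimal charge to the isomorphism class of
#' its rooted induced environment. All shells are stored so that fallback
#' lookups need no rebuild. Histograms are built per class with
#' class-specific Friedman-Diaconis widths.
#'
#' @param molecules list of fully charged \linkS4class{MolecularGraph}.
#' @param k maximal shell size (default 3).
#' @param trackSources retain per-observation source molecule identifiers,
#'   enabling leave-one-out removal (default \code{FALSE}).
#' @return an \linkS4class{EnvironmentDatabase}
#' @export
buildDatabase <- function(molecules, k = 3, trackSources = FALSE) {
  .buildDatabaseCore(molecules, k, trackSources)$db
}

#' Look up an atom's environment with shell fallback
#'
#' Tries shells k, k-1, ..., 0 in order and returns the first database
#' entry whose canonical key matches the atom's rooted environment at that
#' shell. A no-match (NULL) is only possible when even the bare atom type
#' (shell 0) is absent from the database.
#'
#' @param db an \linkS4class{EnvironmentDatabase}.
#' @param molecule a \linkS4class{MolecularGraph} (charges not required).
#' @param v atom index.
#' @param k starting shell (must be <= \code{db@kMax}).
#' @param kFloor smallest shell tried (default 0).
#' @return list with elements \code{entry} and \code{shell}, or \code{NULL}.
#' @export
lookupEnvironment <- function(db, molecule, v, k, kFloor = 0L) {
  if (k > db@kMax) stop("k exceeds the database's kMax (", db@kMax, ")")
  for (s in seq(from = as.integer(k), to = as.integer(kFloor))) {
    key <- canonicalKey(inducedEnvironment(molecule, v, s))
    hit <- db@entries[[.entryName(s, key)]]
    if (!is.null(hit)) return(list(entry = hit, shell = s))
  }
  NULL
}

# cached-key variant used by the assignment/evaluation paths
.lookupByKeys <- function(db, keys, v, k, kFloor = 0L) {
  for (s in seq(from = as.integer(k), to = as.integer(kFloor))) {
    hit <- db@entries[[.entryName(s, keys[v, s + 1L])]]
    if (!is.null(hit)) return(list(entry = hit, shell = s))
  }
  NULL
}

#' Remove one molecule's observations from a database
#'
#' Drops every charge observation contributed by the named source molecule
#' and rebuilds the histograms of the affected entries; entries left empty
#' are removed. Requires a database built with \code{trackSources = TRUE}.
#'
#' @param db an \linkS4class{EnvironmentDatabase} with source tracking.
#' @param id source molecule identifier.
#' @return the reduced \linkS4class{EnvironmentDatabase}.
#' @export
removeMoleculeObservations <- function(db, id) {
  if (!db@trackSources)
    stop("database lacks source tracking; rebuild with trackSources = TRUE ",
         "(CLI: --track-sources)")
  touched <- vapply(db@entries, function(e) id %in% e@sources, logical(1))
  for (nm in names(db@entries)[touched]) {
    e <- db@entries[[nm]]
    keep <- e@sources != id
    if (!any(keep)) {
      db@entries[[nm]] <- NULL
    } else {
      db@entries[[nm]] <- .makeEntry(e@key, e@shell,
                                     e@histogram@values[keep],
                                     e@sources[keep], TRUE)
    }
  }
  db
}

#' Save a database as JSON
#'
#' Schema: \code{{alphabet, k_max, entries: [{key, shell, bin_width,
#' bin_centers, counts, n_values, n_molecules, values?, sources?}]}}.
#' Per-observation \code{values}/\code{sources} arrays are written only for
#' databases built with source tracking, so a reloaded tracked database
#' still supports leave-one-out removal and value-based baselines.
#'
#' @param db an \linkS4class{EnvironmentDatabase}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
saveDatabase <- function(db, path) {
  entries <- lapply(db@entries, function(e) {
    h <- e@histogram
    out <- list(key = e@key, shell = e@shell, bin_width = h@binWidth,
                bin_centers = h@binCenters, counts = h@counts,
                n_values = h@nValues, n_molecules = e@nMolecules)
    if (db@trackSources) {
      out$values <- h@values
      out$sources <- e@sources
    }
    out
  })
  names(entries) <- NULL
  obj <- list(alphabet = db@alphabet, k_max = db@kMax,
              track_sources = db@trackSources, entries = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a database from JSON
#'
#' @param path file written by \code{\link{saveDatabase}}.
#' @return an \linkS4class{EnvironmentDatabase}; loading a saved database
#'   reproduces keys, shells, bin centers, counts and molecule counts
#'   exactly.
#' @export
loadDatabase <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("alphabet", "k_max", "entries"))
    if (is.null(obj[[f]])) stop("database JSON: missing field /", f)
  tracked <- isTRUE(obj$track_sources)
  entries <- list()
  for (i in seq_along(obj$entries)) {
    e <- obj$entries[[i]]
    ptr <- sprintf("/entries/%d", i - 1L)
    for (f in c("key", "shell", "bin_centers", "counts", "n_values"))
      if (is.null(e[[f]])) stop("database JSON: missing field ", ptr, "/", f)
    counts <- as.integer(unlist(e$counts))
    centers <- as.numeric(unlist(e$bin_centers))
    if (sum(counts) != e$n_values)
      stop("database JSON: counts do not sum to n_values at ", ptr)
    values <- if (!is.null(e$values)) as.numeric(unlist(e$values)) else numeric(0)
    hist <- new("ChargeHistogram", values = values,
                binWidth = if (is.null(e$bin_width)) 0 else e$bin_width,
                binCenters = centers, counts = counts,
                nValues = as.integer(e$n_values))
    entry <- new("EnvironmentEntry", key = e$key, shell = as.integer(e$shell),
                 histogram = hist,
                 nMolecules = as.integer(if (is.null(e$n_molecules)) 1L
                                         else e$n_molecules),
                 sources = if (!is.null(e$sources))
                   as.character(unlist(e$sources)) else character(0))
    entries[[.entryName(entry@shell, entry@key)]] <- entry
  }
  new("EnvironmentDatabase", entries = entries, kMax = as.integer(obj$k_max),
      alphabet = as.character(unlist(obj$alphabet)),
      trackSources = tracked)
}
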