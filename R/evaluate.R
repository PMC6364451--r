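#' @include assigner.R
NULL

#' Leave-one-out evaluation of assignment methods
#'
#' Builds a source-tracked environment database from the corpus, and for
#' each molecule removes every charge observation it contributed, assigns
#' charges to it from the remaining data with each requested method, and
#' records the per-atom absolute distance to the held-out true charges and
#' the deviation of the assigned total from the target total charge.
#' Molecules with an atom matching no class at any shell are skipped (and
#' counted); molecules that needed shell fallback below k are evaluated but
#' flagged as not fully covered, and excluded from the per-element
#' aggregation, mirroring the restriction to fully covered molecules.
#'
#' @param corpus list of fully charged \linkS4class{MolecularGraph}
#'   (at least 2, with distinct identifiers).
#' @param params an \linkS4class{AssignmentParams}.
#' @param methods subset of \code{c("mckp", "mean", "median", "mode")}.
#' @return list with components:
#'   \describe{
#'     \item{byElement}{tidy data.frame (method, element,
#'       mean_abs_distance, n) over fully covered molecules, including an
#'       \code{"overall"} row per method.}
#'     \item{perMolecule}{data.frame (molecule, method, total, target,
#'       total_deviation, feasible, fully_covered, mean_abs_distance).}
#'     \item{perAtom}{data.frame of every per-atom comparison.}
#'     \item{nSkipped}{number of molecules skipped as uncoverable.}
#'     \item{skipped}{their identifiers.}
#'   }
#' @export
evaluateLeaveOneOut <- function(corpus, params = assignmentParams(),
                                methods = c("mckp", "mean", "median", "mode")) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(corpus) < 2L)
    stop("leave-one-out needs at least 2 molecules")
  ids <- vapply(corpus, identifier, character(1))
  if (anyDuplicated(ids))
    stop("corpus molecules must have distinct identifiers")
  core <- .buildDatabaseCore(corpus, params@k, trackSources = TRUE)
  db <- core$db
  perAtom <- list(); perMol <- list()
  skipped <- character(0)
  for (mi in seq_along(corpus)) {
    mol <- corpus[[mi]]
    id <- ids[mi]
    dbLoo <- removeMoleculeObservations(db, id)
    match <- tryCatch(
      .matchAtoms(mol, dbLoo, params, keys = core$keyCache[[id]]),
      error = function(e) NULL)
    if (is.null(match)) {
      skipped <- c(skipped, id)
      next
    }
    fully <- all(match$meta$shell == params@k)
    trueCh <- round(atomCharges(mol), 3)
    target <- totalCharge(mol)
    for (meth in methods) {
      if (meth == "mckp") {
        sets <- lapply(match$entries, function(e)
          data.frame(w = e@histogram@binCenters, p = log(e@histogram@counts)))
        inst <- epsMckpInstance(sets, target, params@epsilon)
        sol <- switch(params@solver,
                      dp = solveDp(inst, factor = params@factor),
                      ilp = solveIlp(inst))
        if (!sol@feasible) {
          perMol[[length(perMol) + 1L]] <- data.frame(
            molecule = id, method = meth, total = NA_real_, target = target,
            total_deviation = NA_real_, feasible = FALSE,
            fully_covered = fully, mean_abs_distance = NA_real_,
            stringsAsFactors = FALSE)
          next
        }
        assigned <- vapply(seq_along(sets), function(k)
          sets[[k]]$w[sol@selection[k]], numeric(1))
      } else {
        assigned <- vapply(match$entries, function(e) {
          h <- e@histogram
          switch(meth,
                 mean = round(mean(h@values), 3),
                 median = round(stats::median(h@values), 3),
                 mode = .histogramMode(h))
        }, numeric(1))
      }
      dist <- abs(assigned - trueCh)
      total <- round(sum(assigned), 3)
      perAtom[[length(perAtom) + 1L]] <- data.frame(
        molecule = id, index = match$meta$index, type = match$meta$type,
        element = .elementOf(match$meta$type), shell = match$meta$shell,
        method = meth, assigned = assigned, true = trueCh, distance = dist,
        fully_covered = fully, stringsAsFactors = FALSE)
      perMol[[length(perMol) + 1L]] <- data.frame(
        molecule = id, method = meth, total = total, target = target,
        total_deviation = abs(total - target), feasible = TRUE,
        fully_covered = fully, mean_abs_distance = mean(dist),
        stringsAsFactors = FALSE)
    }
  }
  perAtom <- if (length(perAtom)) do.call(rbind, perAtom) else
    data.frame(molecule = character(0), index = integer(0),
               type = character(0), element = character(0),
               shell = integer(0), method = character(0),
               assigned = numeric(0), true = numeric(0),
               distance = numeric(0), fully_covered = logical(0))
  perMol <- if (length(perMol)) do.call(rbind, perMol) else
    data.frame(molecule = character(0), method = character(0),
               total = numeric(0), target = numeric(0),
               total_deviation = numeric(0), feasible = logical(0),
               fully_covered = logical(0), mean_abs_distance = numeric(0))
  covered <- perAtom[perAtom$fully_covered, , drop = FALSE]
  byElement <- list()
  for (meth in unique(covered$method)) {
    sub <- covered[covered$method == meth, , drop = FALSE]
    for (el in sort(unique(sub$element))) {
      d <- sub$distance[sub$element == el]
      byElement[[length(byElement) + 1L]] <- data.frame(
        method = meth, element = el, mean_abs_distance = mean(d),
        n = length(d), stringsAsFactors = FALSE)
    }
    byElement[[length(byElement) + 1L]] <- data.frame(
      method = meth, element = "overall",
      mean_abs_distance = mean(sub$distance), n = nrow(sub),
      stringsAsFactors = FALSE)
  }
  byElement <- if (length(byElement)) do.call(rbind, byElement) else
    data.frame(method = character(0), element = character(0),
               mean_abs_distance = numeric(0), n = integer(0))
  list(byElement = byElement, perMolecule = perMol, perAtom = perAtom,
       nSkipped = length(skipped), skipped = skipped)
}
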