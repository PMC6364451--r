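#' @include AllClasses.R envdb.R mckp.R
NULL

#' Charge-assignment parameters
#'
#' @param k neighbourhood shell size (default 3).
#' @param epsilon total-charge tolerance in e (default 0.01).
#' @param solver \code{"dp"} (default) or \code{"ilp"}.
#' @param profitRule profit of a histogram bin; \code{"log_count"} is the
#'   natural log of the bin count (a count-1 bin has profit 0 and stays
#'   selectable; the log base only rescales all profits uniformly and
#'   cannot change the optimum).
#' @param kFloor smallest shell used during fallback matching (default 0).
#' @param factor integer scaling factor for the DP (default 1000).
#' @return an \linkS4class{AssignmentParams}
#' @export
assignmentParams <- function(k = 3, epsilon = 0.01, solver = "dp",
                             profitRule = "log_count", kFloor = 0,
                             factor = 1000) {
  new("AssignmentParams", k = as.integer(k), epsilon = as.numeric(epsilon),
      solver = solver, profitRule = profitRule, kFloor = as.integer(kFloor),
      factor = as.integer(factor))
}

# per-atom match metadata: data.frame(index, type, shell, key, nValues)
# plus the matched entries; errors on uncovered atoms.
.matchAtoms <- function(molecule, db, params, keys = NULL) {
  n <- nAtoms(molecule)
  if (is.null(keys)) keys <- .keyMatrix(molecule, params@k)
  entries <- vector("list", n)
  shells <- integer(n)
  uncovered <- integer(0)
  for (v in seq_len(n)) {
    hit <- .lookupByKeys(db, keys, v, params@k, params@kFloor)
    if (is.null(hit)) {
      uncovered <- c(uncovered, v)
    } else {
      entries[[v]] <- hit$entry
      shells[v] <- hit$shell
    }
  }
  if (length(uncovered))
    stop("uncovered atoms (no environment match at any shell): ",
         paste(sprintf("%d(%s)", uncovered, atomTypes(molecule)[uncovered]),
               collapse = ", "), call. = FALSE)
  list(entries = entries,
       meta = data.frame(index = seq_len(n), type = atomTypes(molecule),
                         shell = shells,
                         key = vapply(entries, slot, character(1), name = "key"),
                         nValues = vapply(entries, function(e)
                           e@histogram@nValues, integer(1)),
                         stringsAsFactors = FALSE))
}

#' Build the epsilon-MCKP instance of a query molecule
#'
#' Each atom is matched to an environment class (shells k down to
#' \code{kFloor}); its item set is the class histogram's bins, with the bin
#' center as item weight and the natural log of the bin count as item
#' profit. The capacity is the molecule's target total charge and the
#' window half-width is \code{params@epsilon}.
#'
#' @param molecule a \linkS4class{MolecularGraph} with a known
#'   \code{totalCharge}.
#' @param db an \linkS4class{EnvironmentDatabase}.
#' @param params an \linkS4class{AssignmentParams}.
#' @return list with elements \code{instance}
#'   (\linkS4class{EpsMckpInstance}) and \code{meta} (per-atom match
#'   metadata: matched shell, class key, observation count).
#' @export
makeInstance <- function(molecule, db, params = assignmentParams()) {
  if (is.na(totalCharge(molecule)))
    stop("molecule '", identifier(molecule), "' has no target total charge")
  m <- .matchAtoms(molecule, db, params)
  sets <- lapply(m$entries, function(e)
    data.frame(w = e@histogram@binCenters, p = log(e@histogram@counts)))
  list(instance = epsMckpInstance(sets, totalCharge(molecule), params@epsilon),
       meta = m$meta)
}

#' Assign partial charges to a query molecule
#'
#' Solves the molecule's epsilon-MCKP instance with the chosen solver and
#' maps the selected items back to per-atom charges. Atoms with identical
#' canonical environment keys receive identical item sets. On an infeasible
#' instance no charges are invented: the result carries
#' \code{feasible = FALSE} and the range of achievable total charges.
#'
#' @inheritParams makeInstance
#' @return a \linkS4class{ChargeAssignment}
#' @export
assignCharges <- function(molecule, db, params = assignmentParams()) {
  mi <- makeInstance(molecule, db, params)
  sol <- switch(params@solver,
                dp = solveDp(mi$instance, factor = params@factor),
                ilp = solveIlp(mi$instance))
  meta <- mi$meta
  if (!sol@feasible) {
    meta$charge <- NA_real_
    meta$profit <- NA_real_
    rng <- sol@info$achievableRange
    if (is.null(rng)) rng <- c(NA_real_, NA_real_)
    return(new("ChargeAssignment", atoms = meta, totalCharge = NA_real_,
               totalProfit = NA_real_, solver = params@solver,
               feasible = FALSE, achievableRange = rng))
  }
  sets <- mi$instance@sets
  meta$charge <- vapply(seq_along(sets), function(k)
    sets[[k]]$w[sol@selection[k]], numeric(1))
  meta$profit <- vapply(seq_along(sets), function(k)
    sets[[k]]$p[sol@selection[k]], numeric(1))
  new("ChargeAssignment", atoms = meta,
      totalCharge = round(sum(meta$charge), 3),
      totalProfit = sol@totalProfit, solver = params@solver,
      feasible = TRUE, achievableRange = c(NA_real_, NA_real_))
}

#' Naive per-atom baseline assignment
#'
#' Assigns each atom the mean, median or mode of its matched class's charge
#' distribution independently of the other atoms; the resulting total is
#' NOT constrained to the target. Mean and median are computed over the raw
#' observed values and rounded to 3 decimals; the mode is the center of the
#' highest-count bin, multimodal ties resolved by the mode closest to the
#' median, remaining ties to the lower charge.
#'
#' @inheritParams makeInstance
#' @param statistic \code{"mean"}, \code{"median"} or \code{"mode"}.
#' @return data.frame with per-atom columns (\code{index}, \code{type},
#'   \code{shell}, \code{key}, \code{nValues}, \code{charge}) and the
#'   unconstrained total as attribute \code{"total"}.
#' @export
baselineAssign <- function(molecule, db, params = assignmentParams(),
                           statistic = c("mean", "median", "mode")) {
  statistic <- match.arg(statistic)
  m <- .matchAtoms(molecule, db, params)
  m$meta$charge <- vapply(m$entries, function(e) {
    h <- e@histogram
    if (statistic != "mode" && length(h@values) == 0L)
      stop("database entries carry no raw values; mean/median baselines need ",
           "a database built (or saved) with source tracking")
    switch(statistic,
           mean = round(mean(h@values), 3),
           median = round(stats::median(h@values), 3),
           mode = .histogramMode(h))
  }, numeric(1))
  out <- m$meta
  attr(out, "total") <- round(sum(out$charge), 3)
  out
}
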