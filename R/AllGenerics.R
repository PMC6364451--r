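#' @include AllClasses.R
NULL

#' Number of atoms
#' @param x a \linkS4class{MolecularGraph} or \linkS4class{RootedEnvironment}
#' @return integer(1)
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom type labels
#' @param x a \linkS4class{MolecularGraph} or \linkS4class{RootedEnvironment}
#' @return character vector, one label per atom
#' @export
setGeneric("atomTypes", function(x) standardGeneric("atomTypes"))

#' Per-atom partial charges
#' @param x a \linkS4class{MolecularGraph}
#' @return numeric vector in e (NA where unknown)
#' @export
setGeneric("atomCharges", function(x) standardGeneric("atomCharges"))

#' Replace per-atom partial charges
#' @param x a \linkS4class{MolecularGraph}
#' @param value numeric vector of 3-decimal charges, one per atom
#' @export
setGeneric("atomCharges<-", function(x, value) standardGeneric("atomCharges<-"))

#' Bond list
#' @param x a \linkS4class{MolecularGraph}
#' @return two-column integer matrix of atom index pairs
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' Target total molecular charge
#' @param x a \linkS4class{MolecularGraph} or \linkS4class{ChargeAssignment}
#' @return numeric(1) in e
#' @export
setGeneric("totalCharge", function(x) standardGeneric("totalCharge"))

#' Molecule identifier
#' @param x a \linkS4class{MolecularGraph}
#' @return character(1)
#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MolecularGraph", function(x) nrow(x@atoms))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "RootedEnvironment", function(x) nrow(x@graph@atoms))

#' @rdname atomTypes
#' @export
setMethod("atomTypes", "MolecularGraph", function(x) x@atoms$type)
#' @rdname atomTypes
#' @export
setMethod("atomTypes", "RootedEnvironment", function(x) x@graph@atoms$type)

#' @rdname atomCharges
#' @export
setMethod("atomCharges", "MolecularGraph", function(x) x@atoms$charge)

#' @rdname atomCharges-set
#' @export
setReplaceMethod("atomCharges", "MolecularGraph", function(x, value) {
  if (length(value) != nAtoms(x))
    stop("charge vector length (", length(value), ") does not match atom count (",
         nAtoms(x), ")")
  bad <- which(!vapply(value, .isMulti001, logical(1)))
  if (length(bad))
    stop(sprintf("charge %g of atom %d is not a multiple of 0.001",
                 value[bad[1]], bad[1]))
  x@atoms$charge <- round(value, 3)
  if (is.na(x@totalCharge)) x@totalCharge <- round(sum(value), 3)
  validObject(x)
  x
})

#' @rdname bonds
#' @export
setMethod("bonds", "MolecularGraph", function(x) x@bonds)

#' @rdname totalCharge
#' @export
setMethod("totalCharge", "MolecularGraph", function(x) x@totalCharge)
#' @rdname totalCharge
#' @export
setMethod("totalCharge", "ChargeAssignment", function(x) x@totalCharge)

#' @rdname identifier
#' @export
setMethod("identifier", "MolecularGraph", function(x) x@identifier)

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph '%s': %d atoms, %d bonds, total charge %s\n",
              object@identifier, nAtoms(object), nrow(object@bonds),
              ifelse(is.na(object@totalCharge), "NA",
                     format(object@totalCharge))))
  cat("  types:", paste(utils::head(object@atoms$type, 12), collapse = " "),
      if (nAtoms(object) > 12) "...\n" else "\n")
})

setMethod("show", "RootedEnvironment", function(object) {
  cat(sprintf("RootedEnvironment: shell %d, root atom %d (%s), %d atoms, %d bonds\n",
              object@shell, object@root, object@graph@atoms$type[object@root],
              nAtoms(object), nrow(object@graph@bonds)))
})

setMethod("show", "ChargeHistogram", function(object) {
  cat(sprintf("ChargeHistogram: %d observations, %d bins, bin width %s e\n",
              object@nValues, length(object@binCenters),
              format(object@binWidth, digits = 4)))
})

setMethod("show", "EnvironmentDatabase", function(object) {
  shells <- vapply(object@entries, slot, integer(1), name = "shell")
  cat(sprintf("EnvironmentDatabase: %d entries, kMax %d, alphabet {%s}%s\n",
              length(object@entries), object@kMax,
              paste(object@alphabet, collapse = ", "),
              if (object@trackSources) ", sources tracked" else ""))
  if (length(shells))
    print(table(shell = shells))
})

setMethod("show", "EpsMckpInstance", function(object) {
  cat(sprintf("EpsMckpInstance: %d sets (%d items), capacity %g, epsilon %g\n",
              length(object@sets),
              sum(vapply(object@sets, nrow, integer(1))),
              object@capacity, object@epsilon))
})

setMethod("show", "McKpSolution", function(object) {
  if (object@feasible)
    cat(sprintf("McKpSolution (%s): profit %.6g, weight %g, selection [%s]\n",
                object@method, object@totalProfit, object@totalWeight,
                paste(object@selection, collapse = " ")))
  else
    cat(sprintf("McKpSolution (%s): infeasible\n", object@method))
})

setMethod("show", "ChargeAssignment", function(object) {
  if (object@feasible) {
    cat(sprintf("ChargeAssignment (%s): %d atoms, total %0.3f e, profit %.6g\n",
                object@solver, nrow(object@atoms), object@totalCharge,
                object@totalProfit))
  } else {
    cat(sprintf("ChargeAssignment (%s): infeasible; achievable total in [%0.3f, %0.3f] e\n",
                object@solver, object@achievableRange[1], object@achievableRange[2]))
  }
})
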