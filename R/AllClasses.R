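#' @import methods
NULL

# Fixed-point helpers: all charges are multiples of 0.001 e (millicharges).
# Tolerance 1e-9 on the charge scale.
.MILLI_TOL <- 1e-9

.isMulti001 <- function(x) abs(x - round(x, 3)) <= .MILLI_TOL

.milli <- function(x) as.integer(round(x * 1000))

# Project an atom-type label onto a chemical element. Force-field labels
# refine an element with suffixes (e.g. CAro, HC, NR): the element is the
# leading capital plus an optional following lowercase letter (Cl, Br).
# Labels from other alphabets (not starting with a capital) map to
# themselves.
.elementOf <- function(type) {
  ifelse(grepl("^[A-Z]", type), sub("^([A-Z][a-z]?).*", "\\1", type), type)
}

#' Molecular graph
#'
#' A molecule as a vertex-coloured graph: atoms carry free-form type labels
#' (chemical elements by default, or richer force-field atom types), bonds
#' are untyped undirected edges, and each atom optionally carries a partial
#' charge in elementary-charge units, fixed to 3 decimals. The target total
#' molecular charge is stored separately (it is the knapsack capacity during
#' assignment) and may be \code{NA} for intermediate objects such as
#' extracted environment subgraphs.
#'
#' @slot atoms data.frame with columns \code{type} (character) and
#'   \code{charge} (numeric, \code{NA} when unknown), one row per atom;
#'   atoms are indexed 1-based in file order.
#' @slot bonds two-column integer matrix of atom index pairs, one row per
#'   bond, with \code{bonds[, 1] < bonds[, 2]}.
#' @slot totalCharge numeric(1), target total charge in e (may be \code{NA}).
#' @slot identifier character(1) free-text molecule name.
#' @export
setClass("MolecularGraph",
  representation(
    atoms = "data.frame",
    bonds = "matrix",
    totalCharge = "numeric",
    identifier = "character"
  )
)

setValidity("MolecularGraph", function(object) {
  a <- object@atoms
  b <- object@bonds
  msgs <- character(0)
  if (!all(c("type", "charge") %in% names(a)))
    return("atoms must have columns 'type' and 'charge'")
  n <- nrow(a)
  if (n < 1L) msgs <- c(msgs, "molecule must contain at least one atom")
  if (ncol(b) != 2L) return("bonds must be a two-column matrix")
  if (nrow(b) > 0L) {
    if (any(b < 1L | b > n)) msgs <- c(msgs, "bond endpoint out of range")
    if (any(b[, 1] == b[, 2])) msgs <- c(msgs, "self-loop bond")
    if (any(b[, 1] > b[, 2])) msgs <- c(msgs, "bond rows must be ordered (i < j)")
    if (anyDuplicated(paste(b[, 1], b[, 2]))) msgs <- c(msgs, "duplicate bond")
  }
  if (length(msgs) == 0L && n > 1L) {
    # connectivity: one molecule per record
    comp <- .connectedComponent(n, b, 1L)
    if (length(comp) != n) msgs <- c(msgs, "molecular graph is not connected")
  }
  ch <- a$charge
  bad <- !is.na(ch) & !vapply(ch, function(z) is.na(z) || .isMulti001(z), logical(1))
  if (any(bad))
    msgs <- c(msgs, sprintf("charge of atom %d is not a multiple of 0.001", which(bad)[1]))
  if (length(object@totalCharge) != 1L) msgs <- c(msgs, "totalCharge must be length 1")
  if (length(object@identifier) != 1L) msgs <- c(msgs, "identifier must be length 1")
  if (length(msgs)) msgs else TRUE
})

# vertices reachable from `start` (used by validity and BFS oracle-free code)
.connectedComponent <- function(n, bonds, start) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- logical(n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Rooted chemical environment
#'
#' The subgraph induced by an atom's k-neighbourhood, rooted at that atom.
#' Atom indices are local to the subgraph (1..n); the root is the central
#' atom whose charge the environment characterises.
#'
#' @slot graph a \linkS4class{MolecularGraph} (charges optional,
#'   \code{totalCharge} typically \code{NA}).
#' @slot root integer(1), local index of the central atom.
#' @slot shell integer(1), neighbourhood radius k (>= 0).
#' @export
setClass("RootedEnvironment",
  representation(graph = "MolecularGraph", root = "integer", shell = "integer")
)

setValidity("RootedEnvironment", function(object) {
  n <- nrow(object@graph@atoms)
  if (length(object@root) != 1L || object@root < 1L || object@root > n)
    return("root must be a valid atom index")
  if (length(object@shell) != 1L || object@shell < 0L)
    return("shell must be a single non-negative integer")
  # every atom reachable from root within `shell` steps
  d <- .bfsDistances(n, object@graph@bonds, object@root)
  if (any(!is.finite(d)) || any(d > object@shell))
    return("an atom lies farther than `shell` from the root")
  TRUE
})

.bfsDistances <- function(n, bonds, start) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  d <- rep(Inf, n)
  d[start] <- 0
  frontier <- start
  lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!is.finite(d[nxt])]
    d[nxt] <- lev
    frontier <- nxt
  }
  d
}

#' Charge histogram of an environment class
#'
#' Observed partial charges of one environment isomorphism class, binned
#' with a Friedman-Diaconis bin width and bin centers aligned to the
#' 3-decimal-rounded median charge. When the Friedman-Diaconis width
#' degenerates (rounds below 0.001 e) the distribution is treated as
#' discrete: every distinct value is its own bin and \code{binWidth} is 0.
#'
#' @slot values numeric, the raw observed charges (may be empty when a
#'   database was loaded without per-observation data).
#' @slot binWidth numeric(1), bin width in e (0 on the discrete path).
#' @slot binCenters numeric, strictly increasing 3-decimal charges.
#' @slot counts integer, positive, parallel to \code{binCenters}.
#' @slot nValues integer(1), number of observations (= \code{sum(counts)}).
#' @export
setClass("ChargeHistogram",
  representation(
    values = "numeric", binWidth = "numeric",
    binCenters = "numeric", counts = "integer", nValues = "integer"
  )
)

setValidity("ChargeHistogram", function(object) {
  msgs <- character(0)
  if (length(object@binCenters) != length(object@counts))
    return("binCenters and counts must have equal length")
  if (length(object@binCenters) == 0L) msgs <- c(msgs, "histogram is empty")
  if (any(object@counts <= 0L)) msgs <- c(msgs, "counts must be positive")
  if (sum(object@counts) != object@nValues)
    msgs <- c(msgs, "counts must sum to nValues")
  if (is.unsorted(object@binCenters, strictly = TRUE))
    msgs <- c(msgs, "binCenters must be strictly increasing")
  if (length(object@values) > 0L) {
    if (length(object@values) != object@nValues)
      msgs <- c(msgs, "values length must equal nValues")
    med <- round(sort(object@values)[ceiling(length(object@values) / 2)], 3)
    if (!any(abs(object@binCenters - med) <= .MILLI_TOL))
      msgs <- c(msgs, "no bin center equals the 3-decimal alignment median")
  }
  if (length(msgs)) msgs else TRUE
})

#' Environment database entry
#'
#' One isomorphism class of rooted k-neighbourhood subgraphs together with
#' the histogram of central-atom charges observed for it.
#'
#' @slot key character(1), canonical key of the class.
#' @slot shell integer(1), neighbourhood radius k.
#' @slot histogram a \linkS4class{ChargeHistogram}.
#' @slot nMolecules integer(1), number of distinct source molecules.
#' @slot sources character, per-observation source molecule identifiers,
#'   parallel to \code{histogram@values}; empty unless the database was
#'   built with source tracking.
#' @export
setClass("EnvironmentEntry",
  representation(
    key = "character", shell = "integer",
    histogram = "ChargeHistogram", nMolecules = "integer",
    sources = "character"
  )
)

setValidity("EnvironmentEntry", function(object) {
  if (object@shell < 0L) return("shell must be >= 0")
  if (object@nMolecules < 1L) return("entry must have at least one source molecule")
  if (length(object@sources) > 0L &&
      length(object@sources) != object@histogram@nValues)
    return("sources must be parallel to the histogram observations")
  TRUE
})

#' Database of chemical-environment charge distributions
#'
#' Maps canonical rooted-subgraph keys to charge histograms, for every shell
#' size 0..\code{kMax}. Entries are stored under the composite name
#' \code{"<shell>/<key>"} so a key lookup returns at most one entry per shell.
#'
#' @slot entries named list of \linkS4class{EnvironmentEntry}.
#' @slot kMax integer(1), largest shell size stored.
#' @slot alphabet character, atom-type alphabet observed in the corpus.
#' @slot trackSources logical(1), whether per-observation source molecule
#'   identifiers were retained (required for leave-one-out removal).
#' @export
setClass("EnvironmentDatabase",
  representation(
    entries = "list", kMax = "integer",
    alphabet = "character", trackSources = "logical"
  )
)

setValidity("EnvironmentDatabase", function(object) {
  if (length(object@entries)) {
    ok <- vapply(object@entries, is, logical(1), class2 = "EnvironmentEntry")
    if (!all(ok)) return("entries must all be EnvironmentEntry objects")
    shells <- vapply(object@entries, slot, integer(1), name = "shell")
    if (any(shells > object@kMax)) return("entry shell exceeds kMax")
    nm <- paste0(shells, "/", vapply(object@entries, slot, character(1), name = "key"))
    if (!identical(names(object@entries), nm))
      return("entry names must be '<shell>/<key>'")
  }
  TRUE
})

#' An epsilon-MCKP instance
#'
#' Select exactly one item from each set so that the sum of the selected
#' weights lies in \code{[capacity - epsilon, capacity + epsilon]} and the
#' sum of the selected (non-negative) profits is maximal. Weights and
#' capacity may be negative; in the charge-assignment mapping a set is an
#' atom, an item weight is a candidate charge (a histogram bin center) and
#' an item profit is the log of the bin count.
#'
#' @slot sets list of data.frames with numeric columns \code{w} and \code{p}.
#' @slot capacity numeric(1), target weight sum (target total charge).
#' @slot epsilon numeric(1), allowed deviation (>= 0).
#' @export
setClass("EpsMckpInstance",
  representation(sets = "list", capacity = "numeric", epsilon = "numeric")
)

setValidity("EpsMckpInstance", function(object) {
  if (length(object@sets) < 1L) return("instance needs at least one item set")
  for (i in seq_along(object@sets)) {
    s <- object@sets[[i]]
    if (!is.data.frame(s) || !all(c("w", "p") %in% names(s)))
      return(sprintf("set %d must be a data.frame with columns w and p", i))
    if (nrow(s) < 1L) return(sprintf("set %d is empty", i))
    if (any(s$p < 0)) return(sprintf("set %d has a negative profit", i))
  }
  if (object@epsilon < 0) return("epsilon must be >= 0")
  TRUE
})

#' Integer-transformed epsilon-MCKP instance
#'
#' The result of scaling weights, capacity and epsilon by a fixed factor
#' (10^3 suffices for 3-decimal charges) and shifting each set by its
#' minimum scaled weight, so that all weights are non-negative integers
#' and each set contains a zero weight. Feasibility of full selections is
#' preserved exactly.
#'
#' @slot sets list of data.frames with integer column \code{w} (>= 0) and
#'   numeric column \code{p}.
#' @slot capacity numeric(1), transformed capacity (scaled c minus the sum
#'   of per-set minimum scaled weights).
#' @slot epsilon numeric(1), scaled epsilon.
#' @slot factor integer(1), the scaling factor.
#' @slot offsets numeric, per-set minimum scaled weights w*_i.
#' @export
setClass("IntegerInstance",
  representation(
    sets = "list", capacity = "numeric", epsilon = "numeric",
    factor = "integer", offsets = "numeric"
  )
)

setValidity("IntegerInstance", function(object) {
  for (i in seq_along(object@sets)) {
    w <- object@sets[[i]]$w
    if (any(w < 0)) return(sprintf("set %d has a negative transformed weight", i))
    if (min(w) != 0) return(sprintf("set %d has no zero transformed weight", i))
  }
  if (length(object@offsets) != length(object@sets))
    return("offsets must be parallel to sets")
  TRUE
})

#' Solution of an epsilon-MCKP instance
#'
#' @slot selection integer, one chosen item index per set (all \code{NA}
#'   when infeasible).
#' @slot totalWeight numeric(1), sum of selected weights (original scale).
#' @slot totalProfit numeric(1), sum of selected profits.
#' @slot feasible logical(1).
#' @slot method character(1), one of \code{"dp"}, \code{"ilp"},
#'   \code{"bruteforce"}.
#' @slot info list, solver diagnostics (e.g. the achievable-weight range of
#'   an infeasible instance).
#' @export
setClass("McKpSolution",
  representation(
    selection = "integer", totalWeight = "numeric",
    totalProfit = "numeric", feasible = "logical",
    method = "character", info = "list"
  )
)

#' Parameters of the charge-assignment procedure
#'
#' @slot k integer(1), neighbourhood shell size (default 3).
#' @slot epsilon numeric(1), total-charge tolerance in e (default 0.01).
#' @slot solver character(1), \code{"dp"} or \code{"ilp"}.
#' @slot profitRule character(1), currently \code{"log_count"} (natural log
#'   of the bin count).
#' @slot kFloor integer(1), smallest shell tried during fallback (default 0).
#' @slot factor integer(1), integer scaling factor for the DP (default 1000).
#' @export
setClass("AssignmentParams",
  representation(
    k = "integer", epsilon = "numeric", solver = "character",
    profitRule = "character", kFloor = "integer", factor = "integer"
  )
)

setValidity("AssignmentParams", function(object) {
  if (object@k < 0L) return("k must be >= 0")
  if (object@epsilon < 0) return("epsilon must be >= 0")
  if (!object@solver %in% c("dp", "ilp")) return("solver must be 'dp' or 'ilp'")
  if (!object@profitRule %in% "log_count") return("unknown profit rule")
  if (object@kFloor < 0L || object@kFloor > object@k)
    return("kFloor must lie in [0, k]")
  TRUE
})

#' Result of a charge assignment
#'
#' @slot atoms data.frame with one row per atom: \code{index}, \code{type},
#'   \code{charge} (assigned, \code{NA} if infeasible), \code{shell}
#'   (matched shell), \code{key} (matched class key), \code{profit},
#'   \code{nValues} (observations in the matched class).
#' @slot totalCharge numeric(1), sum of assigned charges.
#' @slot totalProfit numeric(1).
#' @slot solver character(1).
#' @slot feasible logical(1).
#' @slot achievableRange numeric(2), the range of achievable total charges
#'   when the instance is infeasible (\code{NA} otherwise).
#' @export
setClass("ChargeAssignment",
  representation(
    atoms = "data.frame", totalCharge = "numeric", totalProfit = "numeric",
    solver = "character", feasible = "logical", achievableRange = "numeric"
  )
)

#' Specification of a synthetic molecule corpus
#'
#' Generative parameters for corpora with ground-truth environment-
#' conditional charge distributions: random valence-respecting connected
#' molecular graphs, per-environment charge means derived deterministically
#' from the canonical shell-\code{envShell} key, Gaussian observation noise,
#' an optional second mode for heavy-tailed classes, 3-decimal rounding and
#' exact integer total charges.
#'
#' @slot nMolecules integer(1).
#' @slot sizeRange integer(2), atoms per molecule (min, max).
#' @slot alphabet named numeric, valence cap per atom type.
#' @slot typeWeights numeric, sampling weight per type (parallel to
#'   \code{alphabet}).
#' @slot ringProb numeric(1), probability of attempting a ring closure.
#' @slot envShell integer(1), shell size of the generating charge model.
#' @slot meanSd numeric(1), sd of the per-environment base mean (e).
#' @slot noiseSd numeric(1), per-observation noise sd (e).
#' @slot modeOffset numeric(1), offset of the optional second mode (e).
#' @slot modeWeight numeric(1), mixture weight of the second mode (0 = off).
#' @slot targetTotal integer(1), target total charge per molecule.
#' @slot adjustTotals logical(1); when \code{FALSE} the residual is not
#'   distributed and the target total is the raw 3-decimal sum (used to
#'   study the noise model in isolation).
#' @slot minOccurrences integer(1), number of independently charged copies
#'   of each generated structure (>= 2 guarantees leave-one-out coverage).
#' @slot seed integer(1).
#' @export
setClass("SyntheticCorpusSpec",
  representation(
    nMolecules = "integer", sizeRange = "integer", alphabet = "numeric",
    typeWeights = "numeric", ringProb = "numeric", envShell = "integer",
    meanSd = "numeric", noiseSd = "numeric", modeOffset = "numeric",
    modeWeight = "numeric", targetTotal = "integer",
    adjustTotals = "logical", minOccurrences = "integer", seed = "integer"
  )
)

setValidity("SyntheticCorpusSpec", function(object) {
  if (object@nMolecules < 1L) return("nMolecules must be >= 1")
  if (length(object@sizeRange) != 2L || any(object@sizeRange < 1L) ||
      object@sizeRange[1] > object@sizeRange[2])
    return("sizeRange must be (min, max) with 1 <= min <= max")
  if (is.null(names(object@alphabet)) || any(!nzchar(names(object@alphabet))))
    return("alphabet must be a named vector of valence caps")
  if (length(object@typeWeights) != length(object@alphabet))
    return("typeWeights must be parallel to alphabet")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@modeWeight < 0 || object@modeWeight > 1)
    return("modeWeight must lie in [0, 1]")
  if (object@minOccurrences < 1L) return("minOccurrences must be >= 1")
  TRUE
})
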