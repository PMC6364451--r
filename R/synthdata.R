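#' @include AllClasses.R neighbourhood.R mckp.R
NULL

#' Specification of a synthetic molecule corpus
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 200 molecules of 5-25 atoms over a small element alphabet with
#' chemical valence caps, a shell-3 environment charge model with base
#' means of sd 0.1 e, observation noise sd 0.02 e, unimodal classes
#' (\code{modeWeight = 0}; raise it for heavy-tailed multimodal classes),
#' integer target total charge 0, and every generated structure
#' instantiated twice with independent noise so each environment occurs in
#' at least two molecules (which guarantees leave-one-out coverage).
#'
#' @param nMolecules number of molecules.
#' @param sizeRange integer(2), atoms per molecule.
#' @param alphabet named numeric vector, valence cap per atom type.
#' @param typeWeights sampling weight per type (parallel to
#'   \code{alphabet}).
#' @param ringProb probability of each ring-closure attempt.
#' @param envShell shell size of the generating charge model.
#' @param meanSd sd of per-environment base means (e).
#' @param noiseSd per-observation noise sd (e).
#' @param modeOffset absolute offset of the optional second mode (e).
#' @param modeWeight mixture weight of the second mode (0 disables it).
#' @param targetTotal integer target total charge per molecule.
#' @param adjustTotals distribute the rounding residual so totals hit
#'   \code{targetTotal} exactly (default \code{TRUE}); with \code{FALSE}
#'   each molecule's target is simply its raw 3-decimal charge sum, which
#'   isolates the pure environment + noise model.
#' @param minOccurrences independently charged copies of each structure.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a \linkS4class{SyntheticCorpusSpec}
#' @export
syntheticCorpusSpec <- function(nMolecules = 200, sizeRange = c(5, 25),
                                alphabet = c(C = 4, N = 3, O = 2, H = 1),
                                typeWeights = c(0.4, 0.1, 0.15, 0.35),
                                ringProb = 0.2, envShell = 3,
                                meanSd = 0.1, noiseSd = 0.02,
                                modeOffset = 0.3, modeWeight = 0,
                                targetTotal = 0, adjustTotals = TRUE,
                                minOccurrences = 2, seed = 1) {
  new("SyntheticCorpusSpec",
      nMolecules = as.integer(nMolecules), sizeRange = as.integer(sizeRange),
      alphabet = alphabet, typeWeights = as.numeric(typeWeights),
      ringProb = as.numeric(ringProb), envShell = as.integer(envShell),
      meanSd = as.numeric(meanSd), noiseSd = as.numeric(noiseSd),
      modeOffset = as.numeric(modeOffset), modeWeight = as.numeric(modeWeight),
      targetTotal = as.integer(targetTotal),
      adjustTotals = isTRUE(adjustTotals),
      minOccurrences = as.integer(minOccurrences), seed = as.integer(seed))
}

# Deterministic platform-independent hash of a key string folded with the
# seed; all arithmetic stays below 2^53 so doubles are exact.
.keyHash <- function(key, seed) {
  h <- seed %% 2147483647
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  h
}

.lehmer <- function(h) (h * 48271) %% 2147483647

# Environment charge model of one canonical key: base mean ~ N(0, meanSd),
# optional second mode at a hash-determined side. Lazily instantiated per
# key, consistent across molecules, no RNG state touched.
.envModel <- function(key, spec) {
  h <- .lehmer(.keyHash(key, spec@seed))
  u1 <- min(max(h / 2147483647, 1e-12), 1 - 1e-12)
  h <- .lehmer(h)
  side <- if (h %% 2 == 0) 1 else -1
  list(mean = stats::qnorm(u1) * spec@meanSd,
       mode2 = stats::qnorm(u1) * spec@meanSd + side * spec@modeOffset)
}

#' Generate one random valence-respecting molecule
#'
#' Builds a connected graph as a random tree (each new atom bonded to a
#' random atom with free valence) plus ring-closing edges between
#' non-adjacent atoms that both retain free valence. Charges are left
#' unset. Deterministic given \code{seed} (the function seeds R's RNG).
#'
#' @param spec a \linkS4class{SyntheticCorpusSpec}.
#' @param seed integer seed.
#' @return an uncharged \linkS4class{MolecularGraph}
#' @export
genMolecule <- function(spec, seed) {
  set.seed(seed)
  n <- if (spec@sizeRange[1] == spec@sizeRange[2]) spec@sizeRange[1]
       else sample(spec@sizeRange[1]:spec@sizeRange[2], 1)
  valence <- spec@alphabet
  typeNames <- names(valence)
  pickType <- function(minVal) {
    ok <- valence >= minVal
    if (!any(ok))
      stop("unsatisfiable corpus spec: no atom type with valence >= ", minVal)
    sample(typeNames[ok], 1, prob = spec@typeWeights[ok])
  }
  types <- character(n)
  types[1] <- pickType(if (n > 1) 1 else 0)
  free <- numeric(n)
  free[1] <- valence[types[1]]
  bonds <- matrix(integer(0), 0, 2)
  if (n > 1) {
    for (t in 2:n) {
      open <- which(free[seq_len(t - 1L)] > 0)
      if (length(open) == 0L)
        stop("unsatisfiable corpus spec: no free valence to attach atom ", t)
      parent <- if (length(open) == 1L) open else sample(open, 1)
      # keep at least one stub open while atoms remain to be placed
      stubs <- sum(free[seq_len(t - 1L)])
      minVal <- if (t < n && stubs == 1) 2 else 1
      types[t] <- pickType(minVal)
      free[t] <- valence[types[t]] - 1
      free[parent] <- free[parent] - 1
      bonds <- rbind(bonds, c(parent, t))
    }
    attempts <- max(1L, n %/% 10L)
    for (a in seq_len(attempts)) {
      if (stats::runif(1) >= spec@ringProb) next
      open <- which(free > 0)
      if (length(open) < 2L) next
      adj <- .adjacencyList(n, bonds)
      pairs <- utils::combn(open, 2)
      ok <- apply(pairs, 2, function(pr) !(pr[2] %in% adj[[pr[1]]]))
      if (!any(ok)) next
      pick <- pairs[, which(ok)[sample(sum(ok), 1)]]
      bonds <- rbind(bonds, pick)
      free[pick] <- free[pick] - 1
    }
  }
  molecularGraph(types, bonds, totalCharge = NA_real_,
                 identifier = sprintf("gen-%d", seed))
}

#' Generate a fully charged synthetic corpus with ground truth
#'
#' Generates structures, computes each atom's canonical
#' shell-\code{envShell} key, draws its charge from that key's environment
#' model (base mean plus optional second mode plus Gaussian noise), rounds
#' to 0.001 e, and then adjusts the molecule to hit its integer target
#' total exactly by distributing the residual in 0.001-e steps over the
#' atoms with the largest noise draws. Each structure is instantiated
#' \code{minOccurrences} times with independent noise.
#'
#' @param spec a \linkS4class{SyntheticCorpusSpec}.
#' @return list with \code{molecules} (list of charged
#'   \linkS4class{MolecularGraph}) and \code{truth} (data.frame per atom:
#'   molecule, index, type, key, env_mean, component_mean,
#'   pre_adjust_charge, charge, adjustment, over_3_sigma).
#' @export
genCorpus <- function(spec) {
  nStruct <- ceiling(spec@nMolecules / spec@minOccurrences)
  molecules <- vector("list", spec@nMolecules)
  truth <- list()
  count <- 0L
  for (s in seq_len(nStruct)) {
    structSeed <- (spec@seed * 7919 + s) %% 2147483647
    molS <- genMolecule(spec, structSeed)
    keys <- .keyMatrix(molS, spec@envShell)[, spec@envShell + 1L]
    models <- lapply(keys, .envModel, spec = spec)
    nA <- nAtoms(molS)
    for (copy in seq_len(spec@minOccurrences)) {
      if (count >= spec@nMolecules) break
      count <- count + 1L
      id <- sprintf("synth-%04d", count)
      set.seed((spec@seed * 104729 + count) %% 2147483647)
      noise <- stats::rnorm(nA, 0, spec@noiseSd)
      second <- stats::runif(nA) < spec@modeWeight
      base <- vapply(seq_len(nA), function(v)
        if (second[v]) models[[v]]$mode2 else models[[v]]$mean, numeric(1))
      pre <- round(base + noise, 3)
      resid <- if (spec@adjustTotals)
        .milli(spec@targetTotal) - sum(.milli(pre)) else 0L
      adj <- integer(nA)
      if (resid != 0L) {
        ord <- order(abs(noise), decreasing = TRUE)
        step <- sign(resid)
        for (i in seq_len(abs(resid)))
          adj[ord[(i - 1L) %% nA + 1L]] <- adj[ord[(i - 1L) %% nA + 1L]] + step
      }
      charge <- round(pre + adj / 1000, 3)
      over <- abs(adj / 1000) > 3 * spec@noiseSd
      if (any(over))
        warning("corpus ", id, ": residual adjustment exceeded 3 sigma for ",
                sum(over), " atom(s)")
      mol <- molS
      mol@atoms$charge <- charge
      mol@totalCharge <- if (spec@adjustTotals) as.numeric(spec@targetTotal)
                         else round(sum(charge), 3)
      mol@identifier <- id
      molecules[[count]] <- mol
      truth[[count]] <- data.frame(
        molecule = id, index = seq_len(nA), type = atomTypes(molS),
        key = keys,
        env_mean = vapply(models, function(mm) mm$mean, numeric(1)),
        component_mean = base, pre_adjust_charge = pre, charge = charge,
        adjustment = adj / 1000, over_3_sigma = over,
        stringsAsFactors = FALSE)
    }
  }
  list(molecules = molecules, truth = do.call(rbind, truth))
}

#' Generate a random epsilon-MCKP instance
#'
#' Weights are 3-decimal values, profits non-negative; with
#' \code{planted = TRUE} the capacity is set to the weight sum of a random
#' selection so at least one feasible selection exists by construction
#' (recorded in attribute \code{"planted"}). Deterministic given
#' \code{seed}.
#'
#' @param m number of item sets.
#' @param setSizes integer(2) range (or a single size) of items per set.
#' @param weightRange numeric(2) weight range in e.
#' @param profitRange numeric(2) non-negative profit range.
#' @param capacity target weight sum (ignored when \code{planted}).
#' @param epsilon window half-width.
#' @param seed integer seed.
#' @param planted plant a feasible selection (default \code{FALSE}).
#' @return an \linkS4class{EpsMckpInstance}
#' @export
genInstance <- function(m, setSizes = c(1, 6), weightRange = c(-1, 1),
                        profitRange = c(0, 10), capacity = 0, epsilon = 0.01,
                        seed = 1, planted = FALSE) {
  set.seed(seed)
  sizes <- if (length(setSizes) == 1L) rep(setSizes, m)
           else sample(setSizes[1]:setSizes[2], m, replace = TRUE)
  sets <- lapply(sizes, function(sz)
    data.frame(w = round(stats::runif(sz, weightRange[1], weightRange[2]), 3),
               p = stats::runif(sz, profitRange[1], profitRange[2])))
  if (planted) {
    pick <- vapply(sets, function(s) sample(nrow(s), 1), integer(1))
    capacity <- sum(vapply(seq_len(m), function(k) sets[[k]]$w[pick[k]],
                           numeric(1)))
  }
  inst <- epsMckpInstance(sets, capacity, epsilon)
  attr(inst, "planted") <- planted
  inst
}
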