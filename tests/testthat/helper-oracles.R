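# Independent oracles and fixture builders used across the test files.

# type-7 (linear interpolation) quantile, written out by hand so the
# Friedman-Diaconis width has an oracle independent of stats::IQR
refQuantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

refFdWidth <- function(x) {
  2 * (refQuantile(x, 0.75) - refQuantile(x, 0.25)) * length(x)^(-1 / 3)
}

# random connected molecule over a small alphabet (independent of the
# synthetic-corpus generator: plain random tree plus optional extra edges)
randomMolecule <- function(n, alphabet = c("X", "Y"), extraEdges = 0,
                           id = "rand") {
  types <- sample(alphabet, n, replace = TRUE)
  bonds <- if (n > 1)
    cbind(2:n, vapply(2:n, function(i) sample(i - 1L, 1), integer(1)))
  else matrix(integer(0), 0, 2)
  if (extraEdges > 0 && n > 2) {
    for (e in seq_len(extraEdges)) {
      pr <- sort(sample(n, 2))
      bonds <- rbind(bonds, pr)
    }
  }
  molecularGraph(types, bonds, identifier = id)
}

# BFS ball oracle via igraph shortest-path distances
igraphBall <- function(mol, v, k) {
  ig <- igraph::graph_from_edgelist(bonds(mol), directed = FALSE)
  if (igraph::vcount(ig) < nAtoms(mol))
    ig <- igraph::add_vertices(ig, nAtoms(mol) - igraph::vcount(ig))
  d <- igraph::distances(ig, v = v)[1, ]
  sort(which(d <= k))
}

# brute-force canonical certificate of a rooted labelled graph: the
# lexicographically smallest serialisation over all vertex permutations
# that fix the root (exhaustive; for graphs with <= 7 atoms)
permsFixingFirst <- function(n) {
  if (n == 1) return(list(1L))
  rest <- as.matrix(expand.grid(rep(list(2:n), n - 1)))
  rest <- rest[apply(rest, 1, function(r) length(unique(r)) == n - 1), ,
               drop = FALSE]
  lapply(seq_len(nrow(rest)), function(i) c(1L, as.integer(rest[i, ])))
}

bruteRootedCertificate <- function(types, bonds, perms = NULL) {
  n <- length(types)
  if (is.null(perms)) perms <- permsFixingFirst(n)
  best <- NULL
  for (p in perms) {
    tl <- character(n)
    tl[p] <- types
    es <- ""
    if (nrow(bonds)) {
      e <- cbind(p[bonds[, 1]], p[bonds[, 2]])
      e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
      es <- paste(e[, 1], e[, 2], sep = "-", collapse = ";")
    }
    s <- paste(paste(tl, collapse = ","), es, sep = "|")
    if (is.null(best) || s < best) best <- s
  }
  best
}

# apply an atom permutation to a molecule: old atom i becomes perm[i]
permuteMolecule <- function(mol, perm, id = identifier(mol)) {
  n <- nAtoms(mol)
  types <- character(n); types[perm] <- atomTypes(mol)
  charges <- rep(NA_real_, n); charges[perm] <- atomCharges(mol)
  b <- bonds(mol)
  b[] <- perm[b]
  molecularGraph(types, b,
                 charges = if (all(!is.na(charges))) charges else NULL,
                 totalCharge = totalCharge(mol), identifier = id)
}

# enumerate every full selection of an instance; returns a data.frame with
# one row per selection (weight, profit) -- transform-soundness oracle
enumerateSelections <- function(sets) {
  sizes <- vapply(sets, nrow, integer(1))
  grid <- expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  W <- numeric(nrow(grid)); P <- numeric(nrow(grid))
  for (k in seq_along(sets)) {
    W <- W + sets[[k]]$w[grid[, k]]
    P <- P + sets[[k]]$p[grid[, k]]
  }
  data.frame(weight = W, profit = P)
}

# small hand-built corpus: a symmetric X-Y-X path molecule
pathXYX <- function(charges = c(0.1, -0.2, 0.1), id = "xyx") {
  molecularGraph(c("X", "Y", "X"), rbind(c(1, 2), c(2, 3)),
                 charges = charges, identifier = id)
}
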