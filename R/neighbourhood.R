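#' @include AllClasses.R
NULL

.adjacencyList <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' k-neighbourhood of an atom
#'
#' The set of all atoms within graph distance k of atom \code{v}, computed
#' by the shell recursion N_k(v) = N_{k-1}(v) united with the neighbours of
#' every atom in N_{k-1}(v), with N_0(v) = {v}.
#'
#' @param molecule a \linkS4class{MolecularGraph}.
#' @param v atom index (1-based).
#' @param k shell size, integer >= 0.
#' @return sorted integer vector of atom indices (always contains \code{v}).
#' @export
kNeighbourhood <- function(molecule, v, k) {
  n <- nAtoms(molecule)
  v <- as.integer(v)
  if (length(v) != 1L || is.na(v) || v < 1L || v > n)
    stop("invalid atom index: ", v)
  if (k < 0) stop("k must be >= 0")
  adj <- .adjacencyList(n, molecule@bonds)
  nk <- v
  if (k > 0) for (s in seq_len(k)) {
    grown <- unique(c(nk, unlist(adj[nk], use.names = FALSE)))
    if (length(grown) == length(nk)) break   # shell saturated early
    nk <- grown
  }
  sort(nk)
}

#' Rooted environment subgraph of an atom
#'
#' The subgraph of the molecule induced on the k-neighbourhood of \code{v},
#' rooted at \code{v}; atom types (and charges, when present) are preserved
#' and atom indices are renumbered to the subgraph.
#'
#' @inheritParams kNeighbourhood
#' @return a \linkS4class{RootedEnvironment}
#' @export
inducedEnvironment <- function(molecule, v, k) {
  keep <- kNeighbourhood(molecule, v, k)
  b <- molecule@bonds
  inKeep <- b[, 1] %in% keep & b[, 2] %in% keep
  sub <- b[inKeep, , drop = FALSE]
  sub[] <- match(sub, keep)
  g <- new("MolecularGraph",
           atoms = molecule@atoms[keep, , drop = FALSE],
           bonds = sub, totalCharge = NA_real_,
           identifier = sprintf("%s:env(v=%d,k=%d)", molecule@identifier, v, k))
  rownames(g@atoms) <- NULL
  new("RootedEnvironment", graph = g, root = match(as.integer(v), keep),
      shell = as.integer(k))
}

#' Canonical key of a rooted environment
#'
#' Two environments receive the same key if and only if there is a graph
#' isomorphism between them that preserves atom type labels and maps root
#' to root. Vertices are coloured by the pair (atom type, distance from the
#' root) -- the root is the unique distance-0 vertex, so colour-preserving
#' isomorphisms are exactly the root-preserving type-preserving ones -- and
#' the coloured graph is brought to canonical form with igraph's BLISS
#' canonical labelling. The key serialises the canonical type/distance
#' sequence and edge list, so it is deterministic across runs and platforms.
#' Bond orders play no role: the graph model colours vertices only.
#'
#' @param env a \linkS4class{RootedEnvironment}.
#' @return character(1), an opaque canonical key.
#' @export
canonicalKey <- function(env) {
  g <- env@graph
  n <- nAtoms(g)
  d <- .bfsDistances(n, g@bonds, env@root)
  labels <- paste0(g@atoms$type, "@", d)
  if (n == 1L) return(paste0("1|", labels, "|"))
  colors <- as.integer(factor(labels, levels = sort(unique(labels))))
  ig <- igraph::graph_from_edgelist(g@bonds, directed = FALSE)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  perm <- igraph::canonical_permutation(ig, colors = colors)$labeling
  canLabels <- character(n)
  canLabels[perm] <- labels
  e <- cbind(perm[g@bonds[, 1]], perm[g@bonds[, 2]])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  paste0(n, "|", paste(canLabels, collapse = ","), "|",
         paste(e[, 1], e[, 2], sep = "-", collapse = ";"))
}

# All canonical keys of one molecule for shells 0..k: a matrix
# [atom, shell + 1]. Used by the database builder and cached lookups.
.keyMatrix <- function(molecule, k) {
  n <- nAtoms(molecule)
  keys <- matrix(NA_character_, n, k + 1L)
  for (v in seq_len(n))
    for (s in 0:k)
      keys[v, s + 1L] <- canonicalKey(inducedEnvironment(molecule, v, s))
  keys
}
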