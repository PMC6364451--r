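#' @include AllClasses.R
NULL

.PROFIT_TOL <- 1e-9

#' Construct an epsilon-MCKP instance
#'
#' @param sets list of item sets; each set a data.frame (or matrix or list
#'   of \code{list(w, p)}) with weights \code{w} (any sign) and non-negative
#'   profits \code{p}.
#' @param capacity target weight sum (any sign).
#' @param epsilon allowed deviation, >= 0.
#' @return an \linkS4class{EpsMckpInstance}
#' @examples
#' inst <- epsMckpInstance(
#'   list(data.frame(w = c(-0.5, 0.2), p = c(1, 2)),
#'        data.frame(w = 0.3, p = 1.5)),
#'   capacity = 0.5, epsilon = 0)
#' solveDp(inst)
#' @export
epsMckpInstance <- function(sets, capacity, epsilon) {
  norm <- lapply(sets, function(s) {
    if (is.data.frame(s)) data.frame(w = as.numeric(s$w), p = as.numeric(s$p))
    else if (is.matrix(s)) data.frame(w = as.numeric(s[, 1]), p = as.numeric(s[, 2]))
    else data.frame(w = vapply(s, function(it) as.numeric(it$w), numeric(1)),
                    p = vapply(s, function(it) as.numeric(it$p), numeric(1)))
  })
  new("EpsMckpInstance", sets = norm, capacity = as.numeric(capacity),
      epsilon = as.numeric(epsilon))
}

#' Transform an instance to non-negative integer weights
#'
#' Scales weights, capacity and epsilon by \code{factor} (10^3 suffices for
#' 3-decimal charges), then shifts each set by its minimum scaled weight
#' w*_i so all weights are non-negative with a zero in every set; the
#' capacity becomes scaled c minus the sum of the w*_i. Exactly the same
#' full selections are feasible before and after.
#'
#' @param inst an \linkS4class{EpsMckpInstance}.
#' @param factor positive integer scaling factor (default 1000).
#' @return an \linkS4class{IntegerInstance}
#' @export
toIntegerInstance <- function(inst, factor = 1000) {
  factor <- as.integer(factor)
  offsets <- numeric(length(inst@sets))
  sets <- vector("list", length(inst@sets))
  for (i in seq_along(inst@sets)) {
    sw <- inst@sets[[i]]$w * factor
    bad <- which(abs(sw - round(sw)) > 1e-6)
    if (length(bad))
      stop(sprintf("weight %g (set %d, item %d) is not integral at factor %d",
                   inst@sets[[i]]$w[bad[1]], i, bad[1], factor))
    sw <- round(sw)
    offsets[i] <- min(sw)
    sets[[i]] <- data.frame(w = as.integer(sw - offsets[i]),
                            p = inst@sets[[i]]$p)
  }
  new("IntegerInstance", sets = sets,
      capacity = inst@capacity * factor - sum(offsets),
      epsilon = inst@epsilon * factor,
      factor = factor, offsets = offsets)
}

# integer d-window of an IntegerInstance (NULL when empty)
.dWindow <- function(int) {
  lo <- max(ceiling(int@capacity - int@epsilon - 1e-9), 0)
  hi <- floor(int@capacity + int@epsilon + 1e-9)
  if (hi < 0 || lo > hi) NULL else c(as.integer(lo), as.integer(hi))
}

# suffix DP table: S[k, d + 1] = max profit selecting one item from each of
# sets k..m with transformed weight sum exactly d (0 <= d <= hi); -Inf when
# no such selection exists. Row m + 1 is the empty-suffix base case.
.dpSuffixTable <- function(int, hi) {
  m <- length(int@sets)
  W1 <- hi + 1L
  S <- matrix(-Inf, m + 1L, W1)
  S[m + 1L, 1L] <- 0
  for (k in rev(seq_len(m))) {
    prev <- S[k + 1L, ]
    best <- rep(-Inf, W1)
    st <- int@sets[[k]]
    for (j in seq_len(nrow(st))) {
      w <- st$w[j]
      if (w >= W1) next
      cand <- c(rep(-Inf, w), prev[seq_len(W1 - w)]) + st$p[j]
      best <- pmax(best, cand)
    }
    S[k, ] <- best
  }
  S
}

# achievable transformed weight sums (logical over d = 0..sum(max w))
.achievableTotals <- function(int) {
  hiF <- sum(vapply(int@sets, function(s) max(s$w), numeric(1)))
  reach <- c(TRUE, rep(FALSE, hiF))
  for (s in int@sets) {
    nxt <- rep(FALSE, hiF + 1L)
    for (w in unique(s$w)) {
      if (w == 0L) nxt <- nxt | reach
      else nxt[(w + 1L):(hiF + 1L)] <- nxt[(w + 1L):(hiF + 1L)] |
          reach[seq_len(hiF + 1L - w)]
    }
    reach <- nxt
  }
  reach
}

# achievable total-weight range on the original scale
.achievableRange <- function(int) {
  d <- which(.achievableTotals(int)) - 1L
  (range(d) + sum(int@offsets)) / int@factor
}

.infeasibleSolution <- function(inst, method, int = NULL) {
  info <- list()
  if (!is.null(int)) info$achievableRange <- .achievableRange(int)
  new("McKpSolution", selection = rep(NA_integer_, length(inst@sets)),
      totalWeight = NA_real_, totalProfit = NA_real_,
      feasible = FALSE, method = method, info = info)
}

.solutionFromSelection <- function(inst, sel, method, info = list()) {
  w <- vapply(seq_along(sel), function(k) inst@sets[[k]]$w[sel[k]], numeric(1))
  p <- vapply(seq_along(sel), function(k) inst@sets[[k]]$p[sel[k]], numeric(1))
  new("McKpSolution", selection = as.integer(sel),
      totalWeight = sum(w), totalProfit = sum(p),
      feasible = TRUE, method = method, info = info)
}

#' Solve epsilon-MCKP by dynamic programming
#'
#' Pseudo-polynomial exact algorithm: the instance is brought to
#' non-negative integer weights, a profit table over sets x exact weight
#' sums is filled (the empty prefix admits only weight 0, so a cell is
#' finite exactly when some selection attains that weight sum), and the
#' optimum is the maximal profit over weight sums d with
#' max(c - epsilon, 0) <= d <= c + epsilon. Runs in O(n (c + epsilon))
#' time for n items after scaling. Among co-optimal selections the
#' lexicographically smallest item-index vector is returned, recovered by
#' a greedy forward pass over a suffix profit table.
#'
#' @param inst an \linkS4class{EpsMckpInstance}.
#' @param factor integer scaling factor (default 1000; appropriate for
#'   3-decimal charge weights).
#' @param recoverSelection when \code{FALSE}, only the optimal profit and
#'   feasibility are computed, using a single rolling table row (space
#'   O(c + epsilon)); the selection is left \code{NA}.
#' @return an \linkS4class{McKpSolution} (with \code{feasible = FALSE} when
#'   no selection lands in the window).
#' @export
solveDp <- function(inst, factor = 1000, recoverSelection = TRUE) {
  int <- toIntegerInstance(inst, factor)
  win <- .dWindow(int)
  if (is.null(win)) return(.infeasibleSolution(inst, "dp", int))
  lo <- win[1]; hi <- win[2]
  m <- length(int@sets)
  if (!recoverSelection) {
    prev <- c(0, rep(-Inf, hi))
    for (k in rev(seq_len(m))) {
      best <- rep(-Inf, hi + 1L)
      st <- int@sets[[k]]
      for (j in seq_len(nrow(st))) {
        w <- st$w[j]
        if (w > hi) next
        cand <- c(rep(-Inf, w), prev[seq_len(hi + 1L - w)]) + st$p[j]
        best <- pmax(best, cand)
      }
      prev <- best
    }
    pstar <- max(prev[(lo:hi) + 1L])
    if (!is.finite(pstar)) return(.infeasibleSolution(inst, "dp", int))
    return(new("McKpSolution", selection = rep(NA_integer_, m),
               totalWeight = NA_real_, totalProfit = pstar,
               feasible = TRUE, method = "dp", info = list(profitOnly = TRUE)))
  }
  S <- .dpSuffixTable(int, hi)
  pstar <- max(S[1L, (lo:hi) + 1L])
  if (!is.finite(pstar)) return(.infeasibleSolution(inst, "dp", int))
  # lexicographically smallest co-optimal selection
  sel <- integer(m)
  accW <- 0L; accP <- 0
  for (k in seq_len(m)) {
    st <- int@sets[[k]]
    for (j in seq_len(nrow(st))) {
      w <- st$w[j]
      b <- hi - accW - w
      if (b < 0L) next
      a <- max(lo - accW - w, 0L)
      bestRem <- max(S[k + 1L, (a:b) + 1L])
      if (is.finite(bestRem) &&
          accP + st$p[j] + bestRem >= pstar - .PROFIT_TOL) {
        sel[k] <- j
        accW <- accW + w
        accP <- accP + st$p[j]
        break
      }
    }
  }
  .solutionFromSelection(inst, sel, "dp")
}

#' Solve epsilon-MCKP via the 0-1 integer programming formulation
#'
#' Maximises the selected profit subject to the two window constraints on
#' the selected weight sum and one pick-exactly-one constraint per set,
#' over binary selection variables. The binary program is solved exactly by
#' depth-first branch-and-bound: partial selections are pruned when the
#' remaining sets cannot bring the weight sum into the window, or when the
#' sum of the remaining per-set maximum profits cannot beat the incumbent.
#' Optimal profit always equals \code{\link{solveDp}}'s; the returned
#' co-optimal selection may differ.
#'
#' @param inst an \linkS4class{EpsMckpInstance}.
#' @return an \linkS4class{McKpSolution}
#' @export
solveIlp <- function(inst) {
  m <- length(inst@sets)
  wl <- lapply(inst@sets, function(s) s$w)
  pl <- lapply(inst@sets, function(s) s$p)
  lo <- inst@capacity - inst@epsilon - .PROFIT_TOL
  hi <- inst@capacity + inst@epsilon + .PROFIT_TOL
  minW <- rev(cumsum(rev(vapply(wl, min, numeric(1)))))
  maxW <- rev(cumsum(rev(vapply(wl, max, numeric(1)))))
  maxP <- rev(cumsum(rev(vapply(pl, max, numeric(1)))))
  minW <- c(minW, 0); maxW <- c(maxW, 0); maxP <- c(maxP, 0)
  best <- -Inf
  bestSel <- NULL
  sel <- integer(m)
  nodes <- 0L
  dfs <- function(k, accW, accP) {
    nodes <<- nodes + 1L
    if (accW + minW[k] > hi || accW + maxW[k] < lo) return(invisible())
    if (accP + maxP[k] <= best + .PROFIT_TOL) return(invisible())
    if (k > m) {
      best <<- accP
      bestSel <<- sel
      return(invisible())
    }
    for (j in seq_along(wl[[k]])) {
      sel[k] <<- j
      dfs(k + 1L, accW + wl[[k]][j], accP + pl[[k]][j])
    }
    invisible()
  }
  dfs(1L, 0, 0)
  if (is.null(bestSel)) {
    int <- tryCatch(toIntegerInstance(inst), error = function(e) NULL)
    return(.infeasibleSolution(inst, "ilp", int))
  }
  .solutionFromSelection(inst, bestSel, "ilp", info = list(nodes = nodes))
}

#' Solve epsilon-MCKP by exhaustive enumeration
#'
#' Test oracle: enumerates every full selection (at most 10^6 combinations)
#' and returns the maximum-profit feasible one, breaking profit ties by the
#' lexicographically smallest item-index vector.
#'
#' @param inst an \linkS4class{EpsMckpInstance}.
#' @return an \linkS4class{McKpSolution}
#' @export
solveBruteforce <- function(inst) {
  sizes <- vapply(inst@sets, nrow, integer(1))
  if (prod(sizes) > 1e6)
    stop("instance has ", prod(sizes), " selections; bruteforce bound is 1e6")
  m <- length(sizes)
  # rows in lexicographic order of (j_1, ..., j_m), j_1 most significant
  grid <- expand.grid(rev(lapply(sizes, seq_len)), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid[, rev(seq_len(m)), drop = FALSE])
  colnames(grid) <- NULL
  W <- numeric(nrow(grid)); P <- numeric(nrow(grid))
  for (k in seq_len(m)) {
    W <- W + inst@sets[[k]]$w[grid[, k]]
    P <- P + inst@sets[[k]]$p[grid[, k]]
  }
  ok <- W >= inst@capacity - inst@epsilon - .PROFIT_TOL &
        W <= inst@capacity + inst@epsilon + .PROFIT_TOL
  if (!any(ok)) {
    int <- tryCatch(toIntegerInstance(inst), error = function(e) NULL)
    return(.infeasibleSolution(inst, "bruteforce", int))
  }
  pmaxF <- max(P[ok])
  idx <- which(ok & P >= pmaxF - .PROFIT_TOL)[1]
  .solutionFromSelection(inst, grid[idx, ], "bruteforce")
}

#' Reduce a standard MCKP capacity to an epsilon-MCKP window
#'
#' A standard multiple-choice knapsack with non-negative weights and
#' capacity c (weight sum <= c) is equivalent to the windowed problem with
#' capacity c/2 and epsilon c/2, whose window is exactly [0, c].
#'
#' @param c standard MCKP capacity, >= 0.
#' @return list with elements \code{capacity} (= c/2) and \code{epsilon}
#'   (= c/2).
#' @export
reduceMckpToEps <- function(c) {
  if (c < 0) stop("standard MCKP assumes a non-negative capacity")
  list(capacity = c / 2, epsilon = c / 2)
}

# JSON interfaces -----------------------------------------------------------

#' Read an epsilon-MCKP instance from JSON
#'
#' Schema: \code{{sets: [[{w, p}, ...], ...], c, epsilon}}.
#' @param path input file.
#' @return an \linkS4class{EpsMckpInstance}
#' @export
readInstance <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("sets", "c", "epsilon"))
    if (is.null(x[[f]])) stop("instance JSON: missing field /", f)
  epsMckpInstance(x$sets, x$c, x$epsilon)
}

#' Write an epsilon-MCKP instance to JSON
#' @param inst an \linkS4class{EpsMckpInstance}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeInstance <- function(inst, path) {
  sets <- lapply(inst@sets, function(s)
    lapply(seq_len(nrow(s)), function(j) list(w = s$w[j], p = s$p[j])))
  jsonlite::write_json(list(sets = sets, c = inst@capacity,
                            epsilon = inst@epsilon),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a solution to JSON
#'
#' Schema: \code{{selection, total_weight, total_profit, feasible}}.
#' @param sol an \linkS4class{McKpSolution}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSolution <- function(sol, path) {
  obj <- list(selection = if (sol@feasible) sol@selection else NULL,
              total_weight = if (sol@feasible) sol@totalWeight else NULL,
              total_profit = if (sol@feasible) sol@totalProfit else NULL,
              feasible = sol@feasible)
  if (!is.null(sol@info$achievableRange))
    obj$achievable_range <- sol@info$achievableRange
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
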