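test_that("the integer transform follows the printed arithmetic", {
  inst <- epsMckpInstance(list(data.frame(w = c(-0.5, 0.2), p = c(1, 2)),
                               data.frame(w = 0.3, p = 1.5)),
                          capacity = 0, epsilon = 0.1)
  int <- toIntegerInstance(inst, 1000)
  expect_equal(int@sets[[1]]$w, c(0L, 700L))
  expect_equal(int@sets[[2]]$w, 0L)
  expect_equal(int@offsets, c(-500, 300))
  expect_equal(int@capacity, 200)   # 0 - (-500 + 300)
  expect_equal(int@epsilon, 100)

  # already non-negative integers, factor 1: shift by per-set minima only
  inst2 <- epsMckpInstance(list(data.frame(w = c(2, 5), p = c(1, 1))),
                           capacity = 4, epsilon = 1)
  int2 <- toIntegerInstance(inst2, 1)
  expect_equal(int2@sets[[1]]$w, c(0L, 3L))
  expect_equal(int2@capacity, 2)

  # non-integral scaled weight names the offending item
  bad <- epsMckpInstance(list(data.frame(w = 0.0005, p = 1)), 0, 0)
  expect_error(toIntegerInstance(bad, 1000), "set 1, item 1")
})

test_that("the transform preserves the feasible-selection set exactly", {
  set.seed(51)
  for (rep in 1:40) {
    inst <- genInstance(m = sample(1:4, 1), setSizes = c(1, 4),
                        capacity = round(runif(1, -1, 1), 3),
                        epsilon = sample(c(0, 0.01, 0.1, 0.5), 1), seed = rep)
    int <- toIntegerInstance(inst)
    orig <- enumerateSelections(inst@sets)
    trans <- enumerateSelections(int@sets)
    feasO <- abs(orig$weight - inst@capacity) <= inst@epsilon + 1e-9
    feasT <- trans$weight >= int@capacity - int@epsilon - 1e-9 &
             trans$weight <= int@capacity + int@epsilon + 1e-9
    expect_identical(feasT, feasO)
  }
})

test_that("DP reproduces the worked examples and brute force", {
  sets <- list(data.frame(w = c(-0.5, 0.2), p = c(1, 2)),
               data.frame(w = 0.3, p = 1.5))
  s <- solveDp(epsMckpInstance(sets, 0.5, 0))
  expect_true(s@feasible)
  expect_equal(s@totalProfit, 3.5)
  expect_equal(s@totalWeight, 0.5)
  expect_identical(s@selection, c(2L, 1L))

  s2 <- solveDp(epsMckpInstance(sets, 0, 0.1))
  expect_false(s2@feasible)
  expect_equal(s2@info$achievableRange, c(-0.2, 0.5))

  # single set: max profit among in-window items
  s3 <- solveDp(epsMckpInstance(list(data.frame(w = c(0.1, 0.2), p = c(5, 1))),
                                0.15, 0.1))
  expect_equal(s3@totalProfit, 5)
  expect_identical(s3@selection, 1L)

  # profit-only mode agrees and stores no selection
  s4 <- solveDp(epsMckpInstance(sets, 0.5, 0), recoverSelection = FALSE)
  expect_equal(s4@totalProfit, 3.5)
  expect_true(all(is.na(s4@selection)))
})

test_that("the branch-and-bound 0-1 formulation matches DP and brute force", {
  sets <- list(data.frame(w = c(-0.5, 0.2), p = c(1, 2)),
               data.frame(w = 0.3, p = 1.5))
  expect_equal(solveIlp(epsMckpInstance(sets, 0.5, 0))@totalProfit, 3.5)
  expect_false(solveIlp(epsMckpInstance(sets, 0, 0.1))@feasible)

  set.seed(52)
  for (rep in 1:200) {
    inst <- genInstance(m = sample(1:6, 1), setSizes = c(1, 5),
                        capacity = round(runif(1, -2, 2), 3),
                        epsilon = sample(c(0, 0.01, 0.1), 1), seed = 1000 + rep)
    b <- solveBruteforce(inst)
    d <- solveDp(inst)
    l <- solveIlp(inst)
    expect_equal(d@feasible, b@feasible)
    expect_equal(l@feasible, b@feasible)
    if (b@feasible) {
      expect_equal(d@totalProfit, b@totalProfit, tolerance = 1e-9)
      expect_equal(l@totalProfit, b@totalProfit, tolerance = 1e-9)
      # DP and brute force share the lexicographic tie-break
      expect_identical(d@selection, b@selection)
      for (s in list(d, l, b))
        expect_true(abs(s@totalWeight - inst@capacity) <=
                      inst@epsilon + 1e-9)
    }
  }
})

test_that("brute force handles degenerate shapes and respects its bound", {
  one <- epsMckpInstance(list(data.frame(w = c(0.3, 0.1), p = c(1, 9))),
                         0.1, 0.05)
  s <- solveBruteforce(one)
  expect_identical(s@selection, 2L)
  # all-zero weights: profit is the sum of per-set maxima
  zero <- epsMckpInstance(list(data.frame(w = c(0, 0), p = c(1, 4)),
                               data.frame(w = 0, p = 2)), 0, 0)
  expect_equal(solveBruteforce(zero)@totalProfit, 6)
  big <- epsMckpInstance(rep(list(data.frame(w = rep(0, 50), p = rep(1, 50))), 4),
                         0, 0)
  expect_error(solveBruteforce(big), "bruteforce bound")
})

test_that("the capacity-halving reduction solves standard MCKP instances", {
  r <- reduceMckpToEps(10)
  expect_equal(r$capacity, 5)
  expect_equal(r$epsilon, 5)
  expect_error(reduceMckpToEps(-1), "non-negative")

  # c = 0: only zero-weight selections are feasible
  inst0 <- epsMckpInstance(list(data.frame(w = c(0, 0.1), p = c(1, 9))), 0, 0)
  expect_identical(solveDp(inst0)@selection, 1L)

  # random non-negative MCKP: windowed optimum == brute-force <= c optimum
  set.seed(53)
  for (rep in 1:60) {
    m <- sample(1:4, 1)
    sets <- lapply(seq_len(m), function(i) {
      sz <- sample(1:4, 1)
      data.frame(w = round(runif(sz, 0, 1), 3), p = runif(sz, 0, 10))
    })
    cap <- round(runif(1, 0, m), 3)
    sel <- enumerateSelections(sets)
    feas <- sel$weight <= cap + 1e-9
    r <- reduceMckpToEps(cap)
    sol <- solveDp(epsMckpInstance(sets, r$capacity, r$epsilon))
    if (!any(feas)) {
      expect_false(sol@feasible)
    } else {
      expect_equal(sol@totalProfit, max(sel$profit[feas]), tolerance = 1e-9)
    }
  }
})

test_that("optimal profit is non-decreasing in epsilon", {
  set.seed(54)
  for (rep in 1:25) {
    inst <- genInstance(m = sample(2:5, 1), setSizes = c(2, 4),
                        capacity = round(runif(1, -1, 1), 3),
                        epsilon = 0, seed = 2000 + rep)
    prev <- -Inf
    for (eps in c(0, 0.01, 0.05, 0.1, 0.5, 1, 2, 6)) {
      s <- solveDp(epsMckpInstance(inst@sets, inst@capacity, eps))
      p <- if (s@feasible) s@totalProfit else -Inf
      expect_gte(p + 1e-9, prev)
      prev <- p
    }
    # a window covering every achievable sum yields the per-set maxima
    wide <- solveDp(epsMckpInstance(inst@sets, inst@capacity, 20))
    expect_equal(wide@totalProfit,
                 sum(vapply(inst@sets, function(s) max(s$p), numeric(1))),
                 tolerance = 1e-9)
  }
})

test_that("the DP table is finite exactly on achievable weight sums", {
  set.seed(55)
  for (rep in 1:15) {
    inst <- genInstance(m = sample(1:4, 1), setSizes = c(1, 3),
                        capacity = round(runif(1, 0, 1), 3), epsilon = 0.5,
                        seed = 3000 + rep)
    int <- toIntegerInstance(inst)
    win <- knapcharge:::.dWindow(int)
    if (is.null(win)) next
    S <- knapcharge:::.dpSuffixTable(int, win[2])
    m <- length(int@sets)
    ok <- TRUE
    for (k in seq_len(m)) {
      ach <- unique(enumerateSelections(int@sets[k:m])$weight)
      reachable <- (0:win[2]) %in% ach
      ok <- ok && identical(is.finite(S[k, ]), reachable)
    }
    expect_true(ok)
  }
})

test_that("DP work scales with total items times the scaled window", {
  # monotone-trend smoke check, not a wall-clock target
  sizes <- c(200, 800, 3200)
  times <- vapply(sizes, function(cap) {
    sets <- rep(list(data.frame(w = round(seq(0, cap / 1000, length.out = 6), 3),
                                p = 1:6)), 6)
    inst <- epsMckpInstance(sets, 3 * cap / 1000, 0.01)
    median(vapply(1:3, function(i)
      system.time(solveDp(inst, recoverSelection = FALSE))[["elapsed"]],
      numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(times + seq_along(times) * 1e-6))
})

test_that("instances and solutions round-trip through their JSON schemas", {
  inst <- epsMckpInstance(list(data.frame(w = c(-0.5, 0.2), p = c(1, 2)),
                               data.frame(w = 0.3, p = 1.5)), 0.5, 0)
  f <- withr::local_tempfile(fileext = ".json")
  writeInstance(inst, f)
  back <- readInstance(f)
  expect_equal(back@sets, inst@sets)
  expect_equal(back@capacity, 0.5)
  expect_equal(back@epsilon, 0)
  fs <- withr::local_tempfile(fileext = ".json")
  writeSolution(solveDp(inst), fs)
  sol <- jsonlite::fromJSON(fs)
  expect_true(sol$feasible)
  expect_equal(sol$total_profit, 3.5)
  expect_equal(sol$selection, c(2L, 1L))
})
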