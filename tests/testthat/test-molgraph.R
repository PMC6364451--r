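test_that("SDF round-trip preserves atoms, bonds, charges and total exactly", {
  mol <- molecularGraph(c("C", "H", "H", "H", "H"),
                        rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)),
                        charges = c(-0.4, 0.1, 0.1, 0.1, 0.1),
                        identifier = "methane-like")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeMolecules(mol, f)
  back <- readMolecules(f)
  expect_length(back, 1)
  m2 <- back[[1]]
  expect_equal(nAtoms(m2), 5)
  expect_equal(nrow(bonds(m2)), 4)
  expect_identical(atomTypes(m2), atomTypes(mol))
  expect_identical(atomCharges(m2), atomCharges(mol))
  expect_identical(bonds(m2), bonds(mol))
  expect_equal(totalCharge(m2), 0)
  expect_equal(identifier(m2), "methane-like")

  # second round-trip through writeCharges with new charges
  writeCharges(m2, c(0.1, -0.2, 0.1, 0, 0), f)
  m3 <- readMolecules(f)[[1]]
  expect_identical(atomCharges(m3), c(0.1, -0.2, 0.1, 0, 0))
})

test_that("atom-type override and multi-record files survive a round-trip", {
  m1 <- molecularGraph(c("CAro", "HC", "HC"), rbind(c(1, 2), c(1, 3)),
                       charges = c(-0.2, 0.1, 0.1), identifier = "typed")
  m2 <- pathXYX()
  f <- withr::local_tempfile(fileext = ".sdf")
  writeMolecules(list(m1, m2), f)
  back <- readMolecules(f)
  expect_length(back, 2)
  expect_identical(atomTypes(back[[1]]), c("CAro", "HC", "HC"))
  expect_identical(atomTypes(back[[2]]), c("X", "Y", "X"))
  expect_identical(atomCharges(back[[1]]), atomCharges(m1))
})

test_that("empty files and malformed records are handled as specified", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(0), f)
  expect_identical(readMolecules(f), list())

  # charge block with 4 values for a 5-atom record
  mol <- molecularGraph(rep("C", 5),
                        rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
                        charges = rep(0, 5), identifier = "pent")
  writeMolecules(mol, f)
  txt <- readLines(f)
  i <- which(txt == "> <PARTIAL_CHARGES>")
  txt <- txt[-(i + 1)]   # drop one charge line
  writeLines(txt, f)
  expect_error(readMolecules(f), "PARTIAL_CHARGES has 4 values for 5 atoms")

  # neither charges nor total charge present
  writeMolecules(mol, f)
  txt <- readLines(f)
  txt <- txt[!grepl("CHARGE", txt) & !grepl("^-?[0-9.]+$", trimws(txt))]
  writeLines(txt, f)
  expect_error(readMolecules(f), "neither TOTAL_CHARGE nor PARTIAL_CHARGES")
})

test_that("charge precision and length contracts are enforced on write", {
  mol <- pathXYX()
  f <- withr::local_tempfile(fileext = ".sdf")
  expect_error(writeCharges(mol, c(0.1, -0.2), f), "length")
  expect_error(writeCharges(mol, c(0.1234, -0.2, 0.1), f), "0.001")
})

test_that("JSON molecule input matches the schema and the SDF reader", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"identifier":"j1","atoms":[{"type":"X","charge":0.1},
    {"type":"Y","charge":-0.2},{"type":"X","charge":0.1}],
    "bonds":[[1,2],[2,3]],"total_charge":0}', f)
  m <- readMolecules(f)[[1]]
  expect_identical(atomTypes(m), c("X", "Y", "X"))
  expect_identical(atomCharges(m), c(0.1, -0.2, 0.1))
  expect_equal(totalCharge(m), 0)
})

test_that("the SDF writer emits files ChemmineR parses identically", {
  skip_if_not_installed("ChemmineR")
  mol <- molecularGraph(c("C", "N", "O", "H"),
                        rbind(c(1, 2), c(1, 3), c(1, 4)),
                        charges = c(0.3, -0.4, -0.3, 0.4), identifier = "xm")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeMolecules(mol, f)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(f))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  expect_equal(nrow(ab), 4)
  expect_equal(nrow(bb), 3)
  expect_identical(sub("_.*$", "", rownames(ab)), c("C", "N", "O", "H"))
})

test_that("kNeighbourhood follows the shell recursion and matches a BFS ball", {
  # k = 0 and a 1-shell on a path
  path <- molecularGraph(c("X", "Y", "Z"), rbind(c(1, 2), c(2, 3)))
  expect_identical(kNeighbourhood(path, 2, 0), 2L)
  expect_identical(kNeighbourhood(path, 1, 1), c(1L, 2L))
  expect_error(kNeighbourhood(path, 9, 1), "invalid atom index")

  # random graphs: equality with an independent shortest-path ball,
  # shell monotonicity, saturation at the diameter
  set.seed(11)
  for (rep in 1:25) {
    mol <- randomMolecule(sample(10:50, 1), extraEdges = sample(0:3, 1))
    v <- sample(nAtoms(mol), 1)
    prev <- integer(0)
    for (k in 0:4) {
      ball <- kNeighbourhood(mol, v, k)
      expect_identical(ball, igraphBall(mol, v, k))
      expect_true(all(prev %in% ball))
      prev <- ball
    }
    expect_identical(kNeighbourhood(mol, v, nAtoms(mol)),
                     seq_len(nAtoms(mol)))
  }
})

test_that("inducedEnvironment keeps the induced structure and the root", {
  star <- molecularGraph(c("C", "H", "H", "H"),
                         rbind(c(1, 2), c(1, 3), c(1, 4)))
  env <- inducedEnvironment(star, 1, 1)
  expect_equal(nAtoms(env), 4)
  expect_equal(nrow(env@graph@bonds), 3)
  expect_equal(env@root, 1L)

  leafEnv <- inducedEnvironment(star, 2, 1)
  expect_equal(nAtoms(leafEnv), 2)
  expect_identical(sort(atomTypes(leafEnv)), c("C", "H"))

  ring <- molecularGraph(rep("C", 6),
                         rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6)))
  full <- inducedEnvironment(ring, 3, 3)
  expect_equal(nAtoms(full), 6)
  expect_equal(nrow(full@graph@bonds), 6)   # induced: all ring edges kept

  # induced subgraph contains every edge between ball members
  set.seed(4)
  for (rep in 1:10) {
    mol <- randomMolecule(30, extraEdges = 3)
    v <- sample(30, 1)
    keep <- igraphBall(mol, v, 2)
    env <- inducedEnvironment(mol, v, 2)
    b <- bonds(mol)
    nEdges <- sum(b[, 1] %in% keep & b[, 2] %in% keep)
    expect_equal(nrow(env@graph@bonds), nEdges)
  }
})

test_that("canonical keys are invariant under atom reindexing and separate types", {
  set.seed(21)
  for (rep in 1:20) {
    mol <- randomMolecule(sample(4:12, 1), extraEdges = sample(0:2, 1))
    v <- sample(nAtoms(mol), 1)
    k <- sample(0:3, 1)
    key <- canonicalKey(inducedEnvironment(mol, v, k))
    perm <- sample(nAtoms(mol))
    key2 <- canonicalKey(inducedEnvironment(permuteMolecule(mol, perm), perm[v], k))
    expect_identical(key2, key)
  }

  # changing one atom's type changes the key
  m1 <- pathXYX()
  m2 <- molecularGraph(c("X", "Y", "Y"), rbind(c(1, 2), c(2, 3)))
  expect_false(identical(canonicalKey(inducedEnvironment(m1, 1, 2)),
                         canonicalKey(inducedEnvironment(m2, 1, 2))))
  # the root is distinguished: center vs leaf of the same path differ
  expect_false(identical(canonicalKey(inducedEnvironment(m1, 1, 2)),
                         canonicalKey(inducedEnvironment(m1, 2, 2))))
})

test_that("key equality coincides with rooted isomorphism on small graphs", {
  # exhaustive over all connected rooted graphs with <= 3 atoms, 2 letters
  # (the <= 5-atom sweep runs with the acceptance checks)
  for (n in 1:3) {
    pairs <- if (n > 1) t(utils::combn(n, 2)) else matrix(integer(0), 0, 2)
    perms <- permsFixingFirst(n)
    keys <- character(0); certs <- character(0)
    for (mask in 0:(2^nrow(pairs) - 1)) {
      sel <- bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0
      b <- pairs[sel, , drop = FALSE]
      if (n > 1 && length(knapcharge:::.connectedComponent(n, b, 1L)) != n) next
      for (lab in 0:(2^n - 1)) {
        types <- ifelse(bitwAnd(lab, 2^(0:(n - 1))) > 0, "Y", "X")
        mol <- molecularGraph(types, b)
        env <- new("RootedEnvironment", graph = mol, root = 1L,
                   shell = as.integer(n))
        keys <- c(keys, canonicalKey(env))
        certs <- c(certs, bruteRootedCertificate(types, b, perms))
      }
    }
    expect_true(all(tapply(keys, certs, function(k) length(unique(k))) == 1))
    expect_true(all(tapply(certs, keys, function(c) length(unique(c))) == 1))
  }
})

test_that("molecular graph validity rejects broken structures", {
  expect_error(molecularGraph(c("X", "Y"), rbind(c(1, 3))), "out of range")
  expect_error(molecularGraph(c("X", "Y", "Z"), rbind(c(1, 2))), "not connected")
  expect_error(molecularGraph("X", bonds = rbind(c(1, 1))), "self-loop")
  expect_error(molecularGraph(c("X", "Y"), rbind(c(1, 2)),
                              charges = c(0.0005, 0)), "0.001")
})
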