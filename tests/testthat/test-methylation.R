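# In-silico cytosine methylation: counting, geometry, idempotence.

# independent geometry helpers (eigen-based plane fit, direct angles)
planeNormalEigen <- function(m) {
  c0 <- sweep(m, 2, colMeans(m))
  ev <- eigen(crossprod(c0), symmetric = TRUE)
  ev$vectors[, 3]
}
angleDeg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

atomXYZ <- function(structure, uid, name) {
  a <- atoms(structure)
  u <- paste(a$chain, a$seqid, a$icode, sep = ":")
  unlist(a[u == uid & a$name == name, c("x", "y", "z")])
}

test_that("every cytosine gains one methyl and is renamed to 5CM", {
  s <- toyNucSmall()
  nDC <- sum(residues(s)$resname == "DC")
  out <- methylateAllCytosines(s)
  rep <- out$report
  expect_gt(nDC, 0)
  expect_equal(rep@nCytosinesFound, nDC)
  expect_equal(rep@nMethylated, nDC)
  expect_equal(nrow(rep@skipped), 0)
  expect_equal(nAtoms(out$structure), nAtoms(s) + nDC)
  r2 <- residues(out$structure)
  expect_equal(sum(r2$resname == "5CM"), nDC)
  expect_equal(sum(r2$resname == "DC"), 0)
  # guanine/adenine/thymine untouched
  expect_equal(sum(r2$resname %in% c("DA", "DG", "DT")),
               sum(residues(s)$resname %in% c("DA", "DG", "DT")))
})

test_that("pre-existing atoms are bit-exact and serials stay consistent", {
  s <- toyNucSmall()
  out <- methylateAllCytosines(s)
  a2 <- atoms(out$structure)
  old <- a2[a2$name != "C5M", ]
  expect_identical(old$name, atoms(s)$name)
  expect_identical(old$chain, atoms(s)$chain)
  expect_identical(old$seqid, atoms(s)$seqid)
  expect_identical(old$x, atoms(s)$x)
  expect_identical(old$y, atoms(s)$y)
  expect_identical(old$z, atoms(s)$z)
  expect_identical(a2$serial, seq_len(nrow(a2)))
})

test_that("methyl placement satisfies the bond/plane/bisector geometry", {
  s <- toyNucSmall()
  out <- methylateAllCytosines(s, bondLength = 1.50)
  r2 <- residues(out$structure)
  for (u in r2$uid[r2$resname == "5CM"]) {
    c4 <- atomXYZ(out$structure, u, "C4")
    c5 <- atomXYZ(out$structure, u, "C5")
    c6 <- atomXYZ(out$structure, u, "C6")
    c5m <- atomXYZ(out$structure, u, "C5M")
    expect_equal(sqrt(sum((c5m - c5)^2)), 1.50, tolerance = 0.01 / 1.50)
    ring <- t(vapply(c("N1", "C2", "N3", "C4", "C5", "C6"),
                     function(nm) atomXYZ(out$structure, u, nm),
                     numeric(3)))
    nrm <- planeNormalEigen(ring)
    expect_lte(abs(sum((c5m - colMeans(ring)) * nrm)), 0.05)
    expect_lte(abs(angleDeg(c4, c5, c5m) - angleDeg(c6, c5, c5m)), 1)
  }
})

test_that("structures without cytosines pass through unchanged", {
  prot <- parchStructure(data.frame(
    name = "CA", resname = "ALA", chain = "A", seqid = 1:3,
    x = c(0, 4, 8), y = 0, z = 0, element = "C"))
  out <- methylateAllCytosines(prot)
  expect_identical(atoms(out$structure), atoms(prot))
  expect_equal(out$report@nCytosinesFound, 0L)
})

test_that("methylation is idempotent", {
  s <- toyNucSmall()
  once <- methylateAllCytosines(s)$structure
  twice <- methylateAllCytosines(once)
  expect_equal(twice$report@nCytosinesFound, 0L)
  expect_identical(atoms(twice$structure)[, c("name", "x", "y", "z")],
                   atoms(once)[, c("name", "x", "y", "z")])
})

test_that("cytosines missing ring atoms are skipped with a reason", {
  s <- toyNucSmall()
  a <- atoms(s)
  uids <- paste(a$chain, a$seqid, a$icode, sep = ":")
  firstDC <- residues(s)$uid[residues(s)$resname == "DC"][1]
  a <- a[!(uids == firstDC & a$name == "C5"), ]
  broken <- parchStructure(a[, c("name", "resname", "chain", "seqid",
                                 "x", "y", "z", "element")])
  out <- methylateAllCytosines(broken)
  expect_equal(nrow(out$report@skipped), 1)
  expect_match(out$report@skipped$reason, "C5")
  expect_equal(out$report@nMethylated + 1L, out$report@nCytosinesFound)
})

test_that("the methylated structure re-parses and partitions C5M into NB", {
  s <- buildToyNucleosome(nBp = 4)
  out <- methylateAllCytosines(s)
  rt <- parsePDB(writePDB(out$structure))
  expect_equal(nAtoms(rt), nAtoms(out$structure))
  a <- atoms(rt, heavyOnly = TRUE)
  uid <- paste(a$chain, a$seqid, a$icode, sep = ":")
  r <- residues(rt)
  for (u in r$uid[r$resname == "5CM"]) {
    p <- partitionDNAAtoms(a[uid == u, ])
    expect_true("C5M" %in% p$nb$name)
    expect_false("C5M" %in% p$bb$name)
  }
})
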