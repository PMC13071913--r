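# Structure model: residue kinds, DNA partitioning, COG, PDB round trips.

test_that("residue kind is a pure function of the packaged name table", {
  tab <- knownResidueNames()
  expect_identical(residueKind(tab$resname), tab$kind)
  expect_identical(residueKind(c("HOH", "dc", "XYZ", "MG")),
                   c("WATER", "DNA", "OTHER", "ION"))
})

test_that("parsePDB assigns kinds from residue names", {
  s <- parsePDB(c(
    "HETATM    1  O   HOH A   1      10.000  10.000  10.000  1.00  0.00           O",
    "END"))
  expect_equal(nResidues(s), 1L)
  expect_equal(residues(s)$kind, "WATER")

  s2 <- parsePDB(c(
    "ATOM      1  P    DC B   5       1.000   2.000   3.000  1.00  0.00           P",
    "ATOM      2  C1'  DC B   5       2.400   2.000   3.000  1.00  0.00           C",
    "END"))
  expect_equal(residues(s2)$kind, "DNA")
})

test_that("malformed coordinates and empty input raise parse errors", {
  expect_error(parsePDB("REMARK nothing here"), "no ATOM/HETATM")
  bad <- c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.0x0   2.000   3.000  1.00  0.00           C")
  expect_error(parsePDB(bad), "line 2")
})

test_that("alternate locations keep the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       0.000   1.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       9.000   1.000   0.000  0.50  0.00           C",
    "END")
  s <- parsePDB(lines)
  a <- atoms(s)
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$name == "CA"], 5.0)   # occupancy 0.6 wins
  expect_equal(a$x[a$name == "CB"], 0.0)   # tie broken by alt-loc order
})

test_that("multi-model files keep the first model with a warning", {
  lines <- c(
    "MODEL     1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL     2",
    "ATOM      1  CA  ALA A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END")
  expect_warning(s <- parsePDB(lines), "first model")
  expect_equal(atoms(s)$x, 0.0)
})

test_that("parse/write round-trips preserve identity and coordinates", {
  s <- toyNucSmall()
  s2 <- parsePDB(writePDB(s))
  expect_equal(nAtoms(s2), nAtoms(s))
  a <- atoms(s)
  a2 <- atoms(s2)
  expect_identical(a2$name, a$name)
  expect_identical(a2$resname, a$resname)
  expect_identical(a2$chain, a$chain)
  expect_identical(a2$seqid, a$seqid)
  # PDB coordinate fields carry 3 decimals
  expect_lt(max(abs(a2$x - a$x), abs(a2$y - a$y), abs(a2$z - a$z)), 5e-4 + 1e-9)
})

test_that("dC partitions into the dictionary backbone and base sets", {
  bbFull <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
              "C2'", "C1'")
  nbDC <- c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6")
  res <- data.frame(name = c(bbFull, nbDC), resname = "DC", chain = "B",
                    seqid = 1, icode = "", element = substr(c(bbFull, nbDC), 1, 1),
                    kind = "DNA", x = 0, y = 0, z = 0)
  p <- partitionDNAAtoms(res)
  expect_setequal(p$bb$name, bbFull)
  expect_setequal(p$nb$name, nbDC)

  # 5'-terminal residue without the phosphate: subset rule, no error
  term <- res[!res$name %in% c("P", "OP1", "OP2"), ]
  pt <- partitionDNAAtoms(term)
  expect_setequal(pt$bb$name, setdiff(bbFull, c("P", "OP1", "OP2")))

  # 5-methylcytosine: the methyl carbon is part of the base
  m <- res
  m$resname <- "5CM"
  m <- rbind(m, within(m[1, ], name <- "C5M"))
  expect_true("C5M" %in% partitionDNAAtoms(m)$nb$name)

  # unknown atom names are named in the error; non-DNA is a domain error
  bad <- rbind(res, within(res[1, ], name <- "XX9"))
  expect_error(partitionDNAAtoms(bad), "XX9")
  prot <- within(res, {resname <- "ALA"; kind <- "PROTEIN"})
  expect_error(partitionDNAAtoms(prot), "DNA")
})

test_that("every toy DNA residue partitions all heavy atoms exactly once", {
  s <- toyNucSmall()
  a <- atoms(s, heavyOnly = TRUE)
  uid <- paste(a$chain, a$seqid, a$icode, sep = ":")
  r <- residues(s)
  for (u in r$uid[r$kind == "DNA"]) {
    ra <- a[uid == u, ]
    p <- partitionDNAAtoms(ra)
    expect_equal(nrow(p$bb) + nrow(p$nb), nrow(ra))
    expect_length(intersect(p$bb$name, p$nb$name), 0)
  }
})

test_that("center of geometry equals the brute-force coordinate mean", {
  expect_equal(centerOfGeometry(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  expect_equal(centerOfGeometry(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  set.seed(42)
  m <- matrix(runif(30, -50, 50), 10, 3)
  expect_equal(unname(centerOfGeometry(m)), unname(bruteCOG(m)))
  expect_error(centerOfGeometry(matrix(numeric(0), 0, 3)), "empty")
})

test_that("the annotated PDB dialect carries per-moiety values and round-trips", {
  # protein-only toy, all PV zero
  prot <- parchStructure(data.frame(
    name = "CA", resname = "ALA", chain = "A", seqid = 1:3,
    x = c(0, 4, 8), y = 0, z = 0, element = "C"))
  pv0 <- pvTable(data.frame(chain = "A", seqid = 1:3, moiety = "PROT",
                            pv = 0))
  txt <- writeParchPDB(prot, pv0)
  atomLines <- grep("^ATOM", txt, value = TRUE)
  expect_true(all(substr(atomLines, 67, 72) == "  0.00"))

  # a dC with distinct BB/NB values lands them on the right atom lines
  bbFull <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
              "C2'", "C1'")
  nbDC <- c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6")
  dc <- parchStructure(data.frame(
    name = c(bbFull, nbDC), resname = "DC", chain = "B", seqid = 7,
    x = seq_len(19) * 2, y = 0, z = 0,
    element = substr(c(bbFull, nbDC), 1, 1)))
  pv <- pvTable(data.frame(chain = "B", seqid = 7, resname = "DC",
                           moiety = c("BB", "NB"), pv = c(5.0, 0.4)))
  lines <- grep("^ATOM", writeParchPDB(dc, pv), value = TRUE)
  vals <- as.numeric(substr(lines, 67, 72))
  isBB <- trimws(substr(lines, 13, 16)) %in% bbFull
  expect_true(all(vals[isBB] == 5.00))
  expect_true(all(vals[!isBB] == 0.40))

  # reading the annotated file recovers the table at field precision
  rt <- readParchPDB(writeParchPDB(dc, pv))
  expect_equal(pvData(rt$pv)[, c("moiety", "pv")],
               pvData(pv)[, c("moiety", "pv")])

  # missing coverage errors with the residue id
  expect_error(writeParchPDB(dc, pv0), "B:7")
})

test_that("PV sidecar TSV round-trips", {
  pv <- pvTable(data.frame(chain = c("A", "B", "B"), seqid = c(1, 7, 7),
                           resname = c("ALA", "DC", "DC"),
                           moiety = c("PROT", "BB", "NB"),
                           pv = c(2.25, 5, 0.4)))
  f <- tempfile(fileext = ".tsv")
  writePVTable(pv, f, header = "unit test")
  expect_equal(pvData(readPVTable(f)), pvData(pv))
})
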