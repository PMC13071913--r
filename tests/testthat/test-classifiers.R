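# Spatial classifiers: proximal/distal, contacts, inner/outer, named sets.

mkPair <- function(dx) {
  # one protein CA at origin-ish, one DNA pseudo-residue dx away
  parchStructure(data.frame(
    name = c("CA", "C1'"), resname = c("ALA", "DC"),
    chain = c("A", "B"), seqid = 1, x = c(0, dx), y = 0, z = 0,
    element = "C"))
}

test_that("proximal/distal follows the inclusive 3-Angstrom criterion", {
  expect_equal(unname(classLabels(classifyProximalDistal(mkPair(2.5)))),
               "PROXIMAL")
  expect_equal(unname(classLabels(classifyProximalDistal(mkPair(3.5)))),
               "DISTAL")
  expect_equal(unname(classLabels(classifyProximalDistal(mkPair(3.0)))),
               "PROXIMAL")  # boundary counts as within
  dnaOnly <- parchStructure(data.frame(
    name = "C1'", resname = "DC", chain = "B", seqid = 1,
    x = 0, y = 0, z = 0, element = "C"))
  expect_error(classifyProximalDistal(dnaOnly), "protein")
})

test_that("contact residues use inclusive COG-to-COG distance", {
  expect_equal(unname(classLabels(contactResidues(mkPair(7.9)))), "CONTACT")
  expect_equal(unname(classLabels(contactResidues(mkPair(8.0)))), "CONTACT")
  expect_equal(unname(classLabels(contactResidues(mkPair(20)))),
               "NONCONTACT")
})

test_that("classifiers agree with brute-force oracles on random structures", {
  for (seed in 1:40) {
    s <- randomToyStructure(seed)
    expect_identical(classLabels(classifyProximalDistal(s, 4)),
                     bruteProximalDistal(s, 4))
    cr <- as.data.frame(contactResidues(s, 6))
    got <- sort(paste(cr$chain, cr$seqid, cr$icode, sep = ":")[
      cr$label == "CONTACT"])
    expect_identical(got, sort(bruteContacts(s, 6)))
  }
})

test_that("inner/outer matches the cross-unit oracle and is symmetric", {
  for (seed in 1:40) {
    s <- randomToyStructure(seed, units = TRUE)
    u <- unitLabels(s)
    if (length(unique(u)) != 2) next
    got <- classLabels(classifyInnerOuter(s, 6))
    expect_identical(got, bruteInnerOuter(s, 6))
    # swapping unit labels changes nothing
    a <- atoms(s)
    a$unit <- 3L - a$unit
    expect_identical(classLabels(classifyInnerOuter(parchStructure(a), 6)),
                     got)
  }
})

test_that("inner/outer handles separated and touching units, rejects bad labels", {
  mkUnits <- function(gap) parchStructure(data.frame(
    name = "CA", resname = "ALA", chain = c("A", "B"), seqid = 1,
    x = c(0, gap), y = 0, z = 0, element = "C", unit = c(1L, 2L)))
  expect_true(all(classLabels(classifyInnerOuter(mkUnits(30), 20)) ==
                    "OUTER"))
  expect_true(all(classLabels(classifyInnerOuter(mkUnits(19), 20)) ==
                    "INNER"))
  oneUnit <- parchStructure(data.frame(
    name = "CA", resname = "ALA", chain = "A", seqid = 1:2,
    x = c(0, 5), y = 0, z = 0, element = "C", unit = 1L))
  expect_error(classifyInnerOuter(oneUnit), "two")
})

test_that("labels partition the queried set and grow monotonically with cutoff", {
  s <- toyNucSmall()
  for (cutoff in c(2, 3, 5, 8)) {
    cls <- as.data.frame(classifyProximalDistal(s, cutoff))
    expect_equal(nrow(cls), sum(residues(s)$kind == "DNA"))
    expect_true(all(cls$label %in% c("PROXIMAL", "DISTAL")))
  }
  proxAt <- function(cutoff) {
    d <- as.data.frame(classifyProximalDistal(s, cutoff))
    sum(d$label == "PROXIMAL")
  }
  expect_true(all(diff(sapply(c(2, 3, 5, 8, 15), proxAt)) >= 0))
})

test_that("the toy octamer exposes the full acidic patch on both faces", {
  ap <- selectAcidicPatch(toyNuc(), toyChainMap())
  expect_equal(nrow(ap), 16)            # (6 H2A + 2 H2B) x two copies
  expect_true(all(ap$found))
  expect_false(any(ap$mismatch))
})

test_that("named-set selection flags mismatches and missing residues", {
  s <- toyNuc()
  # in the full-size toy every chain carries an ARG anchor at seqid 30
  spec <- residueSpec("H3", "R", 30)
  hit <- selectResidueSet(s, spec, toyChainMap())
  expect_equal(nrow(hit), 2)            # two H3 copies
  expect_false(any(hit$mismatch))
  # expecting lysine at an arginine position flags, never drops
  mis <- selectResidueSet(s, residueSpec("H3", "K", 30), toyChainMap())
  expect_equal(nrow(mis), 2)
  expect_true(all(mis$mismatch))
  # a position outside the chain warns and reports found = FALSE
  expect_warning(expect_warning(  # one warning per H4 copy
    far <- selectResidueSet(s, residueSpec("H4", "A", 9999), toyChainMap()),
    "no residue"), "no residue")
  expect_false(any(far$found))
  expect_error(selectResidueSet(s, spec, list(H2A = "C")), "chainMap")
  expect_error(selectResidueSet(s, spec[0, ], toyChainMap()), "empty")
})
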