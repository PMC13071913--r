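# Shared fixtures (built in code, cached per run) and independent
# brute-force oracles used to validate the vectorized implementations.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

toyNuc <- function() cached("nuc", function() buildToyNucleosome())
toyNucSmall <- function() cached("nucSmall",
                                 function() buildToyNucleosome(nBp = 12))
toyDinuc <- function() cached("dinuc", function() buildToyDinucleosome())

# --- independent oracles (plain double loops, no package internals) ----

bruteDist <- function(p, q) sqrt(sum((p - q)^2))

bruteMinDist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      best <- min(best, bruteDist(A[i, ], B[j, ]))
  best
}

bruteCOG <- function(A) {
  s <- c(0, 0, 0)
  for (i in seq_len(nrow(A))) s <- s + A[i, ]
  s / nrow(A)
}

bruteShellCount <- function(waters, group, r) {
  n <- 0L
  for (i in seq_len(nrow(waters))) {
    inside <- FALSE
    for (j in seq_len(nrow(group)))
      if (bruteDist(waters[i, ], group[j, ]) <= r) inside <- TRUE
    n <- n + inside
  }
  n
}

coordsOfResidue <- function(structure, uid) {
  a <- atoms(structure, heavyOnly = TRUE)
  u <- paste(a$chain, a$seqid, a$icode, sep = ":")
  as.matrix(a[u == uid, c("x", "y", "z")])
}

bruteProximalDistal <- function(structure, cutoff) {
  a <- atoms(structure, heavyOnly = TRUE)
  prot <- as.matrix(a[a$kind == "PROTEIN", c("x", "y", "z")])
  r <- residues(structure)
  r <- r[r$kind == "DNA", ]
  out <- character(nrow(r))
  for (i in seq_len(nrow(r))) {
    d <- bruteMinDist(coordsOfResidue(structure, r$uid[i]), prot)
    out[i] <- if (d <= cutoff) "PROXIMAL" else "DISTAL"
  }
  names(out) <- r$uid
  out
}

bruteContacts <- function(structure, cutoff) {
  r <- residues(structure)
  prot <- r[r$kind == "PROTEIN", ]
  dna <- r[r$kind == "DNA", ]
  dnaCOG <- lapply(dna$uid,
                   function(u) bruteCOG(coordsOfResidue(structure, u)))
  out <- character(0)
  for (i in seq_len(nrow(prot))) {
    cog <- bruteCOG(coordsOfResidue(structure, prot$uid[i]))
    hit <- FALSE
    for (dc in dnaCOG) if (bruteDist(cog, dc) <= cutoff) hit <- TRUE
    if (hit) out <- c(out, prot$uid[i])
  }
  out
}

bruteInnerOuter <- function(structure, cutoff) {
  a <- atoms(structure, heavyOnly = TRUE)
  a <- a[a$kind %in% c("PROTEIN", "DNA"), ]
  r <- residues(structure)
  r <- r[r$kind %in% c("PROTEIN", "DNA"), ]
  out <- character(nrow(r))
  for (i in seq_len(nrow(r))) {
    own <- coordsOfResidue(structure, r$uid[i])
    oth <- as.matrix(a[a$unit != r$unit[i], c("x", "y", "z")])
    d <- bruteMinDist(own, oth)
    out[i] <- if (d <= cutoff) "INNER" else "OUTER"
  }
  names(out) <- r$uid
  out
}

# random small structure for oracle-equivalence sweeps: a handful of
# protein/DNA pseudo-residues with uniform random coordinates (residue
# kinds come from names; atom names are irrelevant to the classifiers)
randomToyStructure <- function(seed, nProt = 4, nDNA = 4, atomsPer = 3,
                               spread = 12, units = FALSE) {
  set.seed(seed)
  mk <- function(kindNames, chain, n) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(name = paste0("X", seq_len(atomsPer)),
                 resname = sample(kindNames, 1), chain = chain, seqid = i,
                 x = runif(atomsPer, 0, spread),
                 y = runif(atomsPer, 0, spread),
                 z = runif(atomsPer, 0, spread),
                 element = "C", stringsAsFactors = FALSE)
    }))
  }
  at <- rbind(mk(c("ALA", "GLY", "ARG"), "A", nProt),
              mk(c("DA", "DC", "DG", "DT"), "B", nDNA))
  if (units) {
    nRes <- nrow(at) %/% atomsPer
    u <- sample(1:2, nRes, TRUE)
    u[1:2] <- 1:2  # guarantee both units occur
    at$unit <- u[rep(seq_len(nRes), each = atomsPer)]
  }
  parchStructure(at, title = "random toy")
}

# planted dinucleosome PV table: values drawn from the inner/outer presets
# according to each residue's actual label (NB gets a milder shift, PROT
# none)
plantedDinucPV <- function(structure, labels, seed = 1) {
  set.seed(seed)
  r <- residues(structure)
  r <- r[r$kind %in% c("PROTEIN", "DNA"), ]
  rows <- list()
  for (i in seq_len(nrow(r))) {
    inner <- labels[[r$uid[i]]] == "INNER"
    if (r$kind[i] == "PROTEIN") {
      moi <- "PROT"
      pv <- max(rnorm(1, 4.0, 1.0), 0)
    } else {
      moi <- c("BB", "NB")
      pv <- c(max(rnorm(1, if (inner) 3.5 else 5.0, 1.2), 0),
              max(rnorm(1, if (inner) 0.32 else 0.38, 0.05), 0))
    }
    rows[[i]] <- data.frame(chain = r$chain[i], seqid = r$seqid[i],
                            icode = r$icode[i], resname = r$resname[i],
                            moiety = moi, pv = pv,
                            stringsAsFactors = FALSE)
  }
  pvTable(do.call(rbind, rows))
}
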