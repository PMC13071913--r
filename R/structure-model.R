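# Residue-name tables and the atom-level structure model.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL", "HSD", "HSE", "HSP")

# DC-style two-letter deoxy names plus recognized modified nucleotides.
# "FMC" is an input alias for 5-methyl-2'-deoxycytidine (standard id 5CM).
.DNA_NAMES <- c("DA", "DC", "DG", "DT", "DI", "5CM", "FMC")
.DNA_LEGACY <- c("A" = "DA", "C" = "DC", "G" = "DG", "T" = "DT")

.WATER_NAMES <- c("HOH", "WAT", "SOL", "TIP3", "TIP", "SPC", "TP3")
.ION_NAMES <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "BR", "IOD",
                "CS", "LI", "RB", "SR", "CD", "NI", "CU")

#' Residue kind from residue name
#'
#' Pure table-driven lookup: standard amino-acid three-letter codes map to
#' `PROTEIN`; `DA/DC/DG/DT` (plus legacy one-letter deoxy names and the
#' recognized modified nucleotides `DI`, `5CM`, with `FMC` accepted as an
#' alias for `5CM`) map to `DNA`; `HOH`/`WAT`/`SOL` and friends to `WATER`;
#' monoatomic ion component ids to `ION`; everything else to `OTHER`.
#'
#' @param resname character vector of residue names.
#' @return character vector of kinds (`PROTEIN`, `DNA`, `WATER`, `ION`,
#'   `OTHER`).
#' @export
residueKind <- function(resname) {
  rn <- toupper(trimws(resname))
  out <- rep("OTHER", length(rn))
  out[rn %in% .AA3] <- "PROTEIN"
  out[rn %in% .DNA_NAMES | rn %in% names(.DNA_LEGACY)] <- "DNA"
  out[rn %in% .WATER_NAMES] <- "WATER"
  out[rn %in% .ION_NAMES] <- "ION"
  out
}

#' Table of residue names the package recognizes
#'
#' @return data.frame with columns `resname` and `kind`, one row per entry
#'   of the packaged lookup tables (exhaustively testable).
#' @export
knownResidueNames <- function() {
  data.frame(
    resname = c(.AA3, .DNA_NAMES, names(.DNA_LEGACY), .WATER_NAMES,
                .ION_NAMES),
    kind = c(rep("PROTEIN", length(.AA3)),
             rep("DNA", length(.DNA_NAMES) + length(.DNA_LEGACY)),
             rep("WATER", length(.WATER_NAMES)),
             rep("ION", length(.ION_NAMES))),
    stringsAsFactors = FALSE)
}

# Heavy-atom partition templates, frozen against the chemical component
# dictionary. Sugar atoms (including the glycosidic C1') belong to the
# sugar-phosphate backbone; NB is the base ring plus exocyclic substituents.
.BB_ATOMS <- c("P", "OP1", "OP2", "OP3", "O5'", "C5'", "C4'", "O4'",
               "C3'", "O3'", "C2'", "C1'")

.NB_ATOMS <- list(
  DA = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  DG = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  DC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  DT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
  DI = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N3", "C4"))
# 5-methylcytosine: cytosine base + ring-attached methyl carbon. The
# dictionary names the methyl C5A; structures methylated by this package
# name it C5M. Both are accepted.
.NB_ATOMS[["5CM"]] <- c(.NB_ATOMS$DC, "C5A", "C5M")
.NB_ATOMS[["FMC"]] <- .NB_ATOMS[["5CM"]]

# map legacy one-letter names onto the template key
.templateKey <- function(resname) {
  rn <- toupper(trimws(resname))
  if (rn %in% names(.DNA_LEGACY)) rn <- .DNA_LEGACY[[rn]]
  rn
}

.normAtomName <- function(name) {
  # legacy PDB uses * for primes and O1P/O2P for OP1/OP2
  nm <- gsub("\\*", "'", trimws(name))
  nm[nm == "O1P"] <- "OP1"
  nm[nm == "O2P"] <- "OP2"
  nm[nm == "O3P"] <- "OP3"
  nm
}

.isHydrogen <- function(element, name) {
  el <- toupper(trimws(element))
  ifelse(nzchar(el), el %in% c("H", "D"),
         grepl("^[0-9]*[HD]", trimws(name)))
}

.residueUID <- function(chain, seqid, icode) {
  paste(chain, seqid, icode, sep = ":")
}

#' Construct a ParchStructure from an atom table
#'
#' @param atoms data.frame with at least name, resname, chain, seqid, x, y,
#'   z; missing bookkeeping columns (serial, altLoc, icode, occupancy,
#'   bfactor, element, unit) are filled with defaults. Residue kind is
#'   (re)derived from `resname` via [residueKind()].
#' @param title character(1).
#' @return a [ParchStructure-class].
#' @export
parchStructure <- function(atoms, title = "") {
  n <- nrow(atoms)
  defaults <- list(serial = seq_len(n), altLoc = "", icode = "",
                   occupancy = 1, bfactor = 0, element = "",
                   unit = NA_integer_)
  for (col in names(defaults))
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  atoms$name <- .normAtomName(atoms$name)
  atoms$kind <- residueKind(atoms$resname)
  atoms$seqid <- as.integer(atoms$seqid)
  atoms$unit <- as.integer(atoms$unit)
  rownames(atoms) <- NULL
  new("ParchStructure", atoms = atoms[, .ATOM_COLS], title = title)
}

#' @rdname accessors
#' @param heavyOnly logical; drop hydrogens/deuteriums.
#' @export
setMethod("atoms", "ParchStructure", function(x, heavyOnly = FALSE) {
  a <- x@atoms
  if (heavyOnly) a <- a[!.isHydrogen(a$element, a$name), , drop = FALSE]
  a
})

#' @rdname accessors
#' @export
setMethod("residues", "ParchStructure", function(x) {
  a <- x@atoms
  uid <- .residueUID(a$chain, a$seqid, a$icode)
  first <- !duplicated(uid)
  data.frame(chain = a$chain[first], seqid = a$seqid[first],
             icode = a$icode[first], resname = a$resname[first],
             kind = a$kind[first], unit = a$unit[first],
             uid = uid[first], stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("nAtoms", "ParchStructure", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setMethod("nResidues", "ParchStructure", function(x) nrow(residues(x)))

#' @rdname accessors
#' @export
setMethod("unitLabels", "ParchStructure", function(x) {
  r <- residues(x)
  stats::setNames(r$unit, r$uid)
})

setMethod("show", "ParchStructure", function(object) {
  r <- residues(object)
  cat("ParchStructure:", object@title, "\n")
  cat(" ", nrow(object@atoms), "atoms,", nrow(r), "residues\n")
  print(table(factor(r$kind, levels = .KINDS)))
  if (any(!is.na(r$unit)))
    cat("  nucleosome units:", paste(sort(unique(stats::na.omit(r$unit))),
                                     collapse = ", "), "\n")
})

#' Center of geometry of an atom set
#'
#' Unweighted mean of the atom coordinates, as used for the 8-Angstrom
#' COG-to-COG histone-DNA contact criterion.
#'
#' @param coords numeric matrix (n x 3) or data.frame with x, y, z columns.
#' @return numeric(3).
#' @export
centerOfGeometry <- function(coords) {
  m <- .coordMatrix(coords)
  if (nrow(m) == 0L) stop("center of geometry of an empty atom set")
  colMeans(m)
}

.coordMatrix <- function(coords) {
  if (is.data.frame(coords)) {
    as.matrix(coords[, c("x", "y", "z")])
  } else {
    m <- as.matrix(coords)
    if (ncol(m) != 3L) stop("coordinates must be n x 3")
    m
  }
}

#' Partition a DNA residue's atoms into backbone and nucleobase sets
#'
#' Splits the heavy atoms of one DNA residue into the sugar-phosphate
#' backbone (`bb`) and nucleobase (`nb`) groups that receive separate
#' PARCH values. Sugar atoms, including the glycosidic C1', are backbone.
#' Atoms of the residue template that are absent (e.g. the 5'-terminal
#' phosphate) are silently skipped; atoms absent from the template raise
#' an error naming them. Hydrogens are excluded unless `includeHydrogens`.
#'
#' @param residueAtoms data.frame of one residue's atom rows (as from
#'   [atoms()]).
#' @param includeHydrogens logical; if TRUE hydrogens are assigned to the
#'   moiety of the template (hydrogen names are not in the templates, so
#'   this is only meaningful for heavy-atom-complete inputs).
#' @return list with data.frame components `bb` and `nb`.
#' @export
partitionDNAAtoms <- function(residueAtoms, includeHydrogens = FALSE) {
  if (nrow(residueAtoms) == 0L) stop("empty residue")
  kind <- unique(residueAtoms$kind)
  if (!identical(kind, "DNA"))
    stop("partitionDNAAtoms requires a DNA residue, got kind ",
         paste(kind, collapse = "/"))
  key <- .templateKey(residueAtoms$resname[1])
  nbTemplate <- .NB_ATOMS[[key]]
  if (is.null(nbTemplate))
    stop("no partition template for DNA residue name ", key)
  a <- residueAtoms
  if (!includeHydrogens)
    a <- a[!.isHydrogen(a$element, a$name), , drop = FALSE]
  nm <- .normAtomName(a$name)
  isBB <- nm %in% .BB_ATOMS
  isNB <- nm %in% nbTemplate
  unknown <- nm[!isBB & !isNB]
  if (length(unknown))
    stop("atom name(s) not in the ", key, " partition template: ",
         paste(unique(unknown), collapse = ", "))
  list(bb = a[isBB, , drop = FALSE], nb = a[isNB, , drop = FALSE])
}

#' Per-residue moiety groups of a structure
#'
#' Expands a structure into the residue/moiety atom groups that PARCH
#' scores: one `PROT` group per protein residue (heavy atoms), one `BB`
#' and one `NB` group per DNA residue. Waters and ions yield no groups.
#'
#' @param structure a [ParchStructure-class].
#' @return named list of coordinate matrices; names are
#'   `chain:seqid:icode:moiety`.
#' @export
moietyGroups <- function(structure) {
  a <- atoms(structure, heavyOnly = TRUE)
  a <- a[a$kind %in% c("PROTEIN", "DNA"), , drop = FALSE]
  if (nrow(a) == 0L) return(list())
  uid <- .residueUID(a$chain, a$seqid, a$icode)
  out <- list()
  for (u in unique(uid)) {
    ra <- a[uid == u, , drop = FALSE]
    if (ra$kind[1] == "PROTEIN") {
      out[[paste(u, "PROT", sep = ":")]] <- .coordMatrix(ra)
    } else {
      p <- partitionDNAAtoms(ra)
      out[[paste(u, "BB", sep = ":")]] <- .coordMatrix(p$bb)
      out[[paste(u, "NB", sep = ":")]] <- .coordMatrix(p$nb)
    }
  }
  out
}

# minimum cross squared-distance helpers --------------------------------

.cross2 <- function(a, b) {
  # squared distance matrix, nrow(a) x nrow(b)
  outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
}

.minCrossDist <- function(a, b, chunk = 512L) {
  # minimum Euclidean distance between two coordinate sets
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  best <- Inf
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(a))
    best <- min(best, min(.cross2(a[idx, , drop = FALSE], b)))
  }
  sqrt(max(best, 0))
}

.minDistPerRow <- function(a, b, chunk = 512L) {
  # for each row of a, its minimum distance to b
  out <- numeric(nrow(a))
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(a))
    d2 <- .cross2(a[idx, , drop = FALSE], b)
    out[idx] <- apply(d2, 1L, min)
  }
  sqrt(pmax(out, 0))
}
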