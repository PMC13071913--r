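# Spatial classification at the histone-DNA interface.
#
# Conventions used throughout: heavy atoms only; "within X Angstrom" is
# inclusive (distance == cutoff counts as within); waters and ions are
# never classified.

#' @rdname accessors
#' @export
setMethod("classLabels", "ClassificationResult", function(x) {
  stats::setNames(x@data$label,
                  .residueUID(x@data$chain, x@data$seqid, x@data$icode))
})

#' Classification result as a data frame
#'
#' @param x a [ClassificationResult-class].
#' @param ... ignored.
#' @return data.frame with residue id columns, `label` and `distance`.
#' @export
setMethod("as.data.frame", "ClassificationResult",
          function(x, ...) x@data)

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult (%s, cutoff %g A):\n",
              object@criterion, object@cutoff))
  print(table(object@data$label))
})

.classResult <- function(r, label, distance, cutoff, criterion) {
  new("ClassificationResult",
      data = data.frame(chain = r$chain, seqid = r$seqid, icode = r$icode,
                        resname = r$resname, label = label,
                        distance = distance, stringsAsFactors = FALSE),
      cutoff = cutoff, criterion = criterion)
}

#' Classify DNA residues as proximal or distal to the histone core
#'
#' A DNA residue is `PROXIMAL` when the minimum distance between its heavy
#' atoms and any protein heavy atom is at most `cutoff` (default 3
#' Angstrom), otherwise `DISTAL`.
#'
#' @param structure a [ParchStructure-class] with at least one DNA and one
#'   protein residue.
#' @param cutoff Angstrom.
#' @return a [ClassificationResult-class] over the DNA residues; the
#'   `distance` column holds each residue's minimum atom distance to
#'   protein.
#' @export
classifyProximalDistal <- function(structure, cutoff = 3.0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- atoms(structure, heavyOnly = TRUE)
  prot <- .coordMatrix(a[a$kind == "PROTEIN", , drop = FALSE])
  if (nrow(prot) == 0L) stop("structure has no protein atoms")
  dna <- a[a$kind == "DNA", , drop = FALSE]
  if (nrow(dna) == 0L) stop("structure has no DNA residues")
  uid <- .residueUID(dna$chain, dna$seqid, dna$icode)
  r <- residues(structure)
  r <- r[r$kind == "DNA", , drop = FALSE]
  dmin <- vapply(r$uid, function(u) {
    .minCrossDist(.coordMatrix(dna[uid == u, , drop = FALSE]), prot)
  }, numeric(1))
  .classResult(r, ifelse(dmin <= cutoff, "PROXIMAL", "DISTAL"),
               unname(dmin), cutoff, "ANY_ATOM")
}

#' Histone residues in contact with DNA
#'
#' A protein residue is a contact when its heavy-atom center of geometry
#' lies within `cutoff` (default 8 Angstrom) of the center of geometry of
#' any DNA residue.
#'
#' @inheritParams classifyProximalDistal
#' @return a [ClassificationResult-class] over the protein residues with
#'   labels `CONTACT`/`NONCONTACT`; `distance` is the minimum COG-COG
#'   distance to DNA.
#' @export
contactResidues <- function(structure, cutoff = 8.0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- atoms(structure, heavyOnly = TRUE)
  if (!any(a$kind == "PROTEIN")) stop("structure has no protein atoms")
  if (!any(a$kind == "DNA")) stop("structure has no DNA residues")
  uid <- .residueUID(a$chain, a$seqid, a$icode)
  cogOf <- function(kind) {
    sel <- a$kind == kind
    t(vapply(unique(uid[sel]), function(u) {
      centerOfGeometry(a[sel & uid == u, , drop = FALSE])
    }, numeric(3)))
  }
  protCOG <- cogOf("PROTEIN")
  dnaCOG <- cogOf("DNA")
  dmin <- .minDistPerRow(protCOG, dnaCOG)
  r <- residues(structure)
  r <- r[r$kind == "PROTEIN", , drop = FALSE]
  stopifnot(identical(r$uid, rownames(protCOG)))
  .classResult(r, ifelse(dmin <= cutoff, "CONTACT", "NONCONTACT"),
               dmin, cutoff, "COG")
}

#' Classify dinucleosome residues as inner or outer
#'
#' For a structure whose residues carry exactly two nucleosome unit
#' labels, a (protein or DNA) residue is `INNER` when any of its heavy
#' atoms lies within `cutoff` (default 20 Angstrom) of any protein or DNA
#' heavy atom of the other unit, otherwise `OUTER`. The criterion is
#' symmetric across units.
#'
#' @param structure a [ParchStructure-class] with `unit` labels covering
#'   all protein/DNA residues.
#' @param cutoff Angstrom.
#' @return a [ClassificationResult-class] over protein and DNA residues;
#'   `distance` is the minimum heavy-atom distance to the other unit.
#' @export
classifyInnerOuter <- function(structure, cutoff = 20.0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- atoms(structure, heavyOnly = TRUE)
  a <- a[a$kind %in% c("PROTEIN", "DNA"), , drop = FALSE]
  units <- sort(unique(a$unit[!is.na(a$unit)]))
  if (length(units) != 2L || anyNA(a$unit))
    stop("inner/outer classification requires exactly two fully labelled ",
         "nucleosome units (found ",
         paste(units, collapse = ", "),
         if (anyNA(a$unit)) "; some residues unlabelled", ")")
  coordsOf <- function(u) .coordMatrix(a[a$unit == u, , drop = FALSE])
  other <- list(coordsOf(units[2]), coordsOf(units[1]))
  uid <- .residueUID(a$chain, a$seqid, a$icode)
  r <- residues(structure)
  r <- r[r$kind %in% c("PROTEIN", "DNA"), , drop = FALSE]
  dmin <- vapply(seq_len(nrow(r)), function(i) {
    own <- .coordMatrix(a[uid == r$uid[i], , drop = FALSE])
    .minCrossDist(own, other[[match(r$unit[i], units)]])
  }, numeric(1))
  .classResult(r, ifelse(dmin <= cutoff, "INNER", "OUTER"),
               dmin, cutoff, "ANY_ATOM")
}

#' Residue-set specification
#'
#' @param histone one of "H2A", "H2B", "H3", "H4".
#' @param aa expected one-letter amino-acid code.
#' @param seqid residue number.
#' @return data.frame row usable in [selectResidueSet()] spec lists.
#' @export
residueSpec <- function(histone, aa, seqid) {
  stopifnot(histone %in% c("H2A", "H2B", "H3", "H4"),
            aa %in% names(.AA1TO3))
  data.frame(histone = histone, aa = aa, seqid = as.integer(seqid),
             stringsAsFactors = FALSE)
}

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Select a named residue set on histone chains
#'
#' Generic selector behind the acidic-patch and arginine-anchor sets.
#' Every chain mapped to the spec's histone type is searched; a residue
#' present but of a different amino-acid type than specified is returned
#' with `mismatch = TRUE` (never silently dropped), and specs with no
#' matching residue on a chain produce a warning and a row with `found =
#' FALSE`.
#'
#' @param structure a [ParchStructure-class].
#' @param specs data.frame with columns histone, aa, seqid (rbind of
#'   [residueSpec()] rows).
#' @param chainMap named list mapping histone type to chain id(s), e.g.
#'   `list(H2A = c("C", "G"), H2B = c("D", "H"))`.
#' @return data.frame: histone, chain, seqid, icode, resname, expected,
#'   found, mismatch.
#' @export
selectResidueSet <- function(structure, specs, chainMap) {
  if (is.null(specs) || nrow(specs) == 0L) stop("empty residue-set spec")
  bad <- setdiff(unique(specs$histone), names(chainMap))
  if (length(bad))
    stop("chainMap does not resolve histone type(s): ",
         paste(bad, collapse = ", "))
  r <- residues(structure)
  out <- list()
  for (i in seq_len(nrow(specs))) {
    expected <- .AA1TO3[[specs$aa[i]]]
    for (ch in chainMap[[specs$histone[i]]]) {
      hit <- r[r$chain == ch & r$seqid == specs$seqid[i], , drop = FALSE]
      if (nrow(hit) == 0L) {
        warning("no residue ", specs$seqid[i], " on chain ", ch,
                " (", specs$histone[i], ")")
        out[[length(out) + 1L]] <-
          data.frame(histone = specs$histone[i], chain = ch,
                     seqid = specs$seqid[i], icode = "",
                     resname = NA_character_, expected = expected,
                     found = FALSE, mismatch = NA, stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <-
          data.frame(histone = specs$histone[i], chain = ch,
                     seqid = hit$seqid, icode = hit$icode,
                     resname = hit$resname, expected = expected,
                     found = TRUE, mismatch = hit$resname != expected,
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The nucleosome acidic patch
#'
#' Conserved acidic residues forming the negatively charged H2A/H2B
#' surface patch: H2A E56, E61, E64, D90, E91, E92 and H2B E102, E110, on
#' every H2A/H2B copy resolved by `chainMap`.
#'
#' @inheritParams selectResidueSet
#' @return as [selectResidueSet()].
#' @export
selectAcidicPatch <- function(structure, chainMap) {
  specs <- rbind(residueSpec("H2A", "E", 56), residueSpec("H2A", "E", 61),
                 residueSpec("H2A", "E", 64), residueSpec("H2A", "D", 90),
                 residueSpec("H2A", "E", 91), residueSpec("H2A", "E", 92),
                 residueSpec("H2B", "E", 102), residueSpec("H2B", "E", 110))
  selectResidueSet(structure, specs, chainMap)
}

#' Arginine-anchor configuration
#'
#' The conserved arginine anchors insert into the DNA minor groove at
#' superhelical contact points; their identities vary between structures
#' and are supplied as configuration rather than hard-coded. This helper
#' reads a spec table from a TSV with columns histone, aa, seqid. The
#' packaged default configuration is empty.
#'
#' @param file TSV path.
#' @return data.frame of specs for [selectResidueSet()].
#' @export
readResidueSpecs <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(d)), function(i)
    residueSpec(d$histone[i], d$aa[i], d$seqid[i])))
}

#' Export a classification result as TSV
#'
#' @param x a [ClassificationResult-class].
#' @param file output path.
#' @param header optional comment lines.
#' @return invisibly, the path.
#' @export
writeClassificationTSV <- function(x, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  writeLines(sprintf("# criterion=%s cutoff_A=%g", x@criterion, x@cutoff),
             con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
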