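# Legacy-PDB reading and writing, including the PARCH-annotated dialect.
#
# Parsing is backed by bio3d::read.pdb; a pre-scan supplies line-numbered
# errors for malformed coordinate fields. The annotated dialect appends the
# per-atom PARCH value as a fixed-width field in columns 67-72 (after the
# B-factor field); the canonical machine-readable artifact is the TSV
# sidecar written by writePVTable().

.pdbLines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
}

#' Parse a legacy PDB file or string
#'
#' Reads ATOM/HETATM records into a [ParchStructure-class]. Residue kinds
#' are assigned by name lookup ([residueKind()]). For alternate locations,
#' the highest-occupancy conformer is kept (ties broken by alt-loc
#' character order). Multi-model files are truncated to the first model
#' with a warning.
#'
#' @param x path to a PDB file, or the file content as a character string
#'   (with embedded newlines) or vector of lines.
#' @return a [ParchStructure-class].
#' @export
parsePDB <- function(x) {
  lines <- .pdbLines(x)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(isAtom))
    stop("no ATOM/HETATM records in input")
  # malformed-coordinate pre-scan with line numbers
  for (i in which(isAtom)) {
    fields <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop("malformed coordinate field at line ", i, ": ", lines[i])
  }
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) && any(isAtom & seq_along(lines) > endmdl[1])) {
    warning("multi-model file: keeping first model only")
    lines <- lines[seq_len(endmdl[1])]
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  at <- data.frame(serial = as.integer(a$eleno),
                   name = .normAtomName(a$elety),
                   altLoc = blank(a$alt),
                   resname = toupper(trimws(a$resid)),
                   chain = blank(a$chain),
                   seqid = as.integer(a$resno),
                   icode = blank(a$insert),
                   x = a$x, y = a$y, z = a$z,
                   occupancy = ifelse(is.na(a$o), 1, a$o),
                   bfactor = ifelse(is.na(a$b), 0, a$b),
                   element = blank(a$elesy),
                   stringsAsFactors = FALSE)
  at <- .resolveAltLoc(at)
  title <- paste(trimws(sub("^TITLE\\s{0,4}", "",
                            grep("^TITLE", lines, value = TRUE))),
                 collapse = " ")
  parchStructure(at, title = title)
}

.resolveAltLoc <- function(at) {
  has <- nzchar(at$altLoc)
  if (!any(has)) return(at)
  key <- paste(at$chain, at$seqid, at$icode, at$name)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[has])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    ord <- order(-at$occupancy[idx], at$altLoc[idx])
    keep[idx[-ord[1]]] <- FALSE
  }
  at[keep, , drop = FALSE]
}

.formatAtomName <- function(name) {
  ifelse(nchar(name) >= 4L, substr(name, 1, 4), sprintf(" %-3s", name))
}

.pdbRecords <- function(a, pvField) {
  one <- function(v) substr(paste0(v, " "), 1, 1)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f%s      %2s",
          ifelse(a$kind %in% c("WATER", "ION", "OTHER"), "HETATM", "ATOM"),
          a$serial %% 100000L, .formatAtomName(a$name), one(a$altLoc),
          a$resname, one(a$chain), a$seqid %% 10000L, one(a$icode),
          a$x, a$y, a$z, a$occupancy, a$bfactor, pvField,
          toupper(a$element))
}

.writePDBLines <- function(structure, pvByAtom = NULL) {
  a <- atoms(structure)
  if (nrow(a) == 0L) stop("empty structure")
  pvField <- if (is.null(pvByAtom)) {
    rep(strrep(" ", 6), nrow(a))
  } else {
    ifelse(is.na(pvByAtom), strrep(" ", 6), sprintf("%6.2f", pvByAtom))
  }
  lines <- character(0)
  if (nzchar(structure@title))
    lines <- sprintf("TITLE     %s", structure@title)
  uid <- .residueUID(a$chain, a$seqid, a$icode)
  chainOfRes <- a$chain[!duplicated(uid)]
  lastOfChain <- c(chainOfRes[-1] != chainOfRes[-length(chainOfRes)], TRUE)
  recs <- .pdbRecords(a, pvField)
  # TER after the last polymer residue of each chain
  resIdx <- match(uid, unique(uid))
  kindOfRes <- a$kind[!duplicated(uid)]
  terAfterRes <- which(lastOfChain & kindOfRes %in% c("PROTEIN", "DNA"))
  terAfterAtom <- vapply(terAfterRes,
                         function(r) max(which(resIdx == r)), integer(1))
  out <- character(length(recs) + length(terAfterAtom))
  pos <- seq_along(recs) +
    findInterval(seq_along(recs) - 0.5, terAfterAtom)
  out[pos] <- recs
  out[setdiff(seq_along(out), pos)] <- "TER"
  c(lines, out, "END")
}

#' Write a structure as legacy PDB
#'
#' @param structure a [ParchStructure-class].
#' @param file output path, or NULL to return the text.
#' @return the PDB text, invisibly when written to file.
#' @export
writePDB <- function(structure, file = NULL) {
  txt <- .writePDBLines(structure)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

.pvByAtom <- function(structure, pv) {
  a <- atoms(structure)
  d <- pvData(pv)
  key <- function(chain, seqid, icode, moiety)
    paste(chain, seqid, icode, moiety, sep = ":")
  lookup <- stats::setNames(d$pv, key(d$chain, d$seqid, d$icode, d$moiety))
  out <- rep(NA_real_, nrow(a))
  uid <- .residueUID(a$chain, a$seqid, a$icode)
  missingIds <- character(0)
  for (u in unique(uid)) {
    rows <- which(uid == u)
    kind <- a$kind[rows[1]]
    if (kind == "PROTEIN") {
      v <- lookup[paste(u, "PROT", sep = ":")]
      if (is.na(v)) { missingIds <- c(missingIds, u); next }
      out[rows] <- v
    } else if (kind == "DNA") {
      vb <- lookup[paste(u, "BB", sep = ":")]
      vn <- lookup[paste(u, "NB", sep = ":")]
      if (is.na(vb) || is.na(vn)) { missingIds <- c(missingIds, u); next }
      part <- partitionDNAAtoms(a[rows, , drop = FALSE])
      nm <- .normAtomName(a$name[rows])
      out[rows[nm %in% .normAtomName(part$bb$name)]] <- vb
      out[rows[nm %in% .normAtomName(part$nb$name)]] <- vn
    }
  }
  if (length(missingIds))
    stop("PV table does not cover residue(s): ",
         paste(missingIds, collapse = ", "))
  out
}

#' Write a PARCH-annotated PDB file
#'
#' Each atom line of a protein residue carries that residue's PROT value;
#' each DNA atom line carries the BB or NB value matching its backbone /
#' nucleobase partition, appended as a fixed-width field after the
#' B-factor (columns 67-72). Waters and ions carry a blank field. The PV
#' table must cover every protein and DNA residue.
#'
#' @param structure a [ParchStructure-class].
#' @param pv a [PVTable-class].
#' @param file output path, or NULL to return the text.
#' @return the annotated PDB text, invisibly when written to file.
#' @export
writeParchPDB <- function(structure, pv, file = NULL) {
  txt <- .writePDBLines(structure, pvByAtom = .pvByAtom(structure, pv))
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read a PARCH-annotated PDB file
#'
#' Recovers both the structure and the [PVTable-class] from the annotated
#' dialect written by [writeParchPDB()].
#'
#' @param x path, string or lines (as for [parsePDB()]).
#' @return list with elements `structure` and `pv`.
#' @export
readParchPDB <- function(x) {
  lines <- .pdbLines(x)
  structure <- parsePDB(lines)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  pvField <- suppressWarnings(as.numeric(substr(lines[isAtom], 67, 72)))
  a <- atoms(structure)
  # after alt-loc resolution atom rows are a subset of file records
  serials <- as.integer(substr(lines[isAtom], 7, 11))
  pvAtom <- pvField[match(a$serial, serials)]
  uid <- .residueUID(a$chain, a$seqid, a$icode)
  recs <- list()
  for (u in unique(uid)) {
    rows <- which(uid == u)
    kind <- a$kind[rows[1]]
    base <- a[rows[1], c("chain", "seqid", "icode", "resname")]
    if (kind == "PROTEIN") {
      recs[[length(recs) + 1L]] <- cbind(base, moiety = "PROT",
                                         pv = pvAtom[rows[1]])
    } else if (kind == "DNA") {
      part <- partitionDNAAtoms(a[rows, , drop = FALSE])
      nm <- .normAtomName(a$name[rows])
      bbRow <- rows[nm %in% .normAtomName(part$bb$name)][1]
      nbRow <- rows[nm %in% .normAtomName(part$nb$name)][1]
      recs[[length(recs) + 1L]] <- cbind(base[c(1, 1), ],
                                         moiety = c("BB", "NB"),
                                         pv = pvAtom[c(bbRow, nbRow)])
    }
  }
  d <- do.call(rbind, recs)
  d <- d[!is.na(d$pv), , drop = FALSE]
  rownames(d) <- NULL
  list(structure = structure, pv = new("PVTable", data = d))
}

#' @rdname accessors
#' @export
setMethod("pvData", "PVTable", function(x) x@data)

setMethod("show", "PVTable", function(object) {
  d <- object@data
  cat("PVTable:", nrow(d), "records\n")
  print(table(factor(d$moiety, levels = .MOIETIES)))
  if (nrow(d))
    cat("  pv range:", sprintf("%.3f .. %.3f", min(d$pv), max(d$pv)), "\n")
})

#' Construct a PVTable from a data frame
#'
#' @param data data.frame with columns chain, seqid, icode, resname,
#'   moiety, pv (icode/resname filled if absent).
#' @return a [PVTable-class].
#' @export
pvTable <- function(data) {
  if (is.null(data$icode)) data$icode <- ""
  if (is.null(data$resname)) data$resname <- ""
  data$seqid <- as.integer(data$seqid)
  rownames(data) <- NULL
  new("PVTable",
      data = data[, c("chain", "seqid", "icode", "resname", "moiety", "pv")])
}

#' Write / read the PV sidecar TSV
#'
#' The TSV (columns chain, seq_id, icode, res_name, moiety, pv) is the
#' authoritative machine-readable form of a PARCH table. Header comment
#' lines (prefixed `# `) may carry configuration provenance.
#'
#' @param pv a [PVTable-class].
#' @param file output path.
#' @param header optional character vector of comment lines.
#' @return invisibly, the file path.
#' @export
writePVTable <- function(pv, file, header = NULL) {
  d <- pvData(pv)
  names(d) <- c("chain", "seq_id", "icode", "res_name", "moiety", "pv")
  con <- file(file, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writePVTable
#' @export
readPVTable <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = c(icode = "character",
                                        chain = "character"))
  names(d) <- c("chain", "seqid", "icode", "resname", "moiety", "pv")
  d$icode[is.na(d$icode)] <- ""
  pvTable(d)
}
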