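# In-silico cytosine methylation: add a methyl carbon at the C5 position
# of every cytosine, with deterministic geometry.

.lsPlaneNormal <- function(coords) {
  # unit normal of the least-squares plane through >= 3 points
  c0 <- sweep(coords, 2, colMeans(coords))
  sv <- svd(c0)
  sv$v[, 3]
}

.unit <- function(v) v / sqrt(sum(v * v))

.placeMethyl <- function(ringCoords, c4, c5, c6, bondLength) {
  # in the ring least-squares plane, along the external bisector of the
  # C4-C5-C6 angle, at bondLength from C5
  nrm <- .lsPlaneNormal(ringCoords)
  d <- -( .unit(c4 - c5) + .unit(c6 - c5) )
  d <- d - sum(d * nrm) * nrm
  c5 + bondLength * .unit(d)
}

#' Methylate every cytosine of a structure at C5
#'
#' Builds the fully methylated counterpart of a DNA-containing structure:
#' each cytosine (residue name `DC`, or legacy `C`) gains one heavy atom
#' named `C5M`, placed in the least-squares plane of the pyrimidine ring
#' along the external bisector of the C4-C5-C6 angle at `bondLength` from
#' C5, and the residue is renamed to the standard modified-nucleotide id
#' `5CM`. Pre-existing coordinates are untouched; serial numbers are
#' reassigned sequentially. Already-methylated residues (`5CM`/`FMC`) are
#' left alone, so the operation is idempotent. Cytosines lacking any of
#' C4/C5/C6, or with a ring deviating from planarity beyond
#' `planarityTol`, are skipped with a reason. A placed methyl landing
#' within 1.8 Angstrom of a non-bonded atom is kept but flagged in the
#' report (relaxation is outside this package's scope).
#'
#' @param structure a [ParchStructure-class].
#' @param bondLength C5-C5M bond length in Angstrom (default 1.50,
#'   standard aromatic C-CH3).
#' @param planarityTol maximum RMS out-of-plane deviation of the ring
#'   atoms in Angstrom (default 0.1).
#' @return list with elements `structure` (methylated) and `report`
#'   ([MethylationReport-class]).
#' @export
methylateAllCytosines <- function(structure, bondLength = 1.50,
                                  planarityTol = 0.1) {
  a <- atoms(structure)
  uid <- .residueUID(a$chain, a$seqid, a$icode)
  resFirst <- !duplicated(uid)
  isCyt <- a$resname[resFirst] %in% c("DC", "C") &
    a$kind[resFirst] == "DNA"
  cytUIDs <- uid[resFirst][isCyt]
  skipped <- list()
  placed <- list()  # uid -> coords of new atom
  ringNames <- c("N1", "C2", "N3", "C4", "C5", "C6")
  for (u in cytUIDs) {
    rows <- which(uid == u)
    nm <- .normAtomName(a$name[rows])
    need <- c("C4", "C5", "C6")
    if (!all(need %in% nm)) {
      skipped[[u]] <- paste("missing atom(s):",
                            paste(setdiff(need, nm), collapse = ", "))
      next
    }
    ring <- .coordMatrix(a[rows[nm %in% ringNames], , drop = FALSE])
    nrm <- .lsPlaneNormal(ring)
    dev <- sqrt(mean((sweep(ring, 2, colMeans(ring)) %*% nrm)^2))
    if (dev > planarityTol) {
      skipped[[u]] <- sprintf("non-planar ring (rms %.3f A)", dev)
      next
    }
    at <- function(name) unlist(a[rows[match(name, nm)], c("x", "y", "z")])
    placed[[u]] <- .placeMethyl(ring, at("C4"), at("C5"), at("C6"),
                                bondLength)
  }
  # rebuild the atom table with the new atoms inserted after each residue
  newRows <- list()
  clash <- list()
  allCoords <- .coordMatrix(a)
  for (u in names(placed)) {
    rows <- which(uid == u)
    p <- placed[[u]]
    tmpl <- a[rows[1], , drop = FALSE]
    tmpl$name <- "C5M"
    tmpl$element <- "C"
    tmpl[, c("x", "y", "z")] <- as.list(p)
    tmpl$occupancy <- 1
    tmpl$bfactor <- 0
    tmpl$altLoc <- ""
    newRows[[u]] <- tmpl
    nm <- .normAtomName(a$name[rows])
    bonded <- rows[nm %in% c("C4", "C5", "C6")]
    d <- .minDistPerRow(matrix(p, 1), allCoords[-bonded, , drop = FALSE])
    if (d < 1.8) clash[[u]] <- d
  }
  pieces <- list()
  for (r in unique(uid)) {
    rows <- which(uid == r)
    block <- a[rows, , drop = FALSE]
    if (!is.null(placed[[r]])) {
      block <- rbind(block, newRows[[r]])
      block$resname <- "5CM"
    }
    pieces[[r]] <- block
  }
  out <- do.call(rbind, pieces)
  out$serial <- seq_len(nrow(out))
  out$kind <- residueKind(out$resname)
  rownames(out) <- NULL
  newStructure <- structure
  newStructure@atoms <- out
  validObject(newStructure)
  splitUID <- function(lst, extraName) {
    us <- names(lst)
    parts <- if (length(us)) {
      do.call(rbind, lapply(strsplit(us, ":", fixed = TRUE),
                            function(p) c(p, "", "")[1:3]))
    } else {
      matrix(character(0), 0, 3)
    }
    d <- data.frame(chain = parts[, 1],
                    seqid = as.integer(parts[, 2]),
                    icode = parts[, 3], stringsAsFactors = FALSE)
    d[[extraName]] <- if (length(lst)) unlist(lst, use.names = FALSE) else
      vector(mode = if (extraName == "reason") "character" else "numeric")
    d
  }
  report <- new("MethylationReport",
                nCytosinesFound = length(cytUIDs),
                nMethylated = length(placed),
                skipped = splitUID(skipped, "reason"),
                clashFlagged = splitUID(clash, "minClash"),
                bondLength = bondLength,
                placedAtomName = "C5M")
  list(structure = newStructure, report = report)
}

setMethod("show", "MethylationReport", function(object) {
  cat(sprintf("MethylationReport: %d/%d cytosines methylated (%s, %.2f A)\n",
              object@nMethylated, object@nCytosinesFound,
              object@placedAtomName, object@bondLength))
  if (nrow(object@skipped)) {
    cat("  skipped:\n")
    print(object@skipped)
  }
  if (nrow(object@clashFlagged))
    cat("  clash-flagged residues:", nrow(object@clashFlagged), "\n")
})

#' Export a methylation report as TSV
#'
#' @param report a [MethylationReport-class].
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeMethylationReport <- function(report, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_cytosines_found=%d n_methylated=%d bond_length_A=%.2f placed_atom=%s",
                     report@nCytosinesFound, report@nMethylated,
                     report@bondLength, report@placedAtomName), con)
  sk <- report@skipped
  if (nrow(sk) == 0L)
    sk <- data.frame(chain = character(0), seqid = integer(0),
                     icode = character(0), reason = character(0))
  utils::write.table(sk, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
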