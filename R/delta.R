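# Paired-system delta-PARCH: DNA stripping and signed differencing.

#' Remove DNA from a structure
#'
#' Produces the histone-only counterpart of a nucleosome: all DNA residues
#' removed, protein residues and coordinates untouched. Waters and ions
#' are retained by default (drop with `dropWaters`/`dropIons`). Idempotent.
#'
#' @param structure a [ParchStructure-class].
#' @param dropWaters,dropIons logical.
#' @return a [ParchStructure-class].
#' @export
stripDNA <- function(structure, dropWaters = FALSE, dropIons = FALSE) {
  a <- atoms(structure)
  drop <- a$kind == "DNA"
  if (dropWaters) drop <- drop | a$kind == "WATER"
  if (dropIons) drop <- drop | a$kind == "ION"
  out <- structure
  out@atoms <- a[!drop, , drop = FALSE]
  rownames(out@atoms) <- NULL
  out
}

.polarity <- function(dpv, zeroTol) {
  ifelse(abs(dpv) < zeroTol, "UNCHANGED",
         ifelse(dpv > 0, "MORE_HYDROPHILIC", "REDUCED_HYDROPHILICITY"))
}

#' Signed PARCH difference between two paired systems
#'
#' Computes `dpv = pvA - pvB` for every (residue, moiety) present in both
#' tables; positive differences mark groups that are more hydrophilic in
#' system A (e.g. DNA present) than in system B (e.g. DNA removed).
#' Matching is by (chain, seqid, icode, moiety) — residue-name changes
#' such as DC to 5CM across a methylation pairing are allowed — with an
#' optional per-chain sequence-number offset for renumbered pairs.
#' Unmatched records are reported separately, never silently dropped.
#'
#' @param pvA,pvB [PVTable-class] objects.
#' @param zeroTol absolute deadband below which polarity is `UNCHANGED`
#'   (default 0.05).
#' @param offsetMap optional named numeric vector: seqid offset added to
#'   system B's residues per chain before matching.
#' @return a [DeltaPVTable-class]; records are ordered by chain, seqid,
#'   icode, moiety.
#' @export
deltaPV <- function(pvA, pvB, zeroTol = 0.05, offsetMap = NULL) {
  a <- pvData(pvA)
  b <- pvData(pvB)
  if (!is.null(offsetMap)) {
    off <- offsetMap[b$chain]
    b$seqid <- b$seqid + ifelse(is.na(off), 0L, as.integer(off))
  }
  keyOf <- function(d) paste(d$chain, d$seqid, d$icode, d$moiety, sep = ":")
  ka <- keyOf(a)
  kb <- keyOf(b)
  common <- intersect(ka, kb)
  ia <- match(common, ka)
  ib <- match(common, kb)
  rec <- data.frame(chain = a$chain[ia], seqid = a$seqid[ia],
                    icode = a$icode[ia], resname = a$resname[ia],
                    moiety = a$moiety[ia], pvA = a$pv[ia], pvB = b$pv[ib],
                    stringsAsFactors = FALSE)
  rec$dpv <- rec$pvA - rec$pvB
  rec$polarity <- .polarity(rec$dpv, zeroTol)
  ord <- order(rec$chain, rec$seqid, rec$icode, rec$moiety)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  new("DeltaPVTable", records = rec,
      unmatchedA = a[!(ka %in% kb), , drop = FALSE],
      unmatchedB = b[!(kb %in% ka), , drop = FALSE],
      zeroTol = zeroTol)
}

#' Delta-PARCH records as a data frame
#'
#' @param x a [DeltaPVTable-class].
#' @param ... ignored.
#' @return the matched records (chain, seqid, icode, resname, moiety,
#'   pvA, pvB, dpv, polarity).
#' @export
setMethod("as.data.frame", "DeltaPVTable", function(x, ...) x@records)

#' Unmatched records of a delta-PARCH comparison
#'
#' @param x a [DeltaPVTable-class].
#' @return list with data.frames `a` and `b`.
#' @export
unmatchedRecords <- function(x) {
  stopifnot(is(x, "DeltaPVTable"))
  list(a = x@unmatchedA, b = x@unmatchedB)
}

setMethod("show", "DeltaPVTable", function(object) {
  cat("DeltaPVTable:", nrow(object@records), "matched records (",
      nrow(object@unmatchedA), "unmatched in A,",
      nrow(object@unmatchedB), "in B )\n")
  print(table(factor(object@records$polarity,
                     levels = c("MORE_HYDROPHILIC", "UNCHANGED",
                                "REDUCED_HYDROPHILICITY"))))
})

#' Export a delta-PARCH table as TSV
#'
#' Mirrors the paired-table layout: residue spec, moiety, pv_a, pv_b, dpv,
#' polarity.
#'
#' @param x a [DeltaPVTable-class].
#' @param file output path.
#' @param header optional comment lines.
#' @return invisibly, the path.
#' @export
writeDeltaTSV <- function(x, file, header = NULL) {
  d <- x@records
  names(d) <- c("chain", "seq_id", "icode", "res_name", "moiety",
                "pv_a", "pv_b", "dpv", "polarity")
  con <- file(file, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  writeLines(sprintf("# zero_tolerance=%g", x@zeroTol), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
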