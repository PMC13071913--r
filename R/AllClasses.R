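#' @import methods
NULL

.MOIETIES <- c("PROT", "BB", "NB")
.KINDS <- c("PROTEIN", "DNA", "WATER", "ION", "OTHER")

.ATOM_COLS <- c("serial", "name", "altLoc", "resname", "chain", "seqid",
                "icode", "x", "y", "z", "occupancy", "bfactor", "element",
                "kind", "unit")

#' Macromolecular structure for hydropathy analysis
#'
#' An atom-level container behind all distance computations in the package.
#' Atoms are stored as a flat data frame (one row per atom, file order
#' preserved); residues are the unique (chain, seqid, icode) triples, each
#' carrying a residue kind (`PROTEIN`, `DNA`, `WATER`, `ION`, `OTHER`)
#' derived from the residue name. The optional `unit` column labels
#' nucleosome units in multi-nucleosome assemblies (dinucleosomes).
#'
#' @slot atoms data.frame with columns serial, name, altLoc, resname, chain,
#'   seqid, icode, x, y, z, occupancy, bfactor, element, kind, unit.
#' @slot title character(1), free-text description.
#' @export
setClass("ParchStructure",
         representation(atoms = "data.frame", title = "character"),
         prototype(title = ""))

setValidity("ParchStructure", function(object) {
  a <- object@atoms
  missing <- setdiff(.ATOM_COLS, names(a))
  if (length(missing))
    return(paste("atoms lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite atom coordinates")
    if (any(!nzchar(a$name)))
      return("empty atom names")
    if (!all(a$kind %in% .KINDS))
      return("unknown residue kind")
  }
  TRUE
})

#' Table of per-residue PARCH values
#'
#' One row per (residue, moiety). Protein residues carry a single `PROT`
#' value; DNA residues carry a `BB` (sugar-phosphate backbone) and an `NB`
#' (nucleobase) value. PARCH values are dimensionless and non-negative:
#' low values mark groups whose hydration shell dewets early in the
#' annealing ramp (hydrophobic), high values mark groups that retain water
#' (hydrophilic).
#'
#' @slot data data.frame with columns chain, seqid, icode, resname, moiety,
#'   pv.
#' @export
setClass("PVTable", representation(data = "data.frame"))

setValidity("PVTable", function(object) {
  d <- object@data
  need <- c("chain", "seqid", "icode", "resname", "moiety", "pv")
  missing <- setdiff(need, names(d))
  if (length(missing))
    return(paste("data lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(d)) {
    if (!all(d$moiety %in% .MOIETIES))
      return("moiety must be PROT, BB or NB")
    if (any(!is.finite(d$pv)) || any(d$pv < 0))
      return("pv must be finite and >= 0")
    key <- paste(d$chain, d$seqid, d$icode, d$moiety)
    if (anyDuplicated(key))
      return("duplicate (residue, moiety) records")
  }
  TRUE
})

#' Linear thermal annealing schedule
#'
#' Metadata describing the temperature ramp under which hydration
#' trajectories are recorded: a linear ramp from `tStart` to `tEnd` at
#' `rate` kelvin per picosecond, with the heavy-atom position-restraint
#' force constant kept as metadata. The default schedule (300 to 800 K at
#' 0.1 K/ps, i.e. 5 ns) is the protocol under which PARCH values are
#' defined.
#'
#' @slot tStart,tEnd numeric(1), temperatures in kelvin.
#' @slot rate numeric(1), heating rate in K per ps.
#' @slot restraintK numeric(1), restraint force constant in kJ mol^-1 nm^-2
#'   (metadata only; no energetics are computed here).
#' @export
setClass("AnnealingSchedule",
         representation(tStart = "numeric", tEnd = "numeric",
                        rate = "numeric", restraintK = "numeric"),
         prototype(tStart = 300, tEnd = 800, rate = 0.1, restraintK = 10000))

setValidity("AnnealingSchedule", function(object) {
  if (object@rate <= 0) return("rate must be > 0")
  if (object@tEnd < object@tStart) return("tEnd must be >= tStart")
  TRUE
})

#' Hydration-shell water-count trajectory
#'
#' Per-group water-oxygen counts over trajectory frames. Rows are groups
#' (named `chain:seqid:icode:moiety`), columns are frames; `times` gives
#' the frame timestamps in ps (strictly increasing, constant spacing
#' `frameIntervalPs`).
#'
#' @slot counts integer-valued numeric matrix, groups x frames, with
#'   rownames.
#' @slot times numeric vector of frame times in ps.
#' @slot frameIntervalPs numeric(1).
#' @export
setClass("HydrationTrajectory",
         representation(counts = "matrix", times = "numeric",
                        frameIntervalPs = "numeric"))

setValidity("HydrationTrajectory", function(object) {
  cts <- object@counts
  if (is.null(rownames(cts))) return("counts must have group-id rownames")
  if (ncol(cts) != length(object@times))
    return("times length must equal frame count")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(cts < 0) || any(cts != round(cts)))
    return("counts must be non-negative integers")
  if (object@frameIntervalPs <= 0) return("frameIntervalPs must be > 0")
  TRUE
})

#' Spatial classification result
#'
#' Labels for a queried residue set from one of the distance classifiers,
#' together with the distance that drove each label.
#'
#' @slot data data.frame with columns chain, seqid, icode, resname, label,
#'   distance (minimum heavy-atom or COG distance in Angstrom, per
#'   `criterion`).
#' @slot cutoff numeric(1), Angstrom.
#' @slot criterion "ANY_ATOM" or "COG".
#' @export
setClass("ClassificationResult",
         representation(data = "data.frame", cutoff = "numeric",
                        criterion = "character"))

setValidity("ClassificationResult", function(object) {
  if (object@cutoff <= 0) return("cutoff must be > 0")
  if (!object@criterion %in% c("ANY_ATOM", "COG"))
    return("criterion must be ANY_ATOM or COG")
  key <- with(object@data, paste(chain, seqid, icode))
  if (anyDuplicated(key)) return("residue labelled more than once")
  TRUE
})

#' Paired-system delta-PARCH table
#'
#' Signed PARCH differences for residues matched across two paired systems
#' (e.g. intact nucleosome vs histone-only, or methylated vs unmethylated).
#' `dpv = pvA - pvB`; polarity is `MORE_HYDROPHILIC` (dpv > tol),
#' `REDUCED_HYDROPHILICITY` (dpv < -tol) or `UNCHANGED` within the
#' zero-tolerance deadband.
#'
#' @slot records data.frame: chain, seqid, icode, resname, moiety, pvA,
#'   pvB, dpv, polarity.
#' @slot unmatchedA,unmatchedB data.frame of records present in only one
#'   input.
#' @slot zeroTol numeric(1).
#' @export
setClass("DeltaPVTable",
         representation(records = "data.frame", unmatchedA = "data.frame",
                        unmatchedB = "data.frame", zeroTol = "numeric"))

#' Report from in-silico cytosine methylation
#'
#' @slot nCytosinesFound,nMethylated integer(1).
#' @slot skipped data.frame (chain, seqid, icode, reason).
#' @slot clashFlagged data.frame (chain, seqid, icode, minClash) of
#'   residues whose placed methyl lies under 1.8 Angstrom from a non-bonded
#'   atom (methylated anyway; relaxation is downstream of this package).
#' @slot bondLength numeric(1), Angstrom.
#' @slot placedAtomName character(1).
#' @export
setClass("MethylationReport",
         representation(nCytosinesFound = "integer", nMethylated = "integer",
                        skipped = "data.frame", clashFlagged = "data.frame",
                        bondLength = "numeric", placedAtomName = "character"))

setValidity("MethylationReport", function(object) {
  if (object@nMethylated + nrow(object@skipped) != object@nCytosinesFound)
    return("nMethylated + skipped must equal nCytosinesFound")
  TRUE
})

#' Kernel density estimate of a PARCH-value sample
#'
#' @slot grid,density numeric vectors (equal length); density is
#'   non-negative and integrates to 1 (trapezoid) within 1e-3.
#' @slot bandwidth numeric(1).
#' @slot n integer(1), sample size.
#' @export
setClass("DensityEstimate",
         representation(grid = "numeric", density = "numeric",
                        bandwidth = "numeric", n = "integer"))

setValidity("DensityEstimate", function(object) {
  if (length(object@grid) != length(object@density))
    return("grid and density lengths differ")
  if (any(object@density < 0)) return("negative density")
  if (object@bandwidth <= 0) return("bandwidth must be > 0")
  TRUE
})

#' Two-group rank-sum comparison
#'
#' Two-sided Mann-Whitney U comparison of two PARCH-value samples, with
#' the significance-star convention used for violin-plot annotations:
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise `ns`.
#'
#' @slot uStatistic,pValue numeric(1).
#' @slot stars character(1).
#' @slot n1,n2 integer(1).
#' @slot medianShift numeric(1), median(x) - median(y).
#' @export
setClass("GroupComparison",
         representation(uStatistic = "numeric", pValue = "numeric",
                        stars = "character", n1 = "integer", n2 = "integer",
                        medianShift = "numeric"))

setValidity("GroupComparison", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("pValue outside [0,1]")
  if (!object@stars %in% c("ns", "*", "**", "***", "****"))
    return("invalid stars")
  TRUE
})

#' Synthetic system with planted ground truth
#'
#' Bundles a toy structure, the realized planted PARCH table and the
#' hydration trajectory generated from it, so that
#' `runParch(structure, trajectory)` recovers `plantedPV` exactly at zero
#' noise (planted values are quantized to the 1/m count lattice of the
#' averaging window; see the methods vignette).
#'
#' @slot structure ParchStructure.
#' @slot plantedPV PVTable (realized, lattice-quantized values).
#' @slot trajectory HydrationTrajectory.
#' @slot seed integer(1).
#' @export
setClass("PlantedSystem",
         representation(structure = "ParchStructure", plantedPV = "PVTable",
                        trajectory = "HydrationTrajectory", seed = "integer"))

#' Pipeline configuration
#'
#' Central knobs of the analysis: classifier cutoffs (Angstrom), the
#' annealing schedule, hydration-shell radius, PARCH averaging window,
#' KDE/statistics settings and the random seed. Serializes to/from YAML.
#'
#' @slot proximalCutoff,contactCutoff,innerCutoff numeric(1), Angstrom
#'   (defaults 3, 8, 20).
#' @slot schedule AnnealingSchedule.
#' @slot rShell numeric(1), hydration-shell radius in Angstrom (default 4).
#' @slot windowFraction numeric(1) in (0,1], PARCH averaging window as a
#'   fraction of trajectory frames (default 0.1).
#' @slot scale numeric(1), PARCH scale factor (default 1).
#' @slot bandwidth "silverman" or a positive number (fixed KDE bandwidth).
#' @slot minProminence numeric(1), mode prominence threshold as a fraction
#'   of the density maximum (default 0.05).
#' @slot zeroTol numeric(1), delta-PARCH polarity deadband (default 0.05).
#' @slot seed integer(1).
#' @export
setClass("PipelineConfig",
         representation(proximalCutoff = "numeric", contactCutoff = "numeric",
                        innerCutoff = "numeric", schedule = "AnnealingSchedule",
                        rShell = "numeric", windowFraction = "numeric",
                        scale = "numeric", bandwidth = "ANY",
                        minProminence = "numeric", zeroTol = "numeric",
                        seed = "integer"))

setValidity("PipelineConfig", function(object) {
  if (any(c(object@proximalCutoff, object@contactCutoff,
            object@innerCutoff, object@rShell) <= 0))
    return("all cutoffs and rShell must be > 0")
  if (object@windowFraction <= 0 || object@windowFraction > 1)
    return("windowFraction must be in (0, 1]")
  if (is.numeric(object@bandwidth)) {
    if (object@bandwidth <= 0) return("fixed bandwidth must be > 0")
  } else if (!identical(object@bandwidth, "silverman")) {
    return("bandwidth must be \"silverman\" or a positive number")
  }
  TRUE
})
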