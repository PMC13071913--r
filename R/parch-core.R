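# PARCH scoring: annealing schedule, hydration-shell counting, and
# per-group PARCH values.
#
# The PARCH value of a residue/moiety group is defined here as the
# time-averaged hydration-shell water count over the final window of the
# annealing trajectory (scale 1, window fraction 0.1 by default).
# Hydrophobic groups dewet early in the ramp and end near zero; hydrophilic
# groups retain shell water to the end and score high.

#' Construct a linear annealing schedule
#'
#' @param tStart,tEnd temperatures in kelvin (defaults 300 and 800).
#' @param rate heating rate in K per ps (default 0.1).
#' @param restraintK heavy-atom restraint force constant in kJ mol^-1
#'   nm^-2, carried as metadata (default 10000).
#' @return an [AnnealingSchedule-class]. The default ramp lasts
#'   `(800 - 300) / 0.1 = 5000` ps, i.e. 5 ns.
#' @export
makeSchedule <- function(tStart = 300, tEnd = 800, rate = 0.1,
                         restraintK = 10000) {
  new("AnnealingSchedule", tStart = tStart, tEnd = tEnd, rate = rate,
      restraintK = restraintK)
}

#' @rdname accessors
#' @export
setMethod("scheduleDuration", "AnnealingSchedule",
          function(x) (x@tEnd - x@tStart) / x@rate)

#' @rdname accessors
#' @param t time in ps, within [0, duration].
#' @export
setMethod("temperatureAt", "AnnealingSchedule", function(x, t) {
  if (any(t < 0 | t > scheduleDuration(x)))
    stop("t outside [0, duration]")
  x@tStart + x@rate * t
})

setMethod("show", "AnnealingSchedule", function(object) {
  cat(sprintf("AnnealingSchedule: %g -> %g K at %g K/ps (%g ps), restraint %g kJ/mol/nm^2\n",
              object@tStart, object@tEnd, object@rate,
              scheduleDuration(object), object@restraintK))
})

#' Count hydration-shell waters around an atom group
#'
#' Number of water oxygens whose minimum distance to any group atom is at
#' most `rShell` (inclusive). Each water is counted at most once per group.
#'
#' @param frame numeric matrix (n x 3) of water-oxygen coordinates, or a
#'   data.frame with x, y, z.
#' @param group coordinates of the group's (heavy) atoms, same formats.
#' @param rShell shell radius in Angstrom (default 4).
#' @return integer count.
#' @export
countShellWaters <- function(frame, group, rShell = 4.0) {
  if (rShell <= 0) stop("rShell must be > 0")
  g <- .coordMatrix(group)
  if (nrow(g) == 0L) stop("empty atom group")
  w <- .coordMatrix(frame)
  if (nrow(w) == 0L) return(0L)
  sum(.minDistPerRow(w, g) <= rShell)
}

#' PARCH value from a water-count series
#'
#' `pv = scale * mean(counts over the final ceiling(windowFraction * n)
#' frames)`.
#'
#' @param counts numeric vector of per-frame shell water counts.
#' @param windowFraction fraction of trailing frames averaged (default
#'   0.1).
#' @param scale multiplicative scale (default 1).
#' @return numeric(1), the PARCH value.
#' @export
computePV <- function(counts, windowFraction = 0.1, scale = 1) {
  n <- length(counts)
  if (n == 0L) stop("empty count series")
  if (windowFraction <= 0 || windowFraction > 1)
    stop("windowFraction must be in (0, 1]")
  m <- ceiling(windowFraction * n)
  scale * mean(counts[(n - m + 1L):n])
}

#' Hydration trajectory constructor
#'
#' @param counts integer matrix, groups x frames, with group-id rownames
#'   (`chain:seqid:icode:moiety`).
#' @param frameIntervalPs frame spacing in ps.
#' @return a [HydrationTrajectory-class].
#' @export
hydrationTrajectory <- function(counts, frameIntervalPs = 10) {
  new("HydrationTrajectory", counts = counts,
      times = seq_len(ncol(counts)) * frameIntervalPs,
      frameIntervalPs = frameIntervalPs)
}

#' @rdname accessors
#' @export
setMethod("counts", "HydrationTrajectory", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("frameTimes", "HydrationTrajectory", function(x) x@times)

setMethod("show", "HydrationTrajectory", function(object) {
  cat("HydrationTrajectory:", nrow(object@counts), "groups x",
      ncol(object@counts), "frames,",
      sprintf("interval %g ps\n", object@frameIntervalPs))
})

#' Build a count trajectory from water-coordinate frames
#'
#' Applies [countShellWaters()] to every residue/moiety group of the
#' structure for every frame.
#'
#' @param structure a [ParchStructure-class]; its waters/ions are ignored
#'   (frames carry the water positions).
#' @param frames list of water-oxygen coordinate matrices, one per frame.
#' @param rShell shell radius in Angstrom.
#' @param frameIntervalPs frame spacing in ps.
#' @return a [HydrationTrajectory-class].
#' @export
countsFromFrames <- function(structure, frames, rShell = 4.0,
                             frameIntervalPs = 10) {
  groups <- moietyGroups(structure)
  if (!length(groups)) stop("structure has no protein or DNA residues")
  cts <- vapply(frames, function(fr) {
    w <- .coordMatrix(fr)
    vapply(groups, function(g) {
      if (nrow(w) == 0L) 0L else sum(.minDistPerRow(w, g) <= rShell)
    }, numeric(1))
  }, numeric(length(groups)))
  cts <- matrix(cts, nrow = length(groups),
                dimnames = list(names(groups), NULL))
  hydrationTrajectory(cts, frameIntervalPs = frameIntervalPs)
}

#' Compute the PARCH table for a structure
#'
#' Maps every residue/moiety group of the structure (PROT per protein
#' residue; BB and NB per DNA residue; waters and ions excluded) onto the
#' trajectory's count series and computes the PARCH value of each.
#'
#' @param structure a [ParchStructure-class].
#' @param traj a [HydrationTrajectory-class] whose rownames are
#'   `chain:seqid:icode:moiety` group ids matching the structure.
#' @param windowFraction,scale see [computePV()].
#' @return a [PVTable-class].
#' @export
runParch <- function(structure, traj, windowFraction = 0.1, scale = 1) {
  r <- residues(structure)
  r <- r[r$kind %in% c("PROTEIN", "DNA"), , drop = FALSE]
  if (nrow(r) == 0L) stop("structure has no protein or DNA residues")
  moiety <- ifelse(r$kind == "PROTEIN", "PROT", "BB")
  ids <- data.frame(chain = rep(r$chain, 1 + (r$kind == "DNA")),
                    seqid = rep(r$seqid, 1 + (r$kind == "DNA")),
                    icode = rep(r$icode, 1 + (r$kind == "DNA")),
                    resname = rep(r$resname, 1 + (r$kind == "DNA")),
                    stringsAsFactors = FALSE)
  moi <- unlist(mapply(function(k) if (k == "DNA") c("BB", "NB") else "PROT",
                       r$kind, SIMPLIFY = FALSE), use.names = FALSE)
  ids$moiety <- moi
  gid <- paste(ids$chain, ids$seqid, ids$icode, ids$moiety, sep = ":")
  cts <- counts(traj)
  missing <- setdiff(gid, rownames(cts))
  extra <- setdiff(rownames(cts), gid)
  if (length(missing) || length(extra))
    stop("group/structure mismatch; structure groups without counts: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ...",
         "; trajectory groups without structure: ",
         paste(utils::head(extra, 10), collapse = ", "),
         if (length(extra) > 10) " ...")
  ids$pv <- apply(cts[gid, , drop = FALSE], 1L, computePV,
                  windowFraction = windowFraction, scale = scale)
  pvTable(ids)
}
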