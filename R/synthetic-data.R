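# Synthetic toy systems with planted ground truth: coarse nucleosome /
# dinucleosome structures, preset PARCH-value mixtures encoding the
# described distributional regimes, and planted hydration trajectories
# that invert the PARCH scorer.
#
# The structures are geometric fixtures (a DNA superhelix around a
# pseudo-octamer of CA-only chains), not physical models: they exist so
# every classifier and the full trajectory->PARCH loop can be exercised
# against known answers.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

# Preset mixtures. Component locations follow the described regimes
# (nucleosomal backbone bimodal near 1 and 5; isolated-fragment backbone
# unimodal near 4; nucleobases near 0.35); weights, spreads and the
# planted methylation (-0.8) and dinucleosome inner (-1.5) shifts are
# synthetic choices documented in presetParameters(). All components are
# truncated at 0.
.PRESETS <- list(
  nucleosomal_bb = list(w = c(0.5, 0.5), loc = c(1, 5), sd = c(0.4, 1.2)),
  fragment_bb    = list(w = 1, loc = 4, sd = 1.0),
  nucleobase     = list(w = 1, loc = 0.35, sd = 0.05),
  methylation_dc = list(w = 1, loc = 4.5, sd = 1.2),
  methylation_fmc = list(w = 1, loc = 3.7, sd = 1.2),
  dinuc_outer_bb = list(w = 1, loc = 5.0, sd = 1.2),
  dinuc_inner_bb = list(w = 1, loc = 3.5, sd = 1.2))

#' Parameter table of the packaged synthetic presets
#'
#' One row per mixture component of each preset: weights, locations and
#' spreads of the truncated-normal components from which
#' [samplePreset()] draws. This is the single authoritative record of the
#' synthetic parameterization.
#'
#' @return data.frame with columns preset, component, weight, location,
#'   spread.
#' @export
presetParameters <- function() {
  do.call(rbind, lapply(names(.PRESETS), function(nm) {
    p <- .PRESETS[[nm]]
    data.frame(preset = nm, component = seq_along(p$w), weight = p$w,
               location = p$loc, spread = p$sd, stringsAsFactors = FALSE)
  }))
}

#' Draw a PARCH-value sample from a named preset
#'
#' Draws n iid values from the named mixture of normals, each component
#' truncated at 0 (negative draws are redrawn within their component, so
#' component frequencies match the stated weights exactly). Identical
#' (name, n, seed) triples give identical samples.
#'
#' @param name preset id; one of `nucleosomal_bb`, `fragment_bb`,
#'   `nucleobase`, `methylation_dc`, `methylation_fmc`, `dinuc_inner_bb`,
#'   `dinuc_outer_bb`.
#' @param n sample size.
#' @param seed integer seed.
#' @param details logical; if TRUE return a data.frame with the component
#'   index of each draw alongside the value.
#' @return numeric vector of length n (or a data.frame when `details`).
#' @export
samplePreset <- function(name, n, seed, details = FALSE) {
  p <- .PRESETS[[name]]
  if (is.null(p))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.PRESETS), collapse = ", "))
  .withSeed(seed, {
    comp <- if (length(p$w) == 1L) rep(1L, n) else
      sample.int(length(p$w), n, replace = TRUE, prob = p$w)
    x <- stats::rnorm(n, p$loc[comp], p$sd[comp])
    while (any(bad <- x < 0))
      x[bad] <- stats::rnorm(sum(bad), p$loc[comp[bad]], p$sd[comp[bad]])
    if (details) data.frame(value = x, component = comp) else x
  })
}

# base templates: planar 2D coordinates (x toward the helix axis once
# mapped, y along the local rise), ring bonds ~1.4 A
.hex <- rbind(N1 = c(0, 0), C2 = c(1.4, 0), N3 = c(2.1, 1.212),
              C4 = c(1.4, 2.424), C5 = c(0, 2.424), C6 = c(-0.7, 1.212))
.hexSub <- function(atom, name) {
  ctr <- c(0.7, 1.212)
  v <- .hex[atom, ] - ctr
  m <- rbind(.hex[atom, ] + 1.3 * v / sqrt(sum(v^2)))
  rownames(m) <- name
  m
}
.pent <- rbind(N7 = c(-0.433, 3.755), C8 = c(0.7, 4.58),
               N9 = c(1.833, 3.755))

.BASE_2D <- list(
  DC = rbind(.hex, .hexSub("C2", "O2"), .hexSub("C4", "N4")),
  DT = rbind(.hex, .hexSub("C2", "O2"), .hexSub("C4", "O4"),
             .hexSub("C5", "C7")),
  DA = rbind(.hex, .pent, .hexSub("C6", "N6")),
  DG = rbind(.hex, .pent, .hexSub("C6", "O6"), .hexSub("C2", "N2")))

# backbone pseudo-atom offsets: (radial du, lateral de2) from the bp center
.BB_2D <- rbind(P = c(5.6, 0), OP1 = c(5.0, 1.2), OP2 = c(5.0, -1.2),
                "O5'" = c(4.4, 0.6), "C5'" = c(3.9, -0.7),
                "C4'" = c(3.3, 0.4), "O4'" = c(2.9, 1.5),
                "C3'" = c(3.5, -1.8), "O3'" = c(4.3, -2.5),
                "C2'" = c(2.6, -0.9), "C1'" = c(2.4, 0.9))

.COMPLEMENT <- c(DA = "DT", DT = "DA", DC = "DG", DG = "DC")

.dnaResidueAtoms <- function(resname, bpCenter, u, e2, nvec, s) {
  # one strand's residue at a base-pair frame; s = +1 (strand I) / -1 (J)
  rows <- list()
  for (nm in rownames(.BB_2D)) {
    off <- .BB_2D[nm, ]
    rows[[nm]] <- bpCenter + off[1] * u + s * off[2] * e2 + s * 1.7 * nvec
  }
  b2 <- .BASE_2D[[resname]]
  for (nm in rownames(b2)) {
    rows[[nm]] <- bpCenter + (2.4 - b2[nm, 2]) * u +
      s * b2[nm, 1] * e2 + s * 1.7 * nvec
  }
  xyz <- do.call(rbind, rows)
  data.frame(name = rownames(xyz), resname = resname,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = substr(rownames(xyz), 1, 1),
             stringsAsFactors = FALSE)
}

.bpFrame <- function(i, nBp, radius, pitch, turns) {
  t <- (i - 1) / (nBp - 1)
  phi <- 2 * pi * turns * t
  u <- c(cos(phi), sin(phi), 0)
  center <- c(radius * u[1:2], pitch * turns * (t - 0.5))
  tv <- c(-radius * sin(phi), radius * cos(phi), 0) * 2 * pi * turns +
    c(0, 0, pitch * turns)
  e2 <- tv / sqrt(sum(tv^2))
  list(center = center, u = u, e2 = e2, nvec = .crossProd(u, e2))
}

.crossProd <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.HISTONE_CHAINS <- data.frame(
  chain = c("A", "B", "C", "D", "E", "F", "G", "H"),
  histone = c("H3", "H4", "H2A", "H2B", "H3", "H4", "H2A", "H2B"),
  n = c(135L, 102L, 130L, 125L, 135L, 102L, 130L, 125L),
  stringsAsFactors = FALSE)

#' Chain map of the toy octamer
#'
#' @return named list mapping histone type to the two toy chains carrying
#'   it, for use with [selectAcidicPatch()] / [selectResidueSet()].
#' @export
toyChainMap <- function() {
  split(.HISTONE_CHAINS$chain, .HISTONE_CHAINS$histone)
}

.ACIDIC <- list(H2A = c("56" = "GLU", "61" = "GLU", "64" = "GLU",
                        "90" = "ASP", "91" = "GLU", "92" = "GLU"),
                H2B = c("102" = "GLU", "110" = "GLU"))

# residues relocated next to DNA phosphates and named ARG: the toy's
# stand-in for minor-groove arginine anchors
.ANCHOR_SEQIDS <- c(30L, 45L, 70L, 85L)

.buildOctamer <- function(nBp, dnaAtoms) {
  # CA-only chains on a 5 x 5 x 6 grid (3 A spacing) in two tetramer
  # layers; selected residues are relocated 2.5 A radially outward from a
  # DNA phosphate to create proximal contacts (named ARG)
  pAtoms <- dnaAtoms[dnaAtoms$name == "P" & dnaAtoms$chain == "I", ,
                     drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(.HISTONE_CHAINS))) {
    ch <- .HISTONE_CHAINS$chain[k]
    hist <- .HISTONE_CHAINS$histone[k]
    n <- .HISTONE_CHAINS$n[k]
    layer <- if (k <= 4) -11 else 11
    ang <- (((k - 1) %% 4) * 90 + 45) * pi / 180
    ctr <- c(15 * cos(ang), 15 * sin(ang), layer)
    i <- seq_len(n) - 1L
    ix <- i %% 5L
    iy <- (i %/% 5L) %% 5L
    iz <- i %/% 25L
    xyz <- cbind(ctr[1] + (ix - 2) * 3, ctr[2] + (iy - 2) * 3,
                 ctr[3] + (iz - 2.5) * 3)
    resname <- rep("ALA", n)
    patch <- .ACIDIC[[hist]]
    if (!is.null(patch))
      resname[as.integer(names(patch))] <- patch
    # anchors: relocate near phosphates of evenly spaced base pairs
    anchorBp <- 8L + 2L * (k - 1L) + c(0L, 32L, 64L, 96L)
    anchorBp <- anchorBp[anchorBp <= nBp - 4L]
    anchorSeq <- .ANCHOR_SEQIDS[seq_along(anchorBp)]
    for (j in seq_along(anchorBp)) {
      p <- pAtoms[pAtoms$seqid == anchorBp[j], c("x", "y", "z")]
      p <- unlist(p[1, ])
      uDir <- c(p[1], p[2], 0)
      uDir <- uDir / sqrt(sum(uDir^2))
      xyz[anchorSeq[j], ] <- p + 2.5 * uDir
      resname[anchorSeq[j]] <- "ARG"
    }
    out[[ch]] <- data.frame(name = "CA", resname = resname, chain = ch,
                            seqid = seq_len(n), x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], element = "C",
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build a toy nucleosome
#'
#' A coarse ~147-bp DNA duplex (standard atom names, idealized planar
#' bases, pseudo-backbone) wound on a superhelical path around a
#' pseudo-octamer of 8 CA-only protein chains, two per histone type
#' (H3: A/E, H4: B/F, H2A: C/G, H2B: D/H; DNA strands I/J). Acidic-patch
#' positions carry their canonical GLU/ASP names; a few residues per chain
#' are relocated to 2.5 Angstrom from a DNA phosphate and named ARG, so
#' the default build has both proximal and distal DNA. No two atoms of
#' different chains lie within 2 Angstrom.
#'
#' @param nBp number of base pairs (default 147).
#' @param superhelixRadius,pitch Angstrom (defaults 42 and 24).
#' @param turns superhelical turns (default 1.65).
#' @return a [ParchStructure-class].
#' @export
buildToyNucleosome <- function(nBp = 147L, superhelixRadius = 42,
                               pitch = 24, turns = 1.65) {
  if (nBp < 2L) stop("nBp must be >= 2")
  if (superhelixRadius <= 0 || pitch < 0 || turns <= 0)
    stop("invalid geometry parameters")
  seqI <- rep(c("DA", "DC", "DG", "DT"), length.out = nBp)
  dna <- list()
  for (i in seq_len(nBp)) {
    fr <- .bpFrame(i, nBp, superhelixRadius, pitch, turns)
    rI <- .dnaResidueAtoms(seqI[i], fr$center, fr$u, fr$e2, fr$nvec, +1)
    rI$chain <- "I"
    rI$seqid <- i
    jSeq <- nBp + 1L - i
    rJ <- .dnaResidueAtoms(.COMPLEMENT[[seqI[i]]], fr$center, fr$u,
                           fr$e2, fr$nvec, -1)
    rJ$chain <- "J"
    rJ$seqid <- jSeq
    dna[[length(dna) + 1L]] <- rbind(rI, rJ)
  }
  dnaAtoms <- do.call(rbind, dna)
  # order strand J by its own seqid
  dnaAtoms <- dnaAtoms[order(dnaAtoms$chain, dnaAtoms$seqid), ,
                       drop = FALSE]
  prot <- .buildOctamer(nBp, dnaAtoms)
  all <- rbind(prot[, names(dnaAtoms)], dnaAtoms)
  parchStructure(all, title = sprintf("toy nucleosome (%d bp)", nBp))
}

#' Build a toy dinucleosome
#'
#' Two toy nucleosomes stacked along z at `separation` Angstrom
#' (center-to-center), with unit labels 1 and 2 and an optional straight
#' linker of `linkerBp` base pairs between them. Linker residues continue
#' the unit-1 DNA strand chains; each linker residue belongs to the unit
#' of its half of the strand segment (split at the midpoint). Unit-2
#' chains are renamed (protein K..R, DNA S/T). Overlapping placement (any
#' inter-unit atom pair under 2 Angstrom) is an error.
#'
#' @param separation Angstrom (default 60).
#' @param linkerBp linker base pairs (default 6; 0 for none).
#' @param ... passed to [buildToyNucleosome()].
#' @return a [ParchStructure-class] with unit labels.
#' @export
buildToyDinucleosome <- function(separation = 60, linkerBp = 6L, ...) {
  if (separation <= 0) stop("separation must be > 0")
  nuc <- buildToyNucleosome(...)
  a1 <- atoms(nuc)
  a1$unit <- 1L
  a2 <- atoms(nuc)
  a2$unit <- 2L
  a2$z <- a2$z + separation
  rename <- c(A = "K", B = "L", C = "M", D = "N", E = "O", F = "P",
              G = "Q", H = "R", I = "S", J = "T")
  a2$chain <- unname(rename[a2$chain])
  if (separation < 50 &&
      .minCrossDist(.coordMatrix(a1), .coordMatrix(a2)) < 2.0)
    stop("overlapping placement: units closer than 2 A")
  pieces <- list(a1, a2)
  if (linkerBp > 0) {
    nBpI <- max(a1$seqid[a1$chain == "I"])
    top1 <- unlist(a1[a1$chain == "I" & a1$seqid == nBpI &
                        a1$name == "C1'", c("x", "y", "z")])
    bot2 <- unlist(a2[a2$chain == "S" & a2$seqid == 1L &
                        a2$name == "C1'", c("x", "y", "z")])
    d <- bot2 - top1
    e2 <- d / sqrt(sum(d^2))
    ref <- if (abs(e2[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- .crossProd(e2, ref)
    u <- u / sqrt(sum(u^2))
    nvec <- .crossProd(u, e2)
    seqL <- rep(c("DA", "DC", "DG", "DT"), length.out = linkerBp)
    for (k in seq_len(linkerBp)) {
      f <- k / (linkerBp + 1)
      ctr <- top1 + f * d
      unit <- if (f <= 0.5) 1L else 2L
      rI <- .dnaResidueAtoms(seqL[k], ctr, u, e2, nvec, +1)
      rI$chain <- "I"
      rI$seqid <- nBpI + k
      rJ <- .dnaResidueAtoms(.COMPLEMENT[[seqL[k]]], ctr, u, e2, nvec, -1)
      rJ$chain <- "J"
      rJ$seqid <- nBpI + k
      blk <- rbind(rI, rJ)
      blk$unit <- unit
      pieces[[length(pieces) + 1L]] <- blk
    }
  }
  all <- do.call(rbind, lapply(pieces, function(p)
    p[, c("name", "resname", "chain", "seqid", "x", "y", "z", "element",
          "unit")]))
  parchStructure(all,
                 title = sprintf("toy dinucleosome (separation %g A)",
                                 separation))
}

.ditherCounts <- function(targets) {
  # error-diffusion integer quantization: partial sums are preserved to
  # within rounding, so segment sums equal round(segment totals)
  cs <- cumsum(pmax(targets, 0))
  cts <- diff(c(0, round(cs)))
  pmax(cts, 0)
}

#' Generate a planted hydration trajectory
#'
#' Builds a per-group integer water-count series whose final-window mean
#' realizes the planted PARCH value of each group. Early frames decay from
#' a hydrated plateau toward the planted value, mimicking annealing
#' dewetting; window frames are the planted value plus optional iid
#' Gaussian noise, quantized to integers by error diffusion so that at
#' `noiseSd = 0` the window mean is exactly `round(m * pv) / m` (m =
#' window frames). Same seed, same trajectory.
#'
#' @param structure a [ParchStructure-class].
#' @param plantedPV a [PVTable-class] covering exactly the structure's
#'   residue/moiety groups.
#' @param schedule an [AnnealingSchedule-class]; its duration divided by
#'   `frameIntervalPs` sets the frame count.
#' @param noiseSd per-frame Gaussian noise sd (default 0).
#' @param seed integer seed.
#' @param frameIntervalPs frame spacing in ps (default 10).
#' @param windowFraction PARCH averaging window (default 0.1); must match
#'   the value used in [runParch()] for exact recovery.
#' @return a [HydrationTrajectory-class].
#' @export
genHydrationTrajectory <- function(structure, plantedPV,
                                   schedule = makeSchedule(), noiseSd = 0,
                                   seed = 1L, frameIntervalPs = 10,
                                   windowFraction = 0.1) {
  d <- pvData(plantedPV)
  gid <- paste(d$chain, d$seqid, d$icode, d$moiety, sep = ":")
  want <- .structureGroupIds(structure)
  missing <- setdiff(want, gid)
  extra <- setdiff(gid, want)
  if (length(missing) || length(extra))
    stop("planted PV does not match the structure's groups; missing: ",
         paste(utils::head(missing, 5), collapse = ", "),
         "; extra: ", paste(utils::head(extra, 5), collapse = ", "))
  nFrames <- max(10L, as.integer(round(scheduleDuration(schedule) /
                                         frameIntervalPs)))
  m <- as.integer(ceiling(windowFraction * nFrames))
  nPre <- nFrames - m
  .withSeed(seed, {
    cts <- t(vapply(seq_len(nrow(d)), function(i) {
      v <- d$pv[i]
      pre <- v + (v + 6) * exp(-4 * seq_len(nPre) / nPre)
      win <- v + stats::rnorm(m, 0, noiseSd)
      c(.ditherCounts(pre), .ditherCounts(win))
    }, numeric(nFrames)))
    rownames(cts) <- gid
    hydrationTrajectory(cts, frameIntervalPs = frameIntervalPs)
  })
}

.structureGroupIds <- function(structure) {
  r <- residues(structure)
  r <- r[r$kind %in% c("PROTEIN", "DNA"), , drop = FALSE]
  unlist(lapply(seq_len(nrow(r)), function(i) {
    moi <- if (r$kind[i] == "DNA") c("BB", "NB") else "PROT"
    paste(r$chain[i], r$seqid[i], r$icode[i], moi, sep = ":")
  }), use.names = FALSE)
}

#' Assemble a planted synthetic system
#'
#' Bundles a structure, a planted PARCH table and the trajectory generated
#' from it. The stored `plantedPV` is the realized (lattice-quantized)
#' table, so `runParch(structure, trajectory, windowFraction)` recovers it
#' exactly at `noiseSd = 0`.
#'
#' @inheritParams genHydrationTrajectory
#' @return a [PlantedSystem-class].
#' @export
plantedSystem <- function(structure, plantedPV, schedule = makeSchedule(),
                          noiseSd = 0, seed = 1L, frameIntervalPs = 10,
                          windowFraction = 0.1) {
  traj <- genHydrationTrajectory(structure, plantedPV, schedule, noiseSd,
                                 seed, frameIntervalPs, windowFraction)
  m <- ceiling(windowFraction * ncol(counts(traj)))
  d <- pvData(plantedPV)
  d$pv <- round(d$pv * m) / m
  new("PlantedSystem", structure = structure, plantedPV = pvTable(d),
      trajectory = traj, seed = as.integer(seed))
}

#' Draw a random planted PV table for a structure
#'
#' Convenience generator for tests: PROT values from the fragment-like
#' range, BB from the nucleosomal backbone preset, NB from the nucleobase
#' preset.
#'
#' @param structure a [ParchStructure-class].
#' @param seed integer seed.
#' @return a [PVTable-class].
#' @export
randomPlantedPV <- function(structure, seed = 1L) {
  r <- residues(structure)
  r <- r[r$kind %in% c("PROTEIN", "DNA"), , drop = FALSE]
  ids <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
    moi <- if (r$kind[i] == "DNA") c("BB", "NB") else "PROT"
    data.frame(chain = r$chain[i], seqid = r$seqid[i], icode = r$icode[i],
               resname = r$resname[i], moiety = moi,
               stringsAsFactors = FALSE)
  }))
  .withSeed(seed, {
    ids$pv <- ifelse(ids$moiety == "NB",
                     pmax(stats::rnorm(nrow(ids), 0.35, 0.05), 0),
                     pmax(stats::rnorm(nrow(ids), 4, 1.5), 0))
    pvTable(ids)
  })
}

#' Write / read a count-series TSV
#'
#' Columns group_id, frame_index, time_ps, n_waters.
#'
#' @param traj a [HydrationTrajectory-class].
#' @param file path.
#' @return invisibly, the path (write) or a trajectory (read).
#' @export
writeCountSeries <- function(traj, file) {
  cts <- counts(traj)
  d <- data.frame(group_id = rep(rownames(cts), ncol(cts)),
                  frame_index = rep(seq_len(ncol(cts)), each = nrow(cts)),
                  time_ps = rep(frameTimes(traj), each = nrow(cts)),
                  n_waters = as.vector(cts))
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCountSeries
#' @export
readCountSeries <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  groups <- unique(d$group_id)
  frames <- sort(unique(d$frame_index))
  cts <- matrix(NA_real_, length(groups), length(frames),
                dimnames = list(groups, NULL))
  cts[cbind(match(d$group_id, groups), match(d$frame_index, frames))] <-
    d$n_waters
  if (anyNA(cts)) stop("count series is ragged: groups differ in frames")
  dt <- unique(diff(sort(unique(d$time_ps))))
  hydrationTrajectory(cts, frameIntervalPs = if (length(dt)) dt[1] else 1)
}
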