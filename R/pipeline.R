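# Orchestration: configuration and the end-to-end analyses that
# reproduce the headline comparisons on packaged synthetic inputs.

#' Build a pipeline configuration
#'
#' @param proximalCutoff,contactCutoff,innerCutoff classifier cutoffs in
#'   Angstrom (defaults 3, 8, 20).
#' @param schedule an [AnnealingSchedule-class] (default 300 to 800 K at
#'   0.1 K/ps).
#' @param rShell hydration-shell radius, Angstrom (default 4).
#' @param windowFraction,scale PARCH averaging window and scale.
#' @param bandwidth KDE bandwidth: "silverman" or a positive number.
#' @param minProminence mode prominence threshold (fraction of maximum).
#' @param zeroTol delta-PARCH polarity deadband.
#' @param seed integer seed used by all stochastic stages.
#' @return a [PipelineConfig-class].
#' @export
parchConfig <- function(proximalCutoff = 3, contactCutoff = 8,
                        innerCutoff = 20, schedule = makeSchedule(),
                        rShell = 4, windowFraction = 0.1, scale = 1,
                        bandwidth = "silverman", minProminence = 0.05,
                        zeroTol = 0.05, seed = 1L) {
  new("PipelineConfig", proximalCutoff = proximalCutoff,
      contactCutoff = contactCutoff, innerCutoff = innerCutoff,
      schedule = schedule, rShell = rShell,
      windowFraction = windowFraction, scale = scale,
      bandwidth = bandwidth, minProminence = minProminence,
      zeroTol = zeroTol, seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  cat(sprintf("  cutoffs (A): proximal %g, contact %g, inner %g\n",
              object@proximalCutoff, object@contactCutoff,
              object@innerCutoff))
  show(object@schedule)
  cat(sprintf("  rShell %g A, window %g, scale %g, bandwidth %s,\n",
              object@rShell, object@windowFraction, object@scale,
              if (is.numeric(object@bandwidth))
                format(object@bandwidth) else object@bandwidth))
  cat(sprintf("  minProminence %g, zeroTol %g, seed %d\n",
              object@minProminence, object@zeroTol, object@seed))
})

.configHeader <- function(config) {
  s <- config@schedule
  sprintf(paste0("config: proximal=%g contact=%g inner=%g rShell=%g ",
                 "window=%g scale=%g bandwidth=%s minProminence=%g ",
                 "zeroTol=%g seed=%d schedule=%g-%gK@%gK/ps"),
          config@proximalCutoff, config@contactCutoff, config@innerCutoff,
          config@rShell, config@windowFraction, config@scale,
          if (is.numeric(config@bandwidth)) format(config@bandwidth)
          else config@bandwidth,
          config@minProminence, config@zeroTol, config@seed,
          s@tStart, s@tEnd, s@rate)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [PipelineConfig-class].
#' @param file path.
#' @return invisibly the path (write); a [PipelineConfig-class] (read).
#' @export
writeParchConfig <- function(config, file) {
  s <- config@schedule
  yaml::write_yaml(list(
    cutoffs = list(proximal_A = config@proximalCutoff,
                   contact_A = config@contactCutoff,
                   inner_A = config@innerCutoff),
    schedule = list(t_start_K = s@tStart, t_end_K = s@tEnd,
                    rate_K_per_ps = s@rate, restraint_k = s@restraintK),
    r_shell_A = config@rShell,
    window_fraction = config@windowFraction,
    scale = config@scale,
    bandwidth = config@bandwidth,
    min_prominence = config@minProminence,
    zero_tolerance = config@zeroTol,
    seed = config@seed), file)
  invisible(file)
}

#' @rdname writeParchConfig
#' @export
readParchConfig <- function(file) {
  y <- yaml::read_yaml(file)
  parchConfig(
    proximalCutoff = y$cutoffs$proximal_A,
    contactCutoff = y$cutoffs$contact_A,
    innerCutoff = y$cutoffs$inner_A,
    schedule = makeSchedule(y$schedule$t_start_K, y$schedule$t_end_K,
                            y$schedule$rate_K_per_ps,
                            y$schedule$restraint_k),
    rShell = y$r_shell_A, windowFraction = y$window_fraction,
    scale = y$scale, bandwidth = y$bandwidth,
    minProminence = y$min_prominence, zeroTol = y$zero_tolerance,
    seed = y$seed)
}

#' Backbone/nucleobase density and mode analysis
#'
#' KDE grids and mode locations for PARCH-value samples, reproducing the
#' nucleosomal-vs-fragment density comparison. With no input samples, the
#' packaged presets are drawn (`nucleosomal_bb`, `fragment_bb`,
#' `nucleobase`; n = 5000, seeds derived from the config seed). Samples
#' may alternatively be supplied as a named list of numeric vectors, or as
#' a data.frame with columns `value`, `group` and optionally `base`
#' (dA/dC/dG/dT), in which case per-base strata are analysed too.
#'
#' @param config a [PipelineConfig-class].
#' @param samples optional, see above.
#' @return list with `density` (data.frame group, grid, density),
#'   `modes` (data.frame group, mode), and `config` header string.
#' @export
runFig2Analysis <- function(config = parchConfig(), samples = NULL) {
  if (is.null(samples)) {
    samples <- list(
      nucleosomal_bb = samplePreset("nucleosomal_bb", 5000, config@seed),
      fragment_bb = samplePreset("fragment_bb", 5000, config@seed + 1L),
      nucleobase = samplePreset("nucleobase", 5000, config@seed + 2L))
  } else if (is.data.frame(samples)) {
    if (!nrow(samples)) stop("empty input sample table")
    key <- samples$group
    if (!is.null(samples$base)) key <- paste(key, samples$base, sep = ".")
    samples <- split(samples$value, key)
  }
  if (!length(samples)) stop("no input samples")
  dens <- list()
  modes <- list()
  for (g in names(samples)) {
    d <- parchKDE(samples[[g]], bandwidth = config@bandwidth)
    dens[[g]] <- cbind(group = g, as.data.frame(d))
    mm <- findModes(d, minProminence = config@minProminence)
    if (length(mm))
      modes[[g]] <- data.frame(group = g, mode = mm)
  }
  list(density = do.call(rbind, c(dens, list(make.row.names = FALSE))),
       modes = if (length(modes))
         do.call(rbind, c(modes, list(make.row.names = FALSE))),
       config = .configHeader(config))
}

#' Paired-system delta-PARCH analysis
#'
#' Differences two PARCH tables (system A minus system B) and optionally
#' restricts the output to a named residue set (e.g. the acidic patch or
#' the 8-Angstrom contact residues), driving the paired-table layouts.
#'
#' @param config a [PipelineConfig-class].
#' @param pvA,pvB [PVTable-class] objects.
#' @param restrict optional data.frame with columns chain and seqid (such
#'   as [selectAcidicPatch()] output or a classification subset); only
#'   matching residues are kept.
#' @return list with `delta` (a [DeltaPVTable-class], restricted),
#'   `table` (its records data.frame) and `config` header string.
#' @export
runPairedDelta <- function(config, pvA, pvB, restrict = NULL) {
  d <- deltaPV(pvA, pvB, zeroTol = config@zeroTol)
  rec <- as.data.frame(d)
  if (!is.null(restrict)) {
    keep <- paste(rec$chain, rec$seqid) %in%
      paste(restrict$chain, restrict$seqid)
    rec <- rec[keep, , drop = FALSE]
    d@records <- rec
  }
  list(delta = d, table = rec, config = .configHeader(config))
}

#' Dinucleosome inner/outer comparison
#'
#' Classifies a two-unit structure at the configured inner cutoff, joins
#' the labels with a PARCH table, and compares inner vs outer values
#' separately for the DNA backbone (BB), nucleobases (NB) and histone
#' residues (PROT), with violin summaries per group.
#'
#' @param config a [PipelineConfig-class].
#' @param structure a unit-labelled [ParchStructure-class].
#' @param pv a [PVTable-class] for the same structure.
#' @return list with `comparisons` (named list of
#'   [GroupComparison-class] for BB, NB, PROT), `summaries` (data.frame of
#'   violin summaries), and `config` header string.
#' @export
runDinucAnalysis <- function(config, structure, pv) {
  cls <- classifyInnerOuter(structure, cutoff = config@innerCutoff)
  lab <- classLabels(cls)
  d <- pvData(pv)
  d$label <- lab[.residueUID(d$chain, d$seqid, d$icode)]
  if (anyNA(d$label))
    stop("PV table contains residues absent from the classification")
  comparisons <- list()
  summaries <- list()
  for (m in .MOIETIES) {
    inner <- d$pv[d$moiety == m & d$label == "INNER"]
    outer <- d$pv[d$moiety == m & d$label == "OUTER"]
    if (length(inner) < 2L || length(outer) < 2L)
      stop("degenerate input: moiety ", m,
           " has an empty or singleton inner/outer group")
    comparisons[[m]] <- compareGroups(inner, outer)
    summaries[[length(summaries) + 1L]] <-
      data.frame(moiety = m, region = c("INNER", "OUTER"),
                 rbind(violinSummary(inner), violinSummary(outer)))
  }
  list(comparisons = comparisons,
       summaries = do.call(rbind, c(summaries,
                                    list(make.row.names = FALSE))),
       config = .configHeader(config))
}
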