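# Command-line style orchestration: one dispatcher exposing the
# analysis stages as subcommands, used by the thin Rscript wrapper in
# inst/scripts/hsp90dyn-cli.R and testable directly in R.  Output files
# carry no timestamps, so identical config + seed gives byte-identical
# results.

.parseArgs <- function(args) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        val <- args[i + 1]
        num <- suppressWarnings(as.numeric(val))
        opts[[key]] <- if (!is.na(num)) num else val
        i <- i + 2L
      }
    } else { pos <- c(pos, a); i <- i + 1L }
  }
  list(positional = pos, options = opts)
}

.opt <- function(opts, name, default = NULL) {
  if (!is.null(opts[[name]])) opts[[name]] else default
}

.parseRegionSpecs <- function(specs) {
  specs <- unlist(strsplit(as.character(specs), ","))
  lapply(specs, function(s) {
    m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
    if (length(m) != 4) stop("bad region spec '", s,
                             "': expected name:first-last")
    Region(m[2], as.integer(m[3]), as.integer(m[4]))
  })
}

.cmdCpmgFit <- function(opts) {
  input <- .opt(opts, "input")
  if (is.null(input)) stop("cpmg-fit requires --input")
  prof <- readDispersion(input)
  fit <- fitDispersion(prof)
  draws <- .opt(opts, "mc-draws", 500)
  seed <- .opt(opts, "seed", 1)
  if (fit@converged && draws >= 2)
    fit <- monteCarloErrors(prof, fit, nDraws = draws, seed = seed)
  cmp <- compareFlatVsExchange(prof, alpha = .opt(opts, "alpha", 0.05))
  prefix <- .opt(opts, "out", "cpmg_fit")
  writeFitReport(list(fit), paste0(prefix, "_report.tsv"),
                 labels = prof@label)
  writeFitJSON(fit, paste0(prefix, "_fit.json"))
  jsonlite::write_json(
    list(preferred = cmp$preferred, f_stat = cmp$fStat,
         p_value = cmp$pValue, alpha = cmp$alpha),
    paste0(prefix, "_model_selection.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(list(fit = fit, comparison = cmp))
}

.cmdLineshape <- function(opts) {
  input <- .opt(opts, "input")
  peaks <- .opt(opts, "peaks")
  if (is.null(input) || is.null(peaks))
    stop("lineshape requires --input and --peaks (comma-separated ppm)")
  spec <- readSpectrum(input)
  centers <- as.numeric(unlist(strsplit(as.character(peaks), ",")))
  tab <- fitLorentzians(spec, length(centers), centers)
  prefix <- .opt(opts, "out", "lineshape")
  .writeTable(tab, paste0(prefix, "_peaks.tsv"))
  invisible(tab)
}

.cmdBuildup <- function(opts) {
  input <- .opt(opts, "input")
  if (is.null(input)) stop("buildup requires --input")
  series <- readBuildup(input)
  res <- fitBuildup(series, nDraws = .opt(opts, "mc-draws", 200),
                    seed = .opt(opts, "seed", 1))
  prefix <- .opt(opts, "out", "buildup")
  jsonlite::write_json(res, paste0(prefix, "_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

.cmdAtpase <- function(opts) {
  plateFile <- .opt(opts, "plate")
  mapFile <- .opt(opts, "wellmap")
  if (is.null(plateFile) || is.null(mapFile))
    stop("atpase requires --plate and --wellmap")
  plate <- readPlate(plateFile)
  wellmap <- readWellMap(mapFile)
  acts <- plateActivities(plate, wellmap,
                          wtLabel = .opt(opts, "wt-label", "WT"),
                          epsilonNADH = .opt(opts, "epsilon-nadh", 6220))
  dm <- buildDeltaMatrix(acts[acts$aha1 == 0, , drop = FALSE])
  prefix <- .opt(opts, "out", "atpase")
  .writeTable(acts, paste0(prefix, "_activities.tsv"))
  writeDeltaMatrix(dm, paste0(prefix, "_delta_matrix.tsv"))
  folds <- aha1FoldTable(acts)
  if (nrow(folds)) .writeTable(folds, paste0(prefix, "_aha1_folds.tsv"))
  invisible(list(activities = acts, delta = dm, aha1 = folds))
}

.cmdDccm <- function(opts) {
  topo <- .opt(opts, "topology")
  if (is.null(topo)) stop("dccm requires --topology")
  traj <- readTrajectory(topo, .opt(opts, "trajectory"),
                         frameSpacing = .opt(opts, "frame-spacing", 10))
  fitFirst <- .opt(opts, "fit-first"); fitLast <- .opt(opts, "fit-last")
  fitRes <- if (!is.null(fitFirst) && !is.null(fitLast))
    seq.int(fitFirst, fitLast) else NULL
  if (!is.null(fitRes) &&
      !any(traj@atomIndex$resno %in% fitRes))
    stop("bad residue range: no atoms in the fit selection")
  sup <- superpose(traj, residues = fitRes)
  dccm <- computeDCCM(sup)
  if (!is.null(.opt(opts, "regions"))) {
    regions <- .parseRegionSpecs(opts$regions)
    bad <- vapply(regions, function(r)
      !any(dccm@residues %in% r@residues), logical(1))
    if (any(bad))
      stop("bad residue range: region(s) ",
           paste(vapply(regions[bad], function(r) r@name, character(1)),
                 collapse = ", "), " match no residues")
    dccm <- regionTotalTable(dccm, regions)
  }
  prefix <- .opt(opts, "out", "dccm")
  writeDCCM(dccm, paste0(prefix, "_matrix.tsv"))
  if (length(regionTotals(dccm)))
    writeRegionTotals(dccm, paste0(prefix, "_totals.tsv"))
  invisible(dccm)
}

.cmdSimulate <- function(opts) {
  gen <- .opt(opts, "generator")
  if (is.null(gen)) stop("simulate requires --generator")
  seed <- .opt(opts, "seed", 1)
  prefix <- .opt(opts, "out", paste0("sim_", gen))
  truthPath <- paste0(prefix, "_truth.json")
  res <- switch(as.character(gen),
    dispersion = {
      sim <- simulateDispersion(
        FastExchangeParams(.opt(opts, "r2-0", 25),
                           .opt(opts, "rex", 8 * 1500),
                           .opt(opts, "kex", 1500)),
        noiseSD = .opt(opts, "noise-sd", 0.5), seed = seed)
      writeDispersion(sim$profile, paste0(prefix, ".tsv"))
      sim
    },
    spectrum = {
      sim <- simulateSpectrum(
        data.frame(center_ppm = c(-60.2, -61.1), t2_ms = c(64.1, 125),
                   area = c(4, 1)),
        noiseSD = .opt(opts, "noise-sd", 0), seed = seed)
      writeSpectrum(sim$spectrum, paste0(prefix, ".tsv"))
      sim
    },
    plate = {
      sim <- simulatePlate(noiseSD = .opt(opts, "noise-sd", 0.002),
                           seed = seed)
      writePlate(sim$plate, paste0(prefix, "_plate.tsv"))
      writeWellMap(sim$wellmap, paste0(prefix, "_wellmap.tsv"))
      sim
    },
    trajectory = {
      sim <- simulateTrajectory(rigidMotion = TRUE, seed = seed)
      writeTrajectoryPDB(sim$window, paste0(prefix, ".pdb"))
      sim
    },
    buildup = {
      sim <- simulateBuildup(noiseSD = .opt(opts, "noise-sd", 0),
                             seed = seed)
      writeBuildup(sim$series, paste0(prefix, ".tsv"))
      sim
    },
    stop("unknown generator '", gen, "'; choose dispersion, spectrum, ",
         "plate, trajectory or buildup"))
  truth <- res$truth
  truth$generator <- as.character(gen)
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(res)
}

.pipelineHelp <- function() {
  cat("hsp90dyn pipeline\n",
      "usage: <subcommand> [--opt value ...]\n\n",
      "subcommands:\n",
      "  cpmg-fit  --input FILE [--mc-draws N --seed S --alpha A --out P]\n",
      "  lineshape --input FILE --peaks ppm1,ppm2 [--out P]\n",
      "  buildup   --input FILE [--mc-draws N --seed S --out P]\n",
      "  atpase    --plate FILE --wellmap FILE [--wt-label L",
      " --epsilon-nadh E --out P]\n",
      "  dccm      --topology FILE [--trajectory FILE --fit-first A",
      " --fit-last B --regions name:a-b,name:a-b --out P]\n",
      "  simulate  --generator NAME [--seed S --noise-sd X --out P]\n",
      sep = "")
  invisible(NULL)
}

#' Run a pipeline subcommand
#'
#' Dispatcher behind the command-line wrapper: the first element of
#' `args` selects the subcommand (`cpmg-fit`, `lineshape`, `buildup`,
#' `atpase`, `dccm`, `simulate`), the rest are `--option value` pairs.
#' Every subcommand writes delimited-text/JSON outputs whose bytes
#' depend only on the inputs and the seed.
#'
#' @param args character vector of command-line arguments
#' @return the subcommand's result, invisibly
#' @examples
#' \dontrun{
#' runPipeline(c("simulate", "--generator", "dispersion",
#'               "--seed", "7", "--out", tempfile()))
#' }
#' @export
runPipeline <- function(args) {
  if (!length(args) || args[1] %in% c("help", "--help", "-h"))
    return(.pipelineHelp())
  parsed <- .parseArgs(args[-1])
  switch(args[1],
         "cpmg-fit" = .cmdCpmgFit(parsed$options),
         "lineshape" = .cmdLineshape(parsed$options),
         "buildup" = .cmdBuildup(parsed$options),
         "atpase" = .cmdAtpase(parsed$options),
         "dccm" = .cmdDccm(parsed$options),
         "simulate" = .cmdSimulate(parsed$options),
         stop("unknown subcommand '", args[1], "'"))
}
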