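# Delimited-text readers and writers for every input/output the
# pipeline handles, plus trajectory ingestion through bio3d.
#
# Tabular files are whitespace/tab delimited with a header row;
# metadata travels in leading "# key=value" comment lines.

.readMeta <- function(lines) {
  meta <- list()
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) {
      val <- suppressWarnings(as.numeric(kv[3]))
      meta[[kv[2]]] <- if (is.na(val)) trimws(kv[3]) else val
    }
  }
  meta
}

.readTable <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in '", path, "'")
  tab <- tryCatch(
    utils::read.table(text = body, header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed table in '", path, "': ",
                             conditionMessage(e)))
  list(meta = .readMeta(lines), table = tab)
}

.writeTable <- function(tab, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 15)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write dispersion tables
#'
#' Files carry columns `nu_cpmg_hz`, `r2_s` and optionally `r2_err_s`,
#' with metadata header lines `# temperature_c=`, `# field_mhz=` and
#' `# label=`.
#'
#' @param path file path
#' @return a [DispersionProfile-class]
#' @export
readDispersion <- function(path) {
  x <- .readTable(path)
  tab <- x$table
  if (!all(c("nu_cpmg_hz", "r2_s") %in% names(tab)))
    stop("dispersion table needs columns nu_cpmg_hz, r2_s")
  DispersionProfile(
    nuCPMG = tab$nu_cpmg_hz, r2Obs = tab$r2_s,
    r2Err = if ("r2_err_s" %in% names(tab)) tab$r2_err_s else numeric(0),
    temperature = if (!is.null(x$meta$temperature_c)) x$meta$temperature_c
                  else NA_real_,
    fieldMHz = if (!is.null(x$meta$field_mhz)) x$meta$field_mhz else 657,
    label = if (!is.null(x$meta$label)) as.character(x$meta$label) else "")
}

#' @param profile a [DispersionProfile-class]
#' @rdname readDispersion
#' @export
writeDispersion <- function(profile, path) {
  tab <- data.frame(nu_cpmg_hz = profile@nuCPMG, r2_s = profile@r2Obs)
  if (length(profile@r2Err)) tab$r2_err_s <- profile@r2Err
  .writeTable(tab, path, list(temperature_c = profile@temperature,
                              field_mhz = profile@fieldMHz,
                              label = profile@label))
}

#' Read and write two-column spectra
#'
#' Columns `ppm`, `intensity`; headers `# field_mhz=`,
#' `# temperature_c=`.
#'
#' @param path file path
#' @return a [Spectrum1D-class]
#' @export
readSpectrum <- function(path) {
  x <- .readTable(path)
  tab <- x$table
  if (!all(c("ppm", "intensity") %in% names(tab)))
    stop("spectrum file needs columns ppm, intensity")
  Spectrum1D(tab$ppm, tab$intensity,
             fieldMHz = if (!is.null(x$meta$field_mhz)) x$meta$field_mhz
                        else 657,
             temperature = if (!is.null(x$meta$temperature_c))
               x$meta$temperature_c else NA_real_)
}

#' @param spec a [Spectrum1D-class]
#' @rdname readSpectrum
#' @export
writeSpectrum <- function(spec, path) {
  .writeTable(data.frame(ppm = spec@ppm, intensity = spec@intensity),
              path, list(field_mhz = spec@fieldMHz,
                         temperature_c = spec@temperature))
}

#' Read and write build-up series
#'
#' Columns `time_s`, `area_nm`, `area_closed`.
#'
#' @param path file path
#' @return a [BuildupSeries-class]
#' @export
readBuildup <- function(path) {
  tab <- .readTable(path)$table
  if (!all(c("time_s", "area_nm", "area_closed") %in% names(tab)))
    stop("build-up file needs columns time_s, area_nm, area_closed")
  BuildupSeries(tab$time_s, tab$area_nm, tab$area_closed)
}

#' @param series a [BuildupSeries-class]
#' @rdname readBuildup
#' @export
writeBuildup <- function(series, path) {
  .writeTable(data.frame(time_s = series@time, area_nm = series@areaNM,
                         area_closed = series@areaClosed), path)
}

#' Read and write plate data
#'
#' The plate file is long-format (`well_id`, `time_min`, `a340`); the
#' well map carries `well_id`, `sample_label`, `subunit1`, `subunit2`,
#' `inhibited`, `aha1`, `hsp90_um`, `replicate`.
#'
#' @param path file path
#' @return a data.frame
#' @export
readPlate <- function(path) {
  tab <- .readTable(path)$table
  if (!all(c("well_id", "time_min", "a340") %in% names(tab)))
    stop("plate file needs columns well_id, time_min, a340")
  tab
}

#' @rdname readPlate
#' @export
readWellMap <- function(path) {
  tab <- .readTable(path)$table
  need <- c("well_id", "sample_label", "subunit1", "subunit2",
            "inhibited", "hsp90_um")
  if (!all(need %in% names(tab)))
    stop("well map needs columns: ", paste(need, collapse = ", "))
  tab
}

#' @param tab a data.frame as returned by the paired reader
#' @rdname readPlate
#' @export
writePlate <- function(tab, path) .writeTable(tab, path)

#' @rdname readPlate
#' @export
writeWellMap <- function(tab, path) .writeTable(tab, path)

#' Write a fit-report table for a set of dispersion fits
#'
#' @param fits list of [CPMGFit-class] (entries that are error objects
#'   are reported with NA parameters)
#' @param labels optional profile labels
#' @param path output file
#' @return the report data.frame, invisibly written to `path`
#' @export
writeFitReport <- function(fits, path, labels = NULL) {
  if (is(fits, "CPMGFit")) fits <- list(fits)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    lab <- if (!is.null(labels)) labels[i] else as.character(i)
    if (!is(f, "CPMGFit"))
      return(data.frame(label = lab, r2_0 = NA, r2_0_sd = NA, rex = NA,
                        rex_sd = NA, kex = NA, kex_sd = NA, sse = NA,
                        n_points = NA, converged = FALSE, mc_draws = 0,
                        error = conditionMessage(f)))
    data.frame(label = lab, r2_0 = f@params@r2_0,
               r2_0_sd = f@paramErrs[["r2_0"]], rex = f@params@rex,
               rex_sd = f@paramErrs[["rex"]], kex = f@params@kex,
               kex_sd = f@paramErrs[["kex"]], sse = f@sse,
               n_points = f@nPoints, converged = f@converged,
               mc_draws = nrow(f@mcSamples), error = "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  .writeTable(tab, path)
  invisible(tab)
}

#' Write a structured JSON record for one dispersion fit
#'
#' Includes the fitted parameters, their Monte Carlo errors, the seed
#' and the number of draws, so a run is fully reproducible.
#'
#' @param fit a [CPMGFit-class]
#' @param path output file
#' @export
writeFitJSON <- function(fit, path) {
  rec <- list(params = list(r2_0 = fit@params@r2_0, rex = fit@params@rex,
                            kex = fit@params@kex),
              param_errs = as.list(fit@paramErrs),
              sse = fit@sse, n_points = fit@nPoints,
              converged = fit@converged,
              mc = list(draws = nrow(fit@mcSamples),
                        seed = fit@seed))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a Delta matrix in the lower-triangular layout
#'
#' @param dm a [DeltaMatrix-class]
#' @param path output file
#' @export
writeDeltaMatrix <- function(dm, path) {
  vals <- deltaValues(dm)
  tab <- data.frame(subunit = rownames(vals),
                    format(round(vals, 6)), check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab[] <- lapply(tab, function(col) gsub("NA", ".", col))
  .writeTable(tab, path)
}

#' Write a DCCM and its region totals
#'
#' The matrix file is square with residue numbers as the header row and
#' first column; totals are a two-column table `region_pair`, `total`.
#'
#' @param dccm a [DCCMResult-class]
#' @param path output file for the matrix
#' @export
writeDCCM <- function(dccm, path) {
  m <- dccmMatrix(dccm)
  tab <- data.frame(residue = dccm@residues, m, check.names = FALSE)
  .writeTable(tab, path)
}

#' @param totalsPath output file for the region totals
#' @rdname writeDCCM
#' @export
writeRegionTotals <- function(dccm, totalsPath) {
  tot <- regionTotals(dccm)
  .writeTable(data.frame(region_pair = names(tot), total = unname(tot),
                         stringsAsFactors = FALSE), totalsPath)
}

#' Read a trajectory into a TrajectoryWindow
#'
#' Accepts a (possibly multi-model) PDB, or a PDB topology plus a DCD
#' trajectory, via bio3d.
#'
#' @param topology path to a PDB file
#' @param trajectory optional path to a DCD file; when NULL the models
#'   of the PDB are the frames
#' @param frameSpacing ns between stored frames
#' @return a [TrajectoryWindow-class]
#' @export
readTrajectory <- function(topology, trajectory = NULL, frameSpacing = 10) {
  pdb <- bio3d::read.pdb(topology, multi = is.null(trajectory))
  xyz <- if (is.null(trajectory)) pdb$xyz else bio3d::read.dcd(trajectory)
  xyz <- as.matrix(xyz)
  natom <- nrow(pdb$atom)
  if (ncol(xyz) != 3 * natom)
    stop("trajectory atom count does not match topology")
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, natom, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  TrajectoryWindow(coords,
                   data.frame(resno = pdb$atom$resno,
                              elety = pdb$atom$elety,
                              stringsAsFactors = FALSE),
                   frameSpacing = frameSpacing)
}

#' Write a TrajectoryWindow as a multi-model PDB
#'
#' @param window a [TrajectoryWindow-class]
#' @param path output PDB path
#' @export
writeTrajectoryPDB <- function(window, path) {
  nf <- dim(window@coords)[1]
  xyz <- t(vapply(seq_len(nf), function(f)
    as.numeric(t(window@coords[f, , , drop = TRUE])),
    numeric(3 * dim(window@coords)[2])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = window@atomIndex$resno,
                   elety = window@atomIndex$elety,
                   resid = rep("ALA", nrow(window@atomIndex)))
  invisible(path)
}
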