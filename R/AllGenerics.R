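# Accessor generics and show methods for the core classes.

#' @name accessors
#' @title Accessors for fitted-parameter and result objects
#' @param object an object of the documented class
#' @return the slot value
NULL

#' @rdname accessors
#' @export
setGeneric("r20", function(object) standardGeneric("r20"))
#' @rdname accessors
#' @export
setGeneric("rex", function(object) standardGeneric("rex"))
#' @rdname accessors
#' @export
setGeneric("kex", function(object) standardGeneric("kex"))
#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setGeneric("paramErrs", function(object) standardGeneric("paramErrs"))
#' @rdname accessors
#' @export
setGeneric("mcSamples", function(object) standardGeneric("mcSamples"))
#' @rdname accessors
#' @export
setGeneric("nuCPMG", function(object) standardGeneric("nuCPMG"))
#' @rdname accessors
#' @export
setGeneric("r2Obs", function(object) standardGeneric("r2Obs"))
#' @rdname accessors
#' @export
setGeneric("dccmMatrix", function(object) standardGeneric("dccmMatrix"))
#' @rdname accessors
#' @export
setGeneric("regionTotals", function(object) standardGeneric("regionTotals"))
#' @rdname accessors
#' @export
setGeneric("deltaValues", function(object) standardGeneric("deltaValues"))
#' @rdname accessors
#' @export
setGeneric("deltaErrors", function(object) standardGeneric("deltaErrors"))
#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
setMethod("r20", "FastExchangeParams", function(object) object@r2_0)
#' @rdname accessors
setMethod("rex", "FastExchangeParams", function(object) object@rex)
#' @rdname accessors
setMethod("kex", "FastExchangeParams", function(object) object@kex)
#' @rdname accessors
setMethod("r20", "CPMGFit", function(object) object@params@r2_0)
#' @rdname accessors
setMethod("rex", "CPMGFit", function(object) object@params@rex)
#' @rdname accessors
setMethod("kex", "CPMGFit", function(object) object@params@kex)
#' @rdname accessors
setMethod("fitParams", "CPMGFit", function(object) object@params)
#' @rdname accessors
setMethod("paramErrs", "CPMGFit", function(object) object@paramErrs)
#' @rdname accessors
setMethod("mcSamples", "CPMGFit", function(object) object@mcSamples)
#' @rdname accessors
setMethod("nuCPMG", "DispersionProfile", function(object) object@nuCPMG)
#' @rdname accessors
setMethod("r2Obs", "DispersionProfile", function(object) object@r2Obs)
#' @rdname accessors
setMethod("dccmMatrix", "DCCMResult", function(object) object@matrix)
#' @rdname accessors
setMethod("regionTotals", "DCCMResult", function(object) object@regionTotals)
#' @rdname accessors
setMethod("deltaValues", "DeltaMatrix", function(object) object@values)
#' @rdname accessors
setMethod("deltaErrors", "DeltaMatrix", function(object) object@errors)
#' @rdname accessors
setMethod("sampleLabels", "DeltaMatrix", function(object) object@labels)
#' @rdname accessors
setMethod("nFrames", "TrajectoryWindow",
          function(object) dim(object@coords)[1])

setMethod("show", "FastExchangeParams", function(object) {
  cat("FastExchangeParams: R2,0 =", format(object@r2_0, digits = 4),
      "s-1; Rex =", format(object@rex, digits = 4),
      "rad2 s-2; kex =", format(object@kex, digits = 4), "s-1\n")
})

setMethod("show", "DispersionProfile", function(object) {
  cat("DispersionProfile '", object@label, "': ",
      length(object@nuCPMG), " points, nuCPMG ",
      format(min(object@nuCPMG)), "-", format(max(object@nuCPMG)),
      " Hz, ", object@temperature, " C, ", object@fieldMHz, " MHz\n",
      sep = "")
})

setMethod("show", "CPMGFit", function(object) {
  p <- object@params; e <- object@paramErrs
  fmt <- function(v, s) if (is.na(s)) format(v, digits = 4) else
    paste0(format(v, digits = 4), " +/- ", format(s, digits = 3))
  cat("CPMGFit (", if (object@converged) "converged" else "NOT converged",
      "):\n  R2,0 = ", fmt(p@r2_0, e[["r2_0"]]), " s-1\n  Rex  = ",
      fmt(p@rex, e[["rex"]]), " rad2 s-2\n  kex  = ",
      fmt(p@kex, e[["kex"]]), " s-1\n  SSE = ",
      format(object@sse, digits = 4), " over ", object@nPoints,
      " points; ", nrow(object@mcSamples), " MC draws\n", sep = "")
})

setMethod("show", "Spectrum1D", function(object) {
  cat("Spectrum1D: ", length(object@ppm), " points, ",
      format(min(object@ppm)), " to ", format(max(object@ppm)),
      " ppm at ", object@fieldMHz, " MHz\n", sep = "")
})

setMethod("show", "TrajectoryWindow", function(object) {
  d <- dim(object@coords)
  cat("TrajectoryWindow: ", d[1], " frames x ", d[2], " atoms, ",
      object@frameSpacing, " ns spacing (", (d[1] - 1) * object@frameSpacing,
      " ns span)\n", sep = "")
})

setMethod("show", "DCCMResult", function(object) {
  cat("DCCMResult: ", nrow(object@matrix), " residues (",
      min(object@residues), "-", max(object@residues), ")\n", sep = "")
  if (length(object@regionTotals)) {
    cat("  total correlations:\n")
    for (nm in names(object@regionTotals))
      cat("    ", nm, ": ", format(object@regionTotals[[nm]], digits = 4),
          "\n", sep = "")
  }
})

setMethod("show", "DeltaMatrix", function(object) {
  cat("DeltaMatrix over", length(object@labels), "subunit variants",
      "(diagonal: Delta_symm; off-diagonal: Delta_asymm)\n")
  print(round(object@values, 3), na.print = ".")
})

setMethod("show", "Region", function(object) {
  cat("Region '", object@name, "': residues ", min(object@residues), "-",
      max(object@residues), "\n", sep = "")
})
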