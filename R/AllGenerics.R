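#' Concentration of a species in a solution
#'
#' Returns 0 mM for species not present in the solution.
#'
#' @param x a [Solution-class].
#' @param ion species name (e.g. "Na", "Ca").
#' @return numeric, concentration in mM.
#' @examples
#' concentrationOf(builtinSolutions()[["high-Na pipette"]], "Na")
#' @export
setGeneric("concentrationOf", function(x, ion) standardGeneric("concentrationOf"))

#' @rdname concentrationOf
setMethod("concentrationOf", "Solution", function(x, ion) {
  conc <- x@concentrations
  vapply(ion, function(i) if (i %in% names(conc)) conc[[i]] else 0,
         numeric(1), USE.NAMES = length(ion) > 1L)
})

#' Solution label and role accessors
#'
#' @param x a [Solution-class].
#' @return character(1).
#' @export
setGeneric("solutionLabel", function(x) standardGeneric("solutionLabel"))
#' @rdname solutionLabel
setMethod("solutionLabel", "Solution", function(x) x@label)

#' @rdname solutionLabel
#' @export
setGeneric("solutionRole", function(x) standardGeneric("solutionRole"))
#' @rdname solutionLabel
setMethod("solutionRole", "Solution", function(x) x@role)

#' Permeability-ratio accessor
#'
#' @param x a [PermeabilitySet-class] or [SimChannelSpec-class].
#' @param ion ion name; if missing, the full named vector is returned.
#' @return numeric, P_ion/P_Na.
#' @export
setGeneric("permRatio", function(x, ion) standardGeneric("permRatio"))

#' @rdname permRatio
setMethod("permRatio", "PermeabilitySet", function(x, ion) {
  if (missing(ion)) return(x@ratios)
  vapply(ion, function(i) if (i %in% names(x@ratios)) x@ratios[[i]] else 0,
         numeric(1), USE.NAMES = length(ion) > 1L)
})

#' @rdname permRatio
setMethod("permRatio", "SimChannelSpec", function(x, ion) {
  if (missing(ion)) permRatio(x@perms) else permRatio(x@perms, ion)
})

#' Boltzmann parameter accessors
#'
#' @param x a [BoltzmannParams-class] or [SimChannelSpec-class].
#' @return numeric(1).
#' @export
setGeneric("vHalf", function(x) standardGeneric("vHalf"))
#' @rdname vHalf
setMethod("vHalf", "BoltzmannParams", function(x) x@vHalf)
#' @rdname vHalf
setMethod("vHalf", "SimChannelSpec", function(x) x@gating@vHalf)

#' @rdname vHalf
#' @export
setGeneric("kSlope", function(x) standardGeneric("kSlope"))
#' @rdname vHalf
setMethod("kSlope", "BoltzmannParams", function(x) x@kSlope)
#' @rdname vHalf
setMethod("kSlope", "SimChannelSpec", function(x) x@gating@kSlope)

#' Trace accessors
#'
#' @param x a [CurrentTrace-class].
#' @return numeric vector (time in ms, command in mV, current in normalized
#'   units) or the metadata list.
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname traceTime
setMethod("traceTime", "CurrentTrace", function(x) x@time)

#' @rdname traceTime
#' @export
setGeneric("traceCommand", function(x) standardGeneric("traceCommand"))
#' @rdname traceTime
setMethod("traceCommand", "CurrentTrace", function(x) x@commandV)

#' @rdname traceTime
#' @export
setGeneric("traceCurrent", function(x) standardGeneric("traceCurrent"))
#' @rdname traceTime
setMethod("traceCurrent", "CurrentTrace", function(x) x@current)

#' @rdname traceTime
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))
#' @rdname traceTime
setMethod("traceMetadata", "CurrentTrace", function(x) x@metadata)

#' Filter-sequence accessors
#'
#' @param x a [FilterSequence-class].
#' @return character(1) residue string, or integer offset.
#' @export
setGeneric("filterResidues", function(x) standardGeneric("filterResidues"))
#' @rdname filterResidues
setMethod("filterResidues", "FilterSequence", function(x) x@residues)

#' @rdname filterResidues
#' @export
setGeneric("parentOffset", function(x) standardGeneric("parentOffset"))
#' @rdname filterResidues
setMethod("parentOffset", "FilterSequence", function(x) x@parentOffset)
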