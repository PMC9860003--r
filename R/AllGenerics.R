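#' @rdname accessors
#' @export
setGeneric("materialName", function(x) standardGeneric("materialName"))

#' Accessors for pcctmd containers
#'
#' Small accessor family: `materialName` returns the identifier of a
#' [Material-class]; `materialNames` the material list of phantoms, sinograms
#' and image sets; `values` the underlying numeric array; `nChannels` the
#' number of spectral channels; `pixelSize` the grid pixel size in mm.
#'
#' @param x a pcctmd object.
#' @return See details; scalars, character vectors or numeric arrays.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("materialNames", function(x) standardGeneric("materialNames"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "PhantomImage", function(x) x@pixelSizeMm)

#' @rdname accessors
#' @export
setMethod("pixelSize", "BasisImageSet", function(x) x@pixelSizeMm)

#' @rdname accessors
#' @export
setMethod("materialName", "Material", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("materialNames", "PhantomImage", function(x) x@materials)

#' @rdname accessors
#' @export
setMethod("materialNames", "LineIntegralSinogram", function(x) x@materials)

#' @rdname accessors
#' @export
setMethod("materialNames", "BasisImageSet", function(x) x@materials)

#' @rdname accessors
#' @export
setMethod("values", "LineIntegralSinogram", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("values", "CountsSinogram", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("values", "BasisImageSet", function(x) x@images)

#' @rdname accessors
#' @export
setMethod("values", "PhantomImage", function(x) x@coeffs)

#' @rdname accessors
#' @export
setMethod("nChannels", "ChannelSet", function(x) nrow(x@bounds))

#' @rdname accessors
#' @export
setMethod("nChannels", "CountsSinogram", function(x) nrow(x@channels@bounds))
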