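#' @title Accessor generics
#' @description Accessors for the package's S4 containers. Slot access from
#'   user code should go through these.
#' @param x an object.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("residues", function(x, ...) standardGeneric("residues"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("unitLabels", function(x) standardGeneric("unitLabels"))

#' @rdname accessors
#' @export
setGeneric("pvData", function(x) standardGeneric("pvData"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("scheduleDuration", function(x) standardGeneric("scheduleDuration"))

#' @rdname accessors
#' @export
setGeneric("temperatureAt", function(x, ...) standardGeneric("temperatureAt"))
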