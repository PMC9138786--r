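#' @rdname drugIds
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname nodeIds
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname vertexVectors
#' @export
setGeneric("vertexVectors", function(x) standardGeneric("vertexVectors"))

#' @rdname vertexVectors
#' @export
setGeneric("contextVectors", function(x) standardGeneric("contextVectors"))

#' @rdname fusedMatrix
#' @export
setGeneric("fusedMatrix", function(x) standardGeneric("fusedMatrix"))

#' @rdname nLevels
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname nLevels
#' @export
setGeneric("levelGraph", function(x, k) standardGeneric("levelGraph"))

#' @rdname nLevels
#' @export
setGeneric("levelMap", function(x, k) standardGeneric("levelMap"))

#' @rdname profileMatrix
#' @export
setGeneric("profileMatrix", function(x, type) standardGeneric("profileMatrix"))

#' @rdname tokenVector
#' @export
setGeneric("tokenVector", function(x, token) standardGeneric("tokenVector"))
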