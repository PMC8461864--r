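#' @rdname accessors
#' @export
setGeneric("labCatalog", function(x) standardGeneric("labCatalog"))

#' @rdname accessors
#' @export
setGeneric("drugCatalog", function(x) standardGeneric("drugCatalog"))

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("exposures", function(x) standardGeneric("exposures"))

#' @rdname accessors
#' @export
setGeneric("signMatrix", function(x) standardGeneric("signMatrix"))

#' @rdname accessors
#' @export
setGeneric("signDetails", function(x) standardGeneric("signDetails"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("indications", function(x) standardGeneric("indications"))

#' @rdname accessors
#' @export
setGeneric("subjectStatus", function(x) standardGeneric("subjectStatus"))

#' @rdname accessors
#' @export
setGeneric("labValues", function(x) standardGeneric("labValues"))
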