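#' Accessors for clinCMap containers
#'
#' Small read-only accessors: `labCatalog()` and `drugCatalog()` return the
#' fixed lab/drug universes; `records()` and `exposures()` the longitudinal
#' table and its row-aligned 0/1 exposure matrix; `signMatrix()` and
#' `signDetails()` the ternary matrix and supporting statistics of a
#' [SignVectorSet-class]; `scores()` the numeric matrix of a
#' [ScoreMatrix-class]; `indications()` the disease -> drugs list of a
#' [GoldStandard-class]; `subjectStatus()` and `labValues()` the status and
#' lab matrices of a [CaseControlData-class].
#'
#' @param x the object.
#' @return the slot contents, never a modifiable reference.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("labCatalog", "LongitudinalLabData", function(x) x@labCatalog)

#' @rdname accessors
#' @export
setMethod("labCatalog", "CaseControlData", function(x) colnames(x@labs))

#' @rdname accessors
#' @export
setMethod("labCatalog", "SignVectorSet", function(x) colnames(x@entries))

#' @rdname accessors
#' @export
setMethod("drugCatalog", "LongitudinalLabData", function(x) x@drugCatalog)

#' @rdname accessors
#' @export
setMethod("records", "LongitudinalLabData", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("exposures", "LongitudinalLabData", function(x) x@exposures)

#' @rdname accessors
#' @export
setMethod("signMatrix", "SignVectorSet", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("signDetails", "SignVectorSet", function(x) x@details)

#' @rdname accessors
#' @export
setMethod("scores", "ScoreMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("indications", "GoldStandard", function(x) x@indications)

#' @rdname accessors
#' @export
setMethod("subjectStatus", "CaseControlData", function(x) x@status)

#' @rdname accessors
#' @export
setMethod("labValues", "CaseControlData", function(x) x@labs)

setMethod("show", "LongitudinalLabData", function(object) {
    cat("LongitudinalLabData:", length(unique(object@records$patient_id)),
        "patients,", nrow(object@records), "measurements,",
        length(object@labCatalog), "labs,",
        length(object@drugCatalog), "drugs\n")
})

setMethod("show", "CaseControlData", function(object) {
    cat("CaseControlData:", length(object@subjectIds), "subjects,",
        ncol(object@status), "diseases,", ncol(object@labs), "labs\n")
})

setMethod("show", "SignVectorSet", function(object) {
    e <- object@entries
    cat("SignVectorSet (", object@kind, "): ", nrow(e), " x ", ncol(e),
        " [+", sum(e == 1), " / -", sum(e == -1), " / 0 ", sum(e == 0), "]\n",
        sep = "")
})

setMethod("show", "ScoreMatrix", function(object) {
    s <- object@scores
    cat("ScoreMatrix:", nrow(s), "drugs x", ncol(s), "diseases; range [",
        if (length(s)) paste(range(s), collapse = ", ") else "", "]\n")
})

setMethod("show", "GoldStandard", function(object) {
    cat("GoldStandard:", length(object@indications), "diseases,",
        sum(lengths(object@indications)), "indications\n")
})

setMethod("show", "CSCCSFit", function(object) {
    cat("CSCCSFit for lab", object@labId, "- lambda =", object@lambda,
        "; support size", length(object@support), "of",
        length(object@beta), "drugs\n")
})
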