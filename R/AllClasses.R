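#' @import methods
NULL

#' Configuration for the longitudinal EHR simulator
#'
#' Holds the generative parameters of the per-patient-baseline linear model
#' from which synthetic prescription/lab histories are drawn: each measurement
#' is baseline + drug effects + Gaussian noise, with i.i.d. Bernoulli drug
#' exposures per measurement.
#'
#' @slot nPatients number of patients (N).
#' @slot nDrugs number of drugs (M).
#' @slot nLabs number of lab tests.
#' @slot measRange integer length-2 range for the per-patient measurement
#'   count J_i (drawn uniformly, inclusive).
#' @slot baselineMean,baselineSd normal distribution of the per-patient,
#'   per-lab baseline alpha_i.
#' @slot noiseSd standard deviation sigma of the measurement noise, >= 0.
#' @slot exposureProb probability a drug is active at a given measurement.
#' @slot seed integer seed; identical config => identical dataset.
#'
#' @seealso [ehrSimConfig()], [simulateEHR()]
#' @export
setClass("EHRSimConfig",
    slots = c(
        nPatients = "integer", nDrugs = "integer", nLabs = "integer",
        measRange = "integer",
        baselineMean = "numeric", baselineSd = "numeric",
        noiseSd = "numeric", exposureProb = "numeric", seed = "integer"
    )
)

setValidity("EHRSimConfig", function(object) {
    msg <- character()
    if (object@nPatients < 0L || object@nDrugs < 0L || object@nLabs < 0L)
        msg <- c(msg, "counts must be >= 0")
    if (length(object@measRange) != 2L || any(object@measRange < 1L) ||
        object@measRange[1L] > object@measRange[2L])
        msg <- c(msg, "measRange must be an increasing pair of counts >= 1")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@baselineSd < 0) msg <- c(msg, "baselineSd must be >= 0")
    if (object@exposureProb < 0 || object@exposureProb > 1)
        msg <- c(msg, "exposureProb must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Configuration for the case/control survey simulator
#'
#' Cases are drawn from Normal(labMeans + diseaseShifts, labSds), controls
#' from Normal(labMeans, labSds), one column per lab.
#'
#' @slot nCases,nControls group sizes.
#' @slot labMeans,labSds named per-lab means and standard deviations.
#' @slot diseaseShifts named per-lab offsets added in the case group
#'   (same names as `labMeans`; zero means no planted effect).
#' @slot seed integer seed.
#'
#' @seealso [surveySimConfig()], [simulateSurvey()]
#' @export
setClass("SurveySimConfig",
    slots = c(
        nCases = "integer", nControls = "integer",
        labMeans = "numeric", labSds = "numeric",
        diseaseShifts = "numeric", seed = "integer"
    )
)

setValidity("SurveySimConfig", function(object) {
    msg <- character()
    if (object@nCases < 0L || object@nControls < 0L)
        msg <- c(msg, "group sizes must be >= 0")
    if (any(object@labSds < 0)) msg <- c(msg, "labSds must be >= 0")
    labs <- names(object@labMeans)
    if (is.null(labs) || anyDuplicated(labs))
        msg <- c(msg, "labMeans must have unique names")
    if (!identical(labs, names(object@labSds)) ||
        !identical(labs, names(object@diseaseShifts)))
        msg <- c(msg, "labMeans, labSds and diseaseShifts must share names")
    if (length(msg)) msg else TRUE
})

#' Longitudinal prescription/lab dataset
#'
#' One record per (patient, measurement index, lab) with the numeric lab value
#' and, row-aligned in `exposures`, the binary drug-exposure vector at the
#' time of that measurement.
#'
#' @slot records data.frame with columns `patient_id`, `meas_index`,
#'   `lab_id`, `value`.
#' @slot exposures 0/1 matrix, one row per record, one column per drug.
#' @slot drugCatalog,labCatalog character vectors fixing the drug and lab
#'   universes for the run.
#'
#' @seealso [simulateEHR()], [buildDesign()], [buildDrugEffectVectors()]
#' @export
setClass("LongitudinalLabData",
    slots = c(
        records = "data.frame", exposures = "matrix",
        drugCatalog = "character", labCatalog = "character"
    )
)

setValidity("LongitudinalLabData", function(object) {
    msg <- character()
    need <- c("patient_id", "meas_index", "lab_id", "value")
    if (!all(need %in% names(object@records)))
        msg <- c(msg, paste("records needs columns:", paste(need, collapse = ", ")))
    else {
        key <- paste(object@records$patient_id, object@records$lab_id,
                     object@records$meas_index)
        if (anyDuplicated(key))
            msg <- c(msg, "(patient, lab, meas_index) must be unique")
        if (!all(object@records$lab_id %in% object@labCatalog))
            msg <- c(msg, "records contain lab ids outside the catalog")
    }
    if (nrow(object@exposures) != nrow(object@records))
        msg <- c(msg, "exposures must have one row per record")
    if (ncol(object@exposures) != length(object@drugCatalog))
        msg <- c(msg, "exposures must have one column per drug")
    if (length(object@exposures) && !all(object@exposures %in% c(0, 1)))
        msg <- c(msg, "exposures must be 0/1")
    if (anyDuplicated(object@drugCatalog) || anyDuplicated(object@labCatalog))
        msg <- c(msg, "catalogs must be unique")
    if (length(msg)) msg else TRUE
})

#' Case/control survey dataset
#'
#' Subjects with per-disease case/control status and numeric lab values.
#' Status is 1 (case), 0 (control) or NA (subject not surveyed for that
#' disease); NA subjects are excluded from that disease's comparison so one
#' disease's cases never contaminate another's control group.
#'
#' @slot subjectIds character vector of subject identifiers.
#' @slot status subjects x diseases matrix with entries in \{0, 1, NA\}.
#' @slot labs subjects x labs numeric matrix (NA = missing measurement).
#'
#' @seealso [simulateSurvey()], [buildDiseaseVector()]
#' @export
setClass("CaseControlData",
    slots = c(subjectIds = "character", status = "matrix", labs = "matrix")
)

setValidity("CaseControlData", function(object) {
    msg <- character()
    n <- length(object@subjectIds)
    if (nrow(object@status) != n || nrow(object@labs) != n)
        msg <- c(msg, "status and labs must have one row per subject")
    ok <- object@status %in% c(0, 1) | is.na(object@status)
    if (length(object@status) && !all(ok))
        msg <- c(msg, "status entries must be 0, 1 or NA")
    if (ncol(object@labs) < 1L)
        msg <- c(msg, "at least one lab column is required")
    if (is.null(colnames(object@labs)) || is.null(colnames(object@status)))
        msg <- c(msg, "status and labs must have column names")
    if (length(msg)) msg else TRUE
})

#' Per-lab fit of the self-controlled case-series model
#'
#' Coefficients, p-values and the penalty used for one lab test; the support
#' indexes the drugs with nonzero coefficients.
#'
#' @slot labId the lab this fit describes.
#' @slot beta named coefficient vector, one entry per drug.
#' @slot pvalues named p-values in [0,1]; drugs off the support carry p = 1.
#' @slot lambda L1 penalty used, >= 0.
#' @slot support integer indices of the nonzero coefficients.
#' @export
setClass("CSCCSFit",
    slots = c(
        labId = "character", beta = "numeric", pvalues = "numeric",
        lambda = "numeric", support = "integer"
    )
)

setValidity("CSCCSFit", function(object) {
    msg <- character()
    if (length(object@beta) != length(object@pvalues))
        msg <- c(msg, "beta and pvalues must have equal length")
    if (any(object@pvalues < 0 | object@pvalues > 1, na.rm = TRUE))
        msg <- c(msg, "pvalues must be in [0, 1]")
    if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
    if (!identical(as.integer(unname(object@support)),
                   as.integer(unname(which(object@beta != 0)))))
        msg <- c(msg, "support must index the nonzero coefficients")
    if (length(msg)) msg else TRUE
})

#' Ternary sign vectors over a shared lab catalog
#'
#' Rows are entities (drugs or diseases), columns are harmonized lab tests,
#' entries are +1 (significant increase), -1 (significant decrease) or 0.
#' `details` optionally carries the per-test statistics behind each call.
#'
#' @slot entries entities x labs matrix with values in \{-1, 0, 1\}.
#' @slot kind "drug" or "disease".
#' @slot details data.frame of supporting statistics (may be empty).
#'
#' @seealso [buildDrugEffectVectors()], [buildDiseaseVectors()],
#'   [computeScoreMatrix()]
#' @export
setClass("SignVectorSet",
    slots = c(entries = "matrix", kind = "character", details = "data.frame")
)

setValidity("SignVectorSet", function(object) {
    msg <- character()
    if (length(object@entries) && !all(object@entries %in% c(-1, 0, 1)))
        msg <- c(msg, "entries must be -1, 0 or +1")
    if (is.null(rownames(object@entries)) || is.null(colnames(object@entries)))
        msg <- c(msg, "entries must have row and column names")
    if (!object@kind %in% c("drug", "disease"))
        msg <- c(msg, "kind must be 'drug' or 'disease'")
    if (length(msg)) msg else TRUE
})

#' Drug x disease repurposing possibility scores
#'
#' Entry (d, s) is the negative dot product of drug d's and disease s's sign
#' vectors: positive scores mean net complementarity (therapeutic potential),
#' negative scores net adversity.
#'
#' @slot scores numeric matrix, drugs in rows, diseases in columns.
#' @seealso [computeScoreMatrix()], [rankDrugs()]
#' @export
setClass("ScoreMatrix", slots = c(scores = "matrix"))

setValidity("ScoreMatrix", function(object) {
    msg <- character()
    if (length(object@scores) && !all(is.finite(object@scores)))
        msg <- c(msg, "scores must be finite")
    if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
        msg <- c(msg, "scores must have drug row names and disease column names")
    if (length(msg)) msg else TRUE
})

#' Gold-standard indication list
#'
#' Maps each disease to the set of drugs with a known indication, used as
#' ground truth by precision at K and the fold-enrichment test.
#'
#' @slot indications named list, disease id -> character vector of drug ids.
#' @seealso [simulateGoldStandard()], [precisionAtK()], [foldEnrichment()]
#' @export
setClass("GoldStandard", slots = c(indications = "list"))

setValidity("GoldStandard", function(object) {
    msg <- character()
    if (length(object@indications) &&
        (is.null(names(object@indications)) ||
         anyDuplicated(names(object@indications))))
        msg <- c(msg, "indications must be uniquely named by disease")
    if (!all(vapply(object@indications, is.character, logical(1L))))
        msg <- c(msg, "each indication entry must be a character vector of drug ids")
    if (length(msg)) msg else TRUE
})
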