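#' Read and write the package's table formats
#'
#' All interchange is plain UTF-8 text with a header row. The longitudinal
#' table is TSV with columns `patient_id`, `meas_index`, `lab_id`, `value`,
#' then one 0/1 column per drug id. The survey table is TSV with
#' `subject_id`, one `status_<disease>` column per disease (1 = case,
#' 0 = control, empty = not surveyed) and one numeric column per lab id.
#' The gold standard is a two-column CSV `disease_id, drug_id`. Sign-vector
#' sets and score matrices are CSVs with entity rows and lab/disease
#' columns. Alias maps are CSVs with columns `source_name, lab_id`.
#'
#' @param x object to write.
#' @param path file path.
#' @param kind for [readSignVectors()], `"drug"` or `"disease"`.
#' @name table-io
NULL

#' @rdname table-io
#' @export
writeLongitudinal <- function(x, path) {
    stopifnot(is(x, "LongitudinalLabData"))
    out <- cbind(x@records, as.data.frame(x@exposures))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname table-io
#' @export
readLongitudinal <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, fileEncoding = "UTF-8")
    need <- c("patient_id", "meas_index", "lab_id", "value")
    if (!all(need %in% names(tab)))
        stop("longitudinal table needs columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    drugs <- setdiff(names(tab), need)
    expo <- as.matrix(tab[, drugs, drop = FALSE])
    storage.mode(expo) <- "double"
    new("LongitudinalLabData",
        records = tab[, need],
        exposures = expo,
        drugCatalog = drugs,
        labCatalog = sort(unique(tab$lab_id)))
}

#' @rdname table-io
#' @export
writeSurvey <- function(x, path) {
    stopifnot(is(x, "CaseControlData"))
    st <- as.data.frame(x@status)
    names(st) <- paste0("status_", colnames(x@status))
    out <- cbind(data.frame(subject_id = x@subjectIds), st,
                 as.data.frame(x@labs))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname table-io
#' @export
readSurvey <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, fileEncoding = "UTF-8")
    if (!"subject_id" %in% names(tab))
        stop("survey table needs a subject_id column", call. = FALSE)
    stCols <- grep("^status_", names(tab), value = TRUE)
    if (!length(stCols))
        stop("survey table needs at least one status_<disease> column",
             call. = FALSE)
    labCols <- setdiff(names(tab), c("subject_id", stCols))
    status <- as.matrix(tab[, stCols, drop = FALSE])
    colnames(status) <- sub("^status_", "", stCols)
    labs <- as.matrix(tab[, labCols, drop = FALSE])
    storage.mode(status) <- "double"
    storage.mode(labs) <- "double"
    new("CaseControlData", subjectIds = as.character(tab$subject_id),
        status = status, labs = labs)
}

#' @rdname table-io
#' @export
writeGoldStandard <- function(x, path) {
    stopifnot(is(x, "GoldStandard"))
    ind <- x@indications
    out <- data.frame(
        disease_id = rep(names(ind), lengths(ind)),
        drug_id = unlist(ind, use.names = FALSE))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname table-io
#' @export
readGoldStandard <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("disease_id", "drug_id") %in% names(tab)))
        stop("gold standard needs columns disease_id, drug_id",
             call. = FALSE)
    new("GoldStandard",
        indications = lapply(split(tab$drug_id, tab$disease_id), unique))
}

#' @rdname table-io
#' @export
writeSignVectors <- function(x, path) {
    stopifnot(is(x, "SignVectorSet"))
    utils::write.csv(as.data.frame(x@entries), path, quote = FALSE)
    invisible(path)
}

#' @rdname table-io
#' @export
readSignVectors <- function(path, kind) {
    tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    new("SignVectorSet", entries = as.matrix(tab), kind = kind,
        details = data.frame())
}

#' @rdname table-io
#' @export
writeScoreMatrixCSV <- function(x, path) {
    stopifnot(is(x, "ScoreMatrix"))
    utils::write.csv(as.data.frame(x@scores), path, quote = FALSE)
    invisible(path)
}

#' @rdname table-io
#' @export
readScoreMatrixCSV <- function(path) {
    tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    new("ScoreMatrix", scores = as.matrix(tab))
}

#' @rdname table-io
#' @export
readAliasMap <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("source_name", "lab_id") %in% names(tab)))
        stop("alias map needs columns source_name, lab_id", call. = FALSE)
    tab
}
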