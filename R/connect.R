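#' Harmonize two lab catalogs through alias maps
#'
#' Maps each source's lab names onto standard identifiers and keeps the
#' intersection, sorted for determinism. Entries flagged non-numeric (an
#' optional `numeric` logical column in either alias table) are excluded.
#'
#' @param aliasA,aliasB data.frames with columns `source_name`, `lab_id`
#'   (and optionally `numeric`).
#' @return character vector of shared standard lab ids, sorted.
#' @export
harmonizeLabs <- function(aliasA, aliasB) {
    pick <- function(a) {
        if (!all(c("source_name", "lab_id") %in% names(a)))
            stop("alias tables need columns source_name, lab_id",
                 call. = FALSE)
        ids <- a$lab_id
        if ("numeric" %in% names(a)) ids <- ids[as.logical(a$numeric)]
        unique(ids)
    }
    shared <- sort(intersect(pick(aliasA), pick(aliasB)))
    if (!length(shared))
        stop("no shared labs after harmonization; scoring is impossible",
             call. = FALSE)
    shared
}

#' Rename and restrict a sign-vector set to a harmonized catalog
#'
#' @param sv a [SignVectorSet-class] whose columns are source lab names.
#' @param alias data.frame with columns `source_name`, `lab_id`.
#' @param catalog harmonized lab ids (from [harmonizeLabs()]).
#' @return a [SignVectorSet-class] with columns exactly `catalog`.
#' @export
mapLabs <- function(sv, alias, catalog) {
    stopifnot(is(sv, "SignVectorSet"))
    m <- setNames(alias$lab_id, alias$source_name)
    e <- sv@entries
    hit <- colnames(e) %in% names(m)
    e <- e[, hit, drop = FALSE]
    colnames(e) <- m[colnames(e)]
    missing <- setdiff(catalog, colnames(e))
    if (length(missing))
        stop("catalog labs absent from this source: ",
             paste(missing, collapse = ", "), call. = FALSE)
    new("SignVectorSet", entries = e[, catalog, drop = FALSE],
        kind = sv@kind, details = sv@details)
}

#' Repurposing possibility score of one drug-disease pair
#'
#' The negative dot product of the two ternary sign vectors:
#' \deqn{TS = - CV_{drug} \cdot CV_{disease}.}
#' Each lab where the two vectors point in opposite directions
#' (complementary) adds +1; each lab where they agree (adverse) adds -1;
#' labs where either is 0 contribute nothing. Positive scores therefore
#' mean more complementary than adverse relations.
#'
#' @param drug,disease named ternary vectors over the same lab catalog
#'   (identical names, same order).
#' @return a single number.
#' @export
repurposingScore <- function(drug, disease) {
    if (!identical(names(drug), names(disease)) || is.null(names(drug)))
        stop("drug and disease vectors must share an identical lab catalog",
             call. = FALSE)
    -sum(drug * disease)
}

#' Score every drug against every disease
#'
#' @param drugs a [SignVectorSet-class] of kind `"drug"`.
#' @param diseases a [SignVectorSet-class] of kind `"disease"`; must share
#'   the drugs' lab catalog.
#' @return a [ScoreMatrix-class] (drugs x diseases).
#' @export
computeScoreMatrix <- function(drugs, diseases) {
    stopifnot(is(drugs, "SignVectorSet"), is(diseases, "SignVectorSet"))
    if (!identical(colnames(drugs@entries), colnames(diseases@entries)))
        stop("drug and disease vectors must share an identical lab catalog",
             call. = FALSE)
    s <- -drugs@entries %*% t(diseases@entries)
    new("ScoreMatrix", scores = s)
}

#' Rank drugs for one disease
#'
#' Descending by repurposing score; ties are broken by ascending drug id so
#' rankings are reproducible regardless of input order.
#'
#' @param sm a [ScoreMatrix-class].
#' @param diseaseId disease column to rank.
#' @return data.frame with columns `rank`, `drug_id`, `score`.
#' @export
rankDrugs <- function(sm, diseaseId) {
    stopifnot(is(sm, "ScoreMatrix"))
    if (!diseaseId %in% colnames(sm@scores))
        stop("unknown disease id: ", diseaseId, call. = FALSE)
    s <- sm@scores[, diseaseId]
    ord <- order(-s, names(s))
    data.frame(rank = seq_along(ord), drug_id = names(s)[ord],
               score = unname(s[ord]), stringsAsFactors = FALSE)
}
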