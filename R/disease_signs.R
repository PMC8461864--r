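#' Wilcoxon rank-sum comparison of case and control lab values
#'
#' Computes both Mann-Whitney U statistics from midranks (so
#' `U_case + U_control = n_case * n_control` holds exactly, ties included)
#' and a two-sided p-value: the exact null distribution when the smaller
#' group has at most 20 observations and there are no ties (reproducing
#' classical U-table look-ups), otherwise the normal approximation with tie
#' and continuity corrections. Missing values are dropped per group.
#'
#' @param caseValues,controlValues numeric vectors; each group must be
#'   nonempty after dropping NAs.
#' @return list with `U_case`, `U_control`, `pvalue`, `mean_case`,
#'   `mean_control`, `n_case`, `n_control`.
#' @export
rankSumTest <- function(caseValues, controlValues) {
    caseValues <- caseValues[!is.na(caseValues)]
    controlValues <- controlValues[!is.na(controlValues)]
    if (!length(caseValues)) stop("case group is empty", call. = FALSE)
    if (!length(controlValues)) stop("control group is empty", call. = FALSE)
    n1 <- length(caseValues)
    n2 <- length(controlValues)
    r <- rank(c(caseValues, controlValues))
    uCase <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    uControl <- n1 * n2 - uCase
    ties <- anyDuplicated(c(caseValues, controlValues)) > 0L
    exact <- min(n1, n2) <= 20L && !ties
    p <- suppressWarnings(stats::wilcox.test(
        caseValues, controlValues, alternative = "two.sided",
        exact = exact, correct = TRUE)$p.value)
    list(U_case = uCase, U_control = uControl, pvalue = p,
         mean_case = mean(caseValues), mean_control = mean(controlValues),
         n_case = n1, n_control = n2)
}

#' Call the ternary disease direction for one lab
#'
#' +1 when the case group is significantly higher than the control group at
#' `alpha`, -1 when significantly lower, 0 otherwise. A significant p with
#' exactly equal group means is called 0 (and noted), since no direction can
#' be assigned.
#'
#' @param result output of [rankSumTest()].
#' @param alpha significance cut-off (default 0.05).
#' @return +1, -1 or 0.
#' @export
callDiseaseDirection <- function(result, alpha = 0.05) {
    if (result$pvalue >= alpha) return(0)
    if (result$mean_case > result$mean_control) return(1)
    if (result$mean_case < result$mean_control) return(-1)
    message("significant rank-sum p with exactly tied means; calling 0")
    0
}

#' Build the clinical sign vector for one disease
#'
#' Applies [rankSumTest()] and [callDiseaseDirection()] to every lab in the
#' catalog, comparing that disease's cases (status 1) with its controls
#' (status 0); subjects with NA status are excluded. A lab where either
#' group is empty after dropping missing values yields 0 with a warning.
#'
#' @param dataset a [CaseControlData-class].
#' @param diseaseId status column to use.
#' @param alpha significance cut-off.
#' @return list with `signs` (named ternary vector over the lab catalog) and
#'   `details` (per-lab data.frame of U statistics, p and group means).
#' @export
buildDiseaseVector <- function(dataset, diseaseId, alpha = 0.05) {
    stopifnot(is(dataset, "CaseControlData"))
    if (!diseaseId %in% colnames(dataset@status))
        stop("unknown disease id: ", diseaseId, call. = FALSE)
    st <- dataset@status[, diseaseId]
    if (!any(st %in% 1) || !any(st %in% 0))
        stop("disease ", diseaseId, " needs both cases and controls",
             call. = FALSE)
    labs <- colnames(dataset@labs)
    signs <- setNames(numeric(length(labs)), labs)
    det <- vector("list", length(labs))
    for (li in seq_along(labs)) {
        cv <- dataset@labs[st %in% 1, li]
        kv <- dataset@labs[st %in% 0, li]
        res <- tryCatch(rankSumTest(cv, kv), error = function(e) {
            warning("lab ", labs[li], " for ", diseaseId, ": ",
                    conditionMessage(e), "; calling 0", call. = FALSE)
            NULL
        })
        if (is.null(res)) {
            det[[li]] <- data.frame(disease = diseaseId, lab = labs[li],
                                    U_case = NA_real_, U_control = NA_real_,
                                    p = NA_real_, mean_case = NA_real_,
                                    mean_control = NA_real_)
            next
        }
        signs[li] <- callDiseaseDirection(res, alpha)
        det[[li]] <- data.frame(disease = diseaseId, lab = labs[li],
                                U_case = res$U_case, U_control = res$U_control,
                                p = res$pvalue, mean_case = res$mean_case,
                                mean_control = res$mean_control)
    }
    list(signs = signs, details = do.call(rbind, det))
}

#' Build clinical disease sign vectors for every disease
#'
#' Diseases with fewer than `minSamples` subjects (cases plus controls) are
#' excluded, mirroring the practice of keeping only conditions with enough
#' survey coverage.
#'
#' @param dataset a [CaseControlData-class].
#' @param alpha significance cut-off.
#' @param minSamples minimum subjects per disease (default 1000; lower it
#'   for small synthetic datasets).
#' @return a [SignVectorSet-class] of kind `"disease"` with per-lab test
#'   statistics in `details`.
#' @export
buildDiseaseVectors <- function(dataset, alpha = 0.05, minSamples = 1000L) {
    stopifnot(is(dataset, "CaseControlData"))
    diseases <- colnames(dataset@status)
    nSub <- colSums(!is.na(dataset@status))
    keep <- diseases[nSub >= minSamples]
    if (!length(keep))
        stop("no disease meets the minimum of ", minSamples, " subjects",
             call. = FALSE)
    labs <- colnames(dataset@labs)
    entries <- matrix(0, length(keep), length(labs),
                      dimnames = list(keep, labs))
    det <- vector("list", length(keep))
    for (di in seq_along(keep)) {
        v <- buildDiseaseVector(dataset, keep[di], alpha)
        entries[di, ] <- v$signs
        det[[di]] <- v$details
    }
    new("SignVectorSet", entries = entries, kind = "disease",
        details = do.call(rbind, det))
}
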