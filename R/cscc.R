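#' Assemble the stacked design for one lab test
#'
#' Stacks all measurements of `labId` into a response vector `y`, the
#' row-aligned binary exposure matrix `X`, and a patient membership vector
#' standing in for the block-diagonal patient-intercept design. Rows are
#' ordered by (patient, measurement index); records with a missing value for
#' this lab are dropped.
#'
#' @param dataset a [LongitudinalLabData-class].
#' @param labId lab to extract; must be in the catalog.
#' @return list with `y` (numeric), `X` (0/1 matrix, one column per drug)
#'   and `patientIndex` (character, one entry per row).
#' @export
buildDesign <- function(dataset, labId) {
    stopifnot(is(dataset, "LongitudinalLabData"))
    if (!labId %in% dataset@labCatalog)
        stop("unknown lab id: ", labId, call. = FALSE)
    rec <- dataset@records
    keep <- which(rec$lab_id == labId & !is.na(rec$value))
    if (!length(keep))
        stop("empty design: no measurements for lab ", labId, call. = FALSE)
    ord <- keep[order(rec$patient_id[keep], rec$meas_index[keep])]
    list(y = rec$value[ord],
         X = dataset@exposures[ord, , drop = FALSE],
         patientIndex = rec$patient_id[ord])
}

#' Remove per-patient baselines by within-patient centering
#'
#' Subtracts each patient's own mean from their responses and exposure
#' columns. This absorbs the per-patient intercepts exactly: the centered
#' least-squares problem has the same drug-coefficient solution as the full
#' fixed-effects problem with one explicit intercept per patient. Patients
#' with a single measurement center to all-zero rows and contribute nothing.
#'
#' @param y,X,patientIndex stacked design from [buildDesign()].
#' @return list with centered `yc` and `Xc`; within every patient each
#'   column sums to zero to machine precision.
#' @export
centerWithinPatient <- function(y, X, patientIndex) {
    yc <- y - stats::ave(y, patientIndex)
    Xc <- X
    for (m in seq_len(ncol(X)))
        Xc[, m] <- X[, m] - stats::ave(X[, m], patientIndex)
    list(yc = yc, Xc = Xc)
}

# Lasso coefficients on the centered problem at each penalty in `lambdas`
# (objective 0.5*||yc - Xc b||^2 + lambda*||b||_1). Single-column designs use
# the soft-threshold closed form; otherwise glmnet with the penalty rescaled
# by n (glmnet minimizes RSS/(2n) + s*||b||_1).
lassoPathCoefs <- function(yc, Xc, lambdas) {
    n <- length(yc)
    M <- ncol(Xc)
    if (M == 1L) {
        z <- sum(Xc[, 1L] * yc)
        xx <- sum(Xc[, 1L]^2)
        b <- if (xx == 0) rep(0, length(lambdas))
             else sign(z) * pmax(abs(z) - lambdas, 0) / xx
        return(matrix(b, 1L, length(lambdas),
                      dimnames = list(colnames(Xc), NULL)))
    }
    fit <- glmnet::glmnet(Xc, yc, family = "gaussian", alpha = 1,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
    cf <- glmnet::coef.glmnet(fit, s = lambdas / n, exact = TRUE,
                              x = Xc, y = yc, standardize = FALSE,
                              intercept = FALSE, thresh = 1e-12)
    out <- as.matrix(cf)[-1L, , drop = FALSE]
    rownames(out) <- colnames(Xc)
    out
}

#' Fit the L1-penalized self-controlled model on centered data
#'
#' Solves \deqn{\hat\beta = \arg\min_\beta \tfrac12 \|y_c - X_c\beta\|_2^2 +
#' \lambda \|\beta\|_1.} At `lambda = 0` this is the least-squares solution
#' of the centered problem (minimum-norm if the design is rank deficient,
#' with a warning), which equals the drug-coefficient block of the full
#' fixed-effects fit with explicit per-patient intercepts.
#'
#' @param yc,Xc centered response and design from [centerWithinPatient()].
#' @param lambda L1 penalty, >= 0. Any `lambda >=` the maximum absolute
#'   column-response inner product returns an exactly zero vector.
#' @return named coefficient vector of length `ncol(Xc)`.
#' @export
fitCSCCS <- function(yc, Xc, lambda) {
    if (!all(is.finite(yc)) || !all(is.finite(Xc)))
        stop("non-finite values in the centered design", call. = FALSE)
    if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
        stop("lambda must be a single number >= 0", call. = FALSE)
    if (lambda == 0) {
        sv <- svd(Xc)
        tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
        pos <- sv$d > tol
        if (sum(pos) < ncol(Xc))
            warning("rank-deficient centered design; returning the ",
                    "minimum-norm least-squares solution")
        beta <- drop(sv$v[, pos, drop = FALSE] %*%
                     (crossprod(sv$u[, pos, drop = FALSE], yc) / sv$d[pos]))
    } else {
        beta <- drop(lassoPathCoefs(yc, Xc, lambda))
    }
    names(beta) <- colnames(Xc)
    beta
}

#' Logarithmic penalty grid for cross-validation
#'
#' Descends from the smallest penalty that zeroes every coefficient
#' (`max |Xc' yc|`) down to `ratio` times it.
#'
#' @param yc,Xc centered data.
#' @param nLambda grid length.
#' @param ratio smallest/largest penalty ratio.
#' @return decreasing numeric vector.
#' @export
lambdaGrid <- function(yc, Xc, nLambda = 20L, ratio = 1e-3) {
    lmax <- max(abs(crossprod(Xc, yc)))
    if (lmax == 0) return(0)
    exp(seq(log(lmax), log(lmax * ratio), length.out = nLambda))
}

#' Select the L1 penalty by patient-grouped cross-validation
#'
#' Patients (not rows) are partitioned into folds, respecting the
#' self-controlled structure: all of a patient's measurements are held out
#' together. Returns the grid value with the smallest cross-validated mean
#' squared error; ties go to the larger (sparser) penalty. Deterministic
#' given the seed.
#'
#' @param yc,Xc,patientIndex centered design and patient membership.
#' @param grid candidate penalties; defaults to [lambdaGrid()].
#' @param nFolds number of folds (>= 2).
#' @param seed integer seed for the patient partition.
#' @return the selected penalty (a single number from the grid).
#' @export
selectLambda <- function(yc, Xc, patientIndex, grid = NULL, nFolds = 5L,
                         seed = 1L) {
    if (is.null(grid)) grid <- lambdaGrid(yc, Xc)
    if (!length(grid)) stop("empty penalty grid", call. = FALSE)
    if (nFolds < 2L) stop("nFolds must be >= 2", call. = FALSE)
    if (length(grid) == 1L) return(grid)
    patients <- unique(patientIndex)
    if (length(patients) < nFolds)
        stop("fewer patients (", length(patients), ") than folds (",
             nFolds, ")", call. = FALSE)
    foldOf <- withSeed(seed,
        sample(rep(seq_len(nFolds), length.out = length(patients))))
    names(foldOf) <- patients
    rowFold <- foldOf[patientIndex]
    grid <- sort(grid, decreasing = TRUE)
    sse <- numeric(length(grid))
    nte <- 0L
    for (f in seq_len(nFolds)) {
        te <- rowFold == f
        if (!any(te) || all(te)) next
        cf <- lassoPathCoefs(yc[!te], Xc[!te, , drop = FALSE], grid)
        resid <- yc[te] - Xc[te, , drop = FALSE] %*% cf
        sse <- sse + colSums(resid^2)
        nte <- nte + sum(te)
    }
    cv <- sse / nte
    grid[which(cv <= min(cv) + 1e-12)[1L]]   # first index = largest penalty
}

#' Post-selection p-values for the penalized coefficients
#'
#' Refits unpenalized least squares on the selected support over the centered
#' data and applies classical t-tests, with the residual degrees of freedom
#' reduced by the number of patients whose intercepts the centering absorbed.
#' Drugs off the support receive p = 1. If the support exceeds the residual
#' degrees of freedom, or the support columns are collinear, every p-value is
#' 1 and a warning is raised.
#'
#' @param beta penalized coefficients from [fitCSCCS()] on the same data.
#' @param yc,Xc,patientIndex the centered design the fit used.
#' @return named p-value vector in [0, 1], one entry per drug.
#' @export
coefPvalues <- function(beta, yc, Xc, patientIndex) {
    M <- ncol(Xc)
    p <- setNames(rep(1, M), colnames(Xc))
    S <- which(beta != 0)
    if (!length(S)) return(p)
    nPat <- length(unique(patientIndex))
    df <- length(yc) - nPat - length(S)
    if (df <= 0) {
        warning("support size exceeds residual degrees of freedom; ",
                "all p-values set to 1")
        return(p)
    }
    Xs <- Xc[, S, drop = FALSE]
    XtX <- crossprod(Xs)
    R <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(R)) {
        warning("collinear support columns; all p-values set to 1")
        return(p)
    }
    bs <- backsolve(R, forwardsolve(t(R), crossprod(Xs, yc)))
    res <- yc - Xs %*% bs
    sigma2 <- sum(res^2) / df
    se <- sqrt(diag(chol2inv(R)) * sigma2)
    tstat <- ifelse(se > 0, bs / se, ifelse(bs == 0, 0, Inf * sign(bs)))
    p[S] <- 2 * stats::pt(-abs(tstat), df)
    p
}

#' Call ternary drug directions for one lab
#'
#' A drug is called +1 when its coefficient is positive and significant at
#' `alpha`, -1 when negative and significant, 0 otherwise (insignificant or
#' exactly zero).
#'
#' @param fit a [CSCCSFit-class].
#' @param alpha significance cut-off (default 0.05).
#' @return named vector of +1/-1/0, one entry per drug.
#' @export
callDrugDirections <- function(fit, alpha = 0.05) {
    stopifnot(is(fit, "CSCCSFit"))
    sig <- fit@pvalues < alpha
    out <- ifelse(sig & fit@beta > 0, 1, ifelse(sig & fit@beta < 0, -1, 0))
    setNames(as.numeric(out), names(fit@beta))
}

#' Build clinical drug effect vectors for every lab
#'
#' Runs the full per-lab chain — design assembly, within-patient centering,
#' penalty selection, penalized fit, post-selection p-values, direction
#' calls — over the lab catalog. Drugs prescribed to fewer than
#' `minPatientsPerDrug` distinct patients are excluded before fitting. A lab
#' whose fit fails (e.g. no measurements) yields an all-zero column with a
#' warning.
#'
#' @param dataset a [LongitudinalLabData-class].
#' @param alpha significance cut-off for direction calls.
#' @param lambda `"cv"` for patient-grouped cross-validation (see
#'   [selectLambda()]) or a fixed non-negative number.
#' @param grid optional penalty grid for cross-validation.
#' @param nFolds cross-validation folds.
#' @param minPatientsPerDrug minimum distinct exposed patients per drug
#'   (default 1000, mirroring large-scale EHR practice; lower it for small
#'   synthetic datasets).
#' @param seed integer seed driving the fold partitions (one derived seed
#'   per lab).
#' @return a [SignVectorSet-class] of kind `"drug"` (retained drugs x labs)
#'   whose `details` hold (lab, drug, beta, p, lambda) for every fitted pair.
#' @export
buildDrugEffectVectors <- function(dataset, alpha = 0.05, lambda = "cv",
                                   grid = NULL, nFolds = 5L,
                                   minPatientsPerDrug = 1000L, seed = 1L) {
    stopifnot(is(dataset, "LongitudinalLabData"))
    if (!nrow(dataset@records)) stop("empty dataset", call. = FALSE)
    rec <- dataset@records
    expo <- dataset@exposures
    nPat <- vapply(seq_len(ncol(expo)), function(m)
        length(unique(rec$patient_id[expo[, m] == 1])), integer(1L))
    keep <- nPat >= minPatientsPerDrug
    if (!any(keep))
        stop("no drug meets the minimum of ", minPatientsPerDrug,
             " exposed patients", call. = FALSE)
    drugs <- dataset@drugCatalog[keep]
    labs <- dataset@labCatalog
    entries <- matrix(0, length(drugs), length(labs),
                      dimnames = list(drugs, labs))
    det <- vector("list", length(labs))
    for (li in seq_along(labs)) {
        lab <- labs[li]
        res <- tryCatch({
            des <- buildDesign(dataset, lab)
            X <- des$X[, keep, drop = FALSE]
            cen <- centerWithinPatient(des$y, X, des$patientIndex)
            lam <- if (identical(lambda, "cv"))
                selectLambda(cen$yc, cen$Xc, des$patientIndex, grid = grid,
                             nFolds = nFolds, seed = seed + li)
            else as.numeric(lambda)
            beta <- fitCSCCS(cen$yc, cen$Xc, lam)
            pv <- coefPvalues(beta, cen$yc, cen$Xc, des$patientIndex)
            fit <- new("CSCCSFit", labId = lab, beta = beta, pvalues = pv,
                       lambda = lam, support = which(beta != 0))
            list(dir = callDrugDirections(fit, alpha), fit = fit)
        }, error = function(e) {
            warning("skipping lab ", lab, ": ", conditionMessage(e),
                    call. = FALSE)
            NULL
        })
        if (is.null(res)) next
        entries[, li] <- res$dir[drugs]
        det[[li]] <- data.frame(lab = lab, drug = drugs,
                                beta = unname(res$fit@beta[drugs]),
                                p = unname(res$fit@pvalues[drugs]),
                                lambda = res$fit@lambda,
                                stringsAsFactors = FALSE)
    }
    details <- do.call(rbind, det[!vapply(det, is.null, logical(1L))])
    if (is.null(details)) details <- data.frame()
    new("SignVectorSet", entries = entries, kind = "drug", details = details)
}
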