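#' Construct an EHR simulation configuration
#'
#' @param nPatients,nDrugs,nLabs counts (N patients, M drugs, number of labs).
#' @param measRange inclusive range the per-patient measurement count J_i is
#'   drawn from (uniformly), to exercise unbalanced panels.
#' @param baselineMean,baselineSd normal distribution of the per-patient,
#'   per-lab baseline level.
#' @param noiseSd standard deviation of the i.i.d. Gaussian measurement noise.
#' @param exposureProb probability a drug is active at any given measurement;
#'   exposures are independent Bernoulli draws per drug per measurement.
#' @param seed integer seed; the generator is fully reproducible.
#' @return an [EHRSimConfig-class] object.
#' @export
ehrSimConfig <- function(nPatients, nDrugs, nLabs, measRange = c(5L, 10L),
                         baselineMean = 50, baselineSd = 5, noiseSd = 1,
                         exposureProb = 0.3, seed = 1L) {
    new("EHRSimConfig",
        nPatients = asCount(nPatients, "nPatients"),
        nDrugs = asCount(nDrugs, "nDrugs"),
        nLabs = asCount(nLabs, "nLabs"),
        measRange = as.integer(measRange),
        baselineMean = as.numeric(baselineMean),
        baselineSd = as.numeric(baselineSd),
        noiseSd = as.numeric(noiseSd),
        exposureProb = as.numeric(exposureProb),
        seed = as.integer(seed))
}

#' Construct a survey simulation configuration
#'
#' @param nCases,nControls group sizes.
#' @param labMeans named per-lab means (names define the lab catalog).
#' @param labSds per-lab standard deviations; recycled if scalar.
#' @param diseaseShifts per-lab offsets added to the case group; recycled if
#'   scalar. Zero everywhere gives a null (no-effect) survey.
#' @param seed integer seed.
#' @return a [SurveySimConfig-class] object.
#' @export
surveySimConfig <- function(nCases, nControls, labMeans, labSds = 1,
                            diseaseShifts = 0, seed = 1L) {
    labs <- names(labMeans)
    if (is.null(labs)) stop("labMeans must be named by lab id", call. = FALSE)
    fill <- function(x) {
        if (length(x) == 1L) x <- rep(x, length(labMeans))
        if (is.null(names(x))) names(x) <- labs
        x[labs]
    }
    new("SurveySimConfig",
        nCases = asCount(nCases, "nCases"),
        nControls = asCount(nControls, "nControls"),
        labMeans = labMeans, labSds = fill(labSds),
        diseaseShifts = fill(diseaseShifts), seed = as.integer(seed))
}

#' Plant a sparse drug x lab effect matrix
#'
#' Places `nEffects` nonzero entries of magnitude `effectSize` (random signs)
#' at random (drug, lab) cells; all other entries are exactly zero, matching
#' the assumption that only a small portion of drugs moves any given lab.
#'
#' @param nDrugs,nLabs matrix dimensions.
#' @param nEffects number of nonzero entries.
#' @param effectSize absolute effect magnitude, in lab units.
#' @param seed integer seed.
#' @param drugIds,labIds optional dimension names.
#' @return a drugs x labs numeric matrix.
#' @export
sparseTrueEffects <- function(nDrugs, nLabs, nEffects, effectSize = 1,
                              seed = 1L, drugIds = NULL, labIds = NULL) {
    nDrugs <- asCount(nDrugs, "nDrugs"); nLabs <- asCount(nLabs, "nLabs")
    if (nEffects > nDrugs * nLabs)
        stop("nEffects exceeds the number of cells", call. = FALSE)
    if (is.null(drugIds)) drugIds <- sprintf("drug%02d", seq_len(nDrugs))
    if (is.null(labIds)) labIds <- sprintf("lab%02d", seq_len(nLabs))
    eff <- matrix(0, nDrugs, nLabs, dimnames = list(drugIds, labIds))
    withSeed(seed, {
        cells <- sample(nDrugs * nLabs, nEffects)
        eff[cells] <- sample(c(-1, 1), nEffects, replace = TRUE) * effectSize
    })
    eff
}

#' Simulate a longitudinal prescription/lab dataset
#'
#' Draws data exactly from the per-patient-baseline linear model: for patient
#' i, measurement j and lab l,
#' \deqn{y_{ijl} = \alpha_{il} + \beta_l^\top x_{ij} + \epsilon_{ijl}}
#' with \eqn{\alpha_{il} \sim N(\mu_\alpha, \sigma_\alpha^2)} per patient and
#' lab, \eqn{x_{ijm} \sim} Bernoulli(exposureProb) i.i.d. per drug and
#' measurement (shared across labs at a measurement), and
#' \eqn{\epsilon \sim N(0, \sigma^2)}. With `noiseSd = 0` the data are an
#' exact solution of the model, so a fixed-effects least-squares fit recovers
#' the planted effects to machine precision.
#'
#' @param config an [EHRSimConfig-class].
#' @param effects drugs x labs matrix of planted effects; dimensions must
#'   match the config (see [sparseTrueEffects()]).
#' @return a [LongitudinalLabData-class]; `nPatients = 0` yields a valid
#'   empty dataset.
#' @export
simulateEHR <- function(config, effects) {
    stopifnot(is(config, "EHRSimConfig"))
    validObject(config)
    if (!is.matrix(effects) ||
        nrow(effects) != config@nDrugs || ncol(effects) != config@nLabs)
        stop("effects must be a ", config@nDrugs, " x ", config@nLabs,
             " matrix matching the config", call. = FALSE)
    drugIds <- rownames(effects)
    labIds <- colnames(effects)
    if (is.null(drugIds)) drugIds <- sprintf("drug%02d", seq_len(config@nDrugs))
    if (is.null(labIds)) labIds <- sprintf("lab%02d", seq_len(config@nLabs))

    N <- config@nPatients; M <- config@nDrugs; L <- config@nLabs
    recs <- vector("list", N)
    expo <- vector("list", N)
    withSeed(config@seed, {
        jChoices <- seq(config@measRange[1L], config@measRange[2L])
        for (i in seq_len(N)) {
            Ji <- jChoices[sample.int(length(jChoices), 1L)]
            alpha <- rnorm(L, config@baselineMean, config@baselineSd)
            X <- matrix(rbinom(Ji * M, 1L, config@exposureProb), Ji, M)
            drift <- X %*% effects                         # Ji x L
            noise <- if (config@noiseSd > 0)
                matrix(rnorm(Ji * L, 0, config@noiseSd), Ji, L)
            else matrix(0, Ji, L)
            vals <- sweep(drift + noise, 2L, alpha, "+")   # Ji x L
            recs[[i]] <- data.frame(
                patient_id = sprintf("p%04d", i),
                meas_index = rep(seq_len(Ji), each = L),
                lab_id = rep(labIds, Ji),
                value = as.vector(t(vals)),
                stringsAsFactors = FALSE)
            expo[[i]] <- X[rep(seq_len(Ji), each = L), , drop = FALSE]
        }
    })
    records <- if (N) do.call(rbind, recs) else
        data.frame(patient_id = character(), meas_index = integer(),
                   lab_id = character(), value = numeric())
    exposures <- if (N) do.call(rbind, expo) else
        matrix(0L, 0L, M)
    colnames(exposures) <- drugIds
    new("LongitudinalLabData", records = records, exposures = exposures,
        drugCatalog = drugIds, labCatalog = labIds)
}

#' Simulate a case/control survey for one disease
#'
#' Cases are drawn from Normal(labMeans + diseaseShifts, labSds), controls
#' from Normal(labMeans, labSds), independently per lab.
#'
#' @param config a [SurveySimConfig-class].
#' @param diseaseId column name for the status column.
#' @return a [CaseControlData-class] with one status column.
#' @export
simulateSurvey <- function(config, diseaseId = "disease1") {
    stopifnot(is(config, "SurveySimConfig"))
    validObject(config)
    labs <- names(config@labMeans)
    L <- length(labs)
    nC <- config@nCases; nK <- config@nControls
    withSeed(config@seed, {
        caseVals <- matrix(rnorm(nC * L,
                                 rep(config@labMeans + config@diseaseShifts, each = nC),
                                 rep(config@labSds, each = nC)), nC, L)
        ctrlVals <- matrix(rnorm(nK * L,
                                 rep(config@labMeans, each = nK),
                                 rep(config@labSds, each = nK)), nK, L)
    })
    labsMat <- rbind(caseVals, ctrlVals)
    colnames(labsMat) <- labs
    status <- matrix(c(rep(1, nC), rep(0, nK)), ncol = 1L,
                     dimnames = list(NULL, diseaseId))
    ids <- c(sprintf("%s_case_%04d", diseaseId, seq_len(nC)),
             sprintf("%s_ctrl_%04d", diseaseId, seq_len(nK)))
    new("CaseControlData", subjectIds = ids, status = status, labs = labsMat)
}

#' Stack per-disease surveys into one dataset
#'
#' Subjects keep NA status for diseases they were not surveyed for, so each
#' disease's comparison uses only its own cases and controls.
#'
#' @param ... [CaseControlData-class] objects sharing a lab catalog.
#' @return a combined [CaseControlData-class].
#' @export
bindSurveys <- function(...) {
    parts <- list(...)
    if (length(parts) == 1L && is.list(parts[[1L]]) && !is(parts[[1L]], "CaseControlData"))
        parts <- parts[[1L]]
    labs <- colnames(parts[[1L]]@labs)
    diseases <- unlist(lapply(parts, function(p) colnames(p@status)))
    if (anyDuplicated(diseases))
        stop("duplicate disease columns across surveys", call. = FALSE)
    n <- sum(vapply(parts, function(p) length(p@subjectIds), integer(1L)))
    status <- matrix(NA_real_, n, length(diseases),
                     dimnames = list(NULL, diseases))
    labsMat <- matrix(NA_real_, n, length(labs), dimnames = list(NULL, labs))
    ids <- character(n)
    at <- 0L
    for (p in parts) {
        if (!identical(colnames(p@labs), labs))
            stop("surveys must share an identical lab catalog", call. = FALSE)
        idx <- at + seq_along(p@subjectIds)
        ids[idx] <- p@subjectIds
        status[idx, colnames(p@status)] <- p@status
        labsMat[idx, ] <- p@labs
        at <- at + length(idx)
    }
    new("CaseControlData", subjectIds = ids, status = status, labs = labsMat)
}

#' Derive the gold standard implied by planted truth
#'
#' A drug is listed as indicated for a disease exactly when the repurposing
#' score of the two *true* sign patterns is strictly positive, i.e. the drug's
#' planted effects oppose the disease's planted shifts on more labs than they
#' reinforce them. Ties at zero are excluded.
#'
#' @param effects drugs x labs matrix of planted drug effects.
#' @param shiftsByDisease named list, disease id -> named per-lab shift
#'   vector (labs must cover the effect matrix columns).
#' @return a [GoldStandard-class].
#' @export
simulateGoldStandard <- function(effects, shiftsByDisease) {
    labs <- colnames(effects)
    drugSigns <- sign(effects)
    ind <- lapply(shiftsByDisease, function(sh) {
        s <- sign(sh[labs])
        ts <- -as.vector(drugSigns %*% s)
        rownames(effects)[ts > 0]
    })
    new("GoldStandard", indications = ind)
}

#' Simulate a complete linked study with planted truth
#'
#' Builds the full synthetic scenario the package's end-to-end checks run on:
#' a longitudinal EHR arm, a stacked multi-disease survey arm on the same lab
#' catalog, and the gold standard implied by the planted truth. Each disease
#' shifts its own block of `labsPerDisease` labs (alternating directions,
#' magnitude `shiftSize`); for each disease, `drugsPerDisease` drugs are
#' planted whose effects oppose three of that disease's shifted labs (true
#' score +3), plus `nInertDrugs` drugs with no effects at all. Opposing
#' three labs leaves the designed drugs clearly separated from the odd
#' spurious match a false-positive direction call can produce.
#'
#' @param nPatients EHR patients.
#' @param nDiseases,labsPerDisease,drugsPerDisease,nInertDrugs scenario shape.
#' @param measRange,baselineMean,baselineSd,noiseSd,exposureProb,effectSize
#'   EHR arm parameters, as in [ehrSimConfig()] / [sparseTrueEffects()].
#' @param nCases,nControls,labMean,labSd,shiftSize survey arm parameters.
#' @param seed integer master seed; per-disease survey seeds are derived as
#'   small offsets.
#' @return list with elements `ehr`, `survey`, `gold`, `effects` (planted
#'   drug x lab matrix) and `shifts` (list of per-disease shift vectors).
#' @export
simulateStudy <- function(nPatients = 300, nDiseases = 3, labsPerDisease = 4,
                          drugsPerDisease = 5, nInertDrugs = 3,
                          measRange = c(5L, 10L), baselineMean = 50,
                          baselineSd = 5, noiseSd = 1, exposureProb = 0.3,
                          effectSize = 1, nCases = 500, nControls = 500,
                          labMean = 50, labSd = 5, shiftSize = 2.5,
                          seed = 1L) {
    nLabs <- nDiseases * labsPerDisease
    nDrugs <- nDiseases * drugsPerDisease + nInertDrugs
    labIds <- sprintf("lab%02d", seq_len(nLabs))
    diseaseIds <- sprintf("disease%d", seq_len(nDiseases))
    drugIds <- sprintf("drug%02d", seq_len(nDrugs))

    shifts <- list()
    effects <- matrix(0, nDrugs, nLabs, dimnames = list(drugIds, labIds))
    # three opposed labs per designed drug; triples cycle within the block
    pairs <- list(c(1L, 2L, 3L), c(2L, 3L, 4L), c(1L, 3L, 4L),
                  c(1L, 2L, 4L))
    for (d in seq_len(nDiseases)) {
        block <- (d - 1L) * labsPerDisease + seq_len(labsPerDisease)
        sgn <- rep_len(c(1, -1), labsPerDisease)
        sh <- setNames(rep(0, nLabs), labIds)
        sh[block] <- sgn * shiftSize
        shifts[[diseaseIds[d]]] <- sh
        for (k in seq_len(drugsPerDisease)) {
            drug <- (d - 1L) * drugsPerDisease + k
            onto <- block[pairs[[((k - 1L) %% length(pairs)) + 1L]]]
            effects[drug, onto] <- -sign(sh[onto]) * effectSize
        }
    }

    ehrCfg <- ehrSimConfig(nPatients, nDrugs, nLabs, measRange = measRange,
                           baselineMean = baselineMean, baselineSd = baselineSd,
                           noiseSd = noiseSd, exposureProb = exposureProb,
                           seed = seed)
    ehr <- simulateEHR(ehrCfg, effects)

    surveys <- lapply(seq_len(nDiseases), function(d) {
        cfg <- surveySimConfig(nCases, nControls,
                               labMeans = setNames(rep(labMean, nLabs), labIds),
                               labSds = labSd,
                               diseaseShifts = shifts[[diseaseIds[d]]],
                               seed = seed + d)
        simulateSurvey(cfg, diseaseIds[d])
    })
    survey <- bindSurveys(surveys)
    gold <- simulateGoldStandard(effects, shifts)
    list(ehr = ehr, survey = survey, gold = gold,
         effects = effects, shifts = shifts)
}
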