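test_that("EHR generation is deterministic and shape-correct", {
    eff <- sparseTrueEffects(4, 3, 2, seed = 5)
    cfg <- ehrSimConfig(6, 4, 3, measRange = c(3L, 3L), seed = 9)
    d1 <- simulateEHR(cfg, eff)
    d2 <- simulateEHR(cfg, eff)
    expect_identical(records(d1), records(d2))
    expect_identical(exposures(d1), exposures(d2))
    # J_i fixed at 3, 6 patients, 3 labs -> 6*3*3 records
    expect_equal(nrow(records(d1)), 54)
    expect_true(all(exposures(d1) %in% c(0, 1)))
    # different seed changes the draw
    d3 <- simulateEHR(ehrSimConfig(6, 4, 3, measRange = c(3L, 3L), seed = 10),
                      eff)
    expect_false(identical(records(d1)$value, records(d3)$value))
})

test_that("noise-free data are an exact solution of the generative model", {
    fx <- tinyNoiselessEHR()
    rec <- records(fx$data)
    ex <- exposures(fx$data)
    onLab <- rec$lab_id == "lab01"
    for (p in unique(rec$patient_id)) {
        rows <- which(onLab & rec$patient_id == p)
        exposed <- rec$value[rows][ex[rows, "drug02"] == 1]
        unexposed <- rec$value[rows][ex[rows, "drug02"] == 0]
        if (length(exposed) && length(unexposed))
            expect_equal(unique(as.vector(
                round(outer(exposed, unexposed, "-"), 10))), 2)
    }
})

test_that("generated noise matches the stated noise level", {
    eff <- sparseTrueEffects(10, 1, 3, effectSize = 1, seed = 1)
    cfg <- ehrSimConfig(50, 10, 1, noiseSd = 1, seed = 1)
    d <- simulateEHR(cfg, eff)
    des <- buildDesign(d, "lab01")
    cen <- centerWithinPatient(des$y, des$X, des$patientIndex)
    resid <- cen$yc - cen$Xc %*% eff[, 1]
    nPat <- length(unique(des$patientIndex))
    sigma2 <- sum(resid^2) / (length(resid) - nPat)
    expect_lt(abs(sqrt(sigma2) - 1), 0.1)
})

test_that("degenerate EHR configs behave as documented", {
    eff <- sparseTrueEffects(2, 1, 0, seed = 1)
    empty <- simulateEHR(ehrSimConfig(0, 2, 1, seed = 1), eff)
    expect_equal(nrow(records(empty)), 0)
    expect_error(simulateEHR(ehrSimConfig(3, 5, 1, seed = 1), eff),
                 "matrix matching the config")
    expect_error(ehrSimConfig(3, 2, 1, noiseSd = -1), "noiseSd")
    expect_error(ehrSimConfig(3, 2, 1, exposureProb = 1.5), "exposureProb")
})

test_that("survey generation is seeded and respects the group model", {
    cfg <- surveySimConfig(200, 150,
                           labMeans = c(A = 10, B = 20), labSds = c(1, 2),
                           diseaseShifts = c(A = 3, B = 0), seed = 4)
    s1 <- simulateSurvey(cfg, "dz")
    s2 <- simulateSurvey(cfg, "dz")
    expect_identical(labValues(s1), labValues(s2))
    st <- subjectStatus(s1)[, "dz"]
    expect_equal(sum(st == 1), 200)
    expect_equal(sum(st == 0), 150)
    # planted shift of 3 sd-units shows up in the case-group mean
    expect_gt(mean(labValues(s1)[st == 1, "A"]) -
              mean(labValues(s1)[st == 0, "A"]), 2)
    expect_error(surveySimConfig(10, 10, labMeans = c(A = 1), labSds = -1),
                 "labSds")
})

test_that("an empty case group is generated but refused downstream", {
    cfg <- surveySimConfig(0, 20, labMeans = c(A = 0), seed = 2)
    s <- simulateSurvey(cfg, "dz")
    expect_equal(sum(subjectStatus(s)[, "dz"] == 1), 0)
    expect_error(buildDiseaseVector(s, "dz"), "cases and controls")
})

test_that("gold standard lists exactly the net-complementary drugs", {
    labs <- c("L1", "L2", "L3")
    eff <- matrix(0, 3, 3, dimnames = list(c("opp", "zero", "same"), labs))
    eff["opp", ] <- c(-1, -1, -1)     # opposes all three shifts
    eff["same", ] <- c(1, 1, 1)       # matches the shifts: adverse
    shifts <- list(dz = stats::setNames(c(2, 2, 2), labs))
    gs <- simulateGoldStandard(eff, shifts)
    expect_identical(indications(gs)$dz, "opp")
})

test_that("the linked study plants a coherent truth", {
    st <- simulateStudy(nPatients = 20, nCases = 30, nControls = 30, seed = 3)
    expect_identical(labCatalog(st$ehr), colnames(st$effects))
    expect_identical(labCatalog(st$survey), colnames(st$effects))
    # every gold drug scores +3 against its disease under the true signs
    for (d in names(st$shifts)) {
        s <- sign(st$shifts[[d]])
        for (g in indications(st$gold)[[d]])
            expect_equal(-sum(sign(st$effects[g, ]) * s), 3)
        expect_length(indications(st$gold)[[d]], 5)
    }
})
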