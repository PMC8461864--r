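test_that("buildDesign stacks rows by patient and drops other labs", {
    fx <- tinyNoiselessEHR()
    des <- buildDesign(fx$data, "lab01")
    # 5 patients x 4 measurements of this lab
    expect_length(des$y, 20)
    expect_equal(nrow(des$X), 20)
    expect_identical(des$patientIndex, sort(des$patientIndex))
    expect_equal(as.vector(table(des$patientIndex)), rep(4, 5))
    expect_error(buildDesign(fx$data, "nope"), "unknown lab")
})

test_that("an empty design raises an explicit error", {
    fx <- tinyNoiselessEHR()
    rec <- records(fx$data)
    rec$value[rec$lab_id == "lab02"] <- NA
    d <- new("LongitudinalLabData", records = rec,
             exposures = exposures(fx$data),
             drugCatalog = drugCatalog(fx$data),
             labCatalog = labCatalog(fx$data))
    expect_error(buildDesign(d, "lab02"), "empty design")
})

test_that("within-patient centering removes patient means exactly", {
    # hand-computed two-patient example
    y <- c(1, 3, 10, 14)
    X <- matrix(c(0, 1, 1, 1), 4, 1)
    pid <- c("a", "a", "b", "b")
    cen <- centerWithinPatient(y, X, pid)
    expect_equal(cen$yc, c(-1, 1, -2, 2))
    expect_equal(as.vector(cen$Xc), c(-0.5, 0.5, 0, 0))
    # single patient mean removal
    cen1 <- centerWithinPatient(c(1, 2, 3), matrix(1, 3, 1), rep("p", 3))
    expect_equal(cen1$yc, c(-1, 0, 1))
    # a J_i = 1 patient centers to an all-zero row
    cen2 <- centerWithinPatient(c(5, 1, 2), matrix(c(1, 0, 1), 3, 1),
                                c("solo", "duo", "duo"))
    expect_equal(cen2$yc[1], 0)
    expect_equal(cen2$Xc[1, 1], 0)
})

test_that("centered columns sum to zero within every patient", {
    eff <- sparseTrueEffects(5, 1, 2, seed = 2)
    d <- simulateEHR(ehrSimConfig(12, 5, 1, seed = 2), eff)
    des <- buildDesign(d, "lab01")
    cen <- centerWithinPatient(des$y, des$X, des$patientIndex)
    sums <- rowsum(cbind(cen$yc, cen$Xc), des$patientIndex)
    expect_true(all(abs(sums) < 1e-10))
})

test_that("the centered lasso at lambda 0 equals the fixed-effects OLS", {
    eff <- sparseTrueEffects(3, 1, 2, effectSize = 1.5, seed = 8)
    d <- simulateEHR(ehrSimConfig(5, 3, 1, measRange = c(4L, 4L),
                                  noiseSd = 1, seed = 8), eff)
    des <- buildDesign(d, "lab01")
    cen <- centerWithinPatient(des$y, des$X, des$patientIndex)
    beta <- fitCSCCS(cen$yc, cen$Xc, 0)
    oracle <- fixedEffectsOLS(des$y, des$X, des$patientIndex)
    expect_lt(max(abs(beta - oracle)), 1e-8)
})

test_that("noise-free planted effects are recovered to machine precision", {
    fx <- tinyNoiselessEHR()
    des <- buildDesign(fx$data, "lab01")
    cen <- centerWithinPatient(des$y, des$X, des$patientIndex)
    beta <- fitCSCCS(cen$yc, cen$Xc, 0)
    expect_equal(unname(beta), unname(fx$effects[, "lab01"]),
                 tolerance = 1e-12)
})

test_that("large penalties return the exactly-zero solution", {
    eff <- sparseTrueEffects(4, 1, 2, seed = 3)
    d <- simulateEHR(ehrSimConfig(15, 4, 1, seed = 3), eff)
    des <- buildDesign(d, "lab01")
    cen <- centerWithinPatient(des$y, des$X, des$patientIndex)
    lmax <- max(abs(crossprod(cen$Xc, cen$yc)))
    expect_true(all(fitCSCCS(cen$yc, cen$Xc, lmax * (1 + 1e-8)) == 0))
    expect_error(fitCSCCS(c(1, NA), matrix(1, 2, 1), 0), "non-finite")
    expect_error(fitCSCCS(c(1, 2), matrix(1, 2, 1), -1), "lambda")
})

test_that("support size is non-increasing along the penalty path", {
    eff <- sparseTrueEffects(8, 1, 3, seed = 4)
    d <- simulateEHR(ehrSimConfig(40, 8, 1, seed = 4), eff)
    des <- buildDesign(d, "lab01")
    cen <- centerWithinPatient(des$y, des$X, des$patientIndex)
    grid <- lambdaGrid(cen$yc, cen$Xc, nLambda = 15)
    sizes <- vapply(grid, function(l) sum(fitCSCCS(cen$yc, cen$Xc, l) != 0),
                    numeric(1))
    expect_true(all(diff(sizes) >= 0))   # grid is decreasing
})

test_that("per-patient level shifts do not move the drug coefficients", {
    eff <- sparseTrueEffects(3, 1, 1, seed = 6)
    d <- simulateEHR(ehrSimConfig(10, 3, 1, seed = 6), eff)
    des <- buildDesign(d, "lab01")
    shift <- stats::setNames(rnorm(10, 0, 100), unique(des$patientIndex))
    yShifted <- des$y + shift[des$patientIndex]
    c1 <- centerWithinPatient(des$y, des$X, des$patientIndex)
    c2 <- centerWithinPatient(yShifted, des$X, des$patientIndex)
    for (lam in c(0, 2)) {
        expect_equal(fitCSCCS(c1$yc, c1$Xc, lam),
                     fitCSCCS(c2$yc, c2$Xc, lam), tolerance = 1e-8)
    }
})

test_that("cross-validated penalty selection is seeded and sane", {
    eff <- sparseTrueEffects(5, 1, 1, effectSize = 2, seed = 12)
    d <- simulateEHR(ehrSimConfig(30, 5, 1, seed = 12), eff)
    des <- buildDesign(d, "lab01")
    cen <- centerWithinPatient(des$y, des$X, des$patientIndex)
    expect_equal(selectLambda(cen$yc, cen$Xc, des$patientIndex,
                              grid = 3.7), 3.7)
    l1 <- selectLambda(cen$yc, cen$Xc, des$patientIndex, seed = 5)
    l2 <- selectLambda(cen$yc, cen$Xc, des$patientIndex, seed = 5)
    expect_identical(l1, l2)
    # the strong planted drug stays in the support at the selected penalty
    beta <- fitCSCCS(cen$yc, cen$Xc, l1)
    planted <- which(eff[, 1] != 0)
    expect_true(beta[planted] != 0)
    expect_error(selectLambda(cen$yc, cen$Xc, des$patientIndex,
                              nFolds = 40), "fewer patients")
})

test_that("null data select an empty support in most replicates", {
    emptySupport <- vapply(1:10, function(s) {
        eff <- sparseTrueEffects(5, 1, 0, seed = s)
        d <- simulateEHR(ehrSimConfig(40, 5, 1, seed = 50 + s), eff)
        des <- buildDesign(d, "lab01")
        cen <- centerWithinPatient(des$y, des$X, des$patientIndex)
        lam <- selectLambda(cen$yc, cen$Xc, des$patientIndex, seed = s)
        pv <- coefPvalues(fitCSCCS(cen$yc, cen$Xc, lam), cen$yc, cen$Xc,
                          des$patientIndex)
        all(pv >= 0.05)
    }, logical(1))
    expect_gte(mean(emptySupport), 0.9)
})

test_that("post-selection p-values behave at the extremes", {
    # empty support -> all ones
    pv <- coefPvalues(stats::setNames(c(0, 0), c("a", "b")),
                      c(-1, 1), matrix(0, 2, 2,
                                       dimnames = list(NULL, c("a", "b"))),
                      c("p", "p"))
    expect_equal(unname(pv), c(1, 1))
    # strong planted effect with tiny noise -> tiny p
    eff <- sparseTrueEffects(4, 1, 1, effectSize = 3, seed = 21)
    d <- simulateEHR(ehrSimConfig(40, 4, 1, noiseSd = 0.1, seed = 21), eff)
    des <- buildDesign(d, "lab01")
    cen <- centerWithinPatient(des$y, des$X, des$patientIndex)
    beta <- fitCSCCS(cen$yc, cen$Xc, 0)
    pv <- coefPvalues(beta, cen$yc, cen$Xc, des$patientIndex)
    expect_lt(pv[which(eff[, 1] != 0)], 0.05)
    # support beyond the residual degrees of freedom -> warning, all ones
    yy <- c(-1, 1); XX <- matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "a"))
    expect_warning(pv2 <- coefPvalues(stats::setNames(1, "a"), yy, XX,
                                      c("p", "p")),
                   "degrees of freedom")
    expect_equal(unname(pv2), 1)
})

test_that("direction calls follow the significance-and-sign rule", {
    mk <- function(beta, p) new("CSCCSFit", labId = "L",
                                beta = stats::setNames(beta, "d"),
                                pvalues = stats::setNames(p, "d"),
                                lambda = 0, support = which(beta != 0))
    expect_equal(unname(callDrugDirections(mk(0.5, 0.01))), 1)
    expect_equal(unname(callDrugDirections(mk(-0.3, 0.2))), 0)
    expect_equal(unname(callDrugDirections(mk(-0.3, 0.01))), -1)
    expect_equal(unname(callDrugDirections(mk(0, 1))), 0)
})

test_that("drug effect vectors recover a noise-free planted pattern", {
    eff <- matrix(0, 3, 2, dimnames = list(sprintf("drug%02d", 1:3),
                                           sprintf("lab%02d", 1:2)))
    eff["drug01", "lab01"] <- 1.5
    eff["drug03", "lab02"] <- -2
    d <- simulateEHR(ehrSimConfig(30, 3, 2, noiseSd = 0, exposureProb = 0.4,
                                  seed = 31), eff)
    dv <- buildDrugEffectVectors(d, minPatientsPerDrug = 1, seed = 31)
    expect_identical(dim(signMatrix(dv)), dim(eff))
    expect_equal(signMatrix(dv), sign(eff))
    expect_true(all(c("lab", "drug", "beta", "p") %in%
                    names(signDetails(dv))))
})

test_that("the minimum-patient threshold excludes sparse drugs", {
    eff <- sparseTrueEffects(3, 1, 0, seed = 41)
    d <- simulateEHR(ehrSimConfig(20, 3, 1, seed = 41), eff)
    dv <- buildDrugEffectVectors(d, minPatientsPerDrug = 1, seed = 41)
    expect_equal(nrow(signMatrix(dv)), 3)
    expect_error(buildDrugEffectVectors(d, minPatientsPerDrug = 10000),
                 "minimum of 10000")
})
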