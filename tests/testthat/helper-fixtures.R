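# Small fixtures shared across test files; everything is generated in code.

# tiny noise-free EHR with one planted effect (+2 of drug 2 on lab 1)
tinyNoiselessEHR <- function(seed = 7L) {
    eff <- matrix(0, 3, 2,
                  dimnames = list(sprintf("drug%02d", 1:3),
                                  sprintf("lab%02d", 1:2)))
    eff["drug02", "lab01"] <- 2
    cfg <- ehrSimConfig(5, 3, 2, measRange = c(4L, 4L), noiseSd = 0,
                        exposureProb = 0.5, seed = seed)
    list(data = simulateEHR(cfg, eff), effects = eff)
}

# Table-style ternary vectors over a six-lab catalog
sixLabs <- c("ALP", "Chol", "Glu", "HDL", "LDL", "TG")
t2dSigns <- stats::setNames(c(-1, 1, 1, -1, 1, 1), sixLabs)
chdSigns <- stats::setNames(c(1, 1, 1, -1, 1, 1), sixLabs)
clopidogrelSigns <- stats::setNames(c(0, -1, 0, 0, -1, 0), sixLabs)
doxycyclineSigns <- stats::setNames(c(0, 0, -1, 0, 0, 0), sixLabs)
alendronateSigns <- stats::setNames(c(-1, 0, 0, 1, 0, 0), sixLabs)

# brute-force fixed-effects least squares: one explicit intercept per
# patient, drug coefficients extracted from the tail
fixedEffectsOLS <- function(y, X, patientIndex) {
    fit <- stats::lm(y ~ 0 + factor(patientIndex) + X)
    cf <- stats::coef(fit)
    unname(cf[(length(cf) - ncol(X) + 1L):length(cf)])
}

# two-sided permutation oracle for the rank-sum test
permutationRankSumP <- function(caseValues, controlValues, nPerm = 10000L,
                                seed = 1L) {
    n1 <- length(caseValues)
    pooled <- c(caseValues, controlValues)
    n <- length(pooled)
    uOf <- function(idx) {
        r <- rank(pooled)
        sum(r[idx]) - n1 * (n1 + 1) / 2
    }
    obs <- uOf(seq_len(n1))
    mu <- n1 * (n - n1) / 2
    set.seed(seed)
    hits <- replicate(nPerm, {
        idx <- sample(n, n1)
        abs(uOf(idx) - mu) >= abs(obs - mu) - 1e-9
    })
    mean(hits)
}

# small survey fixture with known shifts
smallSurvey <- function(shift = c(A = 5, B = 5, C = -5, D = 0),
                        n = 300L, seed = 11L) {
    cfg <- surveySimConfig(n, n,
                           labMeans = stats::setNames(rep(50, length(shift)),
                                                      names(shift)),
                           labSds = 1, diseaseShifts = shift, seed = seed)
    simulateSurvey(cfg, "dz")
}

makeScoreMatrix <- function(m) new("ScoreMatrix", scores = m)
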