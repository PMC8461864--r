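test_that("lab harmonization intersects alias maps deterministically", {
    a <- data.frame(source_name = c("GLU", "HDL"),
                    lab_id = c("glucose", "hdl"))
    b <- data.frame(source_name = "Glucose", lab_id = "glucose")
    expect_equal(harmonizeLabs(a, b), "glucose")
    expect_equal(harmonizeLabs(a, a), c("glucose", "hdl"))
    dis <- data.frame(source_name = "X", lab_id = "x")
    expect_error(harmonizeLabs(a, dis), "no shared labs")
    # a non-numeric flag excludes the lab
    a$numeric <- c(TRUE, FALSE)
    expect_equal(harmonizeLabs(a, a), "glucose")
})

test_that("worked drug-disease scores match the hand computation", {
    # T2D: ALP down, Chol/Glu/LDL/TG up, HDL down; the two clopidogrel
    # downs (Chol, LDL) oppose two ups -> +2; doxycycline's Glu down
    # opposes one up -> +1; alendronate's ALP down + HDL up oppose the
    # coronary-heart-disease pattern on both labs -> +2
    expect_equal(repurposingScore(clopidogrelSigns, t2dSigns), 2)
    expect_equal(repurposingScore(doxycyclineSigns, t2dSigns), 1)
    expect_equal(repurposingScore(alendronateSigns, chdSigns), 2)
})

test_that("score degenerate cases and invariants hold", {
    zero <- stats::setNames(rep(0, 6), sixLabs)
    expect_equal(repurposingScore(zero, t2dSigns), 0)
    # identical vector with k nonzeros scores -k (pure adverse)
    expect_equal(repurposingScore(t2dSigns, t2dSigns), -6)
    # antisymmetry under sign flip
    expect_equal(repurposingScore(-clopidogrelSigns, t2dSigns),
                 -repurposingScore(clopidogrelSigns, t2dSigns))
    # bound by the number of jointly nonzero labs
    set.seed(2)
    for (i in 1:20) {
        u <- stats::setNames(sample(c(-1, 0, 1), 6, TRUE), sixLabs)
        v <- stats::setNames(sample(c(-1, 0, 1), 6, TRUE), sixLabs)
        both <- sum(u != 0 & v != 0)
        expect_lte(abs(repurposingScore(u, v)), both)
        # brute-force oracle: opposed-minus-same count
        opposed <- sum(u * v == -1)
        same <- sum(u * v == 1)
        expect_equal(repurposingScore(u, v), opposed - same)
    }
    expect_error(repurposingScore(t2dSigns, t2dSigns[c(2:6, 1)]),
                 "identical lab catalog")
})

test_that("the score matrix composes pairwise scores", {
    dm <- rbind(clopidogrel = clopidogrelSigns, doxycycline = doxycyclineSigns)
    sm <- rbind(t2d = t2dSigns, chd = chdSigns)
    drugs <- new("SignVectorSet", entries = dm, kind = "drug",
                 details = data.frame())
    dis <- new("SignVectorSet", entries = sm, kind = "disease",
               details = data.frame())
    m <- computeScoreMatrix(drugs, dis)
    expect_equal(dim(scores(m)), c(2L, 2L))
    for (d in rownames(dm)) for (s in rownames(sm))
        expect_equal(scores(m)[d, s], repurposingScore(dm[d, ], sm[s, ]))
    # flipping one drug's signs negates its row
    dm2 <- dm; dm2["clopidogrel", ] <- -dm2["clopidogrel", ]
    drugs2 <- new("SignVectorSet", entries = dm2, kind = "drug",
                  details = data.frame())
    m2 <- computeScoreMatrix(drugs2, dis)
    expect_equal(scores(m2)["clopidogrel", ], -scores(m)["clopidogrel", ])
})

test_that("rankings are descending with id tie-breaks", {
    m <- makeScoreMatrix(matrix(c(2, -1, 2), 3, 1,
                                dimnames = list(c("A", "B", "C"), "dz")))
    rk <- rankDrugs(m, "dz")
    expect_equal(rk$drug_id, c("A", "C", "B"))
    # all-equal scores fall back to alphabetical order
    m2 <- makeScoreMatrix(matrix(1, 3, 1,
                                 dimnames = list(c("b", "a", "c"), "dz")))
    expect_equal(rankDrugs(m2, "dz")$drug_id, c("a", "b", "c"))
    # permuting the input rows leaves the ranking unchanged
    m3 <- makeScoreMatrix(scores(m)[c(3, 1, 2), , drop = FALSE])
    expect_equal(rankDrugs(m3, "dz"), rankDrugs(m, "dz"))
    expect_error(rankDrugs(m, "nope"), "unknown disease")
})

test_that("truth-built gold drugs all score positively", {
    st <- simulateStudy(nPatients = 10, nCases = 20, nControls = 20,
                        seed = 6)
    drugs <- new("SignVectorSet", entries = sign(st$effects), kind = "drug",
                 details = data.frame())
    disM <- do.call(rbind, lapply(st$shifts, sign))
    dis <- new("SignVectorSet", entries = disM, kind = "disease",
               details = data.frame())
    m <- computeScoreMatrix(drugs, dis)
    for (d in names(st$shifts))
        expect_true(all(scores(m)[indications(st$gold)[[d]], d] > 0))
})
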