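test_that("invalid specifications are rejected by name of the invariant", {
    expect_error(trajectorySpec(rbind(c("a", "b"), c("b", "a")),
                                onsets = list(a = "100", b = "200"),
                                durations = c(a = 10, b = 10)),
                 "cycle|single root")
    expect_error(trajectorySpec(rbind(c("a", "b"), c("a", "c")),
                                onsets = list(a = "100"),
                                durations = c(a = 10, b = 10, c = 10),
                                branchProbs = list(a = c(b = 0.7, c = 0.2))),
                 "branchProbs")
    expect_error(trajectorySpec(rbind(c("a", "b")),
                                onsets = list(a = "100", b = "700"),
                                durations = c(a = 10, b = 10),
                                backgroundCodes = "700"),
                 "disjoint")
})

test_that("cohort generation is deterministic and respects the topology", {
    spec <- makeYSpec(stageDays = 90)
    c1 <- generateCohort(spec, nCases = 15, seed = 3)
    c2 <- generateCohort(spec, nCases = 15, seed = 3)
    expect_identical(c1, c2)
    c3 <- generateCohort(spec, nCases = 15, seed = 4)
    expect_false(identical(caseRecords(c1), caseRecords(c3)))
    ## every truth path is a root-to-leaf path of the planted topology
    for (p in cohortTruth(c1)$paths)
        expect_true(identical(p, c("stem", "brA1", "brA2")) ||
                    identical(p, c("stem", "brB1", "brB2")))
    ## adding patients does not perturb existing ones
    c4 <- generateCohort(spec, nCases = 20, seed = 3)
    expect_identical(cohortTruth(c1)$paths[1:15],
                     cohortTruth(c4)$paths[1:15])
    expect_identical(caseRecords(c1)$code[caseRecords(c1)$pid == "C0001"],
                     caseRecords(c4)$code[caseRecords(c4)$pid == "C0001"])
})

test_that("degenerate chains and branch probabilities behave as planted", {
    chain <- trajectorySpec(rbind(c("s1", "s2")),
                            onsets = list(s1 = "111", s2 = "222"),
                            durations = c(s1 = 60, s2 = 60),
                            visitRate = 4, onsetProb = 1)
    one <- generateCohort(chain, nCases = 1, seed = 1, controlRatio = 0)
    expect_equal(cohortTruth(one)$paths[["C0001"]], c("s1", "s2"))
    expect_true("111" %in% caseRecords(one)$code)

    forced <- trajectorySpec(rbind(c("s", "x"), c("s", "y")),
                             onsets = list(s = "111", x = "222", y = "333"),
                             durations = c(s = 30, x = 30, y = 30),
                             branchProbs = list(s = c(x = 1, y = 0)))
    all10 <- generateCohort(forced, nCases = 10, seed = 2, controlRatio = 0)
    expect_true(all(vapply(cohortTruth(all10)$paths,
                           function(p) p[2L] == "x", logical(1))))
})

test_that("balanced branch sampling matches the binomial oracle", {
    spec <- trajectorySpec(rbind(c("s", "x"), c("s", "y")),
                           onsets = list(s = "111", x = "222", y = "333"),
                           durations = c(s = 30, x = 30, y = 30),
                           visitRate = 1)
    big <- generateCohort(spec, nCases = 2000, seed = 5, controlRatio = 0)
    frac <- mean(vapply(cohortTruth(big)$paths, function(p) p[2L] == "x",
                        logical(1)))
    se <- sqrt(0.25 / 2000)
    expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("matched controls satisfy the gender and 1000-day contracts", {
    ## forced choice: 4 eligible + 4 wrong-gender candidates
    cases <- data.frame(pid = "C1", gender = "M",
                        birthdate = as.Date("1950-01-01"))
    pool <- data.frame(pid = sprintf("N%d", 1:8),
                       gender = rep(c("M", "F"), each = 4),
                       birthdate = as.Date("1950-01-01") + seq(-400, 300,
                                                               length.out = 8))
    m <- sampleMatchedControls(cases, pool, ratio = 4)
    expect_setequal(m$controlPid, sprintf("N%d", 1:4))
    ## boundary: a candidate 1001 days away is excluded
    pool2 <- data.frame(pid = c("N1", "N2", "N3", "N4", "N5"),
                        gender = "M",
                        birthdate = as.Date("1950-01-01") +
                            c(0, 500, -999, 1000, 1001))
    m2 <- sampleMatchedControls(cases, pool2, ratio = 4)
    expect_setequal(m2$controlPid, c("N1", "N2", "N3", "N4"))
    expect_error(sampleMatchedControls(cases, pool2[4:5, ], ratio = 2),
                 "insufficient eligible controls for case C1")
    ## controls are never reused across cases
    cases2 <- data.frame(pid = c("C1", "C2"), gender = "M",
                         birthdate = as.Date("1950-01-01"))
    pool3 <- data.frame(pid = sprintf("N%d", 1:4), gender = "M",
                        birthdate = as.Date("1950-01-01"))
    m3 <- sampleMatchedControls(cases2, pool3, ratio = 2)
    expect_equal(anyDuplicated(m3$controlPid), 0L)
})

test_that("generated cohorts keep onset codes out of controls and match 4:1", {
    spec <- makeYSpec(stageDays = 60)
    cohort <- generateCohort(spec, nCases = 40, seed = 11)
    m <- controlMatching(cohort)
    expect_equal(nrow(m), 160L)
    demo <- demographics(cohort)
    rownames(demo) <- demo$pid
    for (i in seq_len(nrow(m))) {
        cs <- demo[m$casePid[i], ]; ct <- demo[m$controlPid[i], ]
        expect_equal(cs$gender, ct$gender)
        expect_lte(abs(as.numeric(cs$birthdate) - as.numeric(ct$birthdate)),
                   1000)
    }
    onset <- unlist(cohortTruth(cohort)$onsets)
    planted <- c("100", "101", "102", branchACodes, branchBCodes)
    expect_length(intersect(controlRecords(cohort)$code, planted), 0L)
})

test_that("background diagnosis intensity is shared by cases and controls", {
    spec <- trajectorySpec(rbind(c("s1", "s2")),
                           onsets = list(s1 = "111", s2 = "222"),
                           durations = c(s1 = 45, s2 = 45),
                           visitRate = 2,
                           backgroundCodes = c("700", "701", "702"),
                           backgroundProb = 0.2)
    cohort <- generateCohort(spec, nCases = 500, seed = 23)
    bg <- c("700", "701", "702")
    nCase <- length(unique(caseRecords(cohort)$pid))
    nCtrl <- length(unique(controlRecords(cohort)$pid))
    ## per-patient background record counts; Poisson-style 3-SE comparison
    xCase <- sum(caseRecords(cohort)$code %in% bg)
    xCtrl <- sum(controlRecords(cohort)$code %in% bg)
    rCase <- xCase / nCase
    rCtrl <- xCtrl / nCtrl
    se <- sqrt(xCase / nCase^2 + xCtrl / nCtrl^2)
    expect_lt(abs(rCase - rCtrl), 3 * se)
})

test_that("claims and truth files export to plain text", {
    spec <- makeYSpec(stageDays = 60)
    cohort <- generateCohort(spec, nCases = 5, seed = 2)
    dir <- withr::local_tempdir()
    writeCohort(cohort, dir)
    rec <- readClaims(file.path(dir, "cases.csv"))
    expect_identical(rec$code, caseRecords(cohort)$code)
    truth <- jsonlite::read_json(file.path(dir, "truth.json"))
    expect_length(truth$paths, 5L)
})
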