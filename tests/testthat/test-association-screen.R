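test_that("contingency counting is patient-level, ever-diagnosed", {
    rec <- data.frame(pid = c("C1", "C1", "C2", "N1"),
                      code = c("335", "335", "335", "100"))
    ct <- contingencyCounts(rec, c("C1", "C2"), c("N1", "N2"), "335")
    expect_equal(unname(ct), c(2L, 0L, 0L, 2L))
    ## absent code
    ct0 <- contingencyCounts(rec, c("C1", "C2"), c("N1", "N2"), "999")
    expect_equal(unname(ct0[c("a", "c")]), c(0L, 0L))
    expect_error(contingencyCounts(rec, c("C1"), c("C1", "N1"), "335"),
                 "overlap")
    ## brute-force scan on random cohorts
    set.seed(21)
    for (rep in 1:30) {
        r <- randomRecords(nPatients = 12, nCodes = 5, nDays = 10,
                           nRecords = 40)
        ids <- sprintf("P%02d", 1:12)
        cases <- ids[1:5]; controls <- ids[6:12]
        for (cd in unique(r$code))
            expect_equal(contingencyCounts(r, cases, controls, cd),
                         bruteContingency(r, cases, controls, cd))
    }
})

test_that("odds ratios follow ad/(bc) with Woolf intervals", {
    null <- oddsRatio(1, 1, 1, 1)
    expect_equal(null$or, 1)
    expect_lt(null$ciLow, 1); expect_gt(null$ciHigh, 1)
    ## direct formula arithmetic: 4*331 / (79*1)
    expect_equal(round(oddsRatio(4, 79, 1, 331)$or, 2), 16.76)
    ## structural zero in controls: infinite OR, corrected lower bound
    sz <- oddsRatio(2, 81, 0, 332)
    expect_equal(sz$or, Inf)
    expect_equal(sz$ciHigh, Inf)
    ## oracle: corrected-Woolf arithmetic on (2.5, 81.5, 0.5, 332.5)
    lorC <- log(2.5 * 332.5 / (81.5 * 0.5))
    seC <- sqrt(1 / 2.5 + 1 / 81.5 + 1 / 0.5 + 1 / 332.5)
    expect_equal(sz$ciLow, exp(lorC - qnorm(0.975) * seC), tolerance = 1e-10)
    ## both-zero exposure: undefined flag, no exception
    ud <- oddsRatio(0, 10, 0, 40)
    expect_true(ud$undefined)
    expect_true(is.na(ud$or))
    expect_error(oddsRatio(-1, 1, 1, 1), "non-negative")
})

test_that("odds-ratio antisymmetry and monotonicity hold", {
    set.seed(8)
    for (rep in 1:50) {
        tb <- sample.int(50, 4)
        o1 <- oddsRatio(tb[1], tb[2], tb[3], tb[4])$or
        o2 <- oddsRatio(tb[3], tb[4], tb[1], tb[2])$or
        expect_equal(o1, 1 / o2, tolerance = 1e-12)
    }
    ## increasing a (and decreasing b to hold the margin) raises the OR
    ors <- vapply(1:9, function(a) oddsRatio(a, 10 - a, 5, 5)$or, numeric(1))
    expect_true(all(diff(ors) > 0))
})

test_that("the screen flags planted case-only codes and filters weak ones", {
    spec <- makeYSpec(stageDays = 150)
    cohort <- generateCohort(spec, nCases = 40, seed = 17)
    rec <- rbind(caseRecords(cohort)[, c("pid", "code")],
                 controlRecords(cohort)[, c("pid", "code")])
    sc <- screenComorbidities(rec, unique(caseRecords(cohort)$pid),
                              unique(controlRecords(cohort)$pid))
    stem <- c("100", "101", "102")
    expect_true(all(sc$significant[sc$code %in% stem]))
    expect_equal(sc$code, sort(sc$code))
    ## the significance rule is a conjunction: OR >= 2 AND ciLow > 1
    weak <- oddsRatio(3, 7, 2, 18)
    expect_gt(weak$or, 2)
    expect_lt(weak$ciLow, 1)
    rule <- weak$or >= 2 & weak$ciLow > 1
    expect_false(rule)
    ## BH adjustment only tightens the selection
    scBH <- screenComorbidities(rec, unique(caseRecords(cohort)$pid),
                                unique(controlRecords(cohort)$pid),
                                adjust = "BH")
    expect_true(all(scBH$significant <= sc$significant))
})

test_that("every printed reference screen row satisfies the rule", {
    path <- system.file("extdata", "table1_odds_ratios.tsv",
                        package = "trajtree")
    t1 <- read.delim(path, colClasses = "character")
    toNum <- function(x) ifelse(x == "inf", Inf, as.numeric(x))
    or <- toNum(t1$or); lo <- toNum(t1$ci_low); hi <- toNum(t1$ci_high)
    expect_true(all(or >= 2))
    expect_true(all(lo > 1))
    expect_true(all(lo <= or & or <= hi))
})
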