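test_that("ICD-9 codes normalize to zero-padded 3-digit categories", {
    expect_equal(normalizeIcd9("335.20"), "335")
    expect_equal(normalizeIcd9("45"), "045")
    expect_equal(normalizeIcd9(" 7 "), "007")
    expect_equal(normalizeIcd9("v82.1"), "V82")
    expect_equal(normalizeIcd9(c("1234.5", "E950")), c("123", "E95"))
})

test_that("claims files read, validate and round-trip", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("pid,date,icd9",
                 "P1,2001-03-04,335.20",
                 "P1,2001-03-05,45"), f)
    rec <- readClaims(f)
    expect_equal(rec$code, c("335", "045"))
    expect_s3_class(rec$date, "Date")

    f2 <- withr::local_tempfile(fileext = ".csv")
    writeClaims(rec, f2)
    expect_identical(readClaims(f2), rec)

    fEmpty <- withr::local_tempfile(fileext = ".csv")
    writeLines("pid,date,icd9", fEmpty)
    expect_equal(nrow(readClaims(fEmpty)), 0L)

    fBad <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("pid,when,icd9", "P1,2001-01-01,335"), fBad)
    expect_error(readClaims(fBad), "missing column")

    fDate <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("pid,date,icd9", "P1,2001-01-01,335",
                 "P1,not-a-date,336"), fDate)
    expect_error(readClaims(fDate), "line\\(s\\): 3")
})

test_that("one-hot counts each diagnosis once per patient per day", {
    rec <- data.frame(
        pid = c("P1", "P1", "P1", "P2"),
        date = as.Date(c("2000-01-01", "2000-01-01", "2000-01-02",
                         "2000-01-01")),
        code = c("100", "100", "100", "200"))
    oh <- oneHotDaily(rec)
    m <- SummarizedExperiment::assay(oh, "onehot")
    cd <- SummarizedExperiment::colData(oh)
    expect_equal(dim(m), c(2L, 3L))
    ## same-day duplicates collapse to a single 1
    expect_equal(unname(m["100", which(cd$pid == "P1" &
                                       cd$date == as.Date("2000-01-01"))]),
                 1L)
    ## one row per (pid, date), both days flagged
    expect_equal(sum(m["100", cd$pid == "P1"]), 2L)
    ## unobserved codes are absent unless a universe is supplied
    expect_false("300" %in% rownames(m))
    oh2 <- oneHotDaily(rec, codes = c("100", "200", "300"))
    expect_true(all(SummarizedExperiment::assay(oh2)["300", ] == 0L))
})

test_that("cumulation prepends a zero pre-state and runs per-code sums", {
    rec <- data.frame(pid = "P1",
                      date = as.Date(c("2000-01-01", "2000-01-02",
                                       "2000-01-02")),
                      code = c("A00", "A00", "B00"))
    cs <- cumulate(oneHotDaily(rec))
    a <- SummarizedExperiment::assay(cs, "cumulative")
    expect_equal(unname(a["A00", ]), c(0, 1, 2))
    expect_equal(unname(a["B00", ]), c(0, 0, 1))
    expect_equal(isPreState(cs), c(TRUE, FALSE, FALSE))

    one <- cumulate(oneHotDaily(rec[1L, ]))
    expect_equal(unname(SummarizedExperiment::assay(one)[, 2L]), 1)
    expect_true(all(SummarizedExperiment::assay(one)[, 1L] == 0))
})

test_that("cumulative cells match a brute-force distinct-day recount", {
    set.seed(42)
    for (rep in 1:20) {
        rec <- randomRecords(nPatients = 5, nCodes = 6, nDays = 15,
                             nRecords = 60)
        cs <- cumulate(oneHotDaily(rec))
        a <- SummarizedExperiment::assay(cs, "cumulative")
        pid <- statePids(cs); date <- stateDates(cs)
        for (j in seq_len(ncol(a))) {
            for (cd in rownames(a)) {
                expect_equal(unname(a[cd, j]),
                             bruteCumulativeCell(rec, pid[j], date[j], cd))
            }
        }
        ## monotone within patient, final row = distinct diagnosis days
        for (p in unique(pid)) {
            block <- a[, pid == p, drop = FALSE]
            expect_true(all(apply(block, 1L, function(v) all(diff(v) >= 0))))
            expect_equal(unname(block[, ncol(block)]),
                         vapply(rownames(a), function(cd)
                             length(unique(rec$date[rec$pid == p &
                                                    rec$code == cd])),
                             numeric(1), USE.NAMES = FALSE))
        }
    }
})

test_that("cumulate refuses unmerged duplicate patient-days", {
    m <- matrix(1L, 1, 2, dimnames = list("100", NULL))
    oh <- SummarizedExperiment::SummarizedExperiment(
        assays = list(onehot = m),
        colData = S4Vectors::DataFrame(pid = c("P1", "P1"),
                                       date = as.Date(c("2000-01-01",
                                                        "2000-01-01"))))
    expect_error(cumulate(oh), "duplicate")
})
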