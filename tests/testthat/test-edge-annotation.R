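test_that("node profiles are group-by means of raw cumulative vectors", {
    set.seed(31)
    rec <- randomRecords(nPatients = 6, nCodes = 5, nDays = 12,
                         nRecords = 50)
    cs <- cumulate(oneHotDaily(rec))
    a <- SummarizedExperiment::assay(cs, "cumulative")
    assign <- sample.int(4, ncol(a), replace = TRUE)
    proj <- data.frame(node = assign, distance = 0)
    prof <- nodeProfiles(proj, cs, 4L)
    oracle <- bruteProfiles(assign, a)
    expect_equal(unname(prof$means), unname(oracle), tolerance = 1e-12)
    for (j in 1:4)
        expect_equal(prof$nPatients[j],
                     length(unique(statePids(cs)[assign == j])))
    ## all states identical -> profile equals that vector
    one <- matrix(rep(c(1, 2), 3), nrow = 2,
                  dimnames = list(c("A", "B"), NULL))
    csOne <- SummarizedExperiment::SummarizedExperiment(
        assays = list(cumulative = one),
        colData = S4Vectors::DataFrame(pid = c("P1", "P2", "P3"),
                                       date = as.Date("2000-01-01") + 0:2,
                                       preState = FALSE))
    csOne <- new("CumulativeStates", csOne)
    pOne <- nodeProfiles(data.frame(node = c(1L, 1L, 1L)), csOne, 2L)
    expect_equal(unname(pOne$means[1L, ]), c(1, 2))
    expect_true(all(is.na(pOne$means[2L, ])))
})

test_that("associated diseases are those whose mean count increases", {
    parent <- c(A = 0.2, B = 1, C = 0)
    child1 <- parent
    expect_length(associatedDiseases(parent, child1, names(parent)), 0L)
    child2 <- c(A = 1.4, B = 1, C = 0.04)
    expect_equal(associatedDiseases(parent, child2, names(parent),
                                    epsilon = 0.05), "A")
    ## candidate restriction
    expect_length(associatedDiseases(parent, child2, "B"), 0L)
})

test_that("branch-only sets exclude sibling and ancestral diseases", {
    fx <- loadTable2Fixture()
    ann <- fx$annotations[, c("parent", "child", "associated")]
    bo <- branchOnlySets(ann, fx$rooted)
    pick <- function(p, ch) bo[[which(ann$parent == p & ann$child == ch)]]
    expect_setequal(pick("1", "3"),
                    c("045", "359", "438", "427", "344", "138"))
    expect_setequal(pick("3", "6"), c("349", "355", "323"))
    expect_setequal(pick("11", "17"), c("290", "718"))
    ## definitional invariants on the whole table
    lab <- nodeLabels(fx$rooted)
    pIdx <- match(ann$parent, lab); cIdx <- match(ann$child, lab)
    for (i in seq_along(bo)) {
        expect_true(all(bo[[i]] %in% ann$associated[[i]]))
        sib <- which(pIdx == pIdx[i] & cIdx != cIdx[i])
        for (s in sib)
            expect_length(intersect(bo[[i]], ann$associated[[s]]), 0L)
        anc <- trajtree:::.pathEdges(fx$rooted, pIdx[i])
        if (!is.null(anc))
            for (r in seq_len(nrow(anc))) {
                row <- which(pIdx == anc[r, 1L] & cIdx == anc[r, 2L])
                expect_length(intersect(bo[[i]], ann$associated[[row]]), 0L)
            }
    }
    ## sibling branch-only sets are pairwise disjoint
    for (p in unique(pIdx)) {
        rows <- which(pIdx == p)
        if (length(rows) > 1L)
            expect_length(unlist(bo[rows]),
                          length(unique(unlist(bo[rows]))))
    }
})

test_that("siblings sharing every associated code have empty branch-only sets", {
    rt <- orientTree(rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L)), root = 1L)
    ann <- data.frame(parent = c("0", "1", "1"), child = c("1", "2", "3"),
                      stringsAsFactors = FALSE)
    ann$associated <- list(c("X"), c("A", "B"), c("A", "B"))
    bo <- branchOnlySets(ann, rt)
    expect_length(bo[[2L]], 0L)
    expect_length(bo[[3L]], 0L)
    expect_equal(bo[[1L]], "X")
})

test_that("the exclusivity summary counts distinct non-index codes", {
    ann <- data.frame(parent = "0", child = "1", stringsAsFactors = FALSE)
    ann$associated <- list(c("A", "B", "335"))
    ann$branchOnly <- list(c("A", "335"))
    expect_equal(unname(exclusivitySummary(ann)), c(2L, 1L, 1L))
    ## code on two branch-only sets is not single-edge
    ann2 <- data.frame(parent = c("0", "1"), child = c("1", "2"),
                       stringsAsFactors = FALSE)
    ann2$associated <- list(c("A", "B"), c("A", "C"))
    ann2$branchOnly <- list(c("A"), c("A", "C"))
    expect_equal(unname(exclusivitySummary(ann2)), c(3L, 2L, 1L))
})
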