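## Shared builders and independent brute-force oracles.

## canonical planted Y: a shared stem, then two branches of two stages each
## (transitional codes near the bifurcation, deep marker codes later)
makeYSpec <- function(visitRate = 2, backgroundProb = 0.1, onsetProb = 0.3,
                      stageDays = 300) {
    trajectorySpec(
        stageEdges = rbind(c("stem", "brA1"), c("brA1", "brA2"),
                           c("stem", "brB1"), c("brB1", "brB2")),
        onsets = list(stem = c("100", "101", "102"),
                      brA1 = c("210", "211", "212"),
                      brA2 = c("200", "201", "202"),
                      brB1 = c("310", "311", "312"),
                      brB2 = c("300", "301", "302")),
        durations = c(stem = stageDays, brA1 = stageDays, brA2 = stageDays,
                      brB1 = stageDays, brB2 = stageDays),
        visitRate = visitRate,
        backgroundCodes = sprintf("7%02d", 0:9),
        backgroundProb = backgroundProb, onsetProb = onsetProb)
}

deepACodes <- c("200", "201", "202")
deepBCodes <- c("300", "301", "302")
branchACodes <- c(deepACodes, "210", "211", "212")
branchBCodes <- c(deepBCodes, "310", "311", "312")

## random small record tables
randomRecords <- function(nPatients, nCodes, nDays, nRecords) {
    data.frame(
        pid = sprintf("P%02d", sample.int(nPatients, nRecords, replace = TRUE)),
        date = as.Date("2000-01-01") + sample.int(nDays, nRecords,
                                                  replace = TRUE),
        code = sprintf("%03d", sample.int(nCodes, nRecords, replace = TRUE)))
}

## oracle: distinct diagnosis-days of `code` for `pid` up to `date`
bruteCumulativeCell <- function(records, pid, date, code) {
    length(unique(records$date[records$pid == pid & records$code == code &
                               records$date <= date]))
}

## oracle: exhaustive nearest-node search
bruteNearest <- function(points, nodes) {
    t(vapply(seq_len(nrow(points)), function(i) {
        d <- sqrt(colSums((t(nodes) - points[i, ])^2))
        j <- which(d == min(d))[1L]
        c(node = j, distance = d[j])
    }, c(node = 0, distance = 0)))
}

## oracle: group-by mean of raw cumulative vectors
bruteProfiles <- function(assign, mat) {
    t(vapply(sort(unique(assign)), function(j)
        rowMeans(mat[, assign == j, drop = FALSE]), numeric(nrow(mat))))
}

## oracle: per-patient set-membership contingency scan
bruteContingency <- function(records, caseIds, controlIds, code) {
    hasCode <- function(p) any(records$code == code & records$pid == p)
    a <- sum(vapply(caseIds, hasCode, logical(1)))
    cc <- sum(vapply(controlIds, hasCode, logical(1)))
    c(a = a, b = length(caseIds) - a, c = cc, d = length(controlIds) - cc)
}

## branch subtree annotation rows of a fitted, rooted Y tree
branchAnnotationRows <- function(bundle, bifChild) {
    lab <- nodeLabels(bundle$rooted)
    sub <- trajtree:::.subtreeNodes(bundle$rooted, bifChild)
    which(match(bundle$annotations$child, lab) %in% sub)
}
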