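## Accessors and show() methods.

#' @rdname PrincipalTree-class
#' @export
setMethod("nodePositions", "PrincipalTree", function(x) x@nodePositions)

#' @rdname PrincipalTree-class
#' @export
setMethod("treeEdges", "PrincipalTree", function(x) x@edges)

#' @rdname PrincipalTree-class
#' @export
setMethod("nNodes", "PrincipalTree", function(x) nrow(x@nodePositions))

#' @rdname RootedTree-class
#' @export
setMethod("nNodes", "RootedTree", function(x) length(x@parent))

#' @rdname RootedTree-class
#' @export
setMethod("treeEdges", "RootedTree", function(x) {
    child <- which(!is.na(x@parent))
    cbind(parent = x@parent[child], child = child)
})

#' @rdname RootedTree-class
#' @export
setMethod("treeLeaves", "RootedTree", function(x) {
    which(lengths(x@children) == 0L)
})

#' @rdname RootedTree-class
#' @export
setMethod("nodeLabels", "RootedTree", function(x) x@labels)

#' @rdname CumulativeStates-class
#' @export
setMethod("statePids", "CumulativeStates", function(x) colData(x)$pid)

#' @rdname CumulativeStates-class
#' @export
setMethod("stateDates", "CumulativeStates", function(x) colData(x)$date)

#' @rdname CumulativeStates-class
#' @export
setMethod("isPreState", "CumulativeStates", function(x) colData(x)$preState)

#' @rdname CumulativeStates-class
#' @export
setMethod("diseaseCodes", "CumulativeStates", function(x) rownames(x))

#' @rdname SyntheticCohort-class
#' @export
setMethod("caseRecords", "SyntheticCohort", function(x) x@caseRecords)

#' @rdname SyntheticCohort-class
#' @export
setMethod("controlRecords", "SyntheticCohort", function(x) x@controlRecords)

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

#' @rdname SyntheticCohort-class
#' @export
setMethod("controlMatching", "SyntheticCohort", function(x) x@matching)

#' @rdname SyntheticCohort-class
#' @export
setMethod("demographics", "SyntheticCohort", function(x) x@demographics)

#' @rdname StateEmbedding-class
#' @export
setMethod("stateScores", "StateEmbedding", function(x) x@scores)

#' @rdname StateEmbedding-class
#' @export
setMethod("stateWeights", "StateEmbedding", function(x) x@weights)

#' @rdname StateEmbedding-class
#' @export
setMethod("explainedVariance", "StateEmbedding", function(x) x@explainedVariance)

setMethod("show", "TrajectorySpec", function(object) {
    e <- object@stageEdges
    root <- setdiff(e[, 1L], e[, 2L])
    leaves <- setdiff(e[, 2L], e[, 1L])
    cat("TrajectorySpec with", length(unique(c(e))), "stages,",
        nrow(e), "edges\n")
    cat("  root:", root, " leaves:", paste(leaves, collapse = ", "), "\n")
    cat("  onset codes:",
        length(unlist(object@onsets, use.names = FALSE)),
        " background codes:", length(object@backgroundCodes), "\n")
    cat("  visit rate:", object@visitRate, "per 30 days\n")
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort:",
        length(unique(object@caseRecords$pid)), "cases /",
        length(unique(object@controlRecords$pid)), "controls\n")
    cat("  case records:", nrow(object@caseRecords),
        " control records:", nrow(object@controlRecords), "\n")
})

setMethod("show", "StateEmbedding", function(object) {
    cat("StateEmbedding:", length(object@center), "codes ->",
        ncol(object@loadings), "components;",
        nrow(object@scores), "unique states (of",
        length(object@stateIndex), ")\n")
})

setMethod("show", "PrincipalTree", function(object) {
    deg <- tabulate(c(object@edges), nrow(object@nodePositions))
    cat("PrincipalTree:", nrow(object@nodePositions), "nodes in",
        ncol(object@nodePositions), "dims;",
        sum(deg == 1L), "leaves,", sum(deg >= 3L), "branch points\n")
    cat("  lambda =", object@lambda, " mu =", object@mu,
        " final energy =", signif(tail(object@energyTrace, 1L), 6), "\n")
})

setMethod("show", "RootedTree", function(object) {
    cat("RootedTree:", nNodes(object), "nodes, root",
        object@labels[object@root], "(",
        length(treeLeaves(object)), "leaves )\n")
})
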