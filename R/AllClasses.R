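## S4 class definitions.  Validity methods enforce the structural contracts
## that the rest of the pipeline assumes.

#' TrajectorySpec: a planted disease-progression topology
#'
#' Describes the ground truth used by the synthetic claims generator: a
#' rooted tree of disease stages, the ICD-9 codes whose onset marks each
#' stage, per-stage dwell times, a visit intensity, shared background
#' diagnoses, and branch probabilities at every bifurcation.
#'
#' @slot stageEdges two-column character matrix of directed stage edges
#'   (from, to) forming a rooted tree.
#' @slot onsets named list: stage -> character vector of ICD-9 category
#'   codes that begin occurring at that stage.
#' @slot durations named numeric: stage -> dwell time in days (positive).
#' @slot visitRate expected case visits per 30 days (positive).
#' @slot backgroundCodes codes diagnosed in cases and controls alike.
#' @slot backgroundProb per-visit probability of each background code.
#' @slot onsetProb per-visit probability that each active onset code is
#'   recorded at a case visit within its stage.
#' @slot branchProbs named list: bifurcation stage -> named numeric of
#'   child-branch probabilities summing to 1.
#' @exportClass TrajectorySpec
setClass("TrajectorySpec", slots = c(
    stageEdges      = "matrix",
    onsets          = "list",
    durations       = "numeric",
    visitRate       = "numeric",
    backgroundCodes = "character",
    backgroundProb  = "numeric",
    onsetProb       = "numeric",
    branchProbs     = "list"
), prototype = prototype(onsetProb = 0.3))

setValidity("TrajectorySpec", function(object) {
    e <- object@stageEdges
    if (ncol(e) != 2L)
        return("stageEdges must have two columns (from, to)")
    stages <- unique(c(e[, 1L], e[, 2L]))
    if (anyDuplicated(e[, 2L]))
        return("topology invariant violated: a stage has two parents")
    roots <- setdiff(e[, 1L], e[, 2L])
    if (length(roots) != 1L)
        return(sprintf(
            "topology invariant violated: expected a single root, found %d",
            length(roots)))
    ## acyclicity + connectedness: |E| = |V| - 1 with unique parents and a
    ## single root implies a tree iff every node is reachable from the root
    reached <- roots
    frontier <- roots
    while (length(frontier)) {
        frontier <- e[e[, 1L] %in% frontier, 2L]
        if (any(frontier %in% reached))
            return("topology invariant violated: cycle detected")
        reached <- c(reached, frontier)
    }
    if (!setequal(reached, stages))
        return("topology invariant violated: graph is not connected")
    if (!all(stages %in% names(object@durations)))
        return("every stage needs a duration")
    if (any(object@durations[stages] <= 0))
        return("stage durations must be positive")
    if (object@visitRate <= 0)
        return("visitRate must be positive")
    if (length(object@onsetProb) != 1L || object@onsetProb <= 0 ||
        object@onsetProb > 1)
        return("onsetProb must be in (0, 1]")
    onsetCodes <- unlist(object@onsets, use.names = FALSE)
    if (length(intersect(onsetCodes, object@backgroundCodes)))
        return(paste0("onset codes must be disjoint from background codes: ",
                      paste(intersect(onsetCodes, object@backgroundCodes),
                            collapse = ", ")))
    for (s in stages) {
        kids <- e[e[, 1L] == s, 2L]
        if (length(kids) >= 2L) {
            bp <- object@branchProbs[[s]]
            if (is.null(bp) || !setequal(names(bp), kids))
                return(sprintf(
                    "branchProbs missing or mislabelled at bifurcation '%s'", s))
            if (abs(sum(bp) - 1) > 1e-9)
                return(sprintf(
                    "branchProbs invariant violated at '%s': sum is %.12f, not 1",
                    s, sum(bp)))
            if (any(bp < 0))
                return(sprintf("negative branch probability at '%s'", s))
        }
    }
    TRUE
})

#' SyntheticCohort: generated case/control claims with ground truth
#'
#' @slot caseRecords data.frame (pid, date, code) of case diagnoses.
#' @slot controlRecords data.frame (pid, date, code) of matched-control
#'   diagnoses.
#' @slot truth list with elements `paths` (pid -> stage path) and `onsets`
#'   (pid -> named vector of first-diagnosis dates per onset code).
#' @slot matching data.frame (casePid, controlPid), `ratio` rows per case.
#' @slot demographics data.frame (pid, group, gender, birthdate).
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", slots = c(
    caseRecords    = "data.frame",
    controlRecords = "data.frame",
    truth          = "list",
    matching       = "data.frame",
    demographics   = "data.frame"
))

setValidity("SyntheticCohort", function(object) {
    m <- object@matching
    if (nrow(m)) {
        tab <- table(m$casePid)
        if (length(unique(tab)) > 1L)
            return("every case must have the same number of matched controls")
        if (anyDuplicated(m$controlPid))
            return("controls must not be reused across cases")
    }
    TRUE
})

#' CumulativeStates: per-patient-day cumulative diagnosis counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are ICD-9
#' category codes and whose columns are patient-day disease states, in
#' (pid, date) order, with one synthetic all-zero pre-diagnosis state per
#' patient.  The single assay, `"cumulative"`, holds for each (code, state)
#' the number of distinct days up to and including that state's date on
#' which the patient received the code.
#'
#' Column metadata: `pid`, `date`, `preState` (logical).
#'
#' @exportClass CumulativeStates
setClass("CumulativeStates", contains = "SummarizedExperiment")

setValidity("CumulativeStates", function(object) {
    cd <- colData(object)
    need <- c("pid", "date", "preState")
    if (!all(need %in% colnames(cd)))
        return("colData must contain pid, date and preState")
    a <- assay(object, "cumulative")
    if (any(a < 0))
        return("cumulative counts must be non-negative")
    ## monotone within patient (columns are (pid, date)-ordered)
    for (p in unique(cd$pid)) {
        idx <- which(cd$pid == p)
        if (length(idx) > 1L && any(a[, idx, drop = FALSE][, -1L, drop = FALSE] -
                                    a[, idx, drop = FALSE][, -length(idx), drop = FALSE] < 0))
            return(sprintf("cumulative counts decrease for patient %s", p))
    }
    TRUE
})

#' StateEmbedding: standardization + PCA model for disease states
#'
#' @slot center per-code means used for centering.
#' @slot scaleValues per-code population standard deviations (1 for
#'   zero-variance codes, whose standardized values are set to 0).
#' @slot loadings orthonormal code-by-component loading matrix.
#' @slot explainedVariance non-increasing component variances.
#' @slot scores unique-state-by-component score matrix (duplicate state
#'   vectors are collapsed before fitting).
#' @slot weights multiplicity of each unique state row.
#' @slot stateIndex integer map: original state column -> unique-state row.
#' @slot zeroVar logical per code; zero-variance codes are standardized to
#'   exactly 0.
#' @exportClass StateEmbedding
setClass("StateEmbedding", slots = c(
    center            = "numeric",
    scaleValues       = "numeric",
    loadings          = "matrix",
    explainedVariance = "numeric",
    scores            = "matrix",
    weights           = "numeric",
    stateIndex        = "integer",
    zeroVar           = "logical"
))

setValidity("StateEmbedding", function(object) {
    L <- object@loadings
    if (ncol(L) != length(object@explainedVariance))
        return("loadings and explainedVariance disagree on component count")
    g <- crossprod(L)
    if (max(abs(g - diag(ncol(L)))) > 1e-8)
        return("loadings are not orthonormal")
    ev <- object@explainedVariance
    if (length(ev) > 1L && any(diff(ev) > 1e-10))
        return("explainedVariance must be non-increasing")
    TRUE
})

#' PrincipalTree: an elastic principal tree in embedded space
#'
#' @slot nodePositions node-by-dimension coordinate matrix.
#' @slot edges two-column integer matrix of undirected node pairs.
#' @slot lambda edge-stretching penalty weight.
#' @slot mu star-bending penalty weight.
#' @slot energyTrace final-energy sequence across grammar steps
#'   (non-increasing position-optimization energies within each step are
#'   asserted during fitting).
#' @exportClass PrincipalTree
setClass("PrincipalTree", slots = c(
    nodePositions = "matrix",
    edges         = "matrix",
    lambda        = "numeric",
    mu            = "numeric",
    energyTrace   = "numeric"
))

setValidity("PrincipalTree", function(object) {
    n <- nrow(object@nodePositions)
    e <- object@edges
    if (ncol(e) != 2L)
        return("edges must have two columns")
    if (nrow(e) != n - 1L)
        return("a tree on n nodes must have n - 1 edges")
    if (any(e < 1L) || any(e > n))
        return("edge endpoints out of range")
    if (any(e[, 1L] == e[, 2L]))
        return("self-loops are not allowed")
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key))
        return("duplicate edges are not allowed")
    if (!.isConnected(n, e))
        return("edge set must be connected")
    TRUE
})

#' RootedTree: a principal tree rooted and oriented away from the root
#'
#' Node indices are 1-based; display labels (0-based by default, matching
#' the usual figure convention) are kept in `labels`.
#'
#' @slot root root node index.
#' @slot parent integer vector, parent index per node (NA at the root).
#' @slot children list of integer child vectors, ordered by node index.
#' @slot depth integer depth per node (0 at the root).
#' @slot labels character display label per node.
#' @exportClass RootedTree
setClass("RootedTree", slots = c(
    root     = "integer",
    parent   = "integer",
    children = "list",
    depth    = "integer",
    labels   = "character"
))

setValidity("RootedTree", function(object) {
    n <- length(object@parent)
    if (length(object@root) != 1L || is.na(object@root))
        return("exactly one root is required")
    if (!is.na(object@parent[object@root]))
        return("the root must have no parent")
    if (sum(is.na(object@parent)) != 1L)
        return("every non-root node needs exactly one parent")
    if (object@depth[object@root] != 0L)
        return("depth of the root must be 0")
    nonroot <- setdiff(seq_len(n), object@root)
    bad <- nonroot[object@depth[nonroot] !=
                   object@depth[object@parent[nonroot]] + 1L]
    if (length(bad))
        return("depth must increase by 1 from parent to child")
    if (length(object@labels) != n)
        return("one label per node is required")
    TRUE
})

## connectivity check used by several validity methods
.isConnected <- function(n, edges) {
    if (n == 1L) return(TRUE)
    adj <- vector("list", n)
    for (i in seq_len(nrow(edges))) {
        u <- edges[i, 1L]; v <- edges[i, 2L]
        adj[[u]] <- c(adj[[u]], v)
        adj[[v]] <- c(adj[[v]], u)
    }
    seen <- logical(n)
    seen[1L] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
        nxt <- unique(unlist(adj[frontier]))
        nxt <- nxt[!seen[nxt]]
        seen[nxt] <- TRUE
        frontier <- nxt
    }
    all(seen)
}
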