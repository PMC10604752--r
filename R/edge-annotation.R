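## Per-edge disease attribution: "associated" diseases (mean cumulative
## count increases across the transition) and "branch-only" diseases
## (associated with the edge but neither shared with sibling edges at the
## same parent nor inherited from ancestor edges).

#' Cohort percentage reporting convention
#'
#' Percentages of the patient cohort are reported rounded to two decimal
#' places, e.g. 55 of 83 patients print as 66.27.
#'
#' @param n patient count.
#' @param total cohort size.
#' @return numeric percentage rounded to 2 decimals.
#' @export
#' @examples
#' pctOfCohort(55, 83)
pctOfCohort <- function(n, total) round(100 * n / total, 2L)

#' Mean cumulative disease profile per tree node
#'
#' For each node, the arithmetic mean of the raw (unstandardized)
#' cumulative count vectors of the states assigned to it, plus the number
#' of states and of distinct patients.
#'
#' @param projection result of [projectStates()] on all state scores.
#' @param states the [CumulativeStates-class] object.
#' @param nNodes total number of tree nodes.
#' @return list with `means` (node x code matrix, NA rows for nodes with
#'   no assigned state), `nStates`, `nPatients`.
#' @export
nodeProfiles <- function(projection, states, nNodes) {
    a <- assay(states, "cumulative")
    pid <- statePids(states)
    means <- matrix(NA_real_, nNodes, nrow(a),
                    dimnames = list(NULL, rownames(a)))
    nStates <- integer(nNodes)
    nPatients <- integer(nNodes)
    for (j in seq_len(nNodes)) {
        idx <- which(projection$node == j)
        nStates[j] <- length(idx)
        nPatients[j] <- length(unique(pid[idx]))
        if (length(idx))
            means[j, ] <- rowMeans(a[, idx, drop = FALSE])
    }
    list(means = means, nStates = nStates, nPatients = nPatients)
}

#' Diseases associated with a state transition
#'
#' Candidate codes whose mean cumulative count increases by more than
#' `epsilon` from the parent node to the child node.
#'
#' @param parentProfile,childProfile named numeric vectors of mean
#'   cumulative counts sharing a code universe.
#' @param candidates candidate code set (normally the significant codes
#'   from [screenComorbidities()] plus the index disease).
#' @param epsilon minimum mean-count increase (default 0.05).
#' @return sorted character vector of codes.
#' @export
associatedDiseases <- function(parentProfile, childProfile, candidates,
                               epsilon = 0.05) {
    candidates <- intersect(candidates, names(childProfile))
    inc <- childProfile[candidates] - parentProfile[candidates]
    sort(candidates[inc > epsilon])
}

#' Annotate every directed edge of the rooted tree
#'
#' Computes per-edge associated-disease sets from the node profiles, the
#' number of patients traversing the edge (distinct patients with at least
#' one state assigned in the child's subtree), the cohort percentage, and
#' the branch-only sets via [branchOnlySets()].
#'
#' @param rooted a [RootedTree-class] object.
#' @param profiles result of [nodeProfiles()].
#' @param candidates candidate code set for attribution.
#' @param projection result of [projectStates()] on all state scores.
#' @param states the [CumulativeStates-class] object.
#' @param epsilon minimum mean-count increase (default 0.05).
#' @return data.frame with columns `parent`, `child` (labels), list-columns
#'   `associated` and `branchOnly`, `nPatients`, `pctPatients`.
#' @export
annotateEdges <- function(rooted, profiles, candidates, projection, states,
                          epsilon = 0.05) {
    E <- treeEdges(rooted)
    pid <- statePids(states)
    nCohort <- length(unique(pid))
    lab <- nodeLabels(rooted)
    assoc <- vector("list", nrow(E))
    nPat <- integer(nrow(E))
    for (i in seq_len(nrow(E))) {
        p <- E[i, 1L]; ch <- E[i, 2L]
        if (anyNA(profiles$means[p, ]) || anyNA(profiles$means[ch, ])) {
            assoc[[i]] <- character(0)
        } else {
            assoc[[i]] <- associatedDiseases(profiles$means[p, ],
                                             profiles$means[ch, ],
                                             candidates, epsilon)
        }
        sub <- .subtreeNodes(rooted, ch)
        nPat[i] <- length(unique(pid[projection$node %in% sub]))
    }
    ann <- data.frame(parent = lab[E[, 1L]], child = lab[E[, 2L]],
                      stringsAsFactors = FALSE)
    ann$associated <- assoc
    ann$branchOnly <- branchOnlySets(ann, rooted)
    ann$nPatients <- nPat
    ann$pctPatients <- pctOfCohort(nPat, nCohort)
    ann
}

#' Branch-only disease sets
#'
#' For each directed edge e = (p, c), the associated codes that are neither
#' shared with any sibling edge at the same parent p nor inherited from any
#' edge on the root-to-p path:
#' `branchOnly(e) = associated(e) \ union(siblings) \ union(ancestors)`.
#'
#' @param annotations data.frame with columns `parent`, `child` (labels)
#'   and list-column `associated`.
#' @param rooted a [RootedTree-class] object whose labels match the
#'   annotation table.
#' @return list of sorted character vectors, one per annotation row.
#' @export
branchOnlySets <- function(annotations, rooted) {
    lab <- nodeLabels(rooted)
    pIdx <- match(annotations$parent, lab)
    cIdx <- match(annotations$child, lab)
    if (anyNA(pIdx) || anyNA(cIdx))
        stop("annotation labels do not match the rooted tree")
    edgeOf <- function(p, ch) which(pIdx == p & cIdx == ch)
    lapply(seq_len(nrow(annotations)), function(i) {
        sib <- which(pIdx == pIdx[i] & cIdx != cIdx[i])
        anc <- .pathEdges(rooted, pIdx[i])
        ancRows <- if (is.null(anc)) integer(0)
                   else vapply(seq_len(nrow(anc)),
                               function(r) edgeOf(anc[r, 1L], anc[r, 2L]),
                               integer(1))
        excl <- unique(unlist(annotations$associated[c(sib, ancRows)]))
        sort(setdiff(annotations$associated[[i]], excl))
    })
}

#' Exclusivity summary of edge-attributed diseases
#'
#' Counts the distinct codes (excluding the index disease) that (i) appear
#' in at least one edge's associated set, (ii) appear in at least one
#' branch-only set, and (iii) appear in exactly one edge's branch-only set.
#'
#' @param annotations result of [annotateEdges()] (or any data.frame with
#'   list-columns `associated` and `branchOnly`).
#' @param indexCode index disease code excluded from the counts
#'   (default `"335"`).
#' @return named integer vector
#'   `c(nAssociated, nBranchOnly, nSingleEdgeBranchOnly)`.
#' @export
exclusivitySummary <- function(annotations, indexCode = "335") {
    assocCodes <- setdiff(unique(unlist(annotations$associated)), indexCode)
    boPerEdge <- lapply(annotations$branchOnly,
                        function(s) setdiff(unique(s), indexCode))
    boCodes <- unique(unlist(boPerEdge))
    tab <- table(unlist(boPerEdge))
    c(nAssociated = length(assocCodes),
      nBranchOnly = length(boCodes),
      nSingleEdgeBranchOnly = sum(tab == 1L))
}

#' Write the edge-annotation table
#'
#' CSV mirroring the reference edge-table schema: edge, comma-separated
#' associated and branch-only code lists, and `n (pct%)`.
#'
#' @param annotations result of [annotateEdges()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeEdgeAnnotations <- function(annotations, path) {
    out <- data.frame(
        edge = paste0(annotations$parent, "-", annotations$child),
        associated = vapply(annotations$associated, paste,
                            character(1), collapse = ","),
        branch_only = vapply(annotations$branchOnly, paste,
                             character(1), collapse = ","),
        n_patients = sprintf("%d (%.2f%%)", annotations$nPatients,
                             annotations$pctPatients))
    write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}
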