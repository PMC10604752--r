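## Mapping each patient's final observed state onto the trajectory network.

#' Classify patients onto trajectories
#'
#' Each patient's last observed state (latest non-pre-diagnosis state) is
#' mapped to its nearest tree node by shortest geometric distance.  If that
#' node lies on exactly one root-to-leaf trajectory the patient is assigned
#' to it; otherwise -- e.g. when the final state has not passed a
#' bifurcation -- the patient joins the uncategorized group (`NA`
#' trajectory).
#'
#' @param states the [CumulativeStates-class] object.
#' @param embedding the fitted [StateEmbedding-class].
#' @param tree the fitted [PrincipalTree-class].
#' @param rooted the [RootedTree-class] orientation of `tree`.
#' @param trajectories result of [enumerateTrajectories()].
#' @param projection optional precomputed [projectStates()] result for all
#'   state columns.
#' @return data.frame: `pid`, `finalNode` (label), `trajectory` (integer id
#'   or `NA` for uncategorized), `nCandidatePaths`.
#' @export
classifyPatients <- function(states, embedding, tree, rooted, trajectories,
                             projection = NULL) {
    pid <- statePids(states)
    date <- stateDates(states)
    pre <- isPreState(states)
    if (all(pre)) stop("no observed (non pre-diagnosis) states to classify")
    if (is.null(projection))
        projection <- projectStates(
            stateScores(embedding)[embedding@stateIndex, , drop = FALSE], tree)
    lab <- nodeLabels(rooted)
    onPath <- lapply(seq_len(nNodes(rooted)), function(j)
        which(vapply(trajectories, function(t) j %in% t, logical(1))))
    pids <- unique(pid)
    rows <- lapply(pids, function(p) {
        idx <- which(pid == p & !pre)
        if (!length(idx))
            stop("patient ", p, " has no observed states")
        final <- idx[which.max(as.numeric(date[idx]))]
        node <- projection$node[final]
        cand <- onPath[[node]]
        data.frame(pid = p, finalNode = lab[node],
                   trajectory = if (length(cand) == 1L) cand else NA_integer_,
                   nCandidatePaths = length(cand))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-trajectory cohort summary
#'
#' Patient counts per trajectory.  With `filterSupport = TRUE`,
#' trajectories carried by fewer than `minSupport` patients are merged into
#' the uncategorized group.
#'
#' @param assignments result of [classifyPatients()].
#' @param minSupport minimum patients per reported trajectory (default 3).
#' @param filterSupport apply the support filter (default `TRUE`).
#' @return data.frame `trajectory` (integer or `NA` = uncategorized),
#'   `nPatients`, `pctPatients`.
#' @export
cohortSummary <- function(assignments, minSupport = 3, filterSupport = TRUE) {
    traj <- assignments$trajectory
    n <- nrow(assignments)
    tab <- table(traj, useNA = "no")
    ids <- as.integer(names(tab))
    counts <- as.integer(tab)
    uncat <- sum(is.na(traj))
    if (filterSupport) {
        weak <- counts < minSupport
        uncat <- uncat + sum(counts[weak])
        ids <- ids[!weak]
        counts <- counts[!weak]
    }
    out <- data.frame(trajectory = c(ids, NA_integer_),
                      nPatients = c(counts, uncat))
    out$pctPatients <- pctOfCohort(out$nPatients, n)
    out <- out[order(-out$nPatients, out$trajectory, na.last = TRUE), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
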