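## Rooting and orienting the principal tree, and enumerating root-to-leaf
## trajectories.

#' Find the root node
#'
#' The root is the node representing the state before any diagnosis, where
#' all cumulative counts are zero.  By default it is located by projecting
#' the patients' all-zero pre-diagnosis states onto the tree; these states
#' are identical vectors, so they agree on a single node.  A configurable
#' fallback picks the node whose assigned states have the smallest mean
#' total cumulative count.
#'
#' @param tree a [PrincipalTree-class] object.
#' @param states the [CumulativeStates-class] the tree was fitted on.
#' @param embedding the [StateEmbedding-class] used for fitting.
#' @param projection optional result of [projectStates()] on all state
#'   scores; recomputed if missing.
#' @param method `"zero-state"` (default) or `"min-count"`.
#' @return root node index (integer).
#' @export
findRoot <- function(tree, states, embedding, projection = NULL,
                     method = c("zero-state", "min-count")) {
    method <- match.arg(method)
    if (is.null(projection))
        projection <- projectStates(
            stateScores(embedding)[embedding@stateIndex, , drop = FALSE], tree)
    if (method == "zero-state") {
        pre <- which(isPreState(states))
        if (!length(pre)) {
            a <- assay(states, "cumulative")
            pre <- which(colSums(a) == 0)
        }
        if (!length(pre))
            stop("no all-zero pre-diagnosis states found; re-run cumulate()",
                 " with preState = TRUE")
        nodes <- unique(projection$node[pre])
        nodes[1L]
    } else {
        a <- assay(states, "cumulative")
        tot <- colSums(a)
        means <- vapply(seq_len(nNodes(tree)), function(j) {
            idx <- which(projection$node == j)
            if (!length(idx)) Inf else mean(tot[idx])
        }, numeric(1))
        which.min(means)
    }
}

#' Orient a tree away from a root
#'
#' Breadth-first orientation of an undirected tree away from the chosen
#' root; children are ordered by node index, making reports deterministic
#' and independent of input edge order.
#'
#' @param tree a [PrincipalTree-class] object, or a two-column matrix of
#'   (undirected) node-index edges.
#' @param root root node index.
#' @param labels optional display labels, one per node; defaults to
#'   0-based indices, the usual figure convention.
#' @return a [RootedTree-class] object.
#' @export
orientTree <- function(tree, root, labels = NULL) {
    E <- if (is(tree, "PrincipalTree")) treeEdges(tree) else as.matrix(tree)
    n <- max(E)
    if (!.isConnected(n, E))
        stop("edge set is not connected; cannot orient")
    root <- as.integer(root)
    if (is.null(labels)) labels <- as.character(seq_len(n) - 1L)
    adj <- .adjacency(n, E)
    parent <- rep(NA_integer_, n)
    depth <- rep(NA_integer_, n)
    depth[root] <- 0L
    children <- vector("list", n)
    frontier <- root
    visited <- logical(n)
    visited[root] <- TRUE
    while (length(frontier)) {
        nxt <- integer(0)
        for (u in frontier) {
            kids <- sort(setdiff(adj[[u]], which(visited)))
            for (v in kids) {
                parent[v] <- u
                depth[v] <- depth[u] + 1L
                visited[v] <- TRUE
            }
            children[[u]] <- kids
            nxt <- c(nxt, kids)
        }
        frontier <- nxt
    }
    children[vapply(children, is.null, logical(1))] <- list(integer(0))
    new("RootedTree", root = root, parent = parent,
        children = children, depth = as.integer(depth), labels = labels)
}

#' Enumerate root-to-leaf trajectories
#'
#' One trajectory per leaf, ordered by leaf index; each is the ordered node
#' sequence from the root to that leaf.
#'
#' @param rooted a [RootedTree-class] object.
#' @return list of integer node-index vectors.
#' @export
enumerateTrajectories <- function(rooted) {
    lapply(treeLeaves(rooted), function(leaf) {
        path <- leaf
        while (!is.na(rooted@parent[path[1L]]))
            path <- c(rooted@parent[path[1L]], path)
        path
    })
}

## edges (indices) on the path root -> node, excluding none
.pathEdges <- function(rooted, node) {
    out <- NULL
    while (!is.na(rooted@parent[node])) {
        out <- rbind(c(rooted@parent[node], node), out)
        node <- rooted@parent[node]
    }
    out
}

## all nodes in the subtree rooted at `node` (inclusive)
.subtreeNodes <- function(rooted, node) {
    out <- node
    frontier <- node
    while (length(frontier)) {
        kids <- unlist(rooted@children[frontier])
        out <- c(out, kids)
        frontier <- kids
    }
    out
}
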