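## Elastic principal tree: a tree of nodes embedded in the data space,
## fitted by minimizing
##
##   U = (1/W) sum_i w_i ||x_i - node(x_i)||^2          (approximation)
##     + lambda * sum_{(u,v) in E} ||p_u - p_v||^2      (edge stretching)
##     + mu * sum_{j: deg(j) >= 2} ||p_j - mean_{N(j)} p||^2   (star bending)
##
## Node positions are optimized by alternating (a) assignment of every data
## point to its nearest node and (b) an exact solve of the quadratic energy
## in the positions (a small symmetric positive-definite linear system).
## Topology is grown greedily from a 2-node segment along the first
## principal component by two grammar operations -- "bisect an edge" and
## "attach a node to a node" -- keeping at each step the candidate with the
## lowest optimized energy.

#' Fit an elastic principal tree
#'
#' @param points numeric matrix of embedded states (rows = points).
#' @param weights optional non-negative point weights (multiplicities from
#'   state deduplication); default 1.
#' @param nNodes number of tree nodes (default 25).
#' @param lambda edge-stretching penalty (default 0.01).
#' @param mu star-bending penalty (default 0.1).
#' @param tol relative-energy convergence tolerance of the position
#'   optimizer (default 1e-6).
#' @param maxIter position-optimization iteration cap per grammar step
#'   (default 100).
#' @param trialIter iteration cap used when scoring candidate grammar
#'   operations before the winner is fully optimized (default 10).
#' @param seed accepted for interface stability; the fit is deterministic
#'   and does not consume randomness.
#' @return a [PrincipalTree-class] object.
#' @export
fitPrincipalTree <- function(points, weights = NULL, nNodes = 25,
                             lambda = 0.01, mu = 0.1,
                             tol = 1e-6, maxIter = 100L, trialIter = 10L,
                             seed = NULL) {
    x <- as.matrix(points)
    if (!all(is.finite(x))) stop("points must be finite")
    n <- nrow(x)
    if (is.null(weights)) weights <- rep(1, n)
    if (length(weights) != n || any(weights < 0))
        stop("weights must be non-negative, one per point")
    nNodes <- as.integer(nNodes)
    if (nNodes < 2L) stop("nNodes must be at least 2")
    if (nNodes > n) stop("nNodes exceeds the number of points")

    W <- sum(weights)
    ## initialization: 2-node segment at +/- 1 sd along PC1
    mu0 <- colSums(x * weights) / W
    xc <- sweep(x, 2L, mu0, "-")
    cv <- crossprod(sweep(xc, 1L, sqrt(weights), "*")) / W
    eg <- eigen(cv, symmetric = TRUE)
    v1 <- eg$vectors[, 1L]
    if (v1[which.max(abs(v1))] < 0) v1 <- -v1
    s1 <- sqrt(max(eg$values[1L], .Machine$double.eps))
    P <- rbind(mu0 - s1 * v1, mu0 + s1 * v1)
    E <- cbind(1L, 2L)
    opt <- .optimizePositions(x, weights, P, E, lambda, mu, tol, maxIter)
    P <- opt$P
    energyTrace <- opt$energy

    while (nrow(P) < nNodes) {
        assign <- .nearestNode(x, P)$node
        cand <- .grammarCandidates(P, E, x, weights, assign)
        best <- NULL
        for (cc in cand) {
            o <- .optimizePositions(x, weights, cc$P, cc$E, lambda, mu,
                                    tol, trialIter)
            if (is.null(best) || o$energy < best$energy - 1e-12)
                best <- list(P = o$P, E = cc$E, energy = o$energy)
        }
        o <- .optimizePositions(x, weights, best$P, best$E, lambda, mu,
                                tol, maxIter)
        P <- o$P
        E <- best$E
        energyTrace <- c(energyTrace, o$energy)
    }
    new("PrincipalTree", nodePositions = unname(P), edges = unname(E),
        lambda = lambda, mu = mu, energyTrace = energyTrace)
}

## squared distances point -> node, nearest assignment with first-index
## tie-break
.nearestNode <- function(x, P) {
    d2 <- outer(rowSums(x^2), rep(1, nrow(P))) +
        outer(rep(1, nrow(x)), rowSums(P^2)) - 2 * x %*% t(P)
    d2[d2 < 0] <- 0
    node <- max.col(-d2, ties.method = "first")
    list(node = node, d2 = d2[cbind(seq_len(nrow(x)), node)])
}

.elasticEnergy <- function(x, w, P, E, lambda, mu, assign = NULL) {
    if (is.null(assign)) assign <- .nearestNode(x, P)$node
    W <- sum(w)
    approx <- sum(w * rowSums((x - P[assign, , drop = FALSE])^2)) / W
    stretch <- lambda * sum((P[E[, 1L], , drop = FALSE] -
                             P[E[, 2L], , drop = FALSE])^2)
    bend <- 0
    deg <- tabulate(c(E), nrow(P))
    adj <- .adjacency(nrow(P), E)
    for (j in which(deg >= 2L)) {
        ctr <- colMeans(P[adj[[j]], , drop = FALSE])
        bend <- bend + sum((P[j, ] - ctr)^2)
    }
    approx + stretch + mu * bend
}

.adjacency <- function(n, E) {
    adj <- vector("list", n)
    for (i in seq_len(nrow(E))) {
        u <- E[i, 1L]; v <- E[i, 2L]
        adj[[u]] <- c(adj[[u]], v)
        adj[[v]] <- c(adj[[v]], u)
    }
    adj
}

## alternate nearest-node assignment with the exact minimizer of the
## quadratic energy in the node positions:
##   (diag(Wj)/W + lambda*L + mu*K) P = S/W
## where L is the graph Laplacian and K = sum_j M_j' M_j over stars.
.optimizePositions <- function(x, w, P, E, lambda, mu, tol, maxIter) {
    n <- nrow(P)
    W <- sum(w)
    L <- matrix(0, n, n)
    for (i in seq_len(nrow(E))) {
        u <- E[i, 1L]; v <- E[i, 2L]
        L[u, u] <- L[u, u] + 1; L[v, v] <- L[v, v] + 1
        L[u, v] <- L[u, v] - 1; L[v, u] <- L[v, u] - 1
    }
    deg <- tabulate(c(E), n)
    adj <- .adjacency(n, E)
    K <- matrix(0, n, n)
    for (j in which(deg >= 2L)) {
        m <- numeric(n)
        m[j] <- 1
        m[adj[[j]]] <- -1 / deg[j]
        K <- K + tcrossprod(m)
    }
    energy <- Inf
    trace <- numeric(0)
    for (it in seq_len(max(maxIter, 1L))) {
        nn <- .nearestNode(x, P)
        assign <- nn$node
        Wj <- vapply(seq_len(n), function(j) sum(w[assign == j]), numeric(1))
        S <- matrix(0, n, ncol(x))
        for (j in seq_len(n)) {
            idx <- which(assign == j)
            if (length(idx))
                S[j, ] <- colSums(x[idx, , drop = FALSE] * w[idx])
        }
        A <- diag(Wj / W, n) + lambda * L + mu * K
        P <- solve(A, S / W)
        eNew <- .elasticEnergy(x, w, P, E, lambda, mu)
        trace <- c(trace, eNew)
        if (is.finite(energy) && abs(energy - eNew) <= tol * max(energy, 1e-12))
            { energy <- eNew; break }
        energy <- eNew
    }
    list(P = P, E = E, energy = energy, trace = trace)
}

## grammar operations: bisect each edge; attach a node to each node that
## has assigned points (new node at the centroid of those points)
.grammarCandidates <- function(P, E, x, w, assign) {
    cand <- list()
    for (i in seq_len(nrow(E))) {
        u <- E[i, 1L]; v <- E[i, 2L]
        newP <- rbind(P, (P[u, ] + P[v, ]) / 2)
        k <- nrow(newP)
        newE <- rbind(E[-i, , drop = FALSE], c(u, k), c(k, v))
        cand[[length(cand) + 1L]] <- list(P = newP, E = newE)
    }
    for (j in seq_len(nrow(P))) {
        idx <- which(assign == j)
        if (!length(idx)) next
        ctr <- colSums(x[idx, , drop = FALSE] * w[idx]) / sum(w[idx])
        if (all(abs(ctr - P[j, ]) < 1e-12)) {
            ## degenerate centroid: nudge toward the nearest neighbour node
            nb <- .adjacency(nrow(P), E)[[j]][1L]
            ctr <- P[j, ] + (P[nb, ] - P[j, ]) * 1e-3
        }
        newP <- rbind(P, ctr)
        newE <- rbind(E, c(j, nrow(newP)))
        cand[[length(cand) + 1L]] <- list(P = newP, E = newE)
    }
    cand
}

#' Project states onto a principal tree
#'
#' Assigns each embedded state to its nearest tree node by Euclidean
#' distance, breaking ties toward the smaller node index.
#'
#' @param points numeric matrix of embedded states (rows = points).
#' @param tree a [PrincipalTree-class] object.
#' @return data.frame with columns `node` (integer index) and `distance`.
#' @export
projectStates <- function(points, tree) {
    x <- as.matrix(points)
    P <- nodePositions(tree)
    if (ncol(x) != ncol(P))
        stop("points have ", ncol(x), " dims; tree has ", ncol(P))
    nn <- .nearestNode(x, P)
    data.frame(node = nn$node, distance = sqrt(nn$d2))
}

#' Persist a principal tree
#'
#' Writes the (optionally rooted) tree as GraphML, with node coordinates
#' as vertex attributes, or as JSON.
#'
#' @param tree a [PrincipalTree-class] object.
#' @param path output path.
#' @param format `"graphml"` or `"json"`.
#' @param rooted optional [RootedTree-class]; when given, edges are written
#'   directed parent -> child with node labels.
#' @return `path`, invisibly.
#' @export
writePrincipalTree <- function(tree, path, format = c("graphml", "json"),
                               rooted = NULL) {
    format <- match.arg(format)
    P <- nodePositions(tree)
    E <- if (is.null(rooted)) treeEdges(tree) else treeEdges(rooted)
    labels <- if (is.null(rooted)) as.character(seq_len(nrow(P)) - 1L)
              else nodeLabels(rooted)
    if (format == "json") {
        obj <- list(nodes = lapply(seq_len(nrow(P)), function(i)
                        list(label = labels[i], position = P[i, ])),
                    edges = lapply(seq_len(nrow(E)), function(i)
                        list(from = labels[E[i, 1L]], to = labels[E[i, 2L]])),
                    directed = !is.null(rooted),
                    lambda = tree@lambda, mu = tree@mu)
        if (!is.null(rooted)) {
            traj <- enumerateTrajectories(rooted)
            obj$root <- labels[rooted@root]
            obj$trajectories <- lapply(traj, function(t) labels[t])
        }
        write_json(obj, path, digits = NA, auto_unbox = TRUE)
    } else {
        vdf <- data.frame(name = labels, as.data.frame(P))
        names(vdf)[-1L] <- paste0("dim", seq_len(ncol(P)))
        edf <- data.frame(from = labels[E[, 1L]], to = labels[E[, 2L]])
        g <- graph_from_data_frame(edf, directed = !is.null(rooted),
                                   vertices = vdf)
        write_graph(g, path, format = "graphml")
    }
    invisible(path)
}
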