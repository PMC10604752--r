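## Standardization and PCA embedding of cumulative disease states.

#' Standardize cumulative states
#'
#' Centers each code to mean 0 and scales to unit variance using the
#' population (1/n) convention.  Zero-variance codes are mapped to all-zero
#' columns, with their scale recorded as 1 so the transform stays
#' invertible on the remaining codes.
#'
#' @param x a [CumulativeStates-class] object or a numeric states-by-codes
#'   matrix.
#' @return list with `z` (states x codes standardized matrix), `center`
#'   and `scale` (per-code).
#' @export
standardizeStates <- function(x) {
    m <- if (is(x, "CumulativeStates")) t(assay(x, "cumulative")) else as.matrix(x)
    if (nrow(m) < 2L)
        stop("standardization needs at least 2 state rows (variance undefined)")
    n <- nrow(m)
    center <- colMeans(m)
    v <- colMeans(m * m) - center^2          # population variance
    v[v < 0] <- 0
    zero <- v <= 1e-24
    scl <- sqrt(v)
    scl[zero] <- 1
    z <- sweep(sweep(m, 2L, center, "-"), 2L, scl, "/")
    z[, zero] <- 0
    list(z = z, center = center, scale = scl, zeroVar = unname(zero))
}

#' Elbow rule for the number of components
#'
#' Picks the component count at the point of maximal curvature of the
#' explained-variance profile: the 1-based index maximizing the discrete
#' second difference `v[i-1] - 2 v[i] + v[i+1]`, with ties broken toward
#' the smallest index.
#'
#' @param explainedVariance non-increasing positive numeric vector of
#'   length at least 3.
#' @return integer component count `k`.
#' @export
#' @examples
#' selectElbow(c(10, 2, 1.9, 1.8))  # 2
selectElbow <- function(explainedVariance) {
    v <- as.numeric(explainedVariance)
    if (length(v) < 3L)
        stop("elbow selection needs at least 3 variances")
    if (any(diff(v) > 1e-12))
        stop("explained variances must be non-increasing")
    i <- 2:(length(v) - 1L)
    curv <- v[i - 1L] - 2 * v[i] + v[i + 1L]
    as.integer(i[which.max(curv)])
}

#' Fit the PCA state embedding
#'
#' Standardizes the cumulative state matrix, collapses duplicate state
#' rows (recording multiplicities as point weights), and fits a principal
#' component analysis by eigen-decomposition of the weighted population
#' covariance.  Component signs follow a fixed convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param states a [CumulativeStates-class] object.
#' @param k number of components, or `"elbow"` to select it with
#'   [selectElbow()].  Capped at the number of codes and of unique states.
#' @return a [StateEmbedding-class] object.
#' @export
fitEmbedding <- function(states, k = 60) {
    std <- standardizeStates(states)
    z <- std$z
    dup <- duplicated(z)
    uniq <- z[!dup, , drop = FALSE]
    ## map every state row to its unique representative
    keyAll <- do.call(paste, c(as.data.frame(z), sep = "\r"))
    keyUniq <- keyAll[!dup]
    stateIndex <- match(keyAll, keyUniq)
    w <- as.numeric(tabulate(stateIndex, nbins = nrow(uniq)))

    ## weighted population covariance of the standardized data;
    ## weighting by multiplicity reproduces the full-data covariance
    n <- sum(w)
    zw <- sweep(uniq, 1L, sqrt(w), "*")
    cv <- crossprod(zw) / n
    eig <- eigen(cv, symmetric = TRUE)
    ev <- pmax(eig$values, 0)

    kmax <- min(ncol(z), nrow(uniq))
    if (identical(k, "elbow")) {
        k <- selectElbow(ev[seq_len(kmax)])
    } else {
        k <- as.integer(k)
        if (k > kmax)
            stop(sprintf("k = %d exceeds min(codes, unique states) = %d",
                         k, kmax))
    }
    L <- eig$vectors[, seq_len(k), drop = FALSE]
    ## deterministic sign convention
    for (j in seq_len(k)) {
        i <- which.max(abs(L[, j]))
        if (L[i, j] < 0) L[, j] <- -L[, j]
    }
    rownames(L) <- colnames(z)
    new("StateEmbedding",
        center = std$center, scaleValues = std$scale,
        loadings = L, explainedVariance = ev[seq_len(k)],
        scores = uniq %*% L, weights = w,
        stateIndex = as.integer(stateIndex),
        zeroVar = std$zeroVar)
}

#' Embed raw cumulative count vectors
#'
#' Applies a fitted embedding (centering, scaling, zero-variance rule,
#' projection onto the loadings) to new cumulative count vectors, e.g. the
#' all-zero pre-diagnosis state or a patient's final state.
#'
#' @param embedding a [StateEmbedding-class] object.
#' @param counts numeric vector (one state) or states-by-codes matrix on
#'   the raw cumulative-count scale, codes in the embedding's order.
#' @return score matrix (states x components).
#' @export
embedCounts <- function(embedding, counts) {
    m <- if (is.null(dim(counts))) matrix(counts, nrow = 1L) else as.matrix(counts)
    if (ncol(m) != length(embedding@center))
        stop("counts have ", ncol(m), " codes; embedding expects ",
             length(embedding@center))
    z <- sweep(sweep(m, 2L, embedding@center, "-"), 2L,
               embedding@scaleValues, "/")
    z[, embedding@zeroVar] <- 0   # matches the fit-time zero-variance rule
    z %*% embedding@loadings
}

#' Persist an embedding model
#'
#' Writes means, scales, loadings and explained variance as JSON and the
#' unique-state scores as CSV.
#'
#' @param embedding a [StateEmbedding-class] object.
#' @param jsonPath path for the JSON model file.
#' @param scoresPath optional path for the scores CSV.
#' @return `jsonPath`, invisibly.
#' @export
writeEmbedding <- function(embedding, jsonPath, scoresPath = NULL) {
    model <- list(center = embedding@center,
                  scale = embedding@scaleValues,
                  loadings = embedding@loadings,
                  explainedVariance = embedding@explainedVariance)
    write_json(model, jsonPath, digits = NA, auto_unbox = FALSE)
    if (!is.null(scoresPath))
        write.csv(as.data.frame(embedding@scores), scoresPath,
                  row.names = FALSE)
    invisible(jsonPath)
}
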