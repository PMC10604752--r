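## End-to-end orchestration and the printed reference edge table.

#' Run the full trajectory pipeline
#'
#' Executes, in order: claims encoding (one-hot, cumulative states with
#' pre-diagnosis rows), standardization + PCA embedding, elastic principal
#' tree fitting on the case states, rooting at the all-zero state and
#' orientation, case/control odds-ratio screening, per-edge
#' associated/branch-only disease attribution, the exclusivity summary,
#' and per-patient trajectory classification.  Fully deterministic given
#' `seed`.
#'
#' Supply either `caseRecords` (+ `controlRecords`) or a synthetic `spec`
#' with `nCases`, not both.
#'
#' @param caseRecords data.frame (`pid`, `date`, `code`) of case
#'   diagnoses, e.g. from [readClaims()].
#' @param controlRecords control-group records (needed for the screen).
#' @param spec a [TrajectorySpec-class]; the cohort is then generated with
#'   [generateCohort()].
#' @param nCases number of synthetic cases (with `spec`).
#' @param indexCode the index disease code (default `"335"`).
#' @param nComponents PCA components: an integer (capped at the data's
#'   rank bound) or `"elbow"` (default 60).
#' @param nNodes,lambda,mu elastic-tree parameters (defaults 25, 0.01,
#'   0.1).
#' @param orThreshold,alpha,ciMethod odds-ratio screen parameters
#'   (defaults 2, 0.05, `"woolf"`).
#' @param epsilon minimum mean-count increase for edge association
#'   (default 0.05).
#' @param minSupport minimum patients per reported trajectory (default 3).
#' @param seed integer seed used for all randomness (default 1).
#' @param controlRatio controls per case for synthetic cohorts (default 4).
#' @param outDir optional output directory; when given, all tables and the
#'   run manifest are written there.
#' @param verbose print per-stage record counts (default `FALSE`).
#' @return a list bundle: `cohort` (synthetic mode), `states`, `embedding`,
#'   `tree`, `rooted`, `projection`, `trajectories`, `screen`,
#'   `candidates`, `profiles`, `annotations`, `exclusivity`,
#'   `assignments`, `summary`, `manifest`.
#' @export
runPipeline <- function(caseRecords = NULL, controlRecords = NULL,
                        spec = NULL, nCases = NULL,
                        indexCode = "335", nComponents = 60,
                        nNodes = 25, lambda = 0.01, mu = 0.1,
                        orThreshold = 2, alpha = 0.05, ciMethod = "woolf",
                        epsilon = 0.05, minSupport = 3, seed = 1,
                        controlRatio = 4, outDir = NULL, verbose = FALSE) {
    if (is.null(spec) == is.null(caseRecords))
        stop("supply exactly one of caseRecords or spec")
    say <- function(...) if (verbose) message(...)
    cohort <- NULL
    if (!is.null(spec)) {
        if (is.null(nCases)) stop("nCases is required with spec")
        cohort <- generateCohort(spec, nCases, seed,
                                 controlRatio = controlRatio)
        caseRecords <- caseRecords(cohort)
        controlRecords <- controlRecords(cohort)
        say("simulate: ", nrow(caseRecords), " case / ",
            nrow(controlRecords), " control records")
    }
    caseIds <- unique(caseRecords$pid)

    oh <- oneHotDaily(caseRecords)
    states <- cumulate(oh)
    say("encode: ", nrow(caseRecords), " records -> ", ncol(states),
        " states x ", nrow(states), " codes")

    kmax <- min(nrow(states), ncol(states))
    k <- if (identical(nComponents, "elbow")) "elbow"
         else min(as.integer(nComponents), kmax)
    embedding <- fitEmbedding(states, k = k)
    say("embed: ", nrow(stateScores(embedding)), " unique states in ",
        ncol(stateScores(embedding)), " dims")

    tree <- fitPrincipalTree(stateScores(embedding),
                             weights = stateWeights(embedding),
                             nNodes = nNodes, lambda = lambda, mu = mu,
                             seed = seed)
    allScores <- stateScores(embedding)[embedding@stateIndex, , drop = FALSE]
    projection <- projectStates(allScores, tree)
    root <- findRoot(tree, states, embedding, projection)
    rooted <- orientTree(tree, root)
    trajectories <- enumerateTrajectories(rooted)
    say("tree: ", nNodes(tree), " nodes, ", length(trajectories),
        " trajectories, root ", nodeLabels(rooted)[root])

    screen <- NULL
    candidates <- indexCode
    if (!is.null(controlRecords) && length(unique(controlRecords$pid))) {
        allRecords <- rbind(caseRecords[, c("pid", "code")],
                            controlRecords[, c("pid", "code")])
        screen <- screenComorbidities(allRecords, caseIds,
                                      unique(controlRecords$pid),
                                      orThreshold = orThreshold,
                                      alpha = alpha, method = ciMethod)
        candidates <- union(screen$code[screen$significant], indexCode)
        say("screen: ", sum(screen$significant), " of ", nrow(screen),
            " codes significant")
    }

    profiles <- nodeProfiles(projection, states, nNodes(tree))
    annotations <- annotateEdges(rooted, profiles, candidates, projection,
                                 states, epsilon = epsilon)
    exclusivity <- exclusivitySummary(annotations, indexCode = indexCode)
    assignments <- classifyPatients(states, embedding, tree, rooted,
                                    trajectories, projection)
    summary <- cohortSummary(assignments, minSupport = minSupport)
    say("classify: ", sum(is.na(assignments$trajectory)),
        " uncategorized of ", nrow(assignments))

    manifest <- list(
        mode = if (is.null(cohort)) "records" else "synthetic",
        nCases = length(caseIds), indexCode = indexCode,
        nComponents = nComponents, nNodes = nNodes,
        lambda = lambda, mu = mu, orThreshold = orThreshold,
        alpha = alpha, ciMethod = ciMethod, epsilon = epsilon,
        minSupport = minSupport, seed = seed, controlRatio = controlRatio,
        nCaseRecords = nrow(caseRecords),
        nControlRecords = if (is.null(controlRecords)) 0L
                          else nrow(controlRecords),
        nStates = ncol(states),
        nUniqueStates = nrow(stateScores(embedding)))

    bundle <- list(cohort = cohort, states = states, embedding = embedding,
                   tree = tree, rooted = rooted, projection = projection,
                   trajectories = trajectories, screen = screen,
                   candidates = candidates, profiles = profiles,
                   annotations = annotations, exclusivity = exclusivity,
                   assignments = assignments, summary = summary,
                   manifest = manifest)
    if (!is.null(outDir)) writePipelineBundle(bundle, outDir)
    bundle
}

#' Write a pipeline result bundle
#'
#' @param bundle result of [runPipeline()].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writePipelineBundle <- function(bundle, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(bundle$screen))
        writeScreen(bundle$screen, file.path(outDir, "association.csv"))
    writePrincipalTree(bundle$tree, file.path(outDir, "tree.graphml"),
                       "graphml", rooted = bundle$rooted)
    writePrincipalTree(bundle$tree, file.path(outDir, "tree.json"),
                       "json", rooted = bundle$rooted)
    writeEdgeAnnotations(bundle$annotations,
                         file.path(outDir, "edge_annotations.csv"))
    write_json(as.list(bundle$exclusivity),
               file.path(outDir, "exclusivity.json"), auto_unbox = TRUE)
    write.csv(bundle$assignments, file.path(outDir, "assignments.csv"),
              row.names = FALSE)
    write.csv(bundle$summary, file.path(outDir, "trajectory_summary.csv"),
              row.names = FALSE)
    write_json(bundle$manifest, file.path(outDir, "manifest.json"),
               auto_unbox = TRUE, digits = NA)
    invisible(outDir)
}

#' Load the printed reference edge table
#'
#' The packaged fixture transcribes a published 25-node, 24-edge disease
#' progression tree: per directed edge, the associated and branch-only
#' ICD-9 code sets and the number (and percentage) of patients traversing
#' the edge.  The loader verifies the file checksum and the structural
#' contract (24 edges over nodes 0-24, root 0).
#'
#' @return list: `annotations` (data.frame with `parent`, `child`,
#'   list-columns `associated`, `branchOnly`, `nPatients`, `pctPatients`),
#'   `rooted` (a [RootedTree-class] rooted at label "0"), `root`.
#' @export
loadTable2Fixture <- function() {
    path <- system.file("extdata", "table2_edges.tsv", package = "trajtree")
    if (!nzchar(path)) stop("fixture file not installed")
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .TABLE2_MD5))
        stop("fixture checksum mismatch: expected ", .TABLE2_MD5,
             ", got ", md5)
    df <- read.delim(path, colClasses = "character")
    splitCodes <- function(x) lapply(strsplit(x, ","),
                                     function(s) s[nzchar(s)])
    ann <- data.frame(parent = df$parent, child = df$child,
                      stringsAsFactors = FALSE)
    ann$associated <- splitCodes(df$associated)
    ann$branchOnly <- splitCodes(df$branch_only)
    ann$nPatients <- as.integer(df$n_patients)
    ann$pctPatients <- as.numeric(df$pct_patients)
    if (nrow(ann) != 24L)
        stop("fixture must have 24 edges, found ", nrow(ann))
    labs <- unique(c(ann$parent, ann$child))
    if (!setequal(labs, as.character(0:24)))
        stop("fixture nodes must be 0-24")
    rooted <- rootedTreeFromEdges(ann[, c("parent", "child")], root = "0")
    list(annotations = ann, rooted = rooted, root = "0")
}

.TABLE2_MD5 <- "7191cc2e32535c3abe9a2b4340463581"

#' Build a rooted tree from labelled edges
#'
#' @param edges data.frame or matrix with two label columns
#'   (parent/from, child/to); edges are treated as undirected and oriented
#'   away from `root`.
#' @param root root node label.
#' @return a [RootedTree-class] object.
#' @export
rootedTreeFromEdges <- function(edges, root) {
    e <- as.matrix(edges)
    labs <- unique(c(e))
    if (all(grepl("^[0-9]+$", labs)))
        labs <- labs[order(as.numeric(labs))]
    else labs <- sort(labs)
    idx <- matrix(match(e, labs), ncol = 2L)
    orientTree(idx, root = match(root, labs), labels = labs)
}

#' Recompute branch-only sets and the exclusivity summary of an edge table
#'
#' Given directed edges with associated-disease sets (for example the
#' printed reference table, or any [annotateEdges()] output), recomputes
#' the branch-only column with the sibling/ancestor exclusion rule and the
#' exclusivity summary.
#'
#' @param annotations data.frame with `parent`, `child` labels and
#'   list-column `associated`.
#' @param root root node label.
#' @param indexCode index disease excluded from the summary
#'   (default `"335"`).
#' @return list: `annotations` (input plus recomputed `branchOnly`),
#'   `exclusivity` (named counts), `leaves` (leaf labels), `rooted`.
#' @export
analyzeEdgeTable <- function(annotations, root, indexCode = "335") {
    rooted <- rootedTreeFromEdges(annotations[, c("parent", "child")], root)
    ## check the printed orientation agrees with the breadth-first one
    E <- treeEdges(rooted)
    lab <- nodeLabels(rooted)
    key <- paste(lab[E[, 1L]], lab[E[, 2L]])
    if (!setequal(key, paste(annotations$parent, annotations$child)))
        stop("edge directions disagree with orientation away from the root")
    out <- annotations
    out$branchOnly <- branchOnlySets(out, rooted)
    list(annotations = out,
         exclusivity = exclusivitySummary(out, indexCode = indexCode),
         leaves = lab[treeLeaves(rooted)],
         rooted = rooted)
}
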