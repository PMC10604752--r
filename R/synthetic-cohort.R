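## Synthetic claims generator with a planted trajectory topology.
##
## Cases walk a root-to-leaf path of the stage tree; each stage's onset
## codes are recorded with probability onsetProb at visits falling inside
## the stage's half-open day window, so cumulative counts of those codes
## grow modestly along the stage.
## Background codes occur in cases and matched controls at the same
## per-visit probability.  Visit days follow a homogeneous Poisson process.
## Every patient has a private pseudo-random stream derived from
## (seed, patient index), so adding patients does not perturb existing
## ones.

#' Construct a trajectory specification
#'
#' @param stageEdges two-column character matrix (or data.frame) of
#'   directed stage edges forming a rooted tree.
#' @param onsets named list: stage -> ICD-9 codes whose onset marks the
#'   stage.
#' @param durations named numeric: stage -> dwell time in days.
#' @param visitRate expected visits per 30 days (default 2).
#' @param backgroundCodes codes shared by cases and controls.
#' @param backgroundProb per-visit probability of each background code
#'   (default 0.1).
#' @param onsetProb per-visit probability that each of the current stage's
#'   onset codes is recorded at a visit (default 0.3): claims record a
#'   diagnosis on some visits, not all, so per-code cumulative counts stay
#'   in a realistic single-digit range.
#' @param branchProbs named list: bifurcation stage -> named child
#'   probabilities.  Unspecified bifurcations default to uniform.
#' @return a validated [TrajectorySpec-class] object.
#' @export
trajectorySpec <- function(stageEdges, onsets, durations, visitRate = 2,
                           backgroundCodes = character(),
                           backgroundProb = 0.1, onsetProb = 0.3,
                           branchProbs = list()) {
    e <- as.matrix(stageEdges)
    storage.mode(e) <- "character"
    stages <- unique(c(e))
    for (s in stages) {
        kids <- e[e[, 1L] == s, 2L]
        if (length(kids) >= 2L && is.null(branchProbs[[s]]))
            branchProbs[[s]] <- setNames(rep(1 / length(kids),
                                             length(kids)), kids)
    }
    onsets <- lapply(onsets, normalizeIcd9)
    new("TrajectorySpec", stageEdges = e, onsets = onsets,
        durations = durations, visitRate = visitRate,
        backgroundCodes = normalizeIcd9(backgroundCodes),
        backgroundProb = backgroundProb, onsetProb = onsetProb,
        branchProbs = branchProbs)
}

## deterministic per-patient substream seed, kept below 2^31
.patientSeed <- function(seed, idx) {
    as.integer((as.numeric(seed) %% 65011 + 1) * 30011 + idx * 7919) %%
        2147483629L
}

.specRoot <- function(spec) {
    setdiff(spec@stageEdges[, 1L], spec@stageEdges[, 2L])
}

## sample one root -> leaf stage path using the patient's RNG stream
.samplePath <- function(spec) {
    cur <- .specRoot(spec)
    path <- cur
    repeat {
        kids <- spec@stageEdges[spec@stageEdges[, 1L] == cur, 2L]
        if (!length(kids)) break
        cur <- if (length(kids) == 1L) kids
               else sample(names(spec@branchProbs[[cur]]), 1L,
                           prob = spec@branchProbs[[cur]])
        path <- c(path, cur)
    }
    path
}

## one case patient's visit records along a stage path
.simulateCase <- function(spec, path, startDate) {
    durs <- spec@durations[path]
    total <- sum(durs)
    ends <- cumsum(durs)                 # half-open windows [start, end)
    starts <- c(0, head(ends, -1L))
    nVisits <- rpois(1L, total * spec@visitRate / 30)
    days <- sort(unique(floor(runif(nVisits, 0, total))))
    recs <- list()
    for (d in days) {
        stage <- path[which(d >= starts & d < ends)[1L]]
        on <- spec@onsets[[stage]]
        codes <- on[runif(length(on)) < spec@onsetProb]
        bg <- spec@backgroundCodes[
            runif(length(spec@backgroundCodes)) < spec@backgroundProb]
        codes <- c(codes, bg)
        if (length(codes))
            recs[[length(recs) + 1L]] <-
                data.frame(date = startDate + d, code = codes)
    }
    list(records = if (length(recs)) do.call(rbind, recs)
                   else data.frame(date = as.Date(character()),
                                   code = character()),
         path = path)
}

## background-only visit records (controls)
.simulateControl <- function(spec, totalDays, visitRate, startDate) {
    nVisits <- rpois(1L, totalDays * visitRate / 30)
    days <- sort(unique(floor(runif(nVisits, 0, totalDays))))
    recs <- list()
    for (d in days) {
        bg <- spec@backgroundCodes[
            runif(length(spec@backgroundCodes)) < spec@backgroundProb]
        if (length(bg))
            recs[[length(recs) + 1L]] <-
                data.frame(date = startDate + d, code = bg)
    }
    if (length(recs)) do.call(rbind, recs)
    else data.frame(date = as.Date(character()), code = character())
}

#' Generate a synthetic case/control cohort
#'
#' Simulates `nCases` case patients walking the planted topology plus a
#' gender- and birthdate-matched control group, with background diagnoses
#' occurring at the same per-visit rate in both groups.  Deterministic
#' given `(spec, nCases, seed)`.
#'
#' @param spec a [TrajectorySpec-class] object.
#' @param nCases number of case patients (>= 1).
#' @param seed integer seed.
#' @param controlRatio controls per case (default 4; 0 generates a
#'   cases-only cohort).
#' @param controlVisitRate control visit intensity per 30 days; the source
#'   data do not pin this down, so it defaults to the case `visitRate`.
#' @param matchWindowDays maximum case-control birthdate difference in
#'   days (default 1000, i.e. a three-year age range).
#' @param pMale probability of male gender (default 0.6145, the case
#'   cohort's share).
#' @param startDate first possible visit date (default `"2000-01-01"`).
#' @return a [SyntheticCohort-class] object.
#' @export
generateCohort <- function(spec, nCases, seed, controlRatio = 4,
                           controlVisitRate = spec@visitRate,
                           matchWindowDays = 1000, pMale = 0.6145,
                           startDate = as.Date("2000-01-01")) {
    validObject(spec)
    nCases <- as.integer(nCases)
    if (nCases < 1L) stop("nCases must be at least 1")
    startDate <- as.Date(startDate)
    birthBase <- as.Date("1950-01-01")
    birthRange <- 7300          # 20-year birth window

    caseIds <- sprintf("C%04d", seq_len(nCases))
    caseRecs <- vector("list", nCases)
    paths <- vector("list", nCases)
    onsetDates <- vector("list", nCases)
    gender <- character(nCases)
    birth <- rep(birthBase, nCases)
    for (i in seq_len(nCases)) {
        set.seed(.patientSeed(seed, i))
        gender[i] <- if (runif(1) < pMale) "M" else "F"
        birth[i] <- birthBase + floor(runif(1, 0, birthRange))
        path <- .samplePath(spec)
        sim <- .simulateCase(spec, path, startDate)
        paths[[i]] <- path
        r <- sim$records
        caseRecs[[i]] <- if (nrow(r))
            data.frame(pid = caseIds[i], date = r$date, code = r$code)
        else data.frame(pid = character(), date = as.Date(character()),
                        code = character())
        onsetAll <- unlist(spec@onsets[path], use.names = FALSE)
        od <- vapply(onsetAll, function(cd) {
            hit <- r$date[r$code == cd]
            if (length(hit)) as.numeric(min(hit)) else NA_real_
        }, numeric(1))
        onsetDates[[i]] <- setNames(as.Date(od, origin = "1970-01-01"),
                                    onsetAll)
    }

    cases <- data.frame(pid = caseIds, gender = gender, birthdate = birth)
    if (controlRatio == 0) {
        empty <- data.frame(pid = character(), date = as.Date(character()),
                            code = character())
        return(new("SyntheticCohort",
                   caseRecords = do.call(rbind, caseRecs),
                   controlRecords = empty,
                   truth = list(paths = setNames(paths, caseIds),
                                onsets = setNames(onsetDates, caseIds)),
                   matching = data.frame(casePid = character(),
                                         controlPid = character()),
                   demographics = cbind(cases, group = "case")))
    }

    ## control pool: controlRatio + 2 candidates jittered around each case,
    ## eligible for their template case by construction
    nPool <- (controlRatio + 2L) * nCases
    poolIds <- sprintf("N%05d", seq_len(nPool))
    poolGender <- character(nPool)
    poolBirth <- rep(birthBase, nPool)
    for (j in seq_len(nPool)) {
        set.seed(.patientSeed(seed, nCases + j))
        tmpl <- ((j - 1L) %% nCases) + 1L
        poolGender[j] <- gender[tmpl]
        poolBirth[j] <- birth[tmpl] +
            round(runif(1, -matchWindowDays, matchWindowDays))
    }
    pool <- data.frame(pid = poolIds, gender = poolGender,
                       birthdate = poolBirth)
    matching <- sampleMatchedControls(cases, pool, ratio = controlRatio,
                                      windowDays = matchWindowDays,
                                      seed = seed)

    totalDays <- max(vapply(paths, function(p) sum(spec@durations[p]),
                            numeric(1)))
    sel <- match(matching$controlPid, poolIds)
    ctrlRecs <- vector("list", length(sel))
    for (k in seq_along(sel)) {
        j <- sel[k]
        set.seed(.patientSeed(seed, nCases + nPool + j))
        r <- .simulateControl(spec, totalDays, controlVisitRate, startDate)
        ctrlRecs[[k]] <- if (nrow(r))
            data.frame(pid = poolIds[j], date = r$date, code = r$code)
        else data.frame(pid = character(), date = as.Date(character()),
                        code = character())
    }

    demo <- rbind(cbind(cases, group = "case"),
                  cbind(pool[sel, , drop = FALSE], group = "control"))
    rownames(demo) <- NULL
    new("SyntheticCohort",
        caseRecords = do.call(rbind, caseRecs),
        controlRecords = do.call(rbind, ctrlRecs),
        truth = list(paths = setNames(paths, caseIds),
                     onsets = setNames(onsetDates, caseIds)),
        matching = matching,
        demographics = demo)
}

#' Sample age/gender-matched controls
#'
#' For each case (in input order), selects `ratio` pool members of the same
#' gender whose birthdate lies within `windowDays` of the case's, without
#' replacement across cases.  Among eligible candidates the closest
#' birthdates are preferred, ties broken by smallest pool index, making the
#' matching deterministic.
#'
#' @param cases data.frame with columns `pid`, `gender`, `birthdate`.
#' @param pool candidate data.frame with the same columns.
#' @param ratio controls per case (default 4).
#' @param windowDays maximum absolute birthdate difference (default 1000).
#' @param seed accepted for interface stability; the matching itself is
#'   deterministic.
#' @return data.frame (`casePid`, `controlPid`), `ratio` rows per case.
#' @export
sampleMatchedControls <- function(cases, pool, ratio = 4, windowDays = 1000,
                                  seed = NULL) {
    used <- logical(nrow(pool))
    out <- vector("list", nrow(cases))
    for (i in seq_len(nrow(cases))) {
        elig <- which(!used &
                      pool$gender == cases$gender[i] &
                      abs(as.numeric(pool$birthdate) -
                          as.numeric(cases$birthdate[i])) <= windowDays)
        if (length(elig) < ratio)
            stop("insufficient eligible controls for case ", cases$pid[i],
                 " (need ", ratio, ", found ", length(elig), ")")
        d <- abs(as.numeric(pool$birthdate[elig]) -
                 as.numeric(cases$birthdate[i]))
        pick <- elig[order(d, elig)][seq_len(ratio)]
        used[pick] <- TRUE
        out[[i]] <- data.frame(casePid = cases$pid[i],
                               controlPid = pool$pid[pick])
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Write cohort claims and ground truth
#'
#' Claims go to `pid,date,icd9` CSVs (cases and controls separately); the
#' planted truth (stage paths, onset dates, matching) to JSON.
#'
#' @param cohort a [SyntheticCohort-class] object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeClaims(caseRecords(cohort), file.path(dir, "cases.csv"))
    writeClaims(controlRecords(cohort), file.path(dir, "controls.csv"))
    truth <- cohortTruth(cohort)
    write_json(list(
        paths = truth$paths,
        onsets = lapply(truth$onsets, function(x)
            setNames(as.list(format(x, "%Y-%m-%d")), names(x))),
        matching = controlMatching(cohort)),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
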