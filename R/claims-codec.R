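## Claims reading/validation and the one-hot -> cumulative state encoding.

#' Normalize ICD-9 codes to 3-character categories
#'
#' Drops any decimal subdivision, upper-cases, and left-pads purely numeric
#' stems with zeros, so that `"335.20"` becomes `"335"` and `"45"` becomes
#' `"045"`.  All downstream analysis works at this 3-digit category level.
#'
#' @param code character vector of raw ICD-9 codes.
#' @return character vector of 3-character category codes.
#' @export
#' @examples
#' normalizeIcd9(c("335.20", "45", "v82.1"))
normalizeIcd9 <- function(code) {
    x <- toupper(trimws(as.character(code)))
    x <- sub("\\..*$", "", x)
    num <- grepl("^[0-9]+$", x)
    x[num] <- sprintf("%03d", as.integer(x[num]))
    substr(x, 1L, 3L)
}

#' Read a claims file
#'
#' Reads a CSV of diagnosis records with header `pid,date,icd9`, normalizes
#' the codes to 3-digit ICD-9 categories and parses the dates.  Malformed
#' rows are reported with their line numbers.
#'
#' @param path path to a CSV file with columns `pid`, `date`, `icd9`.
#' @return data.frame with columns `pid` (character), `date` (`Date`) and
#'   `code` (3-character ICD-9 category).
#' @seealso [writeClaims()], [oneHotDaily()]
#' @export
readClaims <- function(path) {
    df <- read.csv(path, colClasses = "character")
    need <- c("pid", "date", "icd9")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("claims file is missing column(s): ", paste(miss, collapse = ", "))
    date <- as.Date(df$date, format = "%Y-%m-%d")
    bad <- which(is.na(date) & nzchar(df$date))
    bad <- union(bad, which(!nzchar(df$date)))
    if (length(bad))
        stop("unparseable date(s) at line(s): ",
             paste(head(sort(bad) + 1L, 20L), collapse = ", "))
    data.frame(pid = df$pid, date = date, code = normalizeIcd9(df$icd9),
               stringsAsFactors = FALSE)
}

#' Write claims records
#'
#' Writes normalized records back to the `pid,date,icd9` CSV format, so
#' that `readClaims(writeClaims(x))` round-trips.
#'
#' @param records data.frame with columns `pid`, `date`, `code`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeClaims <- function(records, path) {
    out <- data.frame(pid = records$pid,
                      date = format(records$date, "%Y-%m-%d"),
                      icd9 = records$code)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' One-hot daily diagnosis table
#'
#' Collapses records to one diagnosis per patient per day: the resulting
#' binary matrix has one column per (pid, date) state and one row per ICD-9
#' category, with a 1 wherever the patient has at least one record of the
#' code on the date.
#'
#' @param records data.frame with columns `pid`, `date`, `code`
#'   (normalized; see [readClaims()]).
#' @param codes optional code universe; defaults to the sorted set of codes
#'   observed in `records`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"onehot"` (codes x states, 0/1) and colData `pid`, `date`.  Columns
#'   are ordered by (pid, date).
#' @export
oneHotDaily <- function(records, codes = NULL) {
    if (is.null(codes)) codes <- sort(unique(records$code))
    if (is.null(records$code) || is.null(records$pid) || is.null(records$date))
        stop("records need columns pid, date, code")
    keyDf <- unique(data.frame(pid = records$pid, date = records$date))
    keyDf <- keyDf[order(keyDf$pid, keyDf$date), , drop = FALSE]
    key <- paste(keyDf$pid, keyDf$date)
    m <- matrix(0L, nrow = length(codes), ncol = nrow(keyDf),
                dimnames = list(codes, NULL))
    ri <- match(records$code, codes)
    ci <- match(paste(records$pid, records$date), key)
    keep <- !is.na(ri)
    m[cbind(ri[keep], ci[keep])] <- 1L
    SummarizedExperiment(
        assays = list(onehot = m),
        colData = DataFrame(pid = keyDf$pid, date = keyDf$date))
}

#' Cumulative disease-state matrix
#'
#' Turns the per-day one-hot table into cumulative states: for each patient
#' the code counts are summed over date-ordered days, so each state holds
#' the number of distinct diagnosis days per code up to and including its
#' date.  A synthetic all-zero pre-diagnosis state is prepended per patient
#' (dated the day before the first visit); this is the state that later
#' anchors the root of the trajectory tree.
#'
#' @param onehot result of [oneHotDaily()].
#' @param preState logical; materialize the all-zero pre-diagnosis state
#'   per patient (default `TRUE`).
#' @return a [CumulativeStates-class] object.
#' @export
cumulate <- function(onehot, preState = TRUE) {
    m <- assay(onehot, "onehot")
    cd <- colData(onehot)
    if (anyDuplicated(paste(cd$pid, cd$date)))
        stop("duplicate (pid, date) columns; run oneHotDaily() first")
    ord <- order(cd$pid, cd$date)
    m <- m[, ord, drop = FALSE]
    pid <- cd$pid[ord]
    date <- cd$date[ord]

    blocks <- split(seq_along(pid), factor(pid, levels = unique(pid)))
    outCols <- vector("list", length(blocks))
    outMeta <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
        idx <- blocks[[b]]
        blk <- m[, idx, drop = FALSE]
        cum <- blk
        if (ncol(blk) > 1L)
            cum <- matrixCumsumCols(blk)
        if (preState) {
            cum <- cbind(0L, cum)
            outMeta[[b]] <- data.frame(
                pid = pid[idx[1L]],
                date = c(date[idx[1L]] - 1L, date[idx]),
                preState = c(TRUE, rep(FALSE, length(idx))))
        } else {
            outMeta[[b]] <- data.frame(pid = pid[idx[1L]], date = date[idx],
                                       preState = FALSE)
        }
        outCols[[b]] <- cum
    }
    mat <- do.call(cbind, outCols)
    meta <- do.call(rbind, outMeta)
    rownames(mat) <- rownames(m)
    new("CumulativeStates", SummarizedExperiment(
        assays = list(cumulative = mat),
        colData = DataFrame(meta)))
}

## column-wise running sum, one patient block at a time
matrixCumsumCols <- function(m) {
    t(apply(m, 1L, cumsum))
}

#' Export the cumulative matrix
#'
#' Writes the cumulative state matrix as a wide CSV (one row per state) or
#' as a sparse triplet file (`state,code,count`, zero cells omitted).
#'
#' @param states a [CumulativeStates-class] object.
#' @param path output path.
#' @param format `"wide"` or `"triplet"`.
#' @return `path`, invisibly.
#' @export
writeCumulativeStates <- function(states, path, format = c("wide", "triplet")) {
    format <- match.arg(format)
    a <- assay(states, "cumulative")
    cd <- colData(states)
    if (format == "wide") {
        df <- data.frame(pid = cd$pid, date = format(cd$date, "%Y-%m-%d"),
                         preState = cd$preState, t(a), check.names = FALSE)
        write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else {
        nz <- which(a != 0, arr.ind = TRUE)
        df <- data.frame(state = nz[, 2L], code = rownames(a)[nz[, 1L]],
                         count = a[nz])
        df <- df[order(df$state, df$code), , drop = FALSE]
        write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
    invisible(path)
}
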