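## Case/control odds-ratio screen for candidate comorbidities.
##
## Counting is patient-level ("ever diagnosed"): the 2x2 table compares the
## number of case and control *patients* with at least one record of the
## code at any date.  The screening rule follows the usual epidemiological
## convention: OR at least `orThreshold` and the lower bound of the
## log-odds confidence interval above 1 (equivalently, the CI on the log
## scale excludes 0).

#' 2x2 contingency counts for a disease code
#'
#' @param records data.frame with columns `pid`, `code` (dates are
#'   irrelevant for ever-diagnosed counting).
#' @param caseIds,controlIds disjoint patient id vectors.
#' @param code ICD-9 category code.
#' @return named integer vector `c(a, b, c, d)`: cases with/without the
#'   code, controls with/without.
#' @export
contingencyCounts <- function(records, caseIds, controlIds, code) {
    if (length(intersect(caseIds, controlIds)))
        stop("case and control id sets overlap")
    with <- unique(records$pid[records$code == code])
    a <- sum(caseIds %in% with)
    cc <- sum(controlIds %in% with)
    c(a = a, b = length(caseIds) - a,
      c = cc, d = length(controlIds) - cc)
}

#' Odds ratio with confidence interval
#'
#' Point estimate `ad/(bc)`, reported as `+Inf` when controls have zero
#' exposed and cases at least one, and `0` in the mirrored case.  The
#' default Woolf interval is `exp(log(OR) +/- z * sqrt(1/a+1/b+1/c+1/d))`;
#' whenever any cell is zero the interval (and, for method
#' `"haldane-woolf"`, also the point estimate) is computed on the
#' Haldane-Anscombe table with 0.5 added to every cell, keeping the
#' structurally infinite bound at `+Inf`.  Method `"exact"` delegates to
#' the conditional maximum-likelihood interval of [stats::fisher.test()].
#'
#' @param a,b,c,d non-negative 2x2 counts (cases with/without, controls
#'   with/without).
#' @param method `"woolf"` (default), `"haldane-woolf"` or `"exact"`.
#' @param conf confidence level (default 0.95).
#' @return one-row data.frame: `a,b,c,d,or,ciLow,ciHigh,pValue,undefined`.
#'   `undefined` is `TRUE` when `a = 0` and `c = 0` (no signal); no error
#'   is raised in that case.
#' @export
oddsRatio <- function(a, b, c, d, method = c("woolf", "haldane-woolf", "exact"),
                      conf = 0.95) {
    method <- match.arg(method)
    if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
    if (a + b <= 0 || c + d <= 0) stop("both group margins must be positive")
    if (a == 0 && c == 0)
        return(data.frame(a = a, b = b, c = c, d = d, or = NA_real_,
                          ciLow = NA_real_, ciHigh = NA_real_,
                          pValue = NA_real_, undefined = TRUE))
    orPoint <- if (c == 0 && a > 0) Inf
               else if (a == 0 && c > 0) 0
               else (a * d) / (b * c)
    z <- qnorm(1 - (1 - conf) / 2)
    if (method == "exact") {
        ft <- fisher.test(matrix(c(a, c, b, d), 2L), conf.level = conf)
        ci <- unname(ft$conf.int)
        res <- data.frame(a = a, b = b, c = c, d = d, or = orPoint,
                          ciLow = ci[1L], ciHigh = ci[2L],
                          pValue = ft$p.value, undefined = FALSE)
        return(res)
    }
    anyZero <- any(c(a, b, c, d) == 0)
    tab <- if (anyZero) c(a, b, c, d) + 0.5 else c(a, b, c, d)
    lor <- log(tab[1L] * tab[4L] / (tab[2L] * tab[3L]))
    se <- sqrt(sum(1 / tab))
    ciLow <- exp(lor - z * se)
    ciHigh <- exp(lor + z * se)
    if (c == 0 && a > 0) ciHigh <- Inf
    if (a == 0 && c > 0) ciLow <- 0
    if (method == "haldane-woolf" && anyZero) {
        orUse <- tab[1L] * tab[4L] / (tab[2L] * tab[3L])
        if (!(c == 0 && a > 0) && !(a == 0 && c > 0)) orPoint <- orUse
    }
    pValue <- 2 * pnorm(-abs(lor / se))
    data.frame(a = a, b = b, c = c, d = d, or = orPoint,
               ciLow = ciLow, ciHigh = ciHigh, pValue = pValue,
               undefined = FALSE)
}

#' Screen all observed codes for case association
#'
#' Builds the patient-level 2x2 table for every code observed in either
#' group and flags codes whose odds ratio is at least `orThreshold` with a
#' confidence interval excluding 1 (the "CI excludes zero on the log-odds
#' scale" rule).  Results are sorted by code.
#'
#' @param records data.frame with columns `pid`, `code` covering both
#'   groups.
#' @param caseIds,controlIds disjoint patient id vectors.
#' @param orThreshold minimum odds ratio (default 2).
#' @param alpha significance level; the CI level is `1 - alpha`
#'   (default 0.05).
#' @param method CI method passed to [oddsRatio()].
#' @param adjust `"none"` (default; the screening rule is CI-based) or
#'   `"BH"` to additionally require a Benjamini-Hochberg adjusted p-value
#'   below `alpha`.
#' @return data.frame, one row per code: the [oddsRatio()] columns plus
#'   `code` and `significant`.
#' @export
screenComorbidities <- function(records, caseIds, controlIds,
                                orThreshold = 2, alpha = 0.05,
                                method = "woolf",
                                adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    if (orThreshold <= 0 || alpha <= 0) stop("thresholds must be positive")
    inGroups <- records$pid %in% c(caseIds, controlIds)
    codes <- sort(unique(records$code[inGroups]))
    rows <- lapply(codes, function(cd) {
        ct <- contingencyCounts(records, caseIds, controlIds, cd)
        res <- oddsRatio(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]],
                         method = method, conf = 1 - alpha)
        cbind(code = cd, res)
    })
    out <- do.call(rbind, rows)
    out$significant <- !out$undefined &
        !is.na(out$or) & out$or >= orThreshold & out$ciLow > 1
    if (adjust == "BH") {
        out$pAdjusted <- p.adjust(out$pValue, "BH")
        out$significant <- out$significant & !is.na(out$pAdjusted) &
            out$pAdjusted < alpha
    }
    rownames(out) <- NULL
    out
}

#' Write the screen table
#'
#' CSV with columns `code,name,or,ci_low,ci_high,significant`, using the
#' literal `inf` for infinite values.
#'
#' @param screen result of [screenComorbidities()].
#' @param path output CSV path.
#' @param nameLookup optional named character vector code -> disease name.
#' @return `path`, invisibly.
#' @export
writeScreen <- function(screen, path, nameLookup = NULL) {
    fmtInf <- function(x) ifelse(is.infinite(x), "inf",
                                 ifelse(is.na(x), "", format(x, digits = 6)))
    nm <- if (is.null(nameLookup)) "" else unname(nameLookup[screen$code])
    out <- data.frame(code = screen$code, name = ifelse(is.na(nm), "", nm),
                      or = fmtInf(screen$or), ci_low = fmtInf(screen$ciLow),
                      ci_high = fmtInf(screen$ciHigh),
                      significant = screen$significant)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
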